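# Small RNA locus profiling: adapter trimming, structural-RNA filtering,
# exact-match alignment to the single locus copy, RPM and 22-nt-anchored
# normalization, per-position coverage, 50-bp binning, and detection of
# regions that lose 24-nt siRNAs in the mutant.

#' Trim the 3' adapter off raw small RNA reads
#'
#' The insert is the prefix of the read before the leftmost exact match of
#' the adapter's first `k` bases. Reads with no adapter match are rejected
#' (`no_adapter`); inserts outside `[min_len, max_len]` are rejected with
#' reason `too_short` / `too_long`.
#'
#' @param reads Character vector of raw reads.
#' @param adapter Adapter sequence (length >= 6).
#' @param min_len,max_len Retained insert length range (nt).
#' @param k Number of adapter prefix bases matched (default 8).
#' @return data.frame with columns `read`, `insert` (`NA` when no adapter),
#'   `length`, `status` (`kept`, `no_adapter`, `too_short`, `too_long`).
#' @export
trim_adapter <- function(reads, adapter, min_len = 18L, max_len = 30L,
                         k = 8L) {
  if (nchar(adapter) < 6L) stop("adapter must be at least 6 nt")
  k <- min(as.integer(k), nchar(adapter))
  key <- substr(adapter, 1L, k)
  pos <- regexpr(key, reads, fixed = TRUE)
  ins_len <- as.integer(pos) - 1L
  status <- rep("kept", length(reads))
  status[pos < 0L | !nzchar(reads)] <- "no_adapter"
  status[status == "kept" & ins_len < min_len] <- "too_short"
  status[status == "kept" & ins_len > max_len] <- "too_long"
  insert <- rep(NA_character_, length(reads))
  ok <- pos >= 1L
  insert[ok] <- substr(reads[ok], 1L, ins_len[ok])
  data.frame(read = reads, insert = insert,
             length = ifelse(ok, ins_len, NA_integer_),
             status = status, stringsAsFactors = FALSE)
}

#' Collapse inserts into (sequence, count) form
#'
#' @param inserts Character vector of trimmed inserts.
#' @return data.frame with `seq`, `count`, `length`.
#' @export
collapse_reads <- function(inserts) {
  if (length(inserts) == 0L) {
    return(data.frame(seq = character(0), count = integer(0),
                      length = integer(0), stringsAsFactors = FALSE))
  }
  tab <- table(inserts)
  data.frame(seq = names(tab), count = as.integer(tab),
             length = nchar(names(tab)), stringsAsFactors = FALSE)
}

#' Build a structural-RNA substring index
#'
#' A read is structural iff it occurs as an exact substring of any
#' structural reference record or of its reverse complement; the index
#' makes that a hash lookup.
#'
#' @param structural_ref Character vector (or `DNAStringSet`) of
#'   tRNA/rRNA/snRNA/snoRNA reference records.
#' @param min_len,max_len Read length range indexed.
#' @return An environment usable by [filter_structural()].
#' @export
structural_index <- function(structural_ref, min_len = 18L, max_len = 30L) {
  if (length(structural_ref) == 0L) stop("structural reference is empty")
  substring_index(as.character(structural_ref), min_len, max_len,
                  positions = FALSE, both_strands = TRUE)
}

#' Partition collapsed reads into structural and non-structural
#'
#' @param reads data.frame from [collapse_reads()].
#' @param index Environment from [structural_index()], or the structural
#'   reference itself (character/`DNAStringSet`).
#' @return `reads` with a logical `structural` column added.
#' @export
filter_structural <- function(reads, index) {
  if (!is.environment(index)) index <- structural_index(index)
  hit <- index_lookup(index, reads$seq)
  reads$structural <- !vapply(hit, is.null, logical(1L))
  reads
}

#' Build an exact-match index of the locus
#'
#' Maps every substring of the locus (lengths `min_len..max_len`) to its
#' 1-based start positions on the '+' strand; minus-strand hits are found by
#' looking up a read's reverse complement.
#'
#' @param locus A `ReferenceLocus` or a DNA string.
#' @inheritParams structural_index
#' @return An environment usable by [align_perfect()].
#' @export
locus_index <- function(locus, min_len = 18L, max_len = 30L) {
  seq <- if (inherits(locus, "ReferenceLocus")) locus$sequence else locus
  idx <- substring_index(seq, min_len, max_len, positions = TRUE)
  attr(idx, "locus_length") <- nchar(seq)
  idx
}

#' Align reads to the locus by perfect match
#'
#' Reports every zero-mismatch occurrence of each read on the '+' strand
#' and of its reverse complement on the '-' strand (the position is always
#' the leftmost locus coordinate of the matched stretch). Reads with no
#' hits are simply absent from the result.
#'
#' @param reads Character vector of insert sequences (typically unique).
#' @param locus A `ReferenceLocus`, DNA string, or a prebuilt index from
#'   [locus_index()].
#' @return data.frame with columns `seq`, `array_pos`, `strand`, one row
#'   per hit.
#' @export
align_perfect <- function(reads, locus) {
  idx <- if (is.environment(locus)) locus else locus_index(locus)
  empty <- data.frame(seq = character(0), array_pos = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  if (length(reads) == 0L) return(empty)
  plus <- index_lookup(idx, reads)
  minus <- index_lookup(idx, revcomp(reads))
  np <- lengths(plus)
  nm <- lengths(minus)
  out <- data.frame(
    seq = c(rep(reads, np), rep(reads, nm)),
    array_pos = c(unlist(plus, use.names = FALSE),
                  unlist(minus, use.names = FALSE)),
    strand = c(rep("+", sum(np)), rep("-", sum(nm))),
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0L) return(empty)
  out <- out[order(match(out$seq, reads), out$array_pos, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Process one raw small RNA library against the locus
#'
#' Runs adapter trimming, collapsing, structural filtering and exact-match
#' alignment, and assembles the bookkeeping tallies. The normalization
#' denominator (`genome_matched_nonstructural`) is the count of
#' non-structural reads with at least one perfect match to the locus — in
#' the synthetic setting the locus is the genome, so this equals "not in
#' the unmatchable-noise fraction".
#'
#' @param raw_reads Character vector of raw reads.
#' @param adapter Adapter sequence.
#' @param structural_ref Structural reference (or prebuilt index).
#' @param locus A `ReferenceLocus` (or prebuilt [locus_index()]).
#' @param id,genotype,replicate Library metadata.
#' @param min_len,max_len,adapter_k Trimming parameters.
#' @return A `SmallRNALibrary`: list with `id`, `genotype`, `replicate`,
#'   `reads` (collapsed non-structural reads with hit counts), `hits`
#'   (per-hit table with counts and lengths), `matched_by_length`, and
#'   `tallies`.
#' @export
profile_library <- function(raw_reads, adapter, structural_ref, locus,
                            id = "library", genotype = NA_character_,
                            replicate = NA_integer_, min_len = 18L,
                            max_len = 30L, adapter_k = 8L) {
  trimmed <- trim_adapter(raw_reads, adapter, min_len, max_len, adapter_k)
  kept <- collapse_reads(trimmed$insert[trimmed$status == "kept"])
  kept <- filter_structural(kept, structural_ref)
  nonstr <- kept[!kept$structural, , drop = FALSE]

  idx <- if (is.environment(locus)) locus else locus_index(locus, min_len,
                                                           max_len)
  hits <- align_perfect(nonstr$seq, idx)
  n_hits <- integer(nrow(nonstr))
  if (nrow(hits)) {
    ht <- table(hits$seq)
    m <- match(nonstr$seq, names(ht))
    n_hits <- ifelse(is.na(m), 0L, as.integer(ht)[m])
  }
  nonstr$n_hits <- n_hits
  if (nrow(hits)) {
    m <- match(hits$seq, nonstr$seq)
    hits$count <- nonstr$count[m]
    hits$length <- nonstr$length[m]
    hits$n_hits <- nonstr$n_hits[m]
  } else {
    hits$count <- integer(0); hits$length <- integer(0)
    hits$n_hits <- integer(0)
  }

  matched <- nonstr[nonstr$n_hits > 0L, , drop = FALSE]
  matched_by_length <- setNames(integer(length(min_len:max_len)),
                                as.character(min_len:max_len))
  if (nrow(matched)) {
    bylen <- tapply(matched$count, matched$length, sum)
    matched_by_length[names(bylen)] <- as.integer(bylen)
  }

  tallies <- list(
    raw_reads = length(raw_reads),
    rejected_no_adapter = sum(trimmed$status == "no_adapter"),
    rejected_length = sum(trimmed$status %in% c("too_short", "too_long")),
    adapter_trimmed = sum(trimmed$status == "kept"),
    structural = sum(kept$count[kept$structural]),
    nonstructural = sum(nonstr$count),
    locus_matched = sum(matched$count),
    genome_matched_nonstructural = sum(matched$count)
  )
  structure(list(id = id, genotype = genotype, replicate = replicate,
                 reads = nonstr, hits = hits,
                 matched_by_length = matched_by_length, tallies = tallies),
            class = "SmallRNALibrary")
}

#' @export
print.SmallRNALibrary <- function(x, ...) {
  t <- x$tallies
  cat(sprintf(
    "SmallRNALibrary %s (%s): %d raw, %d trimmed, %d structural, %d locus-matched\n",
    x$id, x$genotype, t$raw_reads, t$adapter_trimmed, t$structural,
    t$locus_matched))
  invisible(x)
}

#' Per-library normalization scale factors
#'
#' `rpm` scales each library so the genome-matched non-structural total is
#' one million; `rpm_22anchor` further rescales every library so its 22-nt
#' class equals the reference library's 22-nt abundance (the factor is a
#' single scalar per library, so within-library size-class ratios are
#' untouched). The anchor corrects for the mutant's 24-nt collapse inflating
#' the per-million share of other size classes.
#'
#' @param libraries List of `SmallRNALibrary` objects.
#' @param mode `"rpm"` or `"rpm_22anchor"`.
#' @param reference_library Library id to anchor to, or `"first"`.
#' @param anchor_on `"rpm"` (anchor ratio computed on RPM-normalized 22-nt
#'   abundances, the default) or `"raw"` (on raw 22-nt counts).
#' @return Named numeric vector of scale factors (multiply raw counts by
#'   these).
#' @export
normalize_libraries <- function(libraries, mode = c("rpm", "rpm_22anchor"),
                                reference_library = "first",
                                anchor_on = c("rpm", "raw")) {
  mode <- match.arg(mode)
  anchor_on <- match.arg(anchor_on)
  ids <- vapply(libraries, function(l) l$id, character(1L))
  den <- vapply(libraries, function(l)
    as.numeric(l$tallies$genome_matched_nonstructural), numeric(1L))
  if (any(den == 0)) {
    stop("zero genome-matched non-structural reads in library: ",
         paste(ids[den == 0], collapse = ", "))
  }
  factors <- 1e6 / den
  names(factors) <- ids
  if (mode == "rpm_22anchor") {
    c22 <- vapply(libraries, function(l)
      as.numeric(l$matched_by_length[["22"]]), numeric(1L))
    if (any(c22 == 0)) {
      stop("zero 22-nt class in library: ", paste(ids[c22 == 0],
                                                  collapse = ", "))
    }
    ref <- if (identical(reference_library, "first")) ids[1L]
           else reference_library
    if (!ref %in% ids) stop("unknown reference library: ", ref)
    anchor <- if (anchor_on == "rpm") c22 * factors else c22
    factors <- factors * anchor[ids == ref] / anchor
  }
  factors
}

#' Size-class profile of a library
#'
#' Per-length abundance over genome-matched non-structural reads, in raw
#' counts and in the scaled unit given by `factor`.
#'
#' @param library A `SmallRNALibrary`.
#' @param factor Scale factor for this library (see
#'   [normalize_libraries()]); default 1 reports raw counts.
#' @return data.frame with `length`, `count`, `abundance`.
#' @export
size_distribution <- function(library, factor = 1) {
  lens <- as.integer(names(library$matched_by_length))
  data.frame(length = lens,
             count = as.integer(library$matched_by_length),
             abundance = as.numeric(library$matched_by_length) * factor,
             stringsAsFactors = FALSE)
}

#' Per-position abundance track over the locus
#'
#' Each hit contributes its read's scaled count to every position it spans,
#' separately per strand.
#'
#' @param library A `SmallRNALibrary` (its `hits` are used), or a hits
#'   data.frame with `array_pos`, `strand`, `count`, `length`.
#' @param locus_length Length of the locus in bp.
#' @param size_class Optional read length filter (e.g. 24).
#' @param factor Scale factor.
#' @return List with numeric vectors `sense` and `antisense` of length
#'   `locus_length`.
#' @export
position_coverage <- function(library, locus_length, size_class = NULL,
                              factor = 1) {
  hits <- if (inherits(library, "SmallRNALibrary")) library$hits else library
  if (!is.null(size_class)) {
    hits <- hits[hits$length %in% size_class, , drop = FALSE]
  }
  one_strand <- function(h) {
    cov <- numeric(locus_length)
    if (nrow(h) == 0L) return(cov)
    d <- numeric(locus_length + 1L)
    s <- h$array_pos
    e <- pmin(h$array_pos + h$length - 1L, locus_length)
    w <- h$count * factor
    up <- rowsum(c(w, -w), c(s, e + 1L))
    at <- as.integer(rownames(up))
    keep <- at <= locus_length + 1L
    d[at[keep]] <- up[keep]
    cumsum(d)[seq_len(locus_length)]
  }
  list(sense = one_strand(hits[hits$strand == "+", , drop = FALSE]),
       antisense = one_strand(hits[hits$strand == "-", , drop = FALSE]))
}

#' Export a coverage track as bedGraph
#'
#' @param cov Numeric per-position vector (array coordinates).
#' @param locus A `ReferenceLocus` (for the id).
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(cov, locus, file) {
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based bedGraph starts
  keep <- r$values != 0
  df <- data.frame(chrom = locus$id, start = starts[keep], end = ends[keep],
                   value = r$values[keep])
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}

#' Bin small RNA hits into fixed-width bins across the locus
#'
#' Each hit is counted once in the bin containing its 5' start position
#' (for '-' hits the 5' end is the rightmost matched coordinate). Bins are
#' half-open `[edge, edge + width)` on a grid of TSS-relative values whose
#' edges are congruent to `anchor_offset` modulo `width`. The grid is
#' plain integer arithmetic on the TSS-relative values themselves, so the
#' single bin that straddles the TSS covers `width - 1` actual positions
#' (the nonexistent coordinate 0 falls inside it); all other bins cover
#' `width` positions and the grid tiles the locus without overlap.
#'
#' @param libraries List of `SmallRNALibrary` objects.
#' @param locus A `ReferenceLocus`.
#' @param width Bin width in bp (default 50).
#' @param anchor_offset TSS-relative grid anchor (default 1: edges at
#'   ..., -99, -49, +1, +51, ...; 24 puts edges at ..., -1726, ..., -26,
#'   +24, ..., +5024, ...).
#' @param factors Named scale-factor vector from [normalize_libraries()]
#'   (default: raw counts).
#' @param size_classes Read lengths to tabulate.
#' @return A `BinCountTable`: long data.frame with `library`, `tss_start`,
#'   `tss_end`, `size`, `strand`, `abundance`; grid metadata in attributes.
#' @export
bin_table <- function(libraries, locus, width = 50L, anchor_offset = 1L,
                      factors = NULL, size_classes = 18:30) {
  stopifnot(width >= 1L)
  if (is.null(factors)) {
    factors <- setNames(rep(1, length(libraries)),
                        vapply(libraries, function(l) l$id, character(1L)))
  }
  anchor <- as.integer(anchor_offset)
  rows <- lapply(libraries, function(lib) {
    h <- lib$hits
    h <- h[h$length %in% size_classes, , drop = FALSE]
    if (nrow(h) == 0L) return(NULL)
    start5 <- ifelse(h$strand == "+", h$array_pos,
                     h$array_pos + h$length - 1L)
    t5 <- to_tss_coord(start5, locus$tss_array_pos)
    bin_start <- t5 - ((t5 - anchor) %% width)
    d <- data.frame(bin_start = bin_start, size = h$length,
                    strand = h$strand)
    agg <- aggregate(list(abundance = h$count * factors[[lib$id]]),
                     by = d, FUN = sum)
    cbind(library = lib$id, agg, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(rows)) {
    rows <- data.frame(library = character(0), bin_start = integer(0),
                       size = integer(0), strand = character(0),
                       abundance = numeric(0), stringsAsFactors = FALSE)
  }
  rows$tss_start <- rows$bin_start
  rows$tss_end <- rows$bin_start + width  # printed as start of the next bin
  rows <- rows[order(rows$library, rows$bin_start, rows$size, rows$strand),
               c("library", "tss_start", "tss_end", "size", "strand",
                 "abundance")]
  rownames(rows) <- NULL
  structure(rows, width = width, anchor_offset = anchor_offset,
            locus_id = locus$id,
            class = c("BinCountTable", class(rows)))
}

#' Per-genotype mean bin abundances for one size class
#'
#' Collapses a [bin_table()] to one abundance per bin (strands summed,
#' libraries of the genotype averaged), on the complete bin grid (bins with
#' no reads are 0).
#'
#' @param bins A `BinCountTable`.
#' @param libraries The library list the table was built from (for genotype
#'   membership), or a named character vector id -> genotype.
#' @param genotype Genotype to average.
#' @param size_class Read length (default 24).
#' @return data.frame with `tss_start`, `tss_end`, `abundance`.
#' @export
genotype_bin_means <- function(bins, libraries, genotype, size_class = 24L) {
  width <- attr(bins, "width")
  gmap <- if (is.character(libraries)) libraries else
    setNames(vapply(libraries, function(l) l$genotype, character(1L)),
             vapply(libraries, function(l) l$id, character(1L)))
  ids <- names(gmap)[gmap == genotype]
  if (length(ids) == 0L) stop("no libraries for genotype: ", genotype)
  grid <- sort(unique(bins$tss_start))
  sub <- bins[bins$library %in% ids & bins$size == size_class, , drop = FALSE]
  per_lib <- vapply(ids, function(id) {
    s <- sub[sub$library == id, , drop = FALSE]
    v <- setNames(numeric(length(grid)), grid)
    if (nrow(s)) {
      a <- tapply(s$abundance, s$tss_start, sum)
      v[names(a)] <- a
    }
    v
  }, numeric(length(grid)))
  data.frame(tss_start = grid, tss_end = grid + width,
             abundance = rowMeans(matrix(per_lib, nrow = length(grid))),
             stringsAsFactors = FALSE)
}

#' Call regions that lose siRNAs in the mutant
#'
#' Flags bins whose wild-type abundance clears `min_wt` and whose
#' mutant/wild-type ratio is at most `max_ratio` (mutant 0 always passes),
#' merges maximal runs of adjacent flagged bins into regions, and labels
#' each region with the overlapping (or else nearest) locus feature.
#'
#' @param wt_bins,mut_bins data.frames from [genotype_bin_means()] on the
#'   same grid (replicate means, same normalized unit).
#' @param min_wt Minimum wild-type abundance for a bin to be considered.
#' @param max_ratio Maximum mutant/wild-type ratio to flag.
#' @param locus Optional `ReferenceLocus` for feature labels.
#' @return data.frame of `DifferentialRegion` rows: `feature`, `tss_start`,
#'   `tss_end`, `wt_abundance`, `mut_abundance`, `ratio`.
#' @export
call_lost_regions <- function(wt_bins, mut_bins, min_wt = 5, max_ratio = 0.2,
                              locus = NULL) {
  if (!identical(wt_bins$tss_start, mut_bins$tss_start)) {
    stop("wild-type and mutant bin tables are on different grids")
  }
  width <- wt_bins$tss_end[1L] - wt_bins$tss_start[1L]
  wt <- wt_bins$abundance
  mut <- mut_bins$abundance
  flag <- wt >= min_wt & mut <= max_ratio * wt
  empty <- data.frame(feature = character(0), tss_start = integer(0),
                      tss_end = integer(0), wt_abundance = numeric(0),
                      mut_abundance = numeric(0), ratio = numeric(0),
                      stringsAsFactors = FALSE)
  if (!any(flag)) return(empty)
  starts <- wt_bins$tss_start
  fi <- which(flag)
  run <- cumsum(c(1L, diff(starts[fi]) != width))
  out <- do.call(rbind, lapply(split(fi, run), function(ix) {
    wt_sum <- sum(wt[ix]); mut_sum <- sum(mut[ix])
    data.frame(feature = NA_character_,
               tss_start = wt_bins$tss_start[ix[1L]],
               tss_end = wt_bins$tss_end[ix[length(ix)]],
               wt_abundance = wt_sum, mut_abundance = mut_sum,
               ratio = mut_sum / wt_sum, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(locus) && nrow(locus$features)) {
    f <- locus$features
    out$feature <- vapply(seq_len(nrow(out)), function(i) {
      rs <- out$tss_start[i]; re <- out$tss_end[i] - 1L
      ov <- f$start <= re & f$end >= rs
      if (any(ov)) return(paste(f$name[ov], collapse = ","))
      gap <- pmax(f$start - re, rs - f$end)
      f$name[which.min(gap)]
    }, character(1L))
  }
  out
}

#' End-to-end differential 24-nt siRNA calling between genotypes
#'
#' Convenience wrapper: normalization, binning, per-genotype means, and
#' [call_lost_regions()].
#'
#' @param libraries List of `SmallRNALibrary` objects.
#' @param locus A `ReferenceLocus`.
#' @param wt,mut Genotype labels for wild type and mutant.
#' @param size_class Read length (default 24).
#' @param normalization `"rpm"` or `"rpm_22anchor"`.
#' @param reference_library Passed to [normalize_libraries()].
#' @param width,anchor_offset Passed to [bin_table()].
#' @param min_wt,max_ratio Passed to [call_lost_regions()].
#' @return List with `regions`, `bins`, `factors`.
#' @export
detect_lost_regions <- function(libraries, locus, wt = "Mop1", mut = "mop1",
                                size_class = 24L,
                                normalization = "rpm_22anchor",
                                reference_library = "first", width = 50L,
                                anchor_offset = 1L, min_wt = 5,
                                max_ratio = 0.2) {
  factors <- normalize_libraries(libraries, mode = normalization,
                                 reference_library = reference_library)
  bins <- bin_table(libraries, locus, width = width,
                    anchor_offset = anchor_offset, factors = factors)
  wt_means <- genotype_bin_means(bins, libraries, wt, size_class)
  mut_means <- genotype_bin_means(bins, libraries, mut, size_class)
  regions <- call_lost_regions(wt_means, mut_means, min_wt = min_wt,
                               max_ratio = max_ratio, locus = locus)
  list(regions = regions, bins = bins, factors = factors,
       wt_means = wt_means, mut_means = mut_means)
}
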