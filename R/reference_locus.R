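# Locus representation, TSS-relative coordinates, cytosine context calling.
#
# All internal computation is in 1-based array coordinates along the locus
# sequence; TSS-relative coordinates (which skip 0, so -1 abuts +1 and the
# TSS itself is +1) appear only at I/O boundaries and in reported tables.

FEATURE_CLASSES <- c("exon", "intron_subregion", "enhancer", "transposon",
                     "repeat", "other")
CONTEXTS <- c("CG", "CHG", "CHH")

#' Convert an array coordinate to a TSS-relative coordinate
#'
#' The TSS-relative frame has no position 0: the transcription start site is
#' +1 and the base immediately upstream is -1.
#'
#' @param array_pos Integer vector of 1-based positions along the sequence.
#' @param tss_array_pos 1-based array position of the TSS.
#' @return Integer vector of TSS-relative coordinates (never 0).
#' @export
to_tss_coord <- function(array_pos, tss_array_pos) {
  stopifnot(length(tss_array_pos) == 1L, tss_array_pos >= 1L)
  array_pos <- as.integer(array_pos)
  ifelse(array_pos >= tss_array_pos,
         array_pos - tss_array_pos + 1L,
         array_pos - tss_array_pos)
}

#' Convert a TSS-relative coordinate back to an array coordinate
#'
#' Exact inverse of [to_tss_coord()]. A TSS-relative value of 0 does not
#' exist and is an error.
#'
#' @param tss_pos Integer vector of TSS-relative coordinates (no 0 allowed).
#' @inheritParams to_tss_coord
#' @return Integer vector of 1-based array positions.
#' @export
from_tss_coord <- function(tss_pos, tss_array_pos) {
  stopifnot(length(tss_array_pos) == 1L)
  tss_pos <- as.integer(tss_pos)
  if (any(tss_pos == 0L, na.rm = TRUE)) {
    stop("TSS-relative coordinate 0 does not exist (-1 abuts +1)")
  }
  ifelse(tss_pos > 0L, tss_pos + tss_array_pos - 1L, tss_pos + tss_array_pos)
}

#' Classify cytosine sequence context (CG / CHG / CHH)
#'
#' On the '+' strand the base at `array_pos` must be C and the context is
#' read from the two downstream bases; on the '-' strand the base must be G
#' and the same rules apply to the reverse complement, i.e. the two upstream
#' bases are examined (pos-1 == C gives CG, and so on). H is A, C or T.
#' Any required base that is N or falls outside the sequence yields
#' `"UNKNOWN"`.
#'
#' @param sequence Single DNA string (uppercase, over A/C/G/T/N).
#' @param array_pos Integer vector of 1-based positions to classify.
#' @param strand `"+"` or `"-"`; recycled along `array_pos`.
#' @return Character vector over `CG`, `CHG`, `CHH`, `UNKNOWN`.
#' @export
classify_context <- function(sequence, array_pos, strand) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  array_pos <- as.integer(array_pos)
  if (length(array_pos) == 0L) return(character(0))
  stopifnot(all(array_pos >= 1L & array_pos <= n))
  strand <- rep_len(strand, length(array_pos))
  stopifnot(all(strand %in% c("+", "-")))

  base_at <- function(p) {
    b <- rep("", length(p))
    ok <- p >= 1L & p <= n
    if (any(ok)) b[ok] <- substring(sequence, p[ok], p[ok])
    b
  }

  plus <- strand == "+"
  b0 <- base_at(array_pos)
  expected <- ifelse(plus, "C", "G")
  if (any(b0 != expected)) {
    bad <- which(b0 != expected)[1L]
    stop(sprintf("base at array position %d is '%s', expected '%s' for strand %s",
                 array_pos[bad], b0[bad], expected[bad], strand[bad]))
  }

  off <- ifelse(plus, 1L, -1L)
  b1 <- base_at(array_pos + off)
  b2 <- base_at(array_pos + 2L * off)
  # On '+' the third position of CG/CHG is G and H = {A,C,T}; on '-' the
  # mirrored rules apply to the plus-strand bases: C marks CG/CHG and the
  # complement of H is {A,G,T}.
  g_like <- ifelse(plus, "G", "C")
  h1 <- ifelse(plus, b1 %in% c("A", "C", "T"), b1 %in% c("A", "G", "T"))
  h2 <- ifelse(plus, b2 %in% c("A", "C", "T"), b2 %in% c("A", "G", "T"))

  ctx <- rep("UNKNOWN", length(array_pos))
  ctx[b1 == g_like] <- "CG"
  ctx[b1 != g_like & h1 & b2 == g_like] <- "CHG"
  ctx[b1 != g_like & h1 & h2] <- "CHH"
  ctx
}

# Internal validator shared by the two constructors.
validate_locus <- function(locus) {
  stopifnot(nchar(locus$sequence) >= 1L)
  n <- nchar(locus$sequence)
  if (locus$tss_array_pos < 1L || locus$tss_array_pos > n) {
    stop("tss_array_pos must lie within the sequence")
  }
  f <- locus$features
  if (!is.null(f) && nrow(f) > 0L) {
    if (!all(f$klass %in% FEATURE_CLASSES)) {
      bad <- setdiff(unique(f$klass), FEATURE_CLASSES)
      stop("unknown feature class: ", paste(bad, collapse = ", "))
    }
    out <- f$array_start < 1L | f$array_end > n | f$array_start > f$array_end
    if (any(out)) {
      stop(sprintf("feature '%s' falls outside the %d bp sequence",
                   f$name[which(out)[1L]], n))
    }
  }
  invisible(locus)
}

#' Construct a reference locus from in-memory parts
#'
#' @param sequence Single uppercase DNA string.
#' @param tss_array_pos 1-based array position of the TSS.
#' @param features Optional data.frame with columns `name`, `klass`,
#'   `start`, `end` (inclusive TSS-relative coordinates) and optionally
#'   `strand`.
#' @param id Locus identifier.
#' @return A `ReferenceLocus` object.
#' @export
reference_locus <- function(sequence, tss_array_pos, features = NULL,
                            id = "locus") {
  sequence <- toupper(sequence)
  stopifnot(grepl("^[ACGTN]*$", sequence))
  feats <- data.frame(name = character(0), klass = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), array_start = integer(0),
                      array_end = integer(0), stringsAsFactors = FALSE)
  if (!is.null(features) && nrow(features) > 0L) {
    feats <- data.frame(
      name = as.character(features$name),
      klass = as.character(features$klass),
      start = as.integer(features$start),
      end = as.integer(features$end),
      strand = if ("strand" %in% names(features))
        as.character(features$strand) else rep(".", nrow(features)),
      stringsAsFactors = FALSE
    )
    feats$array_start <- from_tss_coord(feats$start, tss_array_pos)
    feats$array_end <- from_tss_coord(feats$end, tss_array_pos)
  }
  locus <- structure(
    list(id = id, sequence = sequence,
         tss_array_pos = as.integer(tss_array_pos), features = feats),
    class = "ReferenceLocus"
  )
  validate_locus(locus)
}

#' @export
print.ReferenceLocus <- function(x, ...) {
  cat(sprintf("ReferenceLocus '%s': %d bp, TSS at array position %d, %d feature(s)\n",
              x$id, nchar(x$sequence), x$tss_array_pos, nrow(x$features)))
  invisible(x)
}

# Default feature-class inference from BED feature names; callers can
# override any name via `klass_map`.
infer_klass <- function(name) {
  low <- tolower(name)
  klass <- rep("other", length(name))
  klass[grepl("^exon|^e[0-9]$", low)] <- "exon"
  klass[grepl("^int", low)] <- "intron_subregion"
  klass[grepl("enhancer|^de$", low)] <- "enhancer"
  klass[grepl("mule|stowaway|tourist|^hat$|harbinger|mite|helitron", low)] <- "transposon"
  klass[grepl("repeat", low)] <- "repeat"
  klass
}

#' Parse a locus from FASTA sequence and BED feature annotations
#'
#' @param fasta Path to (or text of) a single-record FASTA file.
#' @param bed Optional path to (or text of) a BED file (0-based half-open,
#'   standard BED); intervals are converted to inclusive TSS-relative
#'   feature coordinates.
#' @param tss_array_pos 1-based array position of the TSS.
#' @param klass_map Optional named character vector mapping feature names to
#'   feature classes, overriding name-based inference.
#' @return A `ReferenceLocus` object.
#' @export
parse_locus <- function(fasta, bed = NULL, tss_array_pos, klass_map = NULL) {
  fa <- Biostrings::readDNAStringSet(as_input_file(fasta, "fa"))
  if (length(fa) != 1L) {
    stop(sprintf("locus FASTA must contain exactly one record, found %d",
                 length(fa)))
  }
  sequence <- toupper(as.character(fa[[1L]]))
  id <- sub("\\s.*$", "", names(fa)[1L])
  n <- nchar(sequence)

  features <- NULL
  if (!is.null(bed)) {
    gr <- rtracklayer::import(as_input_file(bed, "bed"), format = "BED")
    nm <- gr$name %||% paste0("feature", seq_along(gr))
    a_start <- GenomicRanges::start(gr)  # rtracklayer converts to 1-based
    a_end <- GenomicRanges::end(gr)
    out <- a_start < 1L | a_end > n
    if (any(out)) {
      stop(sprintf("feature '%s' interval falls outside the %d bp sequence",
                   nm[which(out)[1L]], n))
    }
    klass <- infer_klass(nm)
    if (!is.null(klass_map)) {
      hit <- nm %in% names(klass_map)
      klass[hit] <- unname(klass_map[nm[hit]])
    }
    features <- data.frame(
      name = nm, klass = klass,
      start = to_tss_coord(a_start, tss_array_pos),
      end = to_tss_coord(a_end, tss_array_pos),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE
    )
    features$strand[features$strand == "*"] <- "."
  }
  reference_locus(sequence, tss_array_pos, features, id = id)
}

#' Enumerate cytosine sites in a region of the locus
#'
#' Lists every cytosine (C on '+', G on '-') in the requested TSS-relative
#' region on the requested strands, with its sequence context. Sites whose
#' context window leaves the sequence or touches an N are reported with
#' context `"UNKNOWN"`.
#'
#' @param locus A `ReferenceLocus`.
#' @param region Length-2 TSS-relative interval `c(start, end)` (inclusive),
#'   or `NULL` for the whole locus.
#' @param strands Subset of `c("+", "-")`.
#' @return data.frame with columns `array_pos`, `tss_pos`, `strand`,
#'   `context`, ordered by `array_pos` then strand.
#' @export
enumerate_sites <- function(locus, region = NULL, strands = c("+", "-")) {
  stopifnot(inherits(locus, "ReferenceLocus"), all(strands %in% c("+", "-")))
  n <- nchar(locus$sequence)
  if (is.null(region)) {
    rng <- c(1L, n)
  } else {
    stopifnot(length(region) == 2L)
    rng <- from_tss_coord(as.integer(region), locus$tss_array_pos)
    stopifnot(all(rng >= 1L & rng <= n))
  }
  empty <- data.frame(array_pos = integer(0), tss_pos = integer(0),
                      strand = character(0), context = character(0),
                      stringsAsFactors = FALSE)
  if (rng[1L] > rng[2L]) return(empty)
  bases <- strsplit(substring(locus$sequence, rng[1L], rng[2L]), "")[[1L]]
  pos <- seq.int(rng[1L], rng[2L])
  out <- list()
  if ("+" %in% strands) {
    p <- pos[bases == "C"]
    if (length(p)) {
      out[["+"]] <- data.frame(array_pos = p, strand = "+",
                               stringsAsFactors = FALSE)
    }
  }
  if ("-" %in% strands) {
    p <- pos[bases == "G"]
    if (length(p)) {
      out[["-"]] <- data.frame(array_pos = p, strand = "-",
                               stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  sites <- do.call(rbind, out)
  sites <- sites[order(sites$array_pos, sites$strand), , drop = FALSE]
  sites$tss_pos <- to_tss_coord(sites$array_pos, locus$tss_array_pos)
  sites$context <- classify_context(locus$sequence, sites$array_pos,
                                    sites$strand)
  rownames(sites) <- NULL
  sites[, c("array_pos", "tss_pos", "strand", "context")]
}

#' Export enumerated cytosine sites as TSV
#'
#' @param sites data.frame from [enumerate_sites()].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_sites_tsv <- function(sites, file) {
  write.table(sites, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
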