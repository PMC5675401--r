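# Read-level simulators: bisulfite clone sets, small RNA libraries, and
# qPCR/ChIP Ct tables, all driven by a SyntheticTruth record and a seed.

# Methylation probability for each site, by feature membership of its
# TSS-relative position. The first feature named in truth$region_meth whose
# interval contains the site wins; sites in no named feature fall back to
# the "background" rows. UNKNOWN-context sites (sequence edge) borrow the
# feature's CHH probability; they are excluded from downstream tallies
# anyway.
meth_prob_for_sites <- function(locus, truth, tss_pos, context, genotype) {
  rm <- truth$region_meth
  if (!genotype %in% rm$genotype) stop("unknown genotype: ", genotype)
  rm <- rm[rm$genotype == genotype, , drop = FALSE]
  feat_names <- setdiff(unique(rm$feature), "background")
  feats <- locus$features[locus$features$name %in% feat_names, , drop = FALSE]
  feats <- feats[match(feat_names, feats$name), , drop = FALSE]
  feats <- feats[!is.na(feats$name), , drop = FALSE]

  site_feat <- rep("background", length(tss_pos))
  for (i in rev(seq_len(nrow(feats)))) {
    hit <- tss_pos >= feats$start[i] & tss_pos <= feats$end[i]
    site_feat[hit] <- feats$name[i]
  }
  ctx <- ifelse(context %in% CONTEXTS, context, "CHH")
  key <- paste(site_feat, ctx)
  lookup <- setNames(rm$p, paste(rm$feature, rm$context))
  p <- unname(lookup[key])
  if (anyNA(p)) {
    stop("no methylation probability configured for: ",
         paste(unique(key[is.na(p)]), collapse = ", "))
  }
  p
}

#' Simulate bisulfite clone sets for an amplicon
#'
#' Each clone is the bisulfite readout of one molecule on the read strand:
#' every cytosine site is methylated with its planted per-region per-context
#' probability, unmethylated cytosines convert to T with probability
#' `truth$conversion_rate` (incomplete conversion leaves C), and all
#' non-site bases are copied subject to a per-base substitution error rate.
#' Clones are gap-free and amplicon-length. Deterministic for a given seed.
#'
#' @param locus A `ReferenceLocus`.
#' @param truth A `SyntheticTruth`.
#' @param amplicon Length-2 inclusive TSS-relative interval.
#' @param strand Read strand of the amplicon, `"+"` or `"-"`.
#' @param genotype Genotype key present in `truth$region_meth`.
#' @param n_replicates Number of biological replicates (plants).
#' @param n_clones Clones per replicate.
#' @param seed Integer seed.
#' @return List of `CloneSet` objects, one per replicate.
#' @export
simulate_clones <- function(locus, truth, amplicon, strand = "+", genotype,
                            n_replicates = 2L, n_clones = 10L, seed) {
  stopifnot(inherits(locus, "ReferenceLocus"), length(amplicon) == 2L,
            strand %in% c("+", "-"), n_replicates >= 1L, n_clones >= 1L)
  if (!genotype %in% truth$genotypes) stop("unknown genotype: ", genotype)
  rng <- from_tss_coord(as.integer(amplicon), locus$tss_array_pos)
  n <- nchar(locus$sequence)
  stopifnot(rng[1L] <= rng[2L], rng[1L] >= 1L, rng[2L] <= n)

  sites <- enumerate_sites(locus, region = amplicon, strands = strand)
  # Offset of each site within the read-strand template.
  off <- if (strand == "+") sites$array_pos - rng[1L] + 1L
         else rng[2L] - sites$array_pos + 1L
  template <- substring(locus$sequence, rng[1L], rng[2L])
  if (strand == "-") template <- revcomp(template)
  chars <- strsplit(template, "")[[1L]]
  amp_len <- length(chars)
  p_meth <- meth_prob_for_sites(locus, truth, sites$tss_pos, sites$context,
                                genotype)
  cr <- truth$conversion_rate
  eps <- truth$seq_error_rate
  rho <- truth$block_corr %||% 0
  non_site <- setdiff(seq_len(amp_len), off)

  withr::with_seed(derive_seed(seed, 11L), {
    lapply(seq_len(n_replicates), function(r) {
      clones <- character(n_clones)
      for (k in seq_len(n_clones)) {
        cl <- chars
        if (length(off)) {
          meth <- rbinom(length(off), 1L, p_meth) == 1L
          if (rho > 0 && length(off) > 1L) {
            # Optional along-molecule block correlation: with probability
            # rho a site copies the state of the previous site.
            copy <- runif(length(off) - 1L) < rho
            for (j in which(copy)) meth[j + 1L] <- meth[j]
          }
          converted <- runif(length(off)) < cr
          cl[off] <- ifelse(meth, "C", ifelse(converted, "T", "C"))
        }
        if (eps > 0 && length(non_site)) {
          hit <- non_site[runif(length(non_site)) < eps]
          if (length(hit)) {
            cl[hit] <- vapply(cl[hit], function(b) {
              sample(setdiff(c("A", "C", "G", "T"), b), 1L)
            }, character(1L))
          }
        }
        clones[k] <- paste(cl, collapse = "")
      }
      structure(list(genotype = genotype,
                     replicate_id = paste0(genotype, "_rep", r),
                     amplicon = as.integer(amplicon), strand = strand,
                     clones = clones),
                class = "CloneSet")
    })
  })
}

#' @export
print.CloneSet <- function(x, ...) {
  cat(sprintf("CloneSet %s: %d clones of %d bp, amplicon %d..%d (%s strand)\n",
              x$replicate_id, length(x$clones), nchar(x$clones[1L]),
              x$amplicon[1L], x$amplicon[2L], x$strand))
  invisible(x)
}

#' Simulate small RNA libraries over the locus
#'
#' Reads are drawn from the planted siRNA source loci (start uniform within
#' the source interval, length from the source's size-class mix, strand from
#' its strand mix, abundance proportional to the genotype weight), mixed
#' with a configured fraction of structural-RNA reads (exact substrings of
#' the structural reference) and a fraction of unmatchable noise reads.
#' Each read is emitted as insert + 3' adapter, truncated to the read
#' length. Deterministic for a given seed.
#'
#' @param locus A `ReferenceLocus`.
#' @param truth A `SyntheticTruth`.
#' @param libraries data.frame with columns `id`, `genotype`, `replicate`,
#'   `depth`.
#' @param adapter 3' adapter sequence appended to every insert.
#' @param read_length Raw read length in nt.
#' @param seed Integer seed.
#' @return List of simulated libraries; each has `id`, `genotype`,
#'   `replicate`, `reads` (raw read strings) and `labels` (true category of
#'   each read, kept for validation only — the analysis never uses it).
#' @export
simulate_srna_libraries <- function(locus, truth, libraries,
                                    adapter = "TGGAATTCTCGGGTGCCAAGG",
                                    read_length = 50L, seed) {
  stopifnot(inherits(locus, "ReferenceLocus"), nrow(libraries) >= 1L)
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  if (any(libraries$depth <= 0)) stop("library depth must be > 0")

  sources <- truth$sirna_sources
  src_rng <- lapply(sources, function(s) {
    a <- from_tss_coord(c(s$start, s$end), locus$tss_array_pos)
    max_size <- max(as.integer(names(s$sizes))[s$sizes > 0])
    if (a[2L] - a[1L] + 1L < max_size) {
      stop(sprintf("source '%s' interval is shorter than its largest size class (%d nt)",
                   s$name, max_size))
    }
    a
  })
  pad <- strrep("A", read_length)

  withr::with_seed(derive_seed(seed, 23L), {
    libs <- lapply(seq_len(nrow(libraries)), function(i) {
      gt <- libraries$genotype[i]
      depth <- as.integer(libraries$depth[i])
      w <- vapply(sources, function(s) {
        if (!gt %in% names(s$weights)) stop("unknown genotype: ", gt)
        unname(s$weights[[gt]])
      }, numeric(1L))
      sf <- truth$structural_fraction
      nf <- truth$noise_fraction
      p_src <- if (sum(w) > 0) (1 - sf - nf) * w / sum(w) else rep(0, length(w))
      probs <- c(sf, nf, p_src)
      counts <- as.vector(rmultinom(1L, depth, probs / sum(probs)))

      # Structural reads: substrings of the structural reference records.
      n_struct <- counts[1L]
      struct_reads <- character(0)
      if (n_struct > 0L) {
        recs <- truth$structural_ref
        rec_i <- sample(length(recs), n_struct, replace = TRUE,
                        prob = nchar(recs))
        len <- sample(18:30, n_struct, replace = TRUE)
        rec_len <- nchar(recs)[rec_i]
        start <- 1L + floor(runif(n_struct) * (rec_len - len + 1L))
        struct_reads <- substring(recs[rec_i], start, start + len - 1L)
      }

      # Unmatchable noise: random substrings of a per-library random pool.
      n_noise <- counts[2L]
      noise_reads <- character(0)
      if (n_noise > 0L) {
        pool <- random_dna(max(2000L, 40L * n_noise), 0.5)
        len <- sample(18:30, n_noise, replace = TRUE)
        start <- 1L + floor(runif(n_noise) * (nchar(pool) - len + 1L))
        noise_reads <- substring(pool, start, start + len - 1L)
      }

      src_reads <- character(0)
      src_labels <- character(0)
      for (j in seq_along(sources)) {
        nj <- counts[2L + j]
        if (nj == 0L) next
        s <- sources[[j]]
        a <- src_rng[[j]]
        sz <- as.integer(names(s$sizes))
        len <- sz[sample.int(length(sz), nj, replace = TRUE, prob = s$sizes)]
        start <- 1L + floor(runif(nj) * (a[2L] - a[1L] + 1L - len + 1L))
        start <- a[1L] + start - 1L
        ins <- substring(locus$sequence, start, start + len - 1L)
        minus <- runif(nj) >= s$plus_frac
        if (any(minus)) ins[minus] <- revcomp(ins[minus])
        src_reads <- c(src_reads, ins)
        src_labels <- c(src_labels, rep(s$name, nj))
      }

      inserts <- c(struct_reads, noise_reads, src_reads)
      labels <- c(rep("structural", n_struct), rep("noise", n_noise),
                  src_labels)
      reads <- substr(paste0(inserts, adapter, pad), 1L, read_length)
      list(id = libraries$id[i], genotype = gt,
           replicate = libraries$replicate[i], reads = reads,
           labels = labels)
    })
    names(libs) <- libraries$id
    libs
  })
}

#' Simulate qPCR and ChIP-qPCR Ct tables from planted effects
#'
#' Expression Ct values are generated so that the Livak 2^-ddCt estimate
#' recovers `truth$expression_effect`; ChIP/input/no-antibody Ct values so
#' that the percent-of-input computation (at `truth$input_fraction`)
#' recovers `truth$chip_percent`. Gaussian noise with `ct_sd` cycles is
#' added to every individual Ct measurement.
#'
#' @param truth A `SyntheticTruth`.
#' @param n_bio,n_tech Biological and technical replicates per sample.
#' @param ct_sd Per-measurement Ct noise (cycles).
#' @param seed Integer seed.
#' @return List with data.frames `expression` and `chip`.
#' @export
simulate_ct_tables <- function(truth, n_bio = 3L, n_tech = 3L, ct_sd = 0.2,
                               seed) {
  withr::with_seed(derive_seed(seed, 37L), {
    ctl_mu <- 19
    base_dct <- 8
    expr <- do.call(rbind, lapply(names(truth$expression_effect), function(smp) {
      eff <- truth$expression_effect[[smp]]
      do.call(rbind, lapply(seq_len(n_bio), function(b) {
        rbind(
          data.frame(sample = smp, bio_rep = b, gene = "p1",
                     assay = "expression", tech_rep = seq_len(n_tech),
                     ct = ctl_mu + base_dct - log2(eff) +
                       rnorm(n_tech, 0, ct_sd), stringsAsFactors = FALSE),
          data.frame(sample = smp, bio_rep = b, gene = "actin1",
                     assay = "expression", tech_rep = seq_len(n_tech),
                     ct = ctl_mu + rnorm(n_tech, 0, ct_sd),
                     stringsAsFactors = FALSE)
        )
      }))
    }))

    f <- truth$input_fraction
    input_mu <- 26
    adj <- input_mu - log2(1 / f)
    chip <- do.call(rbind, lapply(names(truth$chip_percent), function(smp) {
      pct <- truth$chip_percent[[smp]]
      do.call(rbind, lapply(seq_len(n_bio), function(b) {
        mk <- function(assay, mu) {
          data.frame(sample = smp, bio_rep = b, target = "DE", assay = assay,
                     tech_rep = seq_len(n_tech),
                     ct = mu + rnorm(n_tech, 0, ct_sd),
                     stringsAsFactors = FALSE)
        }
        rbind(mk("input", input_mu),
              mk("chip", adj - log2(pct / 100)),
              mk("no_antibody", adj - log2(truth$noab_percent / 100)))
      }))
    }))
    list(expression = expr, chip = chip)
  })
}

#' Write reads as FASTQ (Phred+33, constant quality)
#'
#' @param reads Character vector of reads.
#' @param file Output path.
#' @param id_prefix Prefix for read identifiers.
#' @return The path, invisibly.
#' @export
write_fastq <- function(reads, file, id_prefix = "read") {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- paste0(id_prefix, "_", seq_along(reads))
  q <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(x, file, format = "fastq", qualities = q)
  invisible(file)
}

#' Read a FASTQ or FASTA file into a character vector of reads
#'
#' @param file Input path.
#' @param format `"fastq"` or `"fasta"`.
#' @return Character vector of sequences.
#' @export
read_reads <- function(file, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  as.character(Biostrings::readDNAStringSet(file, format = format))
}

#' Write a clone set as FASTA
#'
#' @param clone_set A `CloneSet`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_clone_fasta <- function(clone_set, file) {
  x <- Biostrings::DNAStringSet(clone_set$clones)
  names(x) <- sprintf("%s_clone%02d", clone_set$replicate_id,
                      seq_along(clone_set$clones))
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}
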