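# Independent oracles used to cross-check the implementation. These are
# deliberately written with different primitives (regex window matching,
# naive scans, textbook formulas) than the package code paths they verify.

# Reverse complement without Biostrings.
rc_chr <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1L]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# Brute-force context call by pattern-matching the downstream window; the
# minus strand is handled by mirroring onto the reverse complement.
oracle_context <- function(seq, pos, strand) {
  if (strand == "-") {
    return(oracle_context(rc_chr(seq), nchar(seq) - pos + 1L, "+"))
  }
  two <- substr(seq, pos, pos + 1L)
  three <- substr(seq, pos, pos + 2L)
  if (nchar(two) == 2L && grepl("^CG$", two)) return("CG")
  if (nchar(three) == 3L && grepl("^C[ACT]G$", three)) return("CHG")
  if (nchar(three) == 3L && grepl("^C[ACT][ACT]$", three)) return("CHH")
  "UNKNOWN"
}

# Naive O(n*m) exact-match scan over both strands.
oracle_align <- function(read, locus_seq) {
  m <- nchar(read)
  n <- nchar(locus_seq)
  hits <- list()
  for (strand in c("+", "-")) {
    probe <- if (strand == "+") read else rc_chr(read)
    if (m <= n) {
      for (i in seq_len(n - m + 1L)) {
        if (substr(locus_seq, i, i + m - 1L) == probe) {
          hits[[length(hits) + 1L]] <- data.frame(
            seq = read, array_pos = i, strand = strand,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(seq = character(0), array_pos = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

# Textbook pooled-variance two-sample t statistic and two-sided P.
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), df = na + nb - 2))
}

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# A small two-genotype study configuration: one 700 bp locus, a single
# 500 bp amplicon feature with CG shared between genotypes and contrasts
# planted in CHG and CHH only.
small_meth_config <- function(p_cg = c(0.8, 0.8), p_chg = c(0.7, 0.3),
                              p_chh = c(0.4, 0.1), conversion_rate = 1,
                              seq_error_rate = 0) {
  cfg <- default_locus_config()
  cfg$length <- 700L
  cfg$tss_array_pos <- 101L
  cfg$features <- data.frame(name = "amplicon_region", klass = "other",
                             start = 1L, end = 500L, strand = ".",
                             stringsAsFactors = FALSE)
  cfg$inverted_repeats <- list()
  cfg$sirna_sources <- list(list(name = "s", start = 1L, end = 100L,
                                 weights = c(Mop1 = 1, mop1 = 1),
                                 sizes = c(`24` = 1), plus_frac = 0.5))
  meth_row <- function(f, ctx, p) {
    data.frame(feature = f, context = ctx, genotype = c("Mop1", "mop1"),
               p = p, stringsAsFactors = FALSE)
  }
  cfg$region_meth <- rbind(
    meth_row("amplicon_region", "CG", p_cg),
    meth_row("amplicon_region", "CHG", p_chg),
    meth_row("amplicon_region", "CHH", p_chh),
    meth_row("background", "CG", p_cg),
    meth_row("background", "CHG", p_chg),
    meth_row("background", "CHH", p_chh)
  )
  cfg$conversion_rate <- conversion_rate
  cfg$seq_error_rate <- seq_error_rate
  cfg
}

# Pooled per-context estimates and genotype comparisons for one simulated
# two-genotype clone study; returns replicate table and comparisons.
run_small_meth_study <- function(cfg, seed, n_replicates = 2L,
                                 n_clones = 20L,
                                 amplicon = c(1L, 500L)) {
  built <- build_locus(cfg, seed = seed)
  profiles <- list()
  for (gt in c("Mop1", "mop1")) {
    sets <- simulate_clones(built$locus, built$truth, amplicon,
                            strand = "+", genotype = gt,
                            n_replicates = n_replicates,
                            n_clones = n_clones,
                            seed = seed + match(gt, c("Mop1", "mop1")))
    sites <- enumerate_sites(built$locus, amplicon, "+")
    for (cs in sets) {
      calls <- call_methylation(cs, sites)
      profiles[[length(profiles) + 1L]] <- list(
        genotype = gt, replicate = cs$replicate_id,
        profile = summarize_profile(calls))
    }
  }
  list(built = built, profiles = profiles,
       replicate_table = replicate_context_table(profiles))
}

# Study configuration for siRNA target recovery: five 24-nt-dominated
# source loci (three silenced in the mutant, two unchanged) plus a genic
# 21/22-nt background shared by both genotypes (the anchor class).
srna_recovery_config <- function() {
  cfg <- default_locus_config()
  het_mix <- c(`21` = 0.03, `22` = 0.07, `23` = 0.10, `24` = 0.75,
               `25` = 0.05)
  src <- function(name, start, end, wt, mut, sizes = het_mix) {
    list(name = name, start = start, end = end,
         weights = c(Mop1 = wt, mop1 = mut), sizes = sizes,
         plus_frac = 0.5)
  }
  cfg$sirna_sources <- list(
    src("src_lost_A", -1726L, -1627L, 40, 0),
    src("src_kept_B",  -376L,  -277L, 40, 40),
    src("src_lost_C",  2274L,  2373L, 40, 0),
    src("src_kept_D",  3424L,  3523L, 40, 40),
    src("src_lost_E",  5024L,  5123L, 40, 0),
    src("genic_21_22",  101L,   600L, 150, 150,
        sizes = c(`20` = 0.10, `21` = 0.30, `22` = 0.50, `23` = 0.10))
  )
  cfg
}

# Build a SmallRNALibrary-shaped object directly from tallies (for
# normalization arithmetic tests that need no reads).
fake_library <- function(id, denominator, matched_by_length) {
  lens <- setNames(integer(13L), as.character(18:30))
  lens[names(matched_by_length)] <- as.integer(matched_by_length)
  structure(list(id = id, genotype = NA_character_, replicate = NA_integer_,
                 reads = NULL, hits = NULL, matched_by_length = lens,
                 tallies = list(genome_matched_nonstructural = denominator)),
            class = "SmallRNALibrary")
}
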