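# Synthetic locus generator: a ~10 kb multicopy-style gene model with
# transposon fragments in its regulatory regions, plus the ground-truth
# tables (methylation probabilities, siRNA source loci, expression effects)
# that the downstream analyses are tested against.

#' Default synthetic study configuration
#'
#' Encodes the study conditions the generator emulates: an 11 kb locus with
#' the TSS at array position 5501 (TSS-relative span -5500..+5500), a
#' hypermethylated distal enhancer at -5135..-4637 with no siRNA source, a
#' proximal enhancer carrying a MULE fragment with inverted repeats, intron-2
#' sub-regions Int2-1 (196 bp) and Int2-2 (291 bp) forming a 487 bp bisulfite
#' amplicon, a Stowaway-like MITE just downstream of Int2-2, three exons, and
#' additional transposon fragments (Tourist, Harbinger, hAT). Two genotypes
#' are modelled: `Mop1` (RdDM-proficient wild type) and `mop1`
#' (RdDM-deficient mutant) whose 24-nt siRNA sources collapse. All values are
#' configuration, re-settable by the caller.
#'
#' @return Nested list of generator parameters.
#' @export
default_locus_config <- function() {
  features <- data.frame(
    name = c("distal_enhancer", "Tourist", "proximal_enhancer", "MULE",
             "exon1", "intron1", "exon2", "intron2",
             "Harbinger", "hAT", "Int2-1", "Int2-2", "Stowaway", "exon3"),
    klass = c("enhancer", "transposon", "enhancer", "transposon",
              "exon", "other", "exon", "other",
              "transposon", "transposon", "intron_subregion",
              "intron_subregion", "transposon", "exon"),
    start = c(-5135L, -1726L, -576L, -376L,
              1L, 901L, 1501L, 1901L,
              2274L, 3424L, 4531L, 4727L, 5024L, 5300L),
    end = c(-4637L, -1677L, -1L, -126L,
            900L, 1500L, 1900L, 5299L,
            2323L, 3523L, 4726L, 5017L, 5123L, 5500L),
    strand = ".",
    stringsAsFactors = FALSE
  )

  meth <- function(feature, cg, chg, chh) {
    data.frame(feature = feature,
               context = rep(c("CG", "CHG", "CHH"), each = 2L),
               genotype = rep(c("Mop1", "mop1"), times = 3L),
               p = c(cg, chg, chh), stringsAsFactors = FALSE)
  }
  region_meth <- rbind(
    meth("distal_enhancer",   c(0.94, 0.85), c(0.85, 0.80), c(0.07, 0.04)),
    meth("Int2-1",            c(0.60, 0.58), c(0.35, 0.33), c(0.12, 0.11)),
    meth("Int2-2",            c(0.80, 0.72), c(0.72, 0.41), c(0.46, 0.37)),
    meth("proximal_enhancer", c(0.85, 0.80), c(0.75, 0.62), c(0.35, 0.08)),
    meth("background",        c(0.70, 0.68), c(0.50, 0.48), c(0.05, 0.05))
  )

  het_mix <- c(`21` = 0.03, `22` = 0.07, `23` = 0.10, `24` = 0.75, `25` = 0.05)
  src <- function(name, start, end, wt, mut, sizes = het_mix,
                  plus_frac = 0.5) {
    list(name = name, start = start, end = end,
         weights = c(Mop1 = wt, mop1 = mut), sizes = sizes,
         plus_frac = plus_frac)
  }
  sirna_sources <- list(
    src("Tourist",      -1726L, -1677L, 74, 1),
    src("MULE_small",    -576L,  -527L,  5, 0),
    src("MULE",          -376L,  -127L, 233, 6),
    src("Harbinger",     2274L,  2323L,  7, 0),
    src("hAT",           3424L,  3523L, 23, 0),
    src("Int2-2",        4824L,  4873L,  5, 0),
    src("Stowaway",      5024L,  5123L, 83, 7),
    src("exon3",         5324L,  5373L,  7, 0),
    # Non-RdDM genic small RNA background shared by both genotypes; keeps a
    # stable 21/22-nt class for the 22-nt anchored normalization.
    src("genic_21_22",    101L,   600L, 150, 150,
        sizes = c(`20` = 0.10, `21` = 0.30, `22` = 0.50, `23` = 0.10))
  )

  list(
    id = "P1wr_syn",
    length = 11000L,
    tss_array_pos = 5501L,
    gc = 0.47,
    features = features,
    inverted_repeats = list(list(feature = "MULE", arm = 60L),
                            list(feature = "Stowaway", arm = 25L)),
    genotypes = c("Mop1", "mop1"),
    region_meth = region_meth,
    conversion_rate = 0.99,
    seq_error_rate = 0.001,
    block_corr = 0,
    sirna_sources = sirna_sources,
    structural_fraction = 0.15,
    noise_fraction = 0.02,
    structural_records = c(rRNA_like = 1500L, tRNA_like = 80L,
                           snoRNA_like = 120L),
    adapter = "TGGAATTCTCGGGTGCCAAGG",
    read_length = 50L,
    libraries = data.frame(
      id = c("Mop1_1", "Mop1_2", "Mop1_3", "mop1_1", "mop1_2"),
      genotype = c("Mop1", "Mop1", "Mop1", "mop1", "mop1"),
      replicate = c(1L, 2L, 3L, 1L, 2L),
      depth = 200000L,
      stringsAsFactors = FALSE
    ),
    amplicons = list(
      DE = list(start = -5135L, end = -4637L, strand = "+"),
      F8C = list(start = 4531L, end = 5017L, strand = "+")
    ),
    n_replicates = 2L,
    n_clones = 15L,
    expression_effect = c(Mop1 = 1, mop1 = 3.2),
    chip_percent = c(naive = 10, silenced = 30, silenced_mop1 = 21),
    noab_percent = 0.05,
    input_fraction = 0.01,
    qpcr = list(n_bio = 3L, n_tech = 3L, ct_sd = 0.2)
  )
}

random_dna <- function(n, gc = 0.47) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Overwrite locus sequence in [array_start, array_end] with `piece`.
splice_in <- function(sequence, array_start, piece) {
  paste0(substring(sequence, 1L, array_start - 1L), piece,
         substring(sequence, array_start + nchar(piece), nchar(sequence)))
}

validate_config <- function(config) {
  if (is.null(config$features) || nrow(config$features) == 0L) {
    stop("config must name at least one feature")
  }
  p <- config$region_meth$p
  if (any(p < 0 | p > 1)) stop("methylation probabilities must lie in [0, 1]")
  for (r in c("conversion_rate", "seq_error_rate", "structural_fraction",
              "noise_fraction")) {
    v <- config[[r]]
    if (!is.null(v) && (v < 0 || v > 1)) stop(r, " must lie in [0, 1]")
  }
  ex <- config$features[config$features$klass == "exon", , drop = FALSE]
  if (nrow(ex) > 1L) {
    ex <- ex[order(ex$start), ]
    if (any(ex$start[-1L] <= ex$end[-nrow(ex)])) {
      stop("exon features must not overlap")
    }
  }
  for (s in config$sirna_sources) {
    if (any(s$sizes < 0)) stop("size-class mix must be non-negative")
  }
  invisible(config)
}

#' Generate a synthetic locus and its ground truth
#'
#' Builds a random sequence at the configured GC content, splices inverted
#' repeat arms into the configured transposon fragments, generates a
#' structural-RNA reference, and assembles the `SyntheticTruth` record (the
#' planted methylation probabilities, siRNA sources, expression and ChIP
#' effects) that acceptance tests recover. Deterministic for a given seed.
#'
#' @param config Configuration list, see [default_locus_config()].
#' @param seed Integer seed (required).
#' @return List with elements `locus` (a `ReferenceLocus`) and `truth`
#'   (a `SyntheticTruth` list).
#' @export
build_locus <- function(config = default_locus_config(), seed) {
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  validate_config(config)
  withr::with_seed(derive_seed(seed, 1L), {
    sequence <- random_dna(config$length, config$gc)
    # Inverted-repeat architecture: identical arm at the 5' edge of the
    # element, its reverse complement at the 3' edge (MULE/Stowaway TIRs).
    for (ir in config$inverted_repeats %||% list()) {
      f <- config$features[config$features$name == ir$feature, , drop = FALSE]
      if (nrow(f) == 0L) stop("inverted-repeat feature not found: ", ir$feature)
      a_start <- from_tss_coord(f$start[1L], config$tss_array_pos)
      a_end <- from_tss_coord(f$end[1L], config$tss_array_pos)
      arm_len <- min(ir$arm, (a_end - a_start + 1L) %/% 2L)
      arm <- random_dna(arm_len, config$gc)
      sequence <- splice_in(sequence, a_start, arm)
      sequence <- splice_in(sequence, a_end - arm_len + 1L, revcomp(arm))
    }
    structural_ref <- vapply(config$structural_records,
                             function(n) random_dna(n, 0.52), character(1L))
    locus <- reference_locus(sequence, config$tss_array_pos,
                             config$features, id = config$id)
    n <- nchar(sequence)
    for (s in config$sirna_sources) {
      a <- from_tss_coord(c(s$start, s$end), config$tss_array_pos)
      if (a[1L] < 1L || a[2L] > n) stop("siRNA source outside locus: ", s$name)
    }
    truth <- structure(list(
      region_meth = config$region_meth,
      conversion_rate = config$conversion_rate,
      seq_error_rate = config$seq_error_rate,
      block_corr = config$block_corr %||% 0,
      sirna_sources = config$sirna_sources,
      structural_fraction = config$structural_fraction,
      noise_fraction = config$noise_fraction,
      structural_ref = structural_ref,
      genotypes = config$genotypes,
      expression_effect = config$expression_effect,
      chip_percent = config$chip_percent,
      noab_percent = config$noab_percent,
      input_fraction = config$input_fraction
    ), class = "SyntheticTruth")
    list(locus = locus, truth = truth)
  })
}

#' Tabulate planted siRNA sources as a data.frame
#'
#' @param truth A `SyntheticTruth`.
#' @return data.frame with one row per source (TSS-relative interval and
#'   per-genotype weights).
#' @export
sirna_source_table <- function(truth) {
  do.call(rbind, lapply(truth$sirna_sources, function(s) {
    data.frame(name = s$name, start = s$start, end = s$end,
               t(s$weights), plus_frac = s$plus_frac,
               stringsAsFactors = FALSE)
  }))
}
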