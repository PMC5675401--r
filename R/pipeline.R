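# End-to-end stage runners: simulate -> methylation -> sRNA -> qPCR ->
# combined report. Every run writes its outputs plus a manifest/log that
# records the seed and every parameter, so runs are reproducible from the
# logged config alone.

write_json <- function(x, file) {
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(file)
}

write_tsv <- function(x, file) {
  write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Simulate a complete synthetic study into a directory
#'
#' Emits the locus FASTA, feature BED, ground-truth JSON, bisulfite clone
#' FASTAs per (region, genotype, replicate), small RNA FASTQs plus the
#' structural reference FASTA, qPCR/ChIP Ct TSVs, and a manifest JSON
#' listing every file with its md5 checksum, the seed and the parameters.
#'
#' @param config Study configuration, see [default_locus_config()].
#' @param seed Integer seed (required; there is no default).
#' @param outdir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_simulate <- function(config = default_locus_config(), seed, outdir) {
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  built <- build_locus(config, seed)
  locus <- built$locus
  truth <- built$truth

  files <- character(0)
  add <- function(path) { files[[length(files) + 1L]] <<- path; path }

  fa <- Biostrings::DNAStringSet(locus$sequence)
  names(fa) <- locus$id
  Biostrings::writeXStringSet(fa, add(file.path(outdir, "locus.fasta")))

  gr <- GenomicRanges::GRanges(
    seqnames = locus$id,
    ranges = IRanges::IRanges(locus$features$array_start,
                              locus$features$array_end),
    strand = ifelse(locus$features$strand %in% c("+", "-"),
                    locus$features$strand, "*"),
    name = locus$features$name, score = 0L
  )
  rtracklayer::export(gr, add(file.path(outdir, "features.bed")),
                      format = "BED")

  sf <- Biostrings::DNAStringSet(truth$structural_ref)
  names(sf) <- names(truth$structural_ref)
  Biostrings::writeXStringSet(sf, add(file.path(outdir, "structural.fasta")))

  truth_out <- truth
  class(truth_out) <- NULL
  truth_out$structural_ref <- NULL
  write_json(truth_out, add(file.path(outdir, "truth.json")))

  clone_files <- list()
  for (region in names(config$amplicons)) {
    amp <- config$amplicons[[region]]
    for (gt in config$genotypes) {
      sets <- simulate_clones(locus, truth, c(amp$start, amp$end),
                              strand = amp$strand, genotype = gt,
                              n_replicates = config$n_replicates,
                              n_clones = config$n_clones,
                              seed = derive_seed(seed,
                                                 match(region,
                                                       names(config$amplicons)) * 10L +
                                                 match(gt, config$genotypes)))
      for (cs in sets) {
        path <- file.path(outdir, sprintf("clones_%s_%s.fasta", region,
                                          cs$replicate_id))
        write_clone_fasta(cs, add(path))
        clone_files[[length(clone_files) + 1L]] <- list(
          file = basename(path), region = region, genotype = gt,
          replicate = cs$replicate_id, amplicon = cs$amplicon,
          strand = cs$strand)
      }
    }
  }

  libs <- simulate_srna_libraries(locus, truth, config$libraries,
                                  adapter = config$adapter,
                                  read_length = config$read_length,
                                  seed = seed)
  lib_files <- lapply(libs, function(l) {
    path <- file.path(outdir, sprintf("srna_%s.fastq", l$id))
    write_fastq(l$reads, add(path), id_prefix = l$id)
    list(file = basename(path), id = l$id, genotype = l$genotype,
         replicate = l$replicate)
  })

  ct <- simulate_ct_tables(truth, n_bio = config$qpcr$n_bio,
                           n_tech = config$qpcr$n_tech,
                           ct_sd = config$qpcr$ct_sd, seed = seed)
  write_tsv(ct$expression, add(file.path(outdir, "ct_expression.tsv")))
  write_tsv(ct$chip, add(file.path(outdir, "ct_chip.tsv")))

  files <- unlist(files)
  manifest <- list(
    seed = seed,
    tss_array_pos = locus$tss_array_pos,
    genotypes = config$genotypes,
    adapter = config$adapter,
    read_length = config$read_length,
    amplicons = config$amplicons,
    n_replicates = config$n_replicates,
    n_clones = config$n_clones,
    input_fraction = truth$input_fraction,
    clones = clone_files,
    srna_libraries = unname(lib_files),
    files = lapply(files, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  write_json(manifest, file.path(outdir, "manifest.json"))
  invisible(manifest)
}

read_manifest <- function(sim_dir) {
  path <- file.path(sim_dir, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json in ", sim_dir)
  jsonlite::read_json(path)
}

load_sim_locus <- function(sim_dir, manifest = read_manifest(sim_dir)) {
  parse_locus(file.path(sim_dir, "locus.fasta"),
              file.path(sim_dir, "features.bed"),
              tss_array_pos = manifest$tss_array_pos)
}

#' Run the methylation stage on a simulated (or equivalent) directory
#'
#' Reads clone FASTAs for one amplicon region, calls and summarizes
#' methylation per replicate with the configured sub-region tallies, and
#' writes the per-context summary TSV, the per-site table TSV, and the
#' genotype-comparison JSON.
#'
#' @param sim_dir Directory produced by [run_simulate()].
#' @param region Amplicon region name (e.g. `"F8C"`).
#' @param feature_subsets Optional data.frame (`name`, `start`, `end`);
#'   defaults to the locus's intron_subregion and enhancer features that
#'   overlap the amplicon.
#' @param outdir Output directory (defaults to `sim_dir`).
#' @return List with `profiles`, `summary`, `per_site`, `comparisons`.
#' @export
run_methylation <- function(sim_dir, region, feature_subsets = NULL,
                            outdir = sim_dir) {
  manifest <- read_manifest(sim_dir)
  locus <- load_sim_locus(sim_dir, manifest)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  entries <- Filter(function(e) e$region == region, manifest$clones)
  if (length(entries) == 0L) stop("no clone sets for region: ", region)

  if (is.null(feature_subsets)) {
    amp <- unlist(entries[[1L]]$amplicon)
    f <- locus$features
    keep <- f$klass %in% c("intron_subregion", "enhancer") &
      f$start <= amp[2L] & f$end >= amp[1L]
    feature_subsets <- f[keep, c("name", "start", "end"), drop = FALSE]
  }

  profiles <- lapply(entries, function(e) {
    amp <- as.integer(unlist(e$amplicon))
    clones <- as.character(Biostrings::readDNAStringSet(
      file.path(sim_dir, e$file)))
    cs <- structure(list(genotype = e$genotype, replicate_id = e$replicate,
                         amplicon = amp, strand = e$strand,
                         clones = unname(clones)), class = "CloneSet")
    sites <- enumerate_sites(locus, region = amp, strands = e$strand)
    calls <- call_methylation(cs, sites)
    list(genotype = e$genotype, replicate = e$replicate,
         profile = summarize_profile(calls, feature_subsets))
  })

  summary_tab <- replicate_context_table(profiles)
  site_tab <- per_site_table(profiles)
  genotypes <- unique(summary_tab$genotype)
  comparisons <- list()
  if (length(genotypes) >= 2L) {
    for (ctx in CONTEXTS) {
      comparisons[[ctx]] <- as.list(
        compare_genotypes(profiles, ctx, genotypes = genotypes[1:2]))
    }
    for (feat in unique(feature_subsets$name)) {
      for (ctx in CONTEXTS) {
        comparisons[[paste(feat, ctx, sep = ".")]] <- as.list(
          compare_genotypes(profiles, ctx, feature = feat,
                            genotypes = genotypes[1:2]))
      }
    }
  }
  write_tsv(summary_tab,
            file.path(outdir, sprintf("meth_summary_%s.tsv", region)))
  write_tsv(site_tab,
            file.path(outdir, sprintf("meth_per_site_%s.tsv", region)))
  write_json(comparisons,
             file.path(outdir, sprintf("meth_comparisons_%s.json", region)))
  invisible(list(profiles = profiles, summary = summary_tab,
                 per_site = site_tab, comparisons = comparisons))
}

#' Run the small RNA stage on a simulated (or equivalent) directory
#'
#' Processes every FASTQ through trimming, structural filtering and
#' exact-match alignment, writes the 50-bp bin table, size distributions,
#' per-position 24-nt bedGraph tracks, and the differential (lost-region)
#' table in Table-1 style columns.
#'
#' @param sim_dir Directory produced by [run_simulate()].
#' @param wt,mut Genotype labels.
#' @param normalization,size_class,width,anchor_offset,min_wt,max_ratio,reference_library
#'   Stage parameters, see [detect_lost_regions()].
#' @param outdir Output directory (defaults to `sim_dir`).
#' @return List with `libraries`, `factors`, `bins`, `regions`.
#' @export
run_srna <- function(sim_dir, wt = "Mop1", mut = "mop1",
                     normalization = "rpm_22anchor", size_class = 24L,
                     width = 50L, anchor_offset = 1L, min_wt = 5,
                     max_ratio = 0.2, reference_library = "first",
                     outdir = sim_dir) {
  manifest <- read_manifest(sim_dir)
  locus <- load_sim_locus(sim_dir, manifest)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  structural <- read_reads(file.path(sim_dir, "structural.fasta"), "fasta")
  sidx <- structural_index(structural)
  lidx <- locus_index(locus)

  libraries <- lapply(manifest$srna_libraries, function(e) {
    reads <- read_reads(file.path(sim_dir, e$file), "fastq")
    profile_library(reads, adapter = manifest$adapter,
                    structural_ref = sidx, locus = lidx, id = e$id,
                    genotype = e$genotype, replicate = e$replicate)
  })

  res <- detect_lost_regions(libraries, locus, wt = wt, mut = mut,
                             size_class = size_class,
                             normalization = normalization,
                             reference_library = reference_library,
                             width = width, anchor_offset = anchor_offset,
                             min_wt = min_wt, max_ratio = max_ratio)

  write_tsv(as.data.frame(res$bins), file.path(outdir, "srna_bins.tsv"))
  sizes <- do.call(rbind, lapply(libraries, function(l) {
    cbind(library = l$id,
          size_distribution(l, res$factors[[l$id]]),
          stringsAsFactors = FALSE)
  }))
  write_tsv(sizes, file.path(outdir, "srna_size_distributions.tsv"))
  regions_out <- res$regions
  names(regions_out) <- c("Feature", "Start", "End", "WT_abundance",
                          "mut_abundance", "ratio")
  write_tsv(regions_out, file.path(outdir, "srna_lost_regions.tsv"))
  for (l in libraries) {
    cov <- position_coverage(l, nchar(locus$sequence),
                             size_class = size_class,
                             factor = res$factors[[l$id]])
    write_bedgraph(cov$sense, locus,
                   file.path(outdir, sprintf("cov24_%s_sense.bedgraph",
                                             l$id)))
    write_bedgraph(cov$antisense, locus,
                   file.path(outdir, sprintf("cov24_%s_antisense.bedgraph",
                                             l$id)))
  }
  invisible(list(libraries = libraries, factors = res$factors,
                 bins = res$bins, regions = res$regions))
}

check_ct_schema <- function(tab, required, file) {
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("%s lacks column(s): %s", file,
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- which(!is.finite(tab$ct) | tab$ct <= 0)
  if (length(bad)) {
    stop(sprintf("%s: invalid Ct at row %d", file, bad[1L]))
  }
  invisible(tab)
}

#' Run the qPCR/ChIP stage on a simulated (or equivalent) directory
#'
#' Validates the Ct TSVs, computes 2^-ddCt relative expression (calibrator:
#' the first genotype) and percent-of-input ChIP enrichment, and writes
#' result TSVs.
#'
#' @param sim_dir Directory produced by [run_simulate()].
#' @param calibrator Calibrator sample (default: first genotype in the
#'   manifest).
#' @param control_gene Endogenous control gene name.
#' @param input_fraction ChIP input fraction (default from the manifest).
#' @param background_subtract Passed to [chip_analysis()].
#' @param reference_sample ChIP fold-enrichment reference (default: first
#'   sample in the table).
#' @param outdir Output directory (defaults to `sim_dir`).
#' @return List with `expression` and `chip` data.frames.
#' @export
run_qpcr <- function(sim_dir, calibrator = NULL, control_gene = "actin1",
                     input_fraction = NULL, background_subtract = FALSE,
                     reference_sample = NULL, outdir = sim_dir) {
  manifest <- read_manifest(sim_dir)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  expr_file <- file.path(sim_dir, "ct_expression.tsv")
  chip_file <- file.path(sim_dir, "ct_chip.tsv")
  expr_ct <- check_ct_schema(read.delim(expr_file),
                             c("sample", "bio_rep", "gene", "ct"), expr_file)
  chip_ct <- check_ct_schema(read.delim(chip_file),
                             c("sample", "bio_rep", "assay", "ct"), chip_file)
  calibrator <- calibrator %||% manifest$genotypes[[1L]]
  input_fraction <- input_fraction %||% manifest$input_fraction
  expr <- relative_expression(expr_ct, target = "p1",
                              control = control_gene,
                              calibrator = calibrator)
  reference_sample <- reference_sample %||% unique(chip_ct$sample)[1L]
  chip <- chip_analysis(chip_ct, input_fraction = input_fraction,
                        background_subtract = background_subtract,
                        reference_sample = reference_sample)
  write_tsv(expr, file.path(outdir, "qpcr_expression.tsv"))
  write_tsv(chip, file.path(outdir, "chip_percent_of_input.tsv"))
  invisible(list(expression = expr, chip = chip))
}

#' Combined report joining methylation, sRNA and expression results
#'
#' Joins the per-feature methylation comparisons, the differential siRNA
#' regions (by overlapping feature name) and the expression table into one
#' TSV keyed by feature.
#'
#' @param meth Result of [run_methylation()].
#' @param srna Result of [run_srna()].
#' @param qpcr Result of [run_qpcr()].
#' @param file Output TSV path.
#' @return The combined data.frame, invisibly.
#' @export
run_report <- function(meth, srna, qpcr, file) {
  feats <- unique(unlist(lapply(strsplit(srna$regions$feature, ","), identity)))
  feats <- union(feats, unique(stats::na.omit(
    vapply(meth$comparisons, function(c) c$feature %||% NA_character_,
           character(1L)))))
  rows <- lapply(feats[!is.na(feats)], function(f) {
    reg <- srna$regions[grepl(f, srna$regions$feature, fixed = TRUE), ,
                        drop = FALSE]
    chg <- meth$comparisons[[paste(f, "CHG", sep = ".")]]
    chh <- meth$comparisons[[paste(f, "CHH", sep = ".")]]
    data.frame(
      feature = f,
      srna_wt = if (nrow(reg)) sum(reg$wt_abundance) else NA_real_,
      srna_mut = if (nrow(reg)) sum(reg$mut_abundance) else NA_real_,
      chg_wt = chg$mean_a %||% NA_real_, chg_mut = chg$mean_b %||% NA_real_,
      chg_p = chg$p_value %||% NA_real_,
      chh_wt = chh$mean_a %||% NA_real_, chh_mut = chh$mean_b %||% NA_real_,
      chh_p = chh$p_value %||% NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  expr <- qpcr$expression
  for (i in seq_len(nrow(expr))) {
    out[[paste0("expr_", expr$sample[i])]] <- expr$relative_expression[i]
  }
  write_tsv(out, file)
  invisible(out)
}
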