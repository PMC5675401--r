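# Livak 2^-ddCt relative expression and percent-of-input ChIP-qPCR
# quantification. Technical replicates are always averaged on the Ct scale
# before any delta is computed; SE is computed on the linear (2^-ddCt or
# percent) scale over biological replicates.

tech_average <- function(ct_table, by) {
  stopifnot(all(c(by, "ct") %in% names(ct_table)))
  if (!all(is.finite(ct_table$ct)) || any(ct_table$ct <= 0)) {
    stop("Ct values must be finite and > 0")
  }
  aggregate(list(ct = ct_table$ct), by = ct_table[, by, drop = FALSE],
            FUN = mean)
}

#' Relative expression by the Livak 2^-ddCt method
#'
#' Per biological replicate, dCt = Ct(target) - Ct(control); ddCt is taken
#' against the calibrator sample's mean dCt, so the calibrator's own
#' relative expression is 1 by construction.
#'
#' @param ct_table data.frame with columns `sample`, `bio_rep`, `gene`,
#'   `ct` (and optionally `assay`, filtered to `"expression"`, and
#'   `tech_rep`).
#' @param target Target gene name.
#' @param control Endogenous control gene name.
#' @param calibrator Calibrator sample id.
#' @return data.frame, one row per sample: `delta_ct`, `delta_delta_ct`,
#'   `relative_expression` (point estimate, 2^-ddCt of the mean dCt),
#'   `rel_mean`, `rel_se`, `n_bio`.
#' @export
relative_expression <- function(ct_table, target = "p1",
                                control = "actin1", calibrator) {
  if ("assay" %in% names(ct_table)) {
    ct_table <- ct_table[ct_table$assay == "expression", , drop = FALSE]
  }
  avg <- tech_average(ct_table, c("sample", "bio_rep", "gene"))
  samples <- unique(avg$sample)
  if (!calibrator %in% samples) stop("calibrator sample not found: ",
                                     calibrator)
  dct <- do.call(rbind, lapply(samples, function(smp) {
    s <- avg[avg$sample == smp, , drop = FALSE]
    do.call(rbind, lapply(unique(s$bio_rep), function(b) {
      r <- s[s$bio_rep == b, , drop = FALSE]
      ct_t <- r$ct[r$gene == target]
      ct_c <- r$ct[r$gene == control]
      if (length(ct_c) != 1L) {
        stop(sprintf("missing control gene Ct for sample '%s' replicate %s",
                     smp, b))
      }
      if (length(ct_t) != 1L) {
        stop(sprintf("missing target gene Ct for sample '%s' replicate %s",
                     smp, b))
      }
      data.frame(sample = smp, bio_rep = b, delta_ct = ct_t - ct_c,
                 stringsAsFactors = FALSE)
    }))
  }))
  cal_dct <- mean(dct$delta_ct[dct$sample == calibrator])
  out <- do.call(rbind, lapply(samples, function(smp) {
    d <- dct$delta_ct[dct$sample == smp]
    rel_reps <- 2^(-(d - cal_dct))
    ddct <- mean(d) - cal_dct
    data.frame(sample = smp, calibrator = calibrator,
               delta_ct = mean(d), delta_delta_ct = ddct,
               relative_expression = 2^(-ddct),
               rel_mean = mean(rel_reps),
               rel_se = if (length(d) > 1L) sd(rel_reps) / sqrt(length(d))
                        else NA_real_,
               n_bio = length(d), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' ChIP signal as percent of input
#'
#' The input Ct is first adjusted for the input dilution (an input that is a
#' fraction `f` of the ChIP chromatin is `log2(1/f)` cycles "late"); the
#' signal is then `100 * 2^(adjusted_input_ct - chip_ct)`, so an undiluted
#' input equals 100%.
#'
#' @param ct_chip,ct_input Numeric Ct vectors (recycled together).
#' @param input_fraction Fraction of chromatin used as input, in (0, 1].
#' @return Numeric percent-of-input values.
#' @export
percent_of_input <- function(ct_chip, ct_input, input_fraction = 0.01) {
  if (input_fraction <= 0 || input_fraction > 1) {
    stop("input_fraction must be in (0, 1]")
  }
  adjusted <- ct_input - log2(1 / input_fraction)
  100 * 2^(adjusted - ct_chip)
}

#' Fold enrichment between two percent-of-input values
#'
#' Optionally subtracts the no-antibody background from both percents first
#' (floored at 0).
#'
#' @param percent_a,percent_b Percent-of-input values (numerator /
#'   denominator).
#' @param noab_a,noab_b Optional no-antibody percents for background
#'   subtraction.
#' @return `percent_a / percent_b` after any background subtraction.
#' @export
fold_enrichment <- function(percent_a, percent_b, noab_a = NULL,
                            noab_b = NULL) {
  if (!is.null(noab_a)) percent_a <- pmax(percent_a - noab_a, 0)
  if (!is.null(noab_b)) percent_b <- pmax(percent_b - noab_b, 0)
  if (any(percent_b == 0)) stop("denominator percent is 0")
  percent_a / percent_b
}

#' Analyze a ChIP-qPCR Ct table
#'
#' Technical replicates are averaged on the Ct scale per (sample,
#' biological replicate, assay); percent of input is computed per
#' biological replicate and summarized as mean +/- SE per sample, with
#' optional no-antibody background subtraction and fold enrichment against
#' a reference sample.
#'
#' @param ct_table data.frame with columns `sample`, `bio_rep`, `assay`
#'   (`chip`, `input`, and optionally `no_antibody`), `ct`.
#' @param input_fraction Input dilution fraction, see [percent_of_input()].
#' @param background_subtract Subtract the no-antibody percent before
#'   summarizing?
#' @param reference_sample Optional sample id; adds `fold_vs_reference`.
#' @return data.frame, one row per sample: `percent_mean`, `percent_se`,
#'   `noab_mean`, `n_bio`, and optionally `fold_vs_reference`.
#' @export
chip_analysis <- function(ct_table, input_fraction = 0.01,
                          background_subtract = FALSE,
                          reference_sample = NULL) {
  avg <- tech_average(ct_table, c("sample", "bio_rep", "assay"))
  out <- do.call(rbind, lapply(unique(avg$sample), function(smp) {
    s <- avg[avg$sample == smp, , drop = FALSE]
    reps <- unique(s$bio_rep)
    pct <- vapply(reps, function(b) {
      r <- s[s$bio_rep == b, , drop = FALSE]
      chip <- r$ct[r$assay == "chip"]
      input <- r$ct[r$assay == "input"]
      if (length(chip) != 1L || length(input) != 1L) {
        stop(sprintf("sample '%s' replicate %s lacks chip or input Ct",
                     smp, b))
      }
      percent_of_input(chip, input, input_fraction)
    }, numeric(1L))
    noab <- vapply(reps, function(b) {
      r <- s[s$bio_rep == b, , drop = FALSE]
      na_ct <- r$ct[r$assay == "no_antibody"]
      if (length(na_ct) != 1L) return(NA_real_)
      percent_of_input(na_ct, r$ct[r$assay == "input"], input_fraction)
    }, numeric(1L))
    if (background_subtract) {
      if (anyNA(noab)) stop("background subtraction requires no_antibody Cts")
      pct <- pmax(pct - noab, 0)
    }
    data.frame(sample = smp, percent_mean = mean(pct),
               percent_se = if (length(pct) > 1L)
                 sd(pct) / sqrt(length(pct)) else NA_real_,
               noab_mean = mean(noab), n_bio = length(pct),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(reference_sample)) {
    if (!reference_sample %in% out$sample) {
      stop("reference sample not found: ", reference_sample)
    }
    ref <- out$percent_mean[out$sample == reference_sample]
    out$fold_vs_reference <- fold_enrichment(out$percent_mean, ref)
  }
  out
}
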