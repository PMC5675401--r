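# Livak relative expression and percent-of-input ChIP quantification.

make_ct <- function(rows) {
  do.call(rbind, lapply(rows, function(r) {
    data.frame(sample = r[[1]], bio_rep = r[[2]], gene = r[[3]],
               ct = r[[4]], stringsAsFactors = FALSE)
  }))
}

test_that("2^-ddCt identities hold exactly", {
  ct <- make_ct(list(
    list("cal", 1L, "p1", 25), list("cal", 1L, "actin1", 20),
    list("s", 1L, "p1", 25), list("s", 1L, "actin1", 20)))
  res <- relative_expression(ct, calibrator = "cal")
  expect_equal(res$relative_expression[res$sample == "s"], 1.0)
  expect_equal(res$relative_expression[res$sample == "cal"], 1.0)

  # One cycle less of dCt doubles expression.
  ct2 <- make_ct(list(
    list("cal", 1L, "p1", 26), list("cal", 1L, "actin1", 20),
    list("s", 1L, "p1", 25), list("s", 1L, "actin1", 20)))
  res2 <- relative_expression(ct2, calibrator = "cal")
  expect_equal(res2$relative_expression[res2$sample == "s"], 2.0)

  expect_error(relative_expression(make_ct(list(
    list("cal", 1L, "p1", 25), list("cal", 1L, "actin1", 20),
    list("s", 1L, "p1", 25))), calibrator = "cal"), "control")
})

test_that("2^-ddCt equals a direct spreadsheet recomputation", {
  withr::with_seed(41, {
    samples <- c("cal", "s1", "s2")
    rows <- list()
    for (smp in samples) for (b in 1:3) for (g in c("p1", "actin1")) {
      for (tr in 1:2) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = smp, bio_rep = b, gene = g, tech_rep = tr,
          ct = runif(1, 18, 30), stringsAsFactors = FALSE)
      }
    }
    ct <- do.call(rbind, rows)
  })
  res <- relative_expression(ct, calibrator = "cal")
  # Direct recomputation with plain arithmetic.
  dct <- sapply(samples <- c("cal", "s1", "s2"), function(smp) {
    mean(sapply(1:3, function(b) {
      sub <- ct[ct$sample == smp & ct$bio_rep == b, ]
      mean(sub$ct[sub$gene == "p1"]) - mean(sub$ct[sub$gene == "actin1"])
    }))
  })
  want <- 2^(-(dct - dct["cal"]))
  expect_equal(res$relative_expression[match(samples, res$sample)],
               unname(want), tolerance = 1e-12)
})

test_that("2^-ddCt is invariant to a constant shift of a sample's Cts", {
  ct <- make_ct(list(
    list("cal", 1L, "p1", 27.3), list("cal", 1L, "actin1", 21.1),
    list("s", 1L, "p1", 24.8), list("s", 1L, "actin1", 19.9)))
  base <- relative_expression(ct, calibrator = "cal")
  shifted <- ct
  shifted$ct[shifted$sample == "s"] <- shifted$ct[shifted$sample == "s"] + 3.7
  res <- relative_expression(shifted, calibrator = "cal")
  expect_equal(res$relative_expression, base$relative_expression,
               tolerance = 1e-12)
})

test_that("percent of input follows the dilution-adjusted dCt formula", {
  expect_equal(percent_of_input(25, 25, input_fraction = 1), 100)
  expect_equal(percent_of_input(26, 25, input_fraction = 1), 50)
  # f = 0.01, input Ct 30, chip Ct 25.356.
  expect_equal(percent_of_input(25.356, 30, input_fraction = 0.01),
               100 * 2^((30 - log2(100)) - 25.356))
  expect_equal(percent_of_input(25.356, 30, input_fraction = 0.01), 25.002,
               tolerance = 1e-3)
  expect_error(percent_of_input(25, 25, input_fraction = 0), "input_fraction")
  expect_error(percent_of_input(25, 25, input_fraction = 1.5),
               "input_fraction")

  # Re-expressing the dilution leaves the percent unchanged: a twice-more
  # dilute input measures one cycle later, so (f, ct) ~ (f/2, ct + 1).
  expect_equal(percent_of_input(25, 30, 0.02),
               percent_of_input(25, 31, 0.01), tolerance = 1e-12)
})

test_that("fold enrichment divides percents with optional background", {
  expect_equal(fold_enrichment(30, 10), 3.0)
  expect_equal(fold_enrichment(12, 12), 1.0)
  expect_equal(fold_enrichment(30, 10, noab_a = 5, noab_b = 5), 5)
  expect_error(fold_enrichment(10, 10, noab_a = 10, noab_b = 10), "0")
})

test_that("noisy synthetic Ct tables recover the planted effects", {
  truth <- build_locus(seed = 7)$truth
  ct <- simulate_ct_tables(truth, n_bio = 3L, n_tech = 3L, ct_sd = 0.2,
                           seed = 19)
  res <- relative_expression(ct$expression, calibrator = "Mop1")
  est <- res$relative_expression[res$sample == "mop1"]
  expect_lt(abs(est - truth$expression_effect[["mop1"]]) /
              truth$expression_effect[["mop1"]], 0.15)

  chip <- chip_analysis(ct$chip, input_fraction = truth$input_fraction,
                        reference_sample = "naive")
  fold <- chip$fold_vs_reference[chip$sample == "silenced"]
  expect_lt(abs(fold - 3) / 3, 0.2)
})
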