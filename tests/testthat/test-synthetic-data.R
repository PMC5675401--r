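# Synthetic locus, clone and library generators: determinism, validation,
# and the forced-limit behaviours that downstream estimators rely on.

test_that("locus generation is deterministic and validates its config", {
  a <- build_locus(seed = 7)
  b <- build_locus(seed = 7)
  expect_identical(a$locus$sequence, b$locus$sequence)
  expect_identical(a$locus$features, b$locus$features)
  expect_identical(a$truth$structural_ref, b$truth$structural_ref)
  expect_identical(a$truth$region_meth, b$truth$region_meth)
  c <- build_locus(seed = 8)
  expect_false(identical(a$locus$sequence, c$locus$sequence))

  cfg <- default_locus_config()
  cfg$features <- cfg$features[0, ]
  expect_error(build_locus(cfg, seed = 1), "at least one feature")

  cfg2 <- default_locus_config()
  cfg2$region_meth$p[1] <- 1.2
  expect_error(build_locus(cfg2, seed = 1), "\\[0, 1\\]")

  cfg3 <- default_locus_config()
  cfg3$features$start[cfg3$features$name == "exon2"] <- 850L
  expect_error(build_locus(cfg3, seed = 1), "exon")
})

test_that("generated sequence hits the configured GC content", {
  loc <- build_locus(seed = 11)$locus
  bases <- strsplit(loc$sequence, "")[[1L]]
  gc <- mean(bases %in% c("G", "C"))
  expect_lt(abs(gc - 0.47), 0.05)
})

test_that("inverted-repeat arms are planted in the MULE element", {
  loc <- build_locus(seed = 7)$locus
  f <- loc$features
  mule <- f[f$name == "MULE", ]
  arm5 <- substring(loc$sequence, mule$array_start, mule$array_start + 59L)
  arm3 <- substring(loc$sequence, mule$array_end - 59L, mule$array_end)
  expect_identical(rc_chr(arm5), arm3)
})

test_that("clone simulation obeys the bisulfite forced limits", {
  cfg <- small_meth_config(p_cg = c(0, 0), p_chg = c(0, 0), p_chh = c(0, 0),
                           conversion_rate = 1)
  built <- build_locus(cfg, seed = 3)
  sites <- enumerate_sites(built$locus, c(1L, 500L), "+")
  cs <- simulate_clones(built$locus, built$truth, c(1L, 500L), "+", "Mop1",
                        n_replicates = 1L, n_clones = 3L, seed = 5)[[1L]]
  calls <- call_methylation(cs, sites)
  expect_true(all(calls$state == "unmethylated"))

  cfg2 <- small_meth_config(p_cg = c(1, 1), p_chg = c(1, 1), p_chh = c(1, 1),
                            conversion_rate = 0.5)
  built2 <- build_locus(cfg2, seed = 3)
  cs2 <- simulate_clones(built2$locus, built2$truth, c(1L, 500L), "+",
                         "Mop1", n_replicates = 1L, n_clones = 3L,
                         seed = 5)[[1L]]
  calls2 <- call_methylation(cs2, enumerate_sites(built2$locus, c(1L, 500L),
                                                  "+"))
  expect_true(all(calls2$state == "methylated"))

  expect_error(simulate_clones(built$locus, built$truth, c(1L, 500L), "+",
                               "nosuch", seed = 1), "unknown genotype")
  # Determinism
  d1 <- simulate_clones(built$locus, built$truth, c(1L, 500L), "+", "Mop1",
                        1L, 2L, seed = 9)[[1L]]$clones
  d2 <- simulate_clones(built$locus, built$truth, c(1L, 500L), "+", "Mop1",
                        1L, 2L, seed = 9)[[1L]]$clones
  expect_identical(d1, d2)
})

test_that("pooled clone estimates recover the planted CHG probability", {
  cfg <- small_meth_config(p_chg = c(0.7, 0.7))
  study <- run_small_meth_study(cfg, seed = 21)
  tab <- study$replicate_table
  chg <- tab[tab$context == "CHG" & tab$genotype == "Mop1", ]
  pooled <- sum(chg$percent / 100 * chg$calls) / sum(chg$calls)
  n <- sum(chg$calls)
  expect_lt(abs(pooled - 0.7), 3 * sqrt(0.7 * 0.3 / n))
})

test_that("simulated sRNA libraries honour their construction contracts", {
  b <- build_locus(seed = 7)
  libs_cfg <- data.frame(id = c("wt1", "mu1"),
                         genotype = c("Mop1", "mop1"), replicate = 1L,
                         depth = 20000L, stringsAsFactors = FALSE)
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  sim <- simulate_srna_libraries(b$locus, b$truth, libs_cfg,
                                 adapter = adapter, seed = 13)
  sim2 <- simulate_srna_libraries(b$locus, b$truth, libs_cfg,
                                  adapter = adapter, seed = 13)
  expect_identical(sim$wt1$reads, sim2$wt1$reads)

  # Every non-structural, non-noise read perfect-matches the locus after
  # adapter removal.
  wt <- sim$wt1
  src <- !(wt$labels %in% c("structural", "noise"))
  trimmed <- trim_adapter(wt$reads[src], adapter)
  expect_true(all(trimmed$status == "kept"))
  hits <- align_perfect(unique(trimmed$insert), b$locus)
  expect_true(all(unique(trimmed$insert) %in% hits$seq))

  # Sources with mutant weight 0 contribute no mutant reads.
  zero_wt <- vapply(b$truth$sirna_sources,
                    function(s) s$weights[["mop1"]] == 0, logical(1L))
  zeroed <- vapply(b$truth$sirna_sources, function(s) s$name,
                   character(1L))[zero_wt]
  expect_gt(length(zeroed), 0L)
  expect_false(any(sim$mu1$labels %in% zeroed))

  expect_error(simulate_srna_libraries(
    b$locus, b$truth,
    data.frame(id = "x", genotype = "Mop1", replicate = 1L, depth = 0L),
    seed = 1), "depth")

  short_truth <- b$truth
  short_truth$sirna_sources <- list(list(
    name = "tiny", start = 1L, end = 10L, weights = c(Mop1 = 1, mop1 = 1),
    sizes = c(`24` = 1), plus_frac = 0.5))
  expect_error(simulate_srna_libraries(b$locus, short_truth, libs_cfg,
                                       seed = 1), "shorter")
})
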