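# Methylation calling, per-context aggregation, and genotype comparisons.

mini_clone_set <- function(clones, amplicon = c(1L, 4L), strand = "+",
                           genotype = "gt", replicate_id = "gt_rep1") {
  structure(list(genotype = genotype, replicate_id = replicate_id,
                 amplicon = amplicon, strand = strand, clones = clones),
            class = "CloneSet")
}

test_that("C reads as methylated, T as unmethylated, others ambiguous", {
  loc <- reference_locus("ACGT", 1L)
  sites <- enumerate_sites(loc, c(1L, 4L), "+")  # single C at position 2
  states <- vapply(c("ACGT", "ATGT", "AGGT"), function(cl) {
    call_methylation(mini_clone_set(cl), sites)$state
  }, character(1L), USE.NAMES = FALSE)
  expect_identical(states, c("methylated", "unmethylated", "ambiguous"))
  expect_error(call_methylation(mini_clone_set("ACG"), sites),
               "clone length")
  expect_error(
    call_methylation(mini_clone_set("ACGT"),
                     enumerate_sites(loc, c(1L, 4L), "-")),
    "strand")
})

test_that("every (site, clone) pair yields exactly one call", {
  loc <- reference_locus("CACGTACCGGAC", 1L)
  sites <- enumerate_sites(loc, c(1L, 12L), "+")
  expect_equal(nrow(sites), 5L)
  withr::with_seed(5, {
    clones <- vapply(1:10, function(i) rand_seq(12), character(1L))
  })
  calls <- call_methylation(mini_clone_set(clones, c(1L, 12L)), sites)
  expect_equal(nrow(calls), 50L)
  expect_equal(sum(calls$state %in%
                     c("methylated", "unmethylated", "ambiguous")), 50L)
})

test_that("per-context percents pool clones and exclude ambiguous calls", {
  # 40 CHG calls, 28 methylated -> 70.0%
  calls <- data.frame(
    array_pos = rep(1:4, times = 10), tss_pos = rep(1:4, times = 10),
    strand = "+", context = "CHG",
    clone_index = rep(1:10, each = 4),
    state = rep(c("methylated", "unmethylated"),
                times = c(28, 12)), stringsAsFactors = FALSE)
  prof <- summarize_profile(calls)
  chg <- prof$per_context[prof$per_context$context == "CHG", ]
  expect_equal(chg$percent, 70)
  expect_equal(chg$total_informative_calls, 40L)

  # All ambiguous -> percent is missing, not 0.
  calls$state <- "ambiguous"
  prof2 <- summarize_profile(calls)
  expect_true(all(is.na(prof2$per_context$percent)))

  # Ambiguous calls drop out of numerator and denominator.
  calls$state <- rep(c("methylated", "ambiguous"), times = c(20, 20))
  prof3 <- summarize_profile(calls)
  chg3 <- prof3$per_context[prof3$per_context$context == "CHG", ]
  expect_equal(chg3$percent, 100)
  expect_equal(chg3$total_informative_calls, 20L)
})

test_that("sub-region tallies recombine to the whole-region counts", {
  cfg <- small_meth_config()
  built <- build_locus(cfg, seed = 2)
  sites <- enumerate_sites(built$locus, c(1L, 500L), "+")
  cs <- simulate_clones(built$locus, built$truth, c(1L, 500L), "+", "Mop1",
                        1L, 8L, seed = 4)[[1L]]
  calls <- call_methylation(cs, sites)
  halves <- data.frame(name = c("left", "right"),
                       start = c(1L, 251L), end = c(250L, 500L))
  prof <- summarize_profile(calls, feature_subsets = halves)
  pf <- prof$per_feature
  for (ctx in c("CG", "CHG", "CHH")) {
    whole <- prof$per_context[prof$per_context$context == ctx, ]
    parts <- pf[pf$context == ctx, ]
    expect_equal(sum(parts$meth_calls), whole$meth_calls)
    expect_equal(sum(parts$total_informative_calls),
                 whole$total_informative_calls)
  }
})

test_that("genotype t-test matches the pooled-variance formula", {
  r <- meth_t_test(c(50, 60), c(50, 60))
  expect_equal(r$t_statistic, 0)
  expect_equal(r$p_value, 1)
  expect_false(r$significant)

  withr::with_seed(99, {
    for (i in 1:100) {
      a <- runif(sample(2:6, 1), 0, 100)
      b <- runif(sample(2:6, 1), 0, 100)
      got <- meth_t_test(a, b)
      want <- oracle_pooled_t(a, b)
      expect_equal(got$t_statistic, want$t, tolerance = 1e-9)
      expect_equal(got$p_value, want$p, tolerance = 1e-9)
      swapped <- meth_t_test(b, a)
      expect_equal(swapped$t_statistic, -got$t_statistic, tolerance = 1e-12)
      expect_equal(swapped$p_value, got$p_value, tolerance = 1e-12)
    }
  })
})

test_that("a single-replicate group is reported without t and P", {
  r <- meth_t_test(c(42), c(10, 12, 14))
  expect_false(r$complete)
  expect_true(is.na(r$t_statistic))
  expect_true(is.na(r$p_value))
  expect_equal(r$mean_a, 42)
  expect_equal(r$mean_b, 12)
})

test_that("per-site table is sorted, consistent, and handles empty input", {
  cfg <- small_meth_config()
  study <- run_small_meth_study(cfg, seed = 31, n_replicates = 2L,
                                n_clones = 5L)
  tab <- per_site_table(study$profiles)
  expect_identical(order(tab$tss_pos, tab$genotype), seq_len(nrow(tab)))
  # Each (site, genotype) appears once.
  expect_false(any(duplicated(tab[, c("genotype", "tss_pos", "strand")])))
  # Clone-pooled fractions equal recombined per-replicate counts.
  one <- tab[1, ]
  counts <- do.call(rbind, lapply(study$profiles, function(e) {
    if (e$genotype != one$genotype) return(NULL)
    ps <- e$profile$per_site
    ps[ps$tss_pos == one$tss_pos & ps$strand == one$strand, ]
  }))
  expect_equal(one$fraction,
               sum(counts$n_meth) / sum(counts$n_meth + counts$n_unmeth))

  empty <- per_site_table(list())
  expect_equal(nrow(empty), 0L)
})
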