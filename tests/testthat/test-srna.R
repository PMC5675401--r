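# Small RNA pipeline: trimming, structural filtering, exact-match
# alignment, normalization, coverage, binning, differential calling.

ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

test_that("adapter trimming recovers inserts and rejects by length", {
  withr::with_seed(3, insert <- rand_seq(22))
  t1 <- trim_adapter(paste0(insert, ADAPTER), ADAPTER)
  expect_identical(t1$status, "kept")
  expect_identical(t1$insert, insert)

  expect_identical(trim_adapter("ACGTACGTACGTACGTACGTACGT", ADAPTER)$status,
                   "no_adapter")
  expect_identical(trim_adapter("", ADAPTER)$status, "no_adapter")
  withr::with_seed(4, {
    short <- paste0(rand_seq(17), ADAPTER)
    long <- paste0(rand_seq(31), ADAPTER)
  })
  expect_identical(trim_adapter(short, ADAPTER)$status, "too_short")
  expect_identical(trim_adapter(long, ADAPTER)$status, "too_long")
  expect_error(trim_adapter("ACGT", "ACGTA"), "at least 6")
})

test_that("structural reads are exact substrings of either strand", {
  withr::with_seed(8, rrna <- rand_seq(120))
  idx <- structural_index(c(rRNA = rrna))
  reads <- collapse_reads(c(
    substr(rrna, 40, 60),            # interior 21-mer
    rc_chr(substr(rrna, 70, 91)),    # reverse complement of interior 22-mer
    "ACACACACACACACACACAC"           # unrelated
  ))
  flagged <- filter_structural(reads, idx)
  lookup <- setNames(flagged$structural, flagged$seq)
  expect_true(lookup[[substr(rrna, 40, 60)]])
  expect_true(lookup[[rc_chr(substr(rrna, 70, 91))]])
  expect_false(lookup[["ACACACACACACACACACAC"]])
})

test_that("library tallies conserve reads through the pipeline", {
  b <- build_locus(seed = 7)
  cfg <- data.frame(id = "wt1", genotype = "Mop1", replicate = 1L,
                    depth = 15000L, stringsAsFactors = FALSE)
  sim <- simulate_srna_libraries(b$locus, b$truth, cfg, adapter = ADAPTER,
                                 seed = 2)
  lib <- profile_library(sim$wt1$reads, ADAPTER, b$truth$structural_ref,
                         b$locus, id = "wt1")
  t <- lib$tallies
  expect_equal(t$raw_reads,
               t$rejected_no_adapter + t$rejected_length + t$structural +
                 t$nonstructural)
  # With no structural records matched the denominator equals the trimmed
  # total.
  lib2 <- profile_library(sim$wt1$reads, ADAPTER, c(dummy = "ACGT"),
                          b$locus, id = "wt1")
  expect_equal(lib2$tallies$structural, 0)
})

test_that("perfect-match alignment agrees with a naive scan", {
  withr::with_seed(12, locus_seq <- rand_seq(400))
  # Tandem duplication: every read from the repeated block hits twice.
  block <- substr(locus_seq, 100, 160)
  dup <- paste0(substr(locus_seq, 1, 99), block, block,
                substr(locus_seq, 161, 400))
  read <- substr(block, 10, 33)
  hits <- align_perfect(read, dup)
  expect_equal(nrow(hits[hits$strand == "+", ]), 2L)

  # Palindromic read: one '+' and one '-' hit at the same position.
  pal <- strrep("AT", 12)
  expect_identical(rc_chr(pal), pal)
  with_pal <- paste0(substr(locus_seq, 1, 200), pal,
                     substr(locus_seq, 225, 400))
  h <- align_perfect(pal, with_pal)
  expect_setequal(h$strand, c("+", "-"))
  expect_equal(h$array_pos[1], h$array_pos[2])

  # Absent read.
  expect_equal(nrow(align_perfect(strrep("ACGGT", 5), locus_seq)), 0L)

  # Random (read, locus) pairs against the oracle.
  withr::with_seed(77, {
    idx <- locus_index(locus_seq)
    for (i in 1:50) {
      read <- if (i %% 2 == 0) rand_seq(sample(18:30, 1)) else {
        s <- sample(380, 1); substr(locus_seq, s, s + sample(18:24, 1))
      }
      got <- align_perfect(read, idx)
      want <- oracle_align(read, locus_seq)
      got <- got[order(got$strand, got$array_pos), ]
      want <- want[order(want$strand, want$array_pos), ]
      expect_identical(got$array_pos, want$array_pos)
      expect_identical(got$strand, want$strand)
    }
  })
})

test_that("RPM and 22-nt anchoring produce the documented factors", {
  libA <- fake_library("A", 2e6, c(`22` = 200, `24` = 1000))
  libB <- fake_library("B", 1e6, c(`22` = 50, `24` = 100))
  f_rpm <- normalize_libraries(list(libA, libB), mode = "rpm")
  expect_equal(unname(f_rpm["A"]), 0.5)  # 4 raw reads -> 2.0 RPM
  expect_equal(4 * f_rpm[["A"]], 2.0)

  # A's 22-nt RPM = 100, B's = 50 -> anchor multiplier 2 for B.
  f_anc <- normalize_libraries(list(libA, libB), mode = "rpm_22anchor",
                               reference_library = "A")
  expect_equal(f_anc[["B"]] / (1e6 / 1e6), 2.0)
  # After anchoring, 22-nt totals agree to machine precision.
  expect_equal(200 * f_anc[["A"]], 50 * f_anc[["B"]], tolerance = 1e-12)

  # Anchoring is a single scalar: within-library size-class ratios fixed.
  expect_equal((1000 * f_anc[["A"]]) / (200 * f_anc[["A"]]), 1000 / 200)

  expect_error(normalize_libraries(list(fake_library("Z", 0, c(`22` = 1)))),
               "Z")
  expect_error(normalize_libraries(list(fake_library("Y", 10, c(`24` = 1))),
                                   mode = "rpm_22anchor"), "Y")
})

test_that("size distributions report the requested unit", {
  lib <- fake_library("A", 500, c(`24` = 500))
  d <- size_distribution(lib, factor = 1e6 / 500)
  expect_equal(d$abundance[d$length == 24], 1e6)
  expect_equal(sum(d$abundance), 1e6)
  expect_true(all(d$abundance[d$length != 24] == 0))
})

test_that("position coverage spans reads and conserves mass", {
  loc <- build_locus(seed = 7)$locus
  apos <- from_tss_coord(100L, loc$tss_array_pos)
  hits <- data.frame(seq = "x", array_pos = apos, strand = "+",
                     count = 1L, length = 24L, stringsAsFactors = FALSE)
  cov <- position_coverage(hits, nchar(loc$sequence))
  expect_equal(sum(cov$sense), 24)
  expect_true(all(cov$sense[apos:(apos + 23L)] == 1))
  expect_true(all(cov$antisense == 0))

  hits2 <- rbind(hits, data.frame(seq = "y", array_pos = apos + 10L,
                                  strand = "+", count = 2L, length = 20L))
  cov2 <- position_coverage(hits2, nchar(loc$sequence))
  expect_equal(cov2$sense[apos + 12L], 3)  # overlap is additive
  expect_equal(sum(cov2$sense), 1 * 24 + 2 * 20)
})

test_that("bins are half-open on the anchored TSS grid and conserve hits", {
  loc <- build_locus(seed = 7)$locus
  mk_lib <- function(tss_starts, strand = "+") {
    apos <- from_tss_coord(tss_starts, loc$tss_array_pos)
    hits <- data.frame(seq = paste0("r", seq_along(apos)),
                       array_pos = apos, strand = strand, count = 1L,
                       length = 24L, n_hits = 1L, stringsAsFactors = FALSE)
    structure(list(id = "L", genotype = "Mop1", replicate = 1L,
                   reads = NULL, hits = hits,
                   matched_by_length = c(`24` = length(apos)),
                   tallies = list(genome_matched_nonstructural =
                                    length(apos))),
              class = "SmallRNALibrary")
  }
  # A 5' start exactly on an edge falls in the right-hand bin.
  bt <- bin_table(list(mk_lib(c(51L, 50L))), loc, width = 50L,
                  anchor_offset = 1L)
  expect_identical(sort(bt$tss_start), c(1L, 51L))

  # Grid anchored at 24 reproduces printed edges like -1726..-1676.
  bt2 <- bin_table(list(mk_lib(-1700L)), loc, width = 50L,
                   anchor_offset = 24L)
  expect_identical(bt2$tss_start, -1726L)
  expect_identical(bt2$tss_end, -1676L)

  # Sum over bins equals the library's total hit count.
  withr::with_seed(15, starts <- sample(c(-2000:-1, 1:2000), 300))
  bt3 <- bin_table(list(mk_lib(starts)), loc)
  expect_equal(sum(bt3$abundance), 300)
})

test_that("lost-region calling applies thresholds and merges adjacent bins", {
  grid <- data.frame(tss_start = c(4974L, 5024L, 5074L, 5124L),
                     tss_end = c(5024L, 5074L, 5124L, 5174L))
  wt <- cbind(grid, abundance = c(2, 40, 43, 4))
  mut <- cbind(grid, abundance = c(0, 3, 4, 0))
  # The Stowaway-style pair merges into one region with ratio 7/83.
  reg <- call_lost_regions(wt, mut)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$tss_start, 5024L)
  expect_equal(reg$tss_end, 5124L)
  expect_equal(reg$wt_abundance, 83)
  expect_equal(reg$mut_abundance, 7)
  expect_equal(reg$ratio, 7 / 83, tolerance = 1e-12)

  # wt 233 vs mut 6 in one bin is flagged; wt 4 vs mut 0 is not.
  wt2 <- cbind(grid, abundance = c(233, 4, 0, 10))
  mut2 <- cbind(grid, abundance = c(6, 0, 0, 9))
  reg2 <- call_lost_regions(wt2, mut2)
  expect_equal(nrow(reg2), 1L)
  expect_equal(reg2$wt_abundance, 233)
  # mut = 0 always passes the ratio test when wt clears min_wt.
  wt3 <- cbind(grid, abundance = c(6, 0, 0, 0))
  mut3 <- cbind(grid, abundance = c(0, 0, 0, 0))
  expect_equal(nrow(call_lost_regions(wt3, mut3)), 1L)

  bad <- grid; bad$tss_start <- bad$tss_start + 50L
  expect_error(call_lost_regions(wt, cbind(bad, abundance = 0)),
               "different grids")
})
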