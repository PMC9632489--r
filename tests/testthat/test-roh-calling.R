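test_that("L parameter follows the genome-wide formula with its floor", {
  # numeric oracle: evaluate the formula directly
  expected <- ceiling(log(0.05 / (36964 * 30)) / log(1 - 0.28))
  expect_equal(compute_L(36964, 30, 0.28), as.integer(expected))
  # halving alpha can only increase L
  expect_gte(compute_L(36964, 30, 0.28, alpha = 0.025),
             compute_L(36964, 30, 0.28, alpha = 0.05))
  # near-unit heterozygosity hits the floor of 20 SNPs
  expect_equal(compute_L(1000, 10, 0.95), 20L)
  expect_error(compute_L(1000, 10, 0), "mean_het")
})

test_that("window scan flags homozygous stretches and respects the window budgets", {
  # all-homozygous chromosome: every SNP flagged
  expect_true(all(window_scan(rep(0L, 50), L = 10)))
  # chromosome shorter than L: nothing flagged
  expect_false(any(window_scan(rep(0L, 5), L = 10)))
  # two missing calls inside every window: no window passes
  calls <- rep(0L, 40)
  calls[seq(1, 40, by = 4)] <- NA_integer_
  expect_false(any(window_scan(calls, L = 10, max_missing = 1L)))
  # a single het clears flags in a neighbourhood; compare to brute force
  calls2 <- rep(0L, 60)
  calls2[30] <- 1L
  pos <- seq_len(60) * 1000L
  got <- window_scan(calls2, L = 12)
  ora <- oracle_roh(calls2, pos, L = 12, min_snps = 12, max_density = 1e9)
  expect_false(got[30])
  # flags themselves must agree with the oracle's window enumeration
  flags_ora <- rep(FALSE, 60)
  if (nrow(ora)) for (k in seq_len(nrow(ora)))
    flags_ora[(ora$start_bp[k] / 1000):(ora$end_bp[k] / 1000)] <- TRUE
  expect_equal(which(got), which(flags_ora))
})

test_that("segment assembly applies gap, support and density rules", {
  # 60 flagged SNPs spanning 5.4 Mb, max gap 0.9 Mb -> one 4-8 Mb segment
  pos <- as.integer(seq(1e6, 6.4e6, length.out = 60))
  segs <- assemble_segments(rep(TRUE, 60), pos, max_gap_bp = 1e6,
                            min_snps = 50, max_density = 150000)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$n_snps, 60L)
  expect_equal(as.character(segs$length_class), "4-8Mb")

  # a 1.2 Mb gap splits the run; both halves are re-tested against support
  pos2 <- c(seq(1e6, 3e6, length.out = 30), seq(4.3e6, 6.3e6, length.out = 30))
  segs2 <- assemble_segments(rep(TRUE, 60), as.integer(pos2),
                             max_gap_bp = 1e6, min_snps = 25,
                             max_density = 150000)
  expect_equal(nrow(segs2), 2L)
  segs2b <- assemble_segments(rep(TRUE, 60), as.integer(pos2),
                              max_gap_bp = 1e6, min_snps = 40,
                              max_density = 150000)
  expect_equal(nrow(segs2b), 0L)

  # run of L SNPs spanning 9 Mb violates the 150 kb/SNP density rule
  pos3 <- as.integer(seq(1e6, 10e6, length.out = 50))
  expect_equal(nrow(assemble_segments(rep(TRUE, 50), pos3, max_gap_bp = 1e9,
                                      min_snps = 50, max_density = 150000)),
               0L)
})

test_that("sliding-window segments equal the brute-force enumerator on random instances", {
  set.seed(51)
  for (i in 1:25) {
    m <- sample(60:300, 1)
    L <- sample(8:25, 1)
    calls <- random_calls(1, m, p_het = runif(1, 0.05, 0.3),
                          p_missing = runif(1, 0, 0.08))[1, ]
    pos <- random_positions(m)
    flags <- window_scan(calls, L)
    got <- assemble_segments(flags, pos, max_gap_bp = 1e6, min_snps = L,
                             max_density = 150000)
    ora <- oracle_roh(calls, pos, L, min_snps = L)
    expect_equal(got[, c("start_bp", "end_bp", "n_snps")],
                 ora[, c("start_bp", "end_bp", "n_snps")],
                 ignore_attr = TRUE)
  }
})

test_that("F_ROH arithmetic: totals, classes and degenerate cases", {
  samples <- data.frame(id = c("A", "B"), population = "P1")
  empty <- data.frame(sample_id = character(), chrom = character(),
                      start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), length_bp = numeric(),
                      length_class = roh_length_class(numeric()))
  names(empty)[1] <- "sample_id"
  fr0 <- froh(empty, samples, 1e8)
  expect_equal(fr0$froh_all, c(0, 0))

  segs <- data.frame(sample_id = c("A", "A"), chrom = "1",
                     start_bp = c(1e6, 2e7), end_bp = c(4e6, 3e7),
                     n_snps = c(50L, 100L), length_bp = c(3e6, 1e7))
  segs$length_class <- roh_length_class(segs$length_bp)
  fr <- froh(segs, samples, 1e8)
  expect_equal(fr$froh_all[1], 0.13)
  expect_equal(fr$froh_24[1], 0.03)
  expect_equal(fr$froh_816[1], 0.10)
  expect_equal(fr$froh_all[2], 0)
  expect_error(froh(segs, samples, 0), "coverage")

  # one segment spanning the whole single-chromosome map
  full <- data.frame(sample_id = "A", chrom = "1", start_bp = 1L,
                     end_bp = 1e8 + 1, n_snps = 1000L, length_bp = 1e8)
  full$length_class <- roh_length_class(full$length_bp)
  expect_equal(froh(full, samples, 1e8)$froh_all[1], 1)
})

test_that("class-wise F_ROH sums exactly to the total and hets never lengthen runs", {
  set.seed(61)
  for (i in 1:10) {
    calls <- random_calls(1, 400, p_het = 0.08, p_missing = 0.02)[1, ]
    pos <- random_positions(400)
    flags <- window_scan(calls, 15)
    segs <- assemble_segments(flags, pos, min_snps = 15)
    if (nrow(segs)) {
      segs2 <- cbind(sample_id = "A", chrom = "1", segs)
      fr <- froh(segs2, data.frame(id = "A", population = "P"), max(pos) - min(pos))
      expect_equal(fr$froh_12 + fr$froh_24 + fr$froh_48 + fr$froh_816 +
                     fr$froh_16, fr$froh_all)
    }
    # monotonicity: adding one het call never extends flagged coverage
    j <- sample(400, 1)
    calls_het <- calls; calls_het[j] <- 1L
    expect_true(all(window_scan(calls_het, 15) <= flags))
  }
})

test_that("planted autozygous tracts are recovered to within 0.02", {
  sim <- simulate_breed(seed = 71, n = 10, n_snps = 30000, froh = 0.15,
                        froh_sd = 0.02, tract_length_range = c(4e6, 16e6))
  r <- roh_pipeline_one(sim)
  fr <- froh(r$segments, r$g$samples, snp_coverage_bp(r$g$markers))
  truth <- sim$truth$individuals
  m <- merge(fr, truth, by = "sample_id")
  expect_lt(mean(abs(m$froh_all - m$planted_froh)), 0.02)
})

test_that("no sub-2 Mb segments arise on a chip-density map with formula L", {
  sim <- simulate_breed(seed = 81, n = 15, n_snps = 30000, froh = 0.15,
                        froh_sd = 0.03)
  r <- roh_pipeline_one(sim)
  expect_gt(nrow(r$segments), 0)
  expect_true(all(r$segments$length_bp >= 2e6))
  expect_equal(sum(r$segments$length_class == "1-2Mb"), 0L)
})
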