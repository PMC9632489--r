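test_that("call-rate filtering removes the right markers and samples", {
  # 10 samples x 10 SNPs, SNP 1 missing in 2/10 samples -> rate 0.8 < 0.9
  calls <- matrix(0L, 10, 10)
  calls[1:2, 1] <- NA_integer_
  g <- make_geno(calls)
  res <- filter_call_rate(g, qc_config())
  expect_equal(n_markers(res$genotypes), 9L)
  expect_equal(res$report$n_removed_markers[1], 1L)

  # sample with 50% missing calls goes next
  calls2 <- matrix(0L, 10, 10)
  calls2[1, 1:5] <- NA_integer_
  res2 <- filter_call_rate(make_geno(calls2), qc_config())
  expect_equal(n_samples(res2$genotypes), 9L)
  expect_false("S001" %in% res2$genotypes$samples$id)

  # complete matrix is untouched
  res3 <- filter_call_rate(make_geno(matrix(1L, 5, 5)), qc_config())
  expect_equal(dim(res3$genotypes), c(5L, 5L))
  expect_equal(sum(res3$report$n_removed_markers), 0L)
})

test_that("allele frequencies and the MAF filter count alleles correctly", {
  # counts hom_a=5, het=5, hom_b=0 -> p_b = 5/20 = 0.25
  g <- make_geno(cbind(c(rep(0L, 5), rep(1L, 5)),
                       rep(0L, 10),          # monomorphic -> MAF 0
                       rep(1L, 10)))         # all het -> MAF 0.5
  expect_equal(unname(allele_frequency(g)), c(0.25, 0, 0.5))
  expect_equal(unname(maf(g)), c(0.25, 0, 0.5))
  res <- filter_maf(g, 0.05)
  expect_equal(n_markers(res$genotypes), 2L)
  expect_equal(res$report$removed_marker_ids, "M00002")
  # disabled filter keeps everything
  expect_equal(n_markers(filter_maf(g, NULL)$genotypes), 3L)
})

test_that("exact HWE test agrees with full enumeration", {
  # balanced table: observed het count is the modal configuration
  expect_gte(hwe_exact_p(25, 50, 25), 0.999)
  # total heterozygote deficit at n=100 is far beyond 1e-6
  expect_lt(hwe_exact_p(50, 0, 50), 1e-6)
  # monomorphic: single attainable configuration
  expect_equal(hwe_exact_p(30, 0, 0), 1)

  set.seed(11)
  for (i in 1:60) {
    n <- sample(3:100, 1)
    ab <- sample(0:n, 1)
    aa <- sample(0:(n - ab), 1)
    bb <- n - ab - aa
    expect_equal(hwe_exact_p(aa, ab, bb), oracle_hwe(aa, ab, bb),
                 tolerance = 1e-12,
                 label = sprintf("hwe(%d,%d,%d)", aa, ab, bb))
  }
})

test_that("HWE filtering removes markers below the threshold", {
  calls <- cbind(c(rep(0L, 10), rep(2L, 10)),   # total het deficit
                 rep(c(0L, 1L, 2L, 1L), 5))     # balanced
  g <- make_geno(calls)
  res <- filter_hwe(g, 1e-4)
  expect_equal(res$report$removed_marker_ids, "M00001")
  expect_equal(n_markers(filter_hwe(g, NULL)$genotypes), 2L)
})

test_that("relatedness matrix flags duplicates and is centred for unrelated samples", {
  set.seed(21)
  n_bg <- 40
  p <- runif(600, 0.1, 0.9)
  calls <- t(replicate(n_bg, rbinom(600, 2L, p)))
  # one moderately inbred individual (excess homozygosity, F ~ 0.3), cloned:
  # a genotyping duplicate of an inbred animal sits clearly above 0.95
  ibd <- runif(600) < 0.3
  inbred <- ifelse(ibd, 2L * rbinom(600, 1L, p), rbinom(600, 2L, p))
  calls <- rbind(calls, inbred, inbred)
  calls[n_bg + 2L, 5] <- NA_integer_           # duplicate has lower call rate
  g <- make_geno(calls)
  dup <- c(n_bg + 1L, n_bg + 2L)
  grm <- relatedness_matrix(g)
  expect_gt(grm[dup[1], dup[2]], 0.95)
  mask <- upper.tri(grm)
  mask[dup[1], dup[2]] <- FALSE                # drop the duplicate pair
  off <- grm[mask]
  # unrelated pairs centre near zero (small negative bias from estimating
  # allele frequencies in-sample)
  expect_lt(abs(mean(off)), 3 * sd(off) / sqrt(length(off)) + 1.5 / n_bg)

  res <- drop_related(g, 0.95)
  expect_equal(res$report$removed_sample_ids, g$samples$id[dup[2]])
  expect_equal(n_samples(res$genotypes), n_bg + 1L)
  # permissive threshold (above even an inbred duplicate's 1+F) removes nobody
  expect_equal(n_samples(drop_related(g, 2.0)$genotypes), n_bg + 2L)
})

test_that("LD pruning removes duplicated SNPs and matches an exhaustive greedy oracle", {
  set.seed(31)
  calls <- random_calls(40, 12, p_missing = 0)
  calls[, 12] <- calls[, 11]                   # perfect LD pair
  g <- make_geno(calls)
  res <- prune_ld(g, window_snps = 12, step_snps = 6, r2_max = 0.5)
  removed <- strsplit(res$report$removed_marker_ids, ",")[[1]]
  expect_true(any(c("M00011", "M00012") %in% removed))
  # nothing pruned at r2_max = 1
  expect_equal(n_markers(prune_ld(g, 12, 6, 1.0)$genotypes), 12L)

  # oracle: direct greedy re-implementation, pair-exhaustive on one window
  greedy_oracle <- function(calls, mafs, r2_max) {
    active <- seq_len(ncol(calls))
    repeat {
      best <- NULL; best_r2 <- r2_max
      for (i in seq_along(active)) for (j in seq_along(active)) {
        if (j <= i) next
        r2 <- ld_r2(calls[, active[i]], calls[, active[j]])
        if (r2 > best_r2) { best_r2 <- r2; best <- c(active[i], active[j]) }
      }
      if (is.null(best)) break
      victim <- if (mafs[best[1]] < mafs[best[2]]) best[1]
                else if (mafs[best[2]] < mafs[best[1]]) best[2]
                else max(best)
      active <- setdiff(active, victim)
    }
    active
  }
  for (seed in 1:5) {
    set.seed(seed)
    cc <- random_calls(30, 8, p_missing = 0.02)
    cc[, 8] <- cc[, 7]; cc[, 4] <- cc[, 3]
    gg <- make_geno(cc)
    kept <- prune_ld(gg, window_snps = 8, step_snps = 4,
                     r2_max = 0.3)$genotypes$markers$id
    expect_equal(kept,
                 sprintf("M%05d", greedy_oracle(cc, maf(gg), 0.3)))
  }
})

test_that("QC profiles carry the per-branch settings and stages conserve counts", {
  s <- qc_profile("structure")
  expect_equal(s$maf_min, 0.05)
  expect_equal(s$hwe_p_min, 1e-6)
  expect_equal(s$ld_prune$window_snps, 50L)
  r <- qc_profile("roh")
  expect_equal(r$marker_call_rate_min, 0.95)
  expect_null(r$maf_min); expect_null(r$hwe_p_min); expect_null(r$ld_prune)
  f <- qc_profile("fst")
  expect_null(f$maf_min)
  expect_equal(f$hwe_p_min, 1e-6)

  set.seed(41)
  g <- make_geno(random_calls(15, 60, p_missing = 0.05))
  res <- apply_qc(g, qc_profile("structure"))
  rep <- res$report
  # removed + retained = input at every stage, in application order
  nm <- n_markers(g); ns <- n_samples(g)
  for (i in seq_len(nrow(rep))) {
    expect_equal(rep$n_markers_after[i] + rep$n_removed_markers[i], nm)
    expect_equal(rep$n_samples_after[i] + rep$n_removed_samples[i], ns)
    nm <- rep$n_markers_after[i]; ns <- rep$n_samples_after[i]
  }
  # membership-only: surviving calls are identical to the input's
  gq <- res$genotypes
  expect_identical(gq$calls,
                   g$calls[gq$samples$id, gq$markers$id])
})
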