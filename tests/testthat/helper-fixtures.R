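# Small in-code fixture builders shared across test files.

# genotypes object from a bare call matrix (one chromosome by default)
make_geno <- function(calls, chrom = NULL, pos = NULL, populations = NULL,
                      autosomes = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls); m <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(populations)) populations <- rep("P1", n)
  genotypes(calls,
            samples = data.frame(id = sprintf("S%03d", seq_len(n)),
                                 population = populations,
                                 stringsAsFactors = FALSE),
            markers = data.frame(id = sprintf("M%05d", seq_len(m)),
                                 chrom = chrom, pos = pos,
                                 allele_a = "A", allele_b = "C",
                                 stringsAsFactors = FALSE),
            autosomes = autosomes)
}

# random call matrix with controlled het/missing rates
random_calls <- function(n, m, p_het = 0.3, p_missing = 0.02) {
  x <- matrix(sample(c(0L, 2L), n * m, replace = TRUE), n, m)
  het <- matrix(runif(n * m) < p_het, n, m)
  x[het] <- 1L
  x[matrix(runif(n * m) < p_missing, n, m)] <- NA_integer_
  x
}

# sorted random positions with occasional >1 Mb gaps
random_positions <- function(m, mean_spacing = 6e4, p_big_gap = 0.02) {
  gaps <- ceiling(stats::rexp(m, 1 / mean_spacing)) + 1L
  big <- runif(m) < p_big_gap
  gaps[big] <- gaps[big] + 1.2e6
  as.integer(cumsum(gaps))
}

# single-breed cohort wrapper used by ROH/island tests
simulate_breed <- function(seed, n = 30, n_snps = 30000, froh = 0.05,
                           froh_sd = 0.01, islands = NULL, ...) {
  simulate_cohort(sim_config(
    seed = seed, pop_names = "SM", n_per_pop = n, n_snps = n_snps,
    n_chrom = 18, divergence_F = 0.05, froh_target = froh,
    froh_sd = froh_sd, planted_islands = islands, ...))
}

# 20-sample QC toy with one planted violation per filter:
#   M1, M2  call rate 17/20 = 0.85        (< 0.90 marker threshold)
#   S20     called on 16/36 markers       (< 0.90 sample threshold)
#   M3-M5   MAF 0, 1/38, 0                (< 0.05)
#   M6      total het deficit (10,0,10)   (most extreme table at N = 20)
#   S18/S19 inbred genotyping duplicate   (G > 0.95; S19 lower call rate)
#   M7 = M8 perfect LD pair               (r2 = 1)
# Background: 30 balanced shuffled columns (fixed seed, free of accidental
# violations — the LD stage is additionally cross-checked against the
# exhaustive greedy oracle in the acceptance test).
build_qc_toy <- function() {
  set.seed(90)
  bg <- sapply(1:30, function(j) sample(rep(c(0L, 1L, 2L), c(7L, 6L, 7L))))
  p_col <- colMeans(bg) / 2
  ibd <- runif(30) < 0.5
  s18 <- ifelse(ibd, 2L * rbinom(30, 1L, p_col), bg[18, ])
  bg[18, ] <- s18
  bg[19, ] <- s18
  bg[19, 1] <- NA
  bg[20, sample(30, 20)] <- NA
  pat <- function(...) as.integer(c(...))
  m1 <- pat(NA, NA, NA, rep(c(0, 1, 2, 1), 3), 0, 2, 2, 2, 0)
  m2 <- pat(rep(c(2, 1, 0), 4), 0, NA, NA, NA, 1, 1, 1, 0)
  m3 <- rep(0L, 20)
  m4 <- c(1L, rep(0L, 19))
  m5 <- rep(2L, 20)
  m6 <- pat(rep(0, 9), rep(2, 8), 2, 2, 0)
  m7 <- pat(rep(c(0, 1, 2, 1), 4), 1, 2, 2, 1)
  calls <- cbind(m1, m2, m3, m4, m5, m6, m7, m7, bg)
  colnames(calls) <- NULL
  make_geno(calls)
}

# ROH branch: per-breed QC then segments + incidence track
roh_pipeline_one <- function(sim, pop = "SM") {
  qb <- apply_qc_by_population(sim$genotypes, qc_profile("roh"))
  gb <- qb[[pop]]$genotypes
  segs <- call_roh(gb)
  track <- roh_incidence(segs, gb$markers, gb$samples$id)
  list(g = gb, segments = segs, track = track)
}
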