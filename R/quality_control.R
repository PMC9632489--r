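# Quality-control cascade: call rate -> MAF -> HWE -> relatedness -> LD.
# Stages only change membership (which samples/markers are kept), never calls.

#' Quality-control configuration
#'
#' @param sample_call_rate_min minimum per-sample call rate (fraction).
#' @param marker_call_rate_min minimum per-marker call rate (0.90 general,
#'   0.95 for the ROH branch).
#' @param maf_min minimum minor allele frequency, or `NULL` to disable
#'   (disabled for the ROH and FST branches).
#' @param hwe_p_min exact-test p-value below which a marker is removed, or
#'   `NULL` to disable (disabled for the ROH branch).
#' @param relatedness_max genomic-relationship coefficient above which one
#'   member of a sample pair is removed, or `NULL` to disable.
#' @param ld_prune `NULL`, or a list `(window_snps, step_snps, r2_max)` as in
#'   PLINK `--indep-pairwise` (structure branch: 50 25 0.5).
#' @param markers_first apply the marker call-rate filter before the sample
#'   one (default) or the reverse.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(sample_call_rate_min = 0.90,
                      marker_call_rate_min = 0.90,
                      maf_min = 0.05,
                      hwe_p_min = 1e-6,
                      relatedness_max = 0.95,
                      ld_prune = NULL,
                      markers_first = TRUE) {
  for (x in c(sample_call_rate_min, marker_call_rate_min, maf_min, hwe_p_min))
    if (!is.null(x) && (x < 0 || x > 1))
      stop("QC fractions/probabilities must lie in [0, 1]", call. = FALSE)
  if (!is.null(ld_prune)) {
    stopifnot(ld_prune$window_snps > ld_prune$step_snps,
              ld_prune$step_snps > 0)
  }
  structure(list(sample_call_rate_min = sample_call_rate_min,
                 marker_call_rate_min = marker_call_rate_min,
                 maf_min = maf_min, hwe_p_min = hwe_p_min,
                 relatedness_max = relatedness_max, ld_prune = ld_prune,
                 markers_first = markers_first),
            class = "qc_config")
}

#' Named per-branch QC profiles
#'
#' `"structure"`: 90% call rates, MAF 0.05, HWE 1e-6, LD pruning 50/25/0.5.
#' `"roh"`: 95% marker call rate, no MAF or HWE filter, no LD pruning
#' (run per breed). `"fst"`: 90% call rates, no MAF filter, HWE 1e-6.
#'
#' @param profile one of `"structure"`, `"roh"`, `"fst"`.
#' @return A [qc_config].
#' @export
qc_profile <- function(profile = c("structure", "roh", "fst")) {
  switch(match.arg(profile),
    structure = qc_config(ld_prune = list(window_snps = 50L, step_snps = 25L,
                                          r2_max = 0.5)),
    roh = qc_config(marker_call_rate_min = 0.95, maf_min = NULL,
                    hwe_p_min = NULL),
    fst = qc_config(maf_min = NULL))
}

qc_report_row <- function(stage, removed_samples, removed_markers, g) {
  data.frame(stage = stage,
             n_removed_samples = length(removed_samples),
             n_removed_markers = length(removed_markers),
             n_samples_after = n_samples(g),
             n_markers_after = n_markers(g),
             removed_sample_ids = paste(removed_samples, collapse = ","),
             removed_marker_ids = paste(removed_markers, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Call-rate filtering
#'
#' Removes markers with call rate below `marker_call_rate_min`, then samples
#' with call rate (over the retained markers) below `sample_call_rate_min`;
#' set `markers_first = FALSE` in the config for the reverse order.
#'
#' @param g a [genotypes] object.
#' @param cfg a [qc_config].
#' @return list `(genotypes, report)`.
#' @export
filter_call_rate <- function(g, cfg = qc_config()) {
  report <- list()
  marker_stage <- function(g) {
    cr <- colMeans(!is.na(g$calls))
    drop <- which(cr < cfg$marker_call_rate_min)
    ids <- g$markers$id[drop]
    if (length(drop)) g <- g[, -drop]
    report[[length(report) + 1L]] <<-
      qc_report_row("marker_call_rate", character(), ids, g)
    g
  }
  sample_stage <- function(g) {
    cr <- rowMeans(!is.na(g$calls))
    drop <- which(cr < cfg$sample_call_rate_min)
    ids <- g$samples$id[drop]
    if (length(drop)) g <- g[-drop, ]
    report[[length(report) + 1L]] <<-
      qc_report_row("sample_call_rate", ids, character(), g)
    g
  }
  g <- if (cfg$markers_first) sample_stage(marker_stage(g)) else
    marker_stage(sample_stage(g))
  if (n_samples(g) == 0 || n_markers(g) == 0)
    warning("matrix empty after call-rate filtering", call. = FALSE)
  list(genotypes = g, report = do.call(rbind, report))
}

#' Allele frequency of `allele_b` per marker
#'
#' Computed over non-missing calls only; `NaN` for all-missing markers.
#'
#' @param g a [genotypes] object.
#' @return Numeric vector, one frequency per marker.
#' @export
allele_frequency <- function(g) colMeans(g$calls, na.rm = TRUE) / 2

#' Minor allele frequency per marker
#' @param g a [genotypes] object.
#' @return Numeric vector `min(p, 1 - p)` per marker.
#' @export
maf <- function(g) {
  p <- allele_frequency(g)
  pmin(p, 1 - p)
}

#' MAF filtering
#'
#' Removes markers with minor allele frequency below `maf_min` (monomorphic
#' markers have MAF 0 and are removed whenever `maf_min > 0`). `maf_min =
#' NULL` disables the filter.
#'
#' @param g a [genotypes] object.
#' @param maf_min threshold, or `NULL`.
#' @return list `(genotypes, report)`.
#' @export
filter_maf <- function(g, maf_min = 0.05) {
  drop <- if (is.null(maf_min)) integer() else which(maf(g) < maf_min)
  ids <- g$markers$id[drop]
  if (length(drop)) g <- g[, -drop]
  list(genotypes = g, report = qc_report_row("maf", character(), ids, g))
}

#' Exact Hardy-Weinberg test p-value from genotype counts
#'
#' Two-sided exact test (Wigginton-style, non-mid-p): the sum of
#' probabilities of all heterozygote counts no more likely than the observed
#' one under the exact conditional distribution given the allele counts. A
#' relative tie guard of 1e-10 includes configurations of (numerically)
#' equal probability. Vectorised over count triples.
#'
#' @param n_hom_a,n_het,n_hom_b genotype counts (vectors of equal length).
#' @return p-values in (0, 1]; `NA` where all counts are zero.
#' @export
hwe_exact_p <- function(n_hom_a, n_het, n_hom_b) {
  mapply(function(aa, ab, bb) {
    if (any(c(aa, ab, bb) < 0)) stop("negative genotype counts", call. = FALSE)
    n <- aa + ab + bb
    if (n == 0L) return(NA_real_)
    rare <- 2L * min(aa, bb) + ab         # copies of the rarer allele
    hets <- seq(rare %% 2L, rare, by = 2L)
    probs <- numeric(length(hets))
    # start at the mode of the conditional distribution, recurse outward
    mid <- round(rare * (2 * n - rare) / (2 * n))
    if (mid %% 2L != rare %% 2L) mid <- mid + 1L
    mid <- min(max(mid, rare %% 2L), rare)
    i_mid <- match(mid, hets)
    probs[i_mid] <- 1
    if (i_mid > 1L) {
      for (i in seq(i_mid, 2L)) {
        h <- hets[i]
        probs[i - 1L] <- probs[i] * h * (h - 1) /
          (4 * ((rare - h) / 2 + 1) * ((2 * n - rare - h) / 2 + 1))
      }
    }
    if (i_mid < length(hets)) {
      for (i in seq(i_mid, length(hets) - 1L)) {
        h <- hets[i]
        hom_r <- (rare - h) / 2
        hom_c <- n - h - hom_r
        probs[i + 1L] <- probs[i] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
      }
    }
    probs <- probs / sum(probs)
    p_obs <- probs[match(ab, hets)]
    min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
  }, n_hom_a, n_het, n_hom_b, USE.NAMES = FALSE)
}

#' HWE filtering
#'
#' Removes markers whose exact HWE p-value falls below `hwe_p_min`;
#' all-missing markers are skipped. `hwe_p_min = NULL` disables the filter.
#'
#' @param g a [genotypes] object.
#' @param hwe_p_min threshold (e.g. 1e-6), or `NULL`.
#' @return list `(genotypes, report)`.
#' @export
filter_hwe <- function(g, hwe_p_min = 1e-6) {
  if (is.null(hwe_p_min) || n_markers(g) == 0) {
    return(list(genotypes = g,
                report = qc_report_row("hwe", character(), character(), g)))
  }
  aa <- colSums(g$calls == 0L, na.rm = TRUE)
  ab <- colSums(g$calls == 1L, na.rm = TRUE)
  bb <- colSums(g$calls == 2L, na.rm = TRUE)
  p <- hwe_exact_p(aa, ab, bb)
  drop <- which(!is.na(p) & p < hwe_p_min)
  ids <- g$markers$id[drop]
  if (length(drop)) g <- g[, -drop]
  list(genotypes = g, report = qc_report_row("hwe", character(), ids, g))
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / (2 * sum p_j (1 - p_j))` with `Z` the allele-frequency-centred
#' dosage matrix; markers missing for one member of a pair are skipped
#' pairwise (the denominator is accumulated per pair over the markers both
#' members were called at).
#'
#' @param g a [genotypes] object.
#' @return Symmetric n x n matrix of relationship coefficients.
#' @export
relatedness_matrix <- function(g) {
  p <- allele_frequency(g)
  ok <- !is.na(p)
  calls <- g$calls[, ok, drop = FALSE]
  p <- p[ok]
  z <- sweep(calls, 2L, 2 * p)
  z[is.na(z)] <- 0
  num <- z %*% t(z)
  w <- 2 * p * (1 - p)
  obs <- (!is.na(calls)) * 1
  den <- sweep(obs, 2L, w, `*`) %*% t(obs)
  grm <- num / den
  grm[den == 0] <- 0
  dimnames(grm) <- list(g$samples$id, g$samples$id)
  grm
}

#' Remove one member of each highly related sample pair
#'
#' Pairs with relationship coefficient above `max_coef` are resolved
#' greedily: the pair with the largest coefficient is handled first and its
#' lower-call-rate member removed (ties: the later sample in registry order).
#'
#' @param g a [genotypes] object.
#' @param max_coef threshold (paper-style duplicate removal uses 0.95).
#' @return list `(genotypes, report)`.
#' @export
drop_related <- function(g, max_coef = 0.95) {
  removed <- character()
  if (n_samples(g) >= 2L && !is.null(max_coef)) {
    grm <- relatedness_matrix(g)
    cr <- rowMeans(!is.na(g$calls))
    active <- rep(TRUE, nrow(grm))
    repeat {
      gg <- grm[active, active, drop = FALSE]
      diag(gg) <- -Inf
      if (!length(gg) || max(gg) <= max_coef) break
      idx <- which(gg == max(gg), arr.ind = TRUE)[1L, ]
      pair <- which(active)[sort(idx)]
      victim <- if (cr[pair[1]] < cr[pair[2]]) pair[1] else pair[2]
      removed <- c(removed, g$samples$id[victim])
      active[victim] <- FALSE
    }
    if (length(removed)) g <- g[setdiff(g$samples$id, removed), ]
  }
  list(genotypes = g,
       report = qc_report_row("relatedness", removed, character(), g))
}

#' Squared dosage correlation between two markers
#'
#' Pearson r^2 of 0/1/2 dosages over pairwise-complete samples; 0 when either
#' marker has zero variance.
#'
#' @param x,y integer dosage vectors.
#' @return r^2 in \[0, 1\].
#' @export
ld_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(0)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(0)
  stats::cor(x, y)^2
}

#' Window-based LD pruning (PLINK `--indep-pairwise` style)
#'
#' Within each `window_snps`-marker window (advanced by `step_snps` along
#' each chromosome), pairs with r^2 above `r2_max` are resolved to a
#' fixpoint: the highest-r^2 offending pair is handled first and its
#' lower-MAF member removed (ties: the later-position member).
#'
#' @param g a [genotypes] object.
#' @param window_snps,step_snps,r2_max pruning parameters (50, 25, 0.5).
#' @return list `(genotypes, report)`.
#' @export
prune_ld <- function(g, window_snps = 50L, step_snps = 25L, r2_max = 0.5) {
  keep <- rep(TRUE, n_markers(g))
  mafs <- maf(g)
  for (chr in unique(g$markers$chrom)) {
    idx <- which(g$markers$chrom == chr)
    mc <- length(idx)
    starts <- seq(1L, mc, by = step_snps)
    for (s in starts) {
      win <- idx[s:min(s + window_snps - 1L, mc)]
      repeat {
        act <- win[keep[win]]
        if (length(act) < 2L) break
        r2 <- suppressWarnings(
          stats::cor(g$calls[, act, drop = FALSE],
                     use = "pairwise.complete.obs")^2)
        r2[!is.finite(r2)] <- 0
        diag(r2) <- 0
        r2[lower.tri(r2)] <- 0
        if (max(r2) <= r2_max) break
        hit <- which(r2 == max(r2), arr.ind = TRUE)[1L, ]
        a <- act[hit[1]]; b <- act[hit[2]]
        victim <- if (mafs[a] < mafs[b]) a
                  else if (mafs[b] < mafs[a]) b
                  else max(a, b)              # tie -> later position
        keep[victim] <- FALSE
      }
    }
  }
  ids <- g$markers$id[!keep]
  g <- g[, which(keep)]
  list(genotypes = g, report = qc_report_row("ld_prune", character(), ids, g))
}

#' Run the full QC cascade
#'
#' Stages are applied in the narrative order call rate, MAF, HWE,
#' relatedness, LD pruning; the report records them in application order and
#' each stage conserves `removed + retained = input`.
#'
#' @param g a [genotypes] object.
#' @param cfg a [qc_config] (see [qc_profile] for the named branches).
#' @param verbose emit one message per stage with before/after counts.
#' @return list `(genotypes, report)` with one report row per stage.
#' @export
apply_qc <- function(g, cfg = qc_config(), verbose = FALSE) {
  note <- function(stage, before_s, before_m, g) {
    if (verbose)
      message(sprintf("%-18s samples %d -> %d, markers %d -> %d",
                      stage, before_s, n_samples(g), before_m, n_markers(g)))
  }
  reports <- list()
  run <- function(res, stage) {
    note(stage, ns, nm, res$genotypes)
    reports[[length(reports) + 1L]] <<- res$report
    res$genotypes
  }
  ns <- n_samples(g); nm <- n_markers(g)
  g <- run(filter_call_rate(g, cfg), "call_rate")
  ns <- n_samples(g); nm <- n_markers(g)
  g <- run(filter_maf(g, cfg$maf_min), "maf")
  ns <- n_samples(g); nm <- n_markers(g)
  g <- run(filter_hwe(g, cfg$hwe_p_min), "hwe")
  ns <- n_samples(g); nm <- n_markers(g)
  g <- run(drop_related(g, cfg$relatedness_max), "relatedness")
  if (!is.null(cfg$ld_prune)) {
    ns <- n_samples(g); nm <- n_markers(g)
    g <- run(prune_ld(g, cfg$ld_prune$window_snps, cfg$ld_prune$step_snps,
                      cfg$ld_prune$r2_max), "ld_prune")
  }
  list(genotypes = g, report = do.call(rbind, reports))
}

#' Run QC separately within each population
#'
#' Mirrors breed-by-breed quality control: each population is filtered on
#' its own allele frequencies and call rates.
#'
#' @param g a [genotypes] object.
#' @param cfg a [qc_config].
#' @param verbose passed to [apply_qc].
#' @return Named list (one entry per population) of `(genotypes, report)`.
#' @export
apply_qc_by_population <- function(g, cfg = qc_config(), verbose = FALSE) {
  pops <- unique(g$samples$population)
  out <- lapply(pops, function(p) {
    apply_qc(g[g$samples$population == p, ], cfg, verbose = verbose)
  })
  names(out) <- pops
  out
}
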