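# Per-SNP Weir-Cockerham (1984) FST: variance components a (among
# populations), b (among individuals within populations) and c (within
# individuals), estimated from per-population sample sizes, allele
# frequencies and observed heterozygote frequencies. The genome-wide mean
# is the ratio of sums (weighted) as reported by PLINK.

# core: matrices of per-population size (n), allele-b frequency (p) and
# observed het frequency (h), pops in rows, SNPs in columns
wc_components <- function(n, p, h) {
  present <- n > 0
  r <- colSums(present)
  n[!present] <- 0; p[!present] <- 0; h[!present] <- 0
  nbar <- colSums(n) / r
  nc <- (colSums(n) - colSums(n^2) / colSums(n)) / (r - 1)
  pbar <- colSums(n * p) / (r * nbar)
  s2 <- colSums(n * sweep(p, 2L, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(n * h) / (r * nbar)

  inner <- pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4
  a <- nbar / nc * (s2 - inner / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2

  bad <- r < 2 | nbar <= 1 | !is.finite(nc) | nc <= 0
  a[bad] <- NA_real_; b[bad] <- NA_real_; c_[bad] <- NA_real_
  den <- a + b + c_
  fst <- ifelse(!is.na(den) & den != 0, a / den, NA_real_)
  list(a = a, b = b, c = c_, fst = fst,
       retained = !is.na(den) & den != 0)
}

#' Weir-Cockerham FST components from per-population genotype counts
#'
#' Single-SNP form for count tables: one row per population with columns
#' `n_hom_a`, `n_het`, `n_hom_b`.
#'
#' @param counts matrix or data.frame, populations in rows.
#' @return list `(a, b, c, fst)`; `fst` is `NA` when the SNP is monomorphic
#'   across all populations (`a + b + c = 0`).
#' @export
wc_fst_counts <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == 3)
  n <- rowSums(counts)
  if (sum(n > 0) < 2)
    stop("need >= 2 populations with >= 1 called diploid each", call. = FALSE)
  p <- ifelse(n > 0, (counts[, 2] + 2 * counts[, 3]) / (2 * n), 0)
  h <- ifelse(n > 0, counts[, 2] / n, 0)
  comp <- wc_components(cbind(n), cbind(p), cbind(h))
  list(a = unname(comp$a[1]), b = unname(comp$b[1]),
       c = unname(comp$c[1]), fst = unname(comp$fst[1]))
}

#' Per-SNP Weir-Cockerham FST track
#'
#' Computes the 1984 variance components at every marker for the chosen
#' populations (all by default, giving the multi-population scan; pass two
#' labels for a pairwise one), plus the empirical z-score p-value of the
#' per-SNP estimates (`z` from the genome-wide FST distribution, `p =
#' Phi(z)`). Negative per-SNP estimates are retained (see [fst_mean]);
#' `fst_manhattan` floors them at 0 for export.
#'
#' @param g a [genotypes] object.
#' @param populations labels to include (default: all in `g`).
#' @return data.frame per SNP: `snp`, `chrom`, `pos`, `a`, `b`, `c`, `fst`,
#'   `retained`, `z`, `p`; comparison label in `attr(, "comparison")`.
#' @export
wc_fst <- function(g, populations = NULL) {
  if (is.null(populations)) populations <- unique(g$samples$population)
  if (length(populations) < 2)
    stop("need at least two populations", call. = FALSE)
  m <- n_markers(g)
  n <- p <- h <- matrix(0, nrow = length(populations), ncol = m)
  for (k in seq_along(populations)) {
    calls <- g$calls[g$samples$population == populations[k], , drop = FALSE]
    nn <- colSums(!is.na(calls))
    n[k, ] <- nn
    p[k, ] <- ifelse(nn > 0, colSums(calls, na.rm = TRUE) / (2 * nn), 0)
    h[k, ] <- ifelse(nn > 0, colSums(calls == 1L, na.rm = TRUE) / nn, 0)
  }
  comp <- wc_components(n, p, h)
  out <- data.frame(snp = g$markers$id, chrom = g$markers$chrom,
                    pos = g$markers$pos, a = comp$a, b = comp$b, c = comp$c,
                    fst = comp$fst, retained = comp$retained,
                    stringsAsFactors = FALSE)
  out$z <- out$p <- NA_real_
  f <- out$fst[out$retained]
  s <- stats::sd(f)
  if (length(f) > 1 && !is.na(s) && s > 0) {
    out$z[out$retained] <- (f - mean(f)) / s
    out$p[out$retained] <- stats::pnorm(out$z[out$retained])
  }
  attr(out, "comparison") <- paste(populations, collapse = "-")
  out
}

#' Genome-wide mean FST (ratio of sums)
#'
#' `sum(a) / sum(a + b + c)` over retained SNPs — the weighted mean, which
#' is how genome-wide means are conventionally reported.
#'
#' @param track an FST track from [wc_fst].
#' @return Numeric scalar.
#' @export
fst_mean <- function(track) {
  t2 <- track[track$retained, , drop = FALSE]
  if (!nrow(t2)) stop("no retained SNPs in FST track", call. = FALSE)
  sum(t2$a) / sum(t2$a + t2$b + t2$c)
}

#' Top-fraction FST outliers (selection-signature candidates)
#'
#' Ranks retained SNPs by FST and returns the `ceiling(top_fraction * n)`
#' highest whose empirical p-value exceeds `1 - top_fraction`; ties are
#' broken by genome order.
#'
#' @param track an FST track from [wc_fst].
#' @param top_fraction reported tail fraction (0.001 = top 0.1%).
#' @return data.frame of significant SNPs (subset of the track rows), sorted
#'   by FST descending.
#' @export
fst_outliers <- function(track, top_fraction = 0.001) {
  t2 <- track[track$retained, , drop = FALSE]
  if (!nrow(t2) || all(is.na(t2$p))) {
    warning("degenerate FST distribution (sd = 0): no outliers", call. = FALSE)
    return(track[0, ])
  }
  k <- ceiling(top_fraction * nrow(t2))
  cand <- t2[!is.na(t2$p) & t2$p > 1 - top_fraction, , drop = FALSE]
  if (!nrow(cand)) return(track[0, ])
  ord <- order(-cand$fst, chrom_rank(cand$chrom), cand$pos)
  cand[ord[seq_len(min(k, nrow(cand)))], , drop = FALSE]
}

#' Manhattan-style export of an FST track
#'
#' Per-SNP table (`snp`, `chrom`, `pos`, `fst`, `p`) with negative estimates
#' floored at zero for plotting.
#'
#' @param track an FST track from [wc_fst].
#' @return data.frame.
#' @export
fst_manhattan <- function(track) {
  data.frame(snp = track$snp, chrom = track$chrom, pos = track$pos,
             fst = pmax(track$fst, 0), p = track$p, stringsAsFactors = FALSE)
}
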