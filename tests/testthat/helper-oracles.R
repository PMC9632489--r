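# Independent oracles, deliberately written as plain enumerations/loops so
# they share no code path with the package implementations they check.

# Brute-force ROH enumerator: every window and every candidate run is
# examined explicitly against all rules (window het/missing budget, overlap
# fraction, gap split, minimum SNPs, run-average density).
oracle_roh <- function(calls, pos, L, max_het = 0L, max_missing = 1L,
                       overlap = 0.05, max_gap = 1e6, min_snps = L,
                       max_density = 150000) {
  m <- length(calls)
  flags <- rep(FALSE, m)
  if (m >= L) {
    win_ok <- logical(m - L + 1L)
    for (s in seq_len(m - L + 1L)) {
      w <- calls[s:(s + L - 1L)]
      win_ok[s] <- sum(w == 1L, na.rm = TRUE) <= max_het &&
        sum(is.na(w)) <= max_missing
    }
    for (j in seq_len(m)) {
      covering <- seq(max(1L, j - L + 1L), min(j, m - L + 1L))
      flags[j] <- sum(win_ok[covering]) / length(covering) >= overlap
    }
  }
  segs <- list()
  j <- 1L
  while (j <= m) {
    if (!flags[j]) { j <- j + 1L; next }
    k <- j
    while (k < m && flags[k + 1L]) k <- k + 1L
    run <- j:k
    # split at large gaps
    piece <- run[1]
    pieces <- list()
    for (idx in run[-1]) {
      if (pos[idx] - pos[piece[length(piece)]] > max_gap) {
        pieces[[length(pieces) + 1L]] <- piece
        piece <- idx
      } else piece <- c(piece, idx)
    }
    pieces[[length(pieces) + 1L]] <- piece
    for (pc in pieces) {
      len <- pos[pc[length(pc)]] - pos[pc[1]]
      if (length(pc) >= min_snps && len / length(pc) <= max_density)
        segs[[length(segs) + 1L]] <-
          data.frame(start_bp = pos[pc[1]], end_bp = pos[pc[length(pc)]],
                     n_snps = length(pc), length_bp = as.numeric(len))
    }
    j <- k + 1L
  }
  if (length(segs)) do.call(rbind, segs) else
    data.frame(start_bp = integer(), end_bp = integer(),
               n_snps = integer(), length_bp = numeric())
}

# Closed-form exact HWE enumeration: multinomial probability of every
# heterozygote count compatible with the allele counts, via log-factorials.
oracle_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(NA_real_)
  rare <- 2L * min(n_aa, n_bb) + n_ab
  hets <- seq(rare %% 2L, rare, by = 2L)
  logp <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    lfactorial(n) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c) +
      h * log(2) + lfactorial(rare) + lfactorial(2 * n - rare) -
      lfactorial(2 * n)
  }, numeric(1))
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_ab, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

# Independent transcription of the Weir-Cockerham (1984) per-locus
# variance components, organised around explicit per-population loops.
oracle_wc <- function(counts) {
  counts <- as.matrix(counts)
  n_i <- rowSums(counts)
  keep <- n_i > 0
  counts <- counts[keep, , drop = FALSE]
  n_i <- n_i[keep]
  r <- nrow(counts)
  p_i <- (counts[, 2] + 2 * counts[, 3]) / (2 * n_i)
  h_i <- counts[, 2] / n_i
  n_bar <- 0; for (i in seq_len(r)) n_bar <- n_bar + n_i[i] / r
  sum_n <- sum(n_i)
  n_c <- (sum_n - sum(n_i^2) / sum_n) / (r - 1)
  p_bar <- 0; for (i in seq_len(r)) p_bar <- p_bar + n_i[i] * p_i[i] / sum_n
  s2 <- 0
  for (i in seq_len(r)) s2 <- s2 + n_i[i] * (p_i[i] - p_bar)^2 / ((r - 1) * n_bar)
  h_bar <- 0; for (i in seq_len(r)) h_bar <- h_bar + n_i[i] * h_i[i] / sum_n
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - s2 * (r - 1) / r - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - s2 * (r - 1) / r - h_bar * (2 * n_bar - 1) / (4 * n_bar))
  cc <- h_bar / 2
  list(a = a, b = b, c = cc,
       fst = if (a + b + cc != 0) a / (a + b + cc) else NA_real_)
}

# Brute-force flank lookup: scan every gene, closed intervals.
oracle_flank <- function(chrom, pos, genes, flank) {
  hits <- list()
  for (i in seq_len(nrow(genes))) {
    if (genes$chrom[i] != chrom) next
    d <- if (pos >= genes$start_bp[i] && pos <= genes$end_bp[i]) 0
         else min(abs(pos - genes$start_bp[i]), abs(pos - genes$end_bp[i]))
    if (d <= flank)
      hits[[length(hits) + 1L]] <- data.frame(name = genes$name[i], distance = d)
  }
  if (!length(hits)) return(character())
  df <- do.call(rbind, hits)
  df$name[order(df$distance)]
}
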