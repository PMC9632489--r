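# Sliding-window runs-of-homozygosity detection and genomic inbreeding
# (F_ROH). Window rule: a length-L SNP window is "homozygous" iff it holds
# no heterozygote and at most one missing call; a SNP enters a run iff at
# least a fraction `window_overlap_min` of the windows covering it are
# homozygous. Candidate runs are split at inter-SNP gaps > max_gap_bp and
# must hold >= min_snps_per_run SNPs at an average density of at least one
# SNP per min_density_bp_per_snp bp.

#' ROH-calling parameters
#'
#' @param alpha genome-wide chance-run probability used by [compute_L]
#'   (default 0.05).
#' @param window_overlap_min minimum fraction of homozygous windows covering
#'   a SNP for it to be flagged (0.05).
#' @param max_missing_per_window missing calls tolerated per window (1).
#' @param max_het_per_window heterozygous calls tolerated per window (0).
#' @param min_density_bp_per_snp run-average spacing ceiling: at least one
#'   SNP every this many bp (150,000).
#' @param max_gap_bp maximum gap between consecutive SNPs inside a run
#'   (1,000,000).
#' @param L window length in SNPs; `NULL` to compute from the data with
#'   [compute_L].
#' @param min_snps_per_run minimum SNPs per run; `NULL` means "equal to L".
#' @param min_L floor applied to the computed L (20).
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(alpha = 0.05, window_overlap_min = 0.05,
                       max_missing_per_window = 1L, max_het_per_window = 0L,
                       min_density_bp_per_snp = 150000L, max_gap_bp = 1000000L,
                       L = NULL, min_snps_per_run = NULL, min_L = 20L) {
  stopifnot(alpha > 0, window_overlap_min > 0, max_missing_per_window >= 0,
            max_het_per_window >= 0, min_density_bp_per_snp > 0,
            max_gap_bp > 0, min_L > 0)
  structure(list(alpha = alpha, window_overlap_min = window_overlap_min,
                 max_missing_per_window = as.integer(max_missing_per_window),
                 max_het_per_window = as.integer(max_het_per_window),
                 min_density_bp_per_snp = as.numeric(min_density_bp_per_snp),
                 max_gap_bp = as.numeric(max_gap_bp), L = L,
                 min_snps_per_run = min_snps_per_run,
                 min_L = as.integer(min_L)),
            class = "roh_params")
}

#' Minimum window length L for genome-wide chance-run control
#'
#' `L = ceil( ln(alpha / (n_snps * n_samples)) / ln(1 - mean_het) )`, the
#' window length at which a run of homozygous calls arising by chance
#' anywhere in the dataset has probability about `alpha`; a floor of
#' `min_L` SNPs is applied.
#'
#' @param n_snps number of markers in the dataset.
#' @param n_samples number of individuals.
#' @param mean_het mean heterozygosity per SNP (strictly inside (0, 1)).
#' @param alpha genome-wide false-run probability (0.05).
#' @param min_L floor (20).
#' @return Integer window length.
#' @export
compute_L <- function(n_snps, n_samples, mean_het, alpha = 0.05, min_L = 20L) {
  stopifnot(n_snps >= 1, n_samples >= 1)
  if (!is.finite(mean_het) || mean_het <= 0 || mean_het >= 1)
    stop("mean_het must lie strictly between 0 and 1", call. = FALSE)
  L <- ceiling(log(alpha / (n_snps * n_samples)) / log(1 - mean_het))
  max(as.integer(min_L), as.integer(L))
}

#' Per-SNP in-run flags for one individual on one chromosome
#'
#' Slides every length-`L` window over the calls; a SNP is flagged iff the
#' fraction of homozygous windows among those covering it reaches
#' `window_overlap_min`. Chromosomes with fewer than `L` SNPs yield no flags.
#'
#' @param calls integer vector of calls (0/1/2/NA) in map order.
#' @param L window length in SNPs.
#' @param max_het,max_missing per-window tolerances.
#' @param overlap_min flagging threshold on the covering-window fraction.
#' @return Logical vector of flags, one per SNP.
#' @export
window_scan <- function(calls, L, max_het = 0L, max_missing = 1L,
                        overlap_min = 0.05) {
  m <- length(calls)
  if (m < L) return(rep(FALSE, m))
  het <- as.integer(!is.na(calls) & calls == 1L)
  mis <- as.integer(is.na(calls))
  ch <- c(0L, cumsum(het))
  cm <- c(0L, cumsum(mis))
  nw <- m - L + 1L
  s <- seq_len(nw)
  hom_win <- (ch[s + L] - ch[s]) <= max_het & (cm[s + L] - cm[s]) <= max_missing
  cw <- c(0L, cumsum(as.integer(hom_win)))
  j <- seq_len(m)
  lo <- pmax(1L, j - L + 1L)   # first window start covering SNP j
  hi <- pmin(j, nw)            # last window start covering SNP j
  n_cover <- hi - lo + 1L
  n_hom <- cw[hi + 1L] - cw[lo]
  n_hom / n_cover >= overlap_min
}

roh_class_breaks <- c(0, 2e6, 4e6, 8e6, 16e6, Inf)
roh_class_labels <- c("1-2Mb", "2-4Mb", "4-8Mb", "8-16Mb", ">16Mb")

#' ROH length class
#'
#' Half-open classes `[<2, 2-4, 4-8, 8-16, >=16) Mb`. With an L-scale
#' minimum run length the first class holds the 1-2 Mb runs; degenerate
#' sub-1 Mb runs (possible only with permissive custom parameters) fall in
#' it too.
#'
#' @param length_bp run length(s) in bp.
#' @return Factor with levels `1-2Mb, 2-4Mb, 4-8Mb, 8-16Mb, >16Mb`.
#' @export
roh_length_class <- function(length_bp) {
  cut(length_bp, breaks = roh_class_breaks, labels = roh_class_labels,
      right = FALSE)
}

#' Assemble ROH segments from per-SNP flags
#'
#' Maximal runs of consecutive flagged SNPs are split at inter-SNP gaps
#' larger than `max_gap_bp`, then filtered to `n_snps >= min_snps` and
#' average density `length_bp / n_snps <= max_density` bp/SNP. Segment
#' length is `end_bp - start_bp` (positions of the first and last SNP).
#'
#' @param flags logical vector from [window_scan].
#' @param pos integer positions (same order).
#' @param max_gap_bp,min_snps,max_density run rules (see [roh_params]).
#' @return data.frame with `start_bp`, `end_bp`, `n_snps`, `length_bp`,
#'   `length_class` (possibly zero rows).
#' @export
assemble_segments <- function(flags, pos, max_gap_bp = 1e6, min_snps = 20L,
                              max_density = 150000) {
  empty <- data.frame(start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), length_bp = numeric(),
                      length_class = roh_length_class(numeric()))
  if (!any(flags)) return(empty)
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    # split at large gaps
    gaps <- diff(pos[idx])
    cut_pts <- which(gaps > max_gap_bp)
    grp <- cumsum(c(1L, as.integer(seq_along(gaps) %in% cut_pts)))
    for (piece in split(idx, grp)) {
      ns <- length(piece)
      len <- pos[piece[ns]] - pos[piece[1]]
      if (ns >= min_snps && len / ns <= max_density) {
        out[[length(out) + 1L]] <-
          data.frame(start_bp = pos[piece[1]], end_bp = pos[piece[ns]],
                     n_snps = ns, length_bp = as.numeric(len))
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res$length_class <- roh_length_class(res$length_bp)
  res
}

#' Call runs of homozygosity for every individual
#'
#' Runs [window_scan] and [assemble_segments] per individual and chromosome.
#' When `params$L` is `NULL`, L is computed once from the matrix via
#' [compute_L] using the overall heterozygote fraction among non-missing
#' calls; `min_snps_per_run` defaults to the same L.
#'
#' @param g a post-QC [genotypes] object (typically one breed).
#' @param params a [roh_params].
#' @return data.frame of segments: `sample_id`, `population`, `chrom`,
#'   `start_bp`, `end_bp`, `n_snps`, `length_bp`, `length_class`, with the
#'   L used stored in `attr(, "L")`.
#' @export
call_roh <- function(g, params = roh_params()) {
  L <- params$L
  if (is.null(L)) {
    mean_het <- mean(g$calls == 1L, na.rm = TRUE)
    L <- compute_L(n_markers(g), n_samples(g), mean_het,
                   alpha = params$alpha, min_L = params$min_L)
  }
  min_snps <- if (is.null(params$min_snps_per_run)) L else
    params$min_snps_per_run

  chroms <- unique(g$markers$chrom)
  out <- list()
  for (chr in chroms) {
    jdx <- which(g$markers$chrom == chr)
    pos <- g$markers$pos[jdx]
    for (i in seq_len(n_samples(g))) {
      flags <- window_scan(g$calls[i, jdx], L,
                           max_het = params$max_het_per_window,
                           max_missing = params$max_missing_per_window,
                           overlap_min = params$window_overlap_min)
      segs <- assemble_segments(flags, pos, max_gap_bp = params$max_gap_bp,
                                min_snps = min_snps,
                                max_density = params$min_density_bp_per_snp)
      if (nrow(segs)) {
        segs <- cbind(sample_id = g$samples$id[i],
                      population = g$samples$population[i],
                      chrom = chr, segs, stringsAsFactors = FALSE)
        out[[length(out) + 1L]] <- segs
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(), population = character(),
               chrom = character(), start_bp = integer(), end_bp = integer(),
               n_snps = integer(), length_bp = numeric(),
               length_class = roh_length_class(numeric()))
  rownames(res) <- NULL
  attr(res, "L") <- L
  res
}

#' Genomic inbreeding coefficient F_ROH per individual
#'
#' `froh_all` is the summed ROH length divided by `coverage_bp` (the
#' SNP-covered autosomal genome, [snp_coverage_bp]); per-length-class
#' coefficients use the same denominator and sum exactly to `froh_all`.
#' Individuals without segments get zeros, so pass the full sample table.
#'
#' @param segments a segment data.frame from [call_roh].
#' @param samples sample registry data.frame (`id`, `population`) covering
#'   every individual the segments were called on.
#' @param coverage_bp denominator in bp (must be > 0).
#' @return data.frame per sample: `sample_id`, `population`, `n_roh`,
#'   `sum_roh_kb`, `froh_all`, and one `froh_<class>` column per length
#'   class.
#' @export
froh <- function(segments, samples, coverage_bp) {
  if (is.null(coverage_bp) || coverage_bp <= 0)
    stop("coverage_bp must be positive", call. = FALSE)
  res <- data.frame(sample_id = samples$id, population = samples$population,
                    n_roh = 0L, sum_roh_kb = 0, froh_all = 0,
                    stringsAsFactors = FALSE)
  class_cols <- paste0("froh_", gsub("[->]", "", sub("Mb$", "", roh_class_labels)))
  for (cc in class_cols) res[[cc]] <- 0
  if (nrow(segments)) {
    i <- match(segments$sample_id, res$sample_id)
    if (anyNA(i))
      stop("segments refer to samples absent from the registry", call. = FALSE)
    res$n_roh <- as.integer(tabulate(i, nbins = nrow(res)))
    tot <- tapply(segments$length_bp, factor(i, levels = seq_len(nrow(res))),
                  sum, default = 0)
    res$sum_roh_kb <- as.numeric(tot) / 1000
    res$froh_all <- as.numeric(tot) / coverage_bp
    for (k in seq_along(roh_class_labels)) {
      sel <- segments$length_class == roh_class_labels[k]
      cls <- tapply(segments$length_bp[sel],
                    factor(i[sel], levels = seq_len(nrow(res))),
                    sum, default = 0)
      res[[class_cols[k]]] <- as.numeric(cls) / coverage_bp
    }
  }
  res
}
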