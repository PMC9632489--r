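# ROH incidence and island calling. Incidence is the percentage of a
# breed's individuals whose ROH cover a SNP; islands are contiguous SNPs in
# the extreme upper tail of the breed's incidence distribution (normal
# z-score p above a threshold) that also clear an absolute incidence floor.

#' Per-SNP ROH incidence within one breed
#'
#' A SNP counts as covered for an individual iff its position lies inside
#' `[start_bp, end_bp]` of any of that individual's segments. The z-score
#' and p-value (`p = Phi(z)`) are computed over all SNPs of the breed's map;
#' with a degenerate (constant) incidence track they are `NA`.
#'
#' @param segments segment data.frame from [call_roh] for the breed.
#' @param markers the breed's post-QC marker map (`id`, `chrom`, `pos`).
#' @param sample_ids ids of every individual in the breed (the denominator;
#'   individuals without ROH count too).
#' @return data.frame per SNP: `snp`, `chrom`, `pos`, `incidence_pct`, `z`,
#'   `p`.
#' @export
roh_incidence <- function(segments, markers, sample_ids) {
  n <- length(sample_ids)
  if (n == 0) stop("empty breed: no individuals", call. = FALSE)
  counts <- numeric(nrow(markers))
  chroms <- unique(markers$chrom)
  chr_idx <- lapply(chroms, function(ch) which(markers$chrom == ch))
  names(chr_idx) <- chroms
  for (sid in sample_ids) {
    segs <- segments[segments$sample_id == sid, , drop = FALSE]
    if (!nrow(segs)) next
    covered <- logical(nrow(markers))
    for (k in seq_len(nrow(segs))) {
      jdx <- chr_idx[[as.character(segs$chrom[k])]]
      if (is.null(jdx)) next
      pos <- markers$pos[jdx]
      hit <- jdx[pos >= segs$start_bp[k] & pos <= segs$end_bp[k]]
      covered[hit] <- TRUE
    }
    counts <- counts + covered
  }
  inc <- 100 * counts / n
  s <- stats::sd(inc)
  if (is.na(s) || s == 0) {
    z <- p <- rep(NA_real_, length(inc))
  } else {
    z <- (inc - mean(inc)) / s
    p <- stats::pnorm(z)
  }
  data.frame(snp = markers$id, chrom = markers$chrom, pos = markers$pos,
             incidence_pct = inc, z = z, p = p, stringsAsFactors = FALSE)
}

#' Call ROH islands from an incidence track
#'
#' A SNP is an island member iff `p > p_min` and `incidence_pct >=
#' incidence_floor_pct`. Adjacent members on a chromosome are merged into
#' one island when separated by at most `max_gap_bp`. If no SNP passes and a
#' `fallback` is supplied (list with `p_min` and/or `incidence_min_pct`,
#' applied with `>=`), the fallback rule is used instead and the calls are
#' flagged `fallback = TRUE` — the relaxation used for a breed so inbred
#' that no SNP clears the primary threshold.
#'
#' @param track incidence track from [roh_incidence].
#' @param p_min primary z-score p threshold (0.999, i.e. the top 0.1% of a
#'   normal incidence distribution).
#' @param incidence_floor_pct population floor: an island SNP must sit in
#'   ROH in at least this percentage of the breed (30).
#' @param max_gap_bp merge tolerance between member SNPs (1,000,000).
#' @param fallback `NULL`, or e.g. `list(p_min = 0.998, incidence_min_pct =
#'   55)`.
#' @return data.frame of islands: `chrom`, `start_bp`, `end_bp`,
#'   `n_member_snps`, `peak_snp`, `peak_incidence_pct`, `fallback`; plus
#'   attribute `"members"` with the member SNP table.
#' @export
call_islands <- function(track, p_min = 0.999, incidence_floor_pct = 30,
                         max_gap_bp = 1e6, fallback = NULL) {
  empty <- data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), n_member_snps = integer(),
                      peak_snp = character(), peak_incidence_pct = numeric(),
                      fallback = logical(), stringsAsFactors = FALSE)
  if (all(is.na(track$p))) {
    warning("constant incidence track (sd = 0): no islands callable",
            call. = FALSE)
    attr(empty, "members") <- track[0, ]
    return(empty)
  }
  member <- !is.na(track$p) & track$p > p_min &
    track$incidence_pct >= incidence_floor_pct
  used_fallback <- FALSE
  if (!any(member) && !is.null(fallback)) {
    fb_p <- if (!is.null(fallback$p_min)) fallback$p_min else p_min
    fb_inc <- if (!is.null(fallback$incidence_min_pct))
      fallback$incidence_min_pct else incidence_floor_pct
    member <- !is.na(track$p) & track$p >= fb_p & track$incidence_pct >= fb_inc
    used_fallback <- TRUE
  }
  if (!any(member)) {
    attr(empty, "members") <- track[0, ]
    return(empty)
  }

  mem <- track[member, , drop = FALSE]
  mem <- mem[order(chrom_rank(mem$chrom), mem$pos), , drop = FALSE]
  new_island <- c(TRUE, mem$chrom[-1] != mem$chrom[-nrow(mem)] |
                    diff(mem$pos) > max_gap_bp)
  grp <- cumsum(new_island)
  out <- lapply(split(seq_len(nrow(mem)), grp), function(ii) {
    sub <- mem[ii, , drop = FALSE]
    # peak = central member of the maximal-incidence plateau (shared ROH
    # cores produce flat-topped incidence profiles; the middle of the
    # plateau is the stable representative)
    tied <- which(sub$incidence_pct == max(sub$incidence_pct))
    peak <- tied[ceiling(length(tied) / 2)]
    data.frame(chrom = sub$chrom[1], start_bp = min(sub$pos),
               end_bp = max(sub$pos), n_member_snps = nrow(sub),
               peak_snp = sub$snp[peak],
               peak_incidence_pct = sub$incidence_pct[peak],
               fallback = used_fallback, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  mem$fallback <- used_fallback
  attr(res, "members") <- mem
  res
}
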