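# Observed heterozygosity and its relationship with genomic inbreeding.

#' Observed heterozygosity per individual
#'
#' `Ho = (non-missing - homozygous) / non-missing`, i.e. the heterozygote
#' fraction among an individual's called genotypes; `NA` for all-missing
#' individuals.
#'
#' @param g a [genotypes] object.
#' @return data.frame: `sample_id`, `population`, `ho`, `n_called`.
#' @export
observed_het <- function(g) {
  called <- rowSums(!is.na(g$calls))
  het <- rowSums(g$calls == 1L, na.rm = TRUE)
  data.frame(sample_id = g$samples$id, population = g$samples$population,
             ho = ifelse(called > 0, het / called, NA_real_),
             n_called = called, stringsAsFactors = FALSE)
}

#' Breed means of observed heterozygosity
#'
#' @param div per-individual table from [observed_het].
#' @return data.frame: `population`, `mean_ho`, `n`.
#' @export
diversity_summary <- function(div) {
  agg <- stats::aggregate(ho ~ population, data = div, FUN = mean)
  n <- stats::aggregate(ho ~ population, data = div, FUN = length)
  data.frame(population = agg$population, mean_ho = agg$ho, n = n$ho,
             stringsAsFactors = FALSE)
}

#' Pearson correlation between heterozygosity and genomic inbreeding
#'
#' Pairs each individual's `ho` with its `froh_all` (across breeds) and
#' returns the Pearson r with its two-sided t-test p-value.
#'
#' @param div table from [observed_het].
#' @param froh_tab table from [froh].
#' @return list `(r, p, n, data)`; `data` is the paired per-sample table.
#' @export
ho_froh_correlation <- function(div, froh_tab) {
  merged <- merge(div[, c("sample_id", "population", "ho")],
                  froh_tab[, c("sample_id", "froh_all")], by = "sample_id")
  merged <- merged[stats::complete.cases(merged[, c("ho", "froh_all")]), ]
  if (nrow(merged) < 3)
    stop("need at least 3 paired samples for the correlation", call. = FALSE)
  if (stats::var(merged$ho) == 0 || stats::var(merged$froh_all) == 0)
    stop("zero variance in Ho or F_ROH: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(merged$ho, merged$froh_all, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(merged),
       data = merged)
}
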