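#' SNP-array genotype container
#'
#' A `genotypes` object holds a samples x markers matrix of biallelic calls
#' coded `0` (homozygous for `allele_a`), `1` (heterozygous), `2` (homozygous
#' for `allele_b`) and `NA` (missing), together with a sample registry
#' (`id`, `population`) and a marker map (`id`, `chrom`, `pos`, `allele_a`,
#' `allele_b`). Markers are kept sorted by (chromosome, position) and the
#' call matrix columns follow the map; positions are 1-based.
#'
#' @param calls integer matrix, samples in rows, markers in columns; values
#'   in `{0, 1, 2, NA}`.
#' @param samples data.frame with columns `id` (unique) and `population`.
#' @param markers data.frame with columns `id` (unique), `chrom` (character),
#'   `pos` (integer >= 1), `allele_a`, `allele_b`.
#' @param autosomes character vector of retained chromosome labels, or `NULL`
#'   to keep every chromosome. Markers on other chromosomes (unmapped "0",
#'   sex chromosomes, mitochondrion) are dropped with a message, as is
#'   standard for autosomal ROH/FST work. Default: pig autosomes `"1".."18"`.
#' @return An object of class `genotypes`.
#' @export
genotypes <- function(calls, samples, markers,
                      autosomes = as.character(1:18)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)

  stopifnot(all(c("id", "population") %in% names(samples)),
            all(c("id", "chrom", "pos") %in% names(markers)))
  if (is.null(markers$allele_a)) markers$allele_a <- "A"
  if (is.null(markers$allele_b)) markers$allele_b <- "B"
  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.integer(markers$pos)

  if (nrow(calls) != nrow(samples) || ncol(calls) != nrow(markers))
    stop("call matrix dimensions do not match the sample/marker registries",
         call. = FALSE)
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype calls must be 0, 1, 2 or NA", call. = FALSE)
  if (anyDuplicated(samples$id))
    stop("sample ids must be unique", call. = FALSE)
  if (anyDuplicated(markers$id))
    stop("marker ids must be unique", call. = FALSE)
  if (any(!is.na(markers$pos) & markers$pos < 1L))
    stop("marker positions must be >= 1", call. = FALSE)

  if (!is.null(autosomes)) {
    keep <- markers$chrom %in% autosomes
    if (any(!keep)) {
      message(sum(!keep), " non-autosomal/unmapped marker(s) dropped; ",
              sum(keep), " retained")
      markers <- markers[keep, , drop = FALSE]
      calls <- calls[, keep, drop = FALSE]
    }
  }

  ord <- order(chrom_rank(markers$chrom), markers$pos)
  markers <- markers[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  if (anyDuplicated(markers[, c("chrom", "pos")]))
    stop("duplicate (chromosome, position) pairs in marker map", call. = FALSE)
  rownames(markers) <- NULL
  rownames(samples) <- NULL
  dimnames(calls) <- list(samples$id, markers$id)

  structure(list(calls = calls, samples = samples, markers = markers),
            class = "genotypes")
}

# numeric-aware chromosome ordering ("2" before "10", letters after numbers)
chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  lev <- unique(chrom[order(is.na(num), num, chrom)])
  match(chrom, lev)
}

#' @export
print.genotypes <- function(x, ...) {
  cat("genotypes: ", nrow(x$samples), " samples x ", nrow(x$markers),
      " markers on ", length(unique(x$markers$chrom)), " chromosome(s)\n",
      sep = "")
  tab <- table(x$samples$population)
  cat("populations:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotypes <- function(x) c(nrow(x$samples), nrow(x$markers))

#' Subset a genotypes object
#'
#' `i` selects samples, `j` selects markers; either may be an index vector,
#' a logical vector or a character vector of ids.
#'
#' @param x a [genotypes] object.
#' @param i,j sample / marker selectors.
#' @param ... unused.
#' @return A `genotypes` object (registries subset accordingly).
#' @export
`[.genotypes` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$samples))
  if (missing(j)) j <- seq_len(nrow(x$markers))
  if (is.character(i)) i <- match(i, x$samples$id)
  if (is.character(j)) j <- match(j, x$markers$id)
  out <- list(calls = x$calls[i, j, drop = FALSE],
              samples = x$samples[i, , drop = FALSE],
              markers = x$markers[j, , drop = FALSE])
  rownames(out$samples) <- NULL
  rownames(out$markers) <- NULL
  class(out) <- "genotypes"
  out
}

#' Number of samples / markers
#' @param g a [genotypes] object.
#' @return Integer count.
#' @export
n_samples <- function(g) nrow(g$samples)

#' @rdname n_samples
#' @export
n_markers <- function(g) nrow(g$markers)

#' Attach population labels from a two-column assignment table
#'
#' @param g a [genotypes] object.
#' @param pops data.frame with columns `id` and `population` (extra samples
#'   in the table are ignored; samples absent from it keep their label).
#' @return `g` with updated population labels.
#' @export
assign_populations <- function(g, pops) {
  m <- match(g$samples$id, pops$id)
  hit <- !is.na(m)
  g$samples$population[hit] <- as.character(pops$population[m[hit]])
  g
}

#' Per-chromosome SNP coverage of the map
#'
#' Sum over chromosomes of (last SNP position - first SNP position), the
#' denominator used for F_ROH ("autosomal genome coverage expressed by SNPs").
#'
#' @param markers a marker map data.frame (`chrom`, `pos`).
#' @return Coverage in base pairs (numeric scalar).
#' @export
snp_coverage_bp <- function(markers) {
  spans <- tapply(markers$pos, markers$chrom,
                  function(p) max(p) - min(p))
  sum(as.numeric(spans))
}
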