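# Candidate-gene lookup: genes whose interval intersects a flank around a
# significant SNP, and report tables combining FST outliers and ROH-island
# members with their genes.

#' Genes within a flank of a SNP
#'
#' Returns every gene whose 1-based inclusive `[start_bp, end_bp]` interval
#' intersects `[pos - flank_bp, pos + flank_bp]` (closed on both ends: a
#' gene ending exactly `flank_bp` away is a hit). Results are ordered by
#' distance (0 for genes containing the SNP), ties by genome order.
#'
#' @param chrom,pos SNP coordinates (same coordinate system as the genes).
#' @param genes gene table from [read_gene_annotation].
#' @param flank_bp flank on either side (100,000).
#' @return data.frame: `name`, `chrom`, `start_bp`, `end_bp`, `distance_bp`
#'   (possibly zero rows).
#' @export
flank_genes <- function(chrom, pos, genes, flank_bp = 100000) {
  hit <- genes$chrom == as.character(chrom) &
    genes$start_bp <= pos + flank_bp & genes$end_bp >= pos - flank_bp
  out <- genes[hit, , drop = FALSE]
  out$distance_bp <- pmax(out$start_bp - pos, pos - out$end_bp, 0)
  out <- out[order(out$distance_bp, out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

collapse_genes <- function(chrom, pos, genes, flank_bp) {
  vapply(seq_along(pos), function(i) {
    paste(flank_genes(chrom[i], pos[i], genes, flank_bp)$name, collapse = ", ")
  }, character(1))
}

#' Gene-annotated report tables for FST outliers and ROH islands
#'
#' Builds the two summary tables of a selection-signature report: per-SNP
#' rows (comparison or breed, chromosome, SNP, position, statistic, genes)
#' sorted by statistic descending. SNPs significant in more than one
#' pairwise FST comparison get a shared-SNP label (letters, in order of
#' appearance). SNPs with no gene within the flank are dropped from the
#' gene tables but kept in the raw significant-SNP tables.
#'
#' @param fst_sig named list of outlier tables from [fst_outliers] (names =
#'   comparison labels), or `NULL`.
#' @param island_members named list of island member-SNP tables (the
#'   `"members"` attribute of [call_islands]; names = breeds), or `NULL`.
#' @param genes gene table from [read_gene_annotation].
#' @param flank_bp flank on either side (100,000).
#' @return list `(fst_genes, fst_raw, island_genes, island_raw)` of
#'   data.frames.
#' @export
annotate_tables <- function(fst_sig = NULL, island_members = NULL, genes,
                            flank_bp = 100000) {
  fst_raw <- fst_genes <- island_raw <- island_genes <- NULL

  if (!is.null(fst_sig) && length(fst_sig)) {
    rows <- lapply(names(fst_sig), function(cmp) {
      t <- fst_sig[[cmp]]
      if (!nrow(t)) return(NULL)
      data.frame(comparison = cmp, chrom = t$chrom, snp = t$snp, pos = t$pos,
                 fst = t$fst, stringsAsFactors = FALSE)
    })
    fst_raw <- do.call(rbind, rows)
    if (!is.null(fst_raw) && nrow(fst_raw)) {
      shared <- names(which(table(unique(
        fst_raw[, c("comparison", "snp")])$snp) > 1))
      lab <- stats::setNames(letters[seq_along(shared)], shared)
      fst_raw$shared <- ifelse(fst_raw$snp %in% shared, lab[fst_raw$snp], "")
      fst_raw <- fst_raw[order(fst_raw$comparison, -fst_raw$fst), ]
      rownames(fst_raw) <- NULL
      fst_raw$genes <- collapse_genes(fst_raw$chrom, fst_raw$pos, genes,
                                      flank_bp)
      fst_genes <- fst_raw[nzchar(fst_raw$genes), , drop = FALSE]
      rownames(fst_genes) <- NULL
    }
  }

  if (!is.null(island_members) && length(island_members)) {
    rows <- lapply(names(island_members), function(br) {
      t <- island_members[[br]]
      if (is.null(t) || !nrow(t)) return(NULL)
      data.frame(breed = br, chrom = t$chrom, snp = t$snp, pos = t$pos,
                 incidence_pct = t$incidence_pct, stringsAsFactors = FALSE)
    })
    island_raw <- do.call(rbind, rows)
    if (!is.null(island_raw) && nrow(island_raw)) {
      island_raw <- island_raw[order(island_raw$breed,
                                     -island_raw$incidence_pct), ]
      rownames(island_raw) <- NULL
      island_raw$genes <- collapse_genes(island_raw$chrom, island_raw$pos,
                                         genes, flank_bp)
      island_genes <- island_raw[nzchar(island_raw$genes), , drop = FALSE]
      rownames(island_genes) <- NULL
    }
  }

  empty <- function() data.frame()
  list(fst_genes = if (is.null(fst_genes)) empty() else fst_genes,
       fst_raw = if (is.null(fst_raw)) empty() else fst_raw,
       island_genes = if (is.null(island_genes)) empty() else island_genes,
       island_raw = if (is.null(island_raw)) empty() else island_raw)
}
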