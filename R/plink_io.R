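# PLINK text (PED/MAP) and binary (BED/BIM/FAM) readers and writers.
# Coordinates are 1-based throughout; the BED 2-bit alphabet is
# 00 = hom allele_a, 10 = het, 11 = hom allele_b, 01 = missing (SNP-major).

# lookup table: byte value (0..255) -> 4 genotype codes, low bits first
.bed_decode_lut <- local({
  codes <- c(0L, NA_integer_, 1L, 2L)   # bit pairs 00, 01, 10, 11
  lut <- matrix(NA_integer_, nrow = 4, ncol = 256)
  for (b in 0:255)
    for (k in 0:3)
      lut[k + 1L, b + 1L] <- codes[bitwAnd(bitwShiftR(b, 2L * k), 3L) + 1L]
  lut
})

#' Read a PLINK binary fileset (BED/BIM/FAM)
#'
#' Verifies the BED magic bytes (0x6c, 0x1b) and SNP-major flag (0x01),
#' checks the payload size against the BIM/FAM line counts, decodes the
#' 2-bit genotype codes, and returns a [genotypes] object with markers
#' sorted by (chromosome, position); call columns are permuted along with
#' any re-sorting of an out-of-order BIM.
#'
#' @param prefix path prefix (`prefix.bed/.bim/.fam`), or give all three
#'   paths explicitly.
#' @param bed_path,bim_path,fam_path explicit file paths (override `prefix`).
#' @param autosomes retained chromosome labels (see [genotypes]).
#' @return A [genotypes] object.
#' @export
read_plink_binary <- function(prefix = NULL, bed_path = NULL, bim_path = NULL,
                              fam_path = NULL, autosomes = as.character(1:18)) {
  if (!is.null(prefix)) {
    if (is.null(bed_path)) bed_path <- paste0(prefix, ".bed")
    if (is.null(bim_path)) bim_path <- paste0(prefix, ".bim")
    if (is.null(fam_path)) fam_path <- paste0(prefix, ".fam")
  }
  for (f in c(bed_path, bim_path, fam_path))
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)

  bim <- utils::read.table(bim_path, colClasses = "character")
  names(bim) <- c("chrom", "id", "cm", "pos", "allele_a", "allele_b")[seq_len(ncol(bim))]
  fam <- utils::read.table(fam_path, colClasses = "character")
  n <- nrow(fam); m <- nrow(bim)

  raw <- readBin(bed_path, what = "raw", n = file.size(bed_path))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK BED file (bad magic number): ", bed_path, call. = FALSE)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major PLINK BED files are supported", call. = FALSE)
  bpc <- ceiling(n / 4)                    # bytes per SNP column
  if (length(raw) - 3L != bpc * m)
    stop("BED payload size does not match BIM/FAM dimensions", call. = FALSE)

  vals <- .bed_decode_lut[, as.integer(raw[-(1:3)]) + 1L]
  dim(vals) <- c(4L * bpc, m)        # rows: within-column sample slots
  calls <- vals[seq_len(n), , drop = FALSE]

  samples <- data.frame(id = fam[[2]],
                        population = if (ncol(fam) >= 1) fam[[1]] else "pop",
                        stringsAsFactors = FALSE)
  markers <- data.frame(id = bim$id, chrom = bim$chrom,
                        pos = as.integer(bim$pos),
                        allele_a = bim$allele_a, allele_b = bim$allele_b,
                        stringsAsFactors = FALSE)
  genotypes(calls, samples, markers, autosomes = autosomes)
}

#' Write a PLINK binary fileset (BED/BIM/FAM)
#'
#' @param g a [genotypes] object.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink_binary <- function(g, prefix) {
  n <- n_samples(g); m <- n_markers(g)
  # code -> bit pair: 0->00, 1->10, 2->11, NA->01
  bits <- matrix(1L, nrow = n, ncol = m)
  ok <- !is.na(g$calls)
  bits[ok] <- c(0L, 2L, 3L)[g$calls[ok] + 1L]
  bpc <- ceiling(n / 4)
  pad <- matrix(0L, nrow = 4L * bpc - n, ncol = m)
  bits <- rbind(bits, pad)
  dim(bits) <- c(4L, bpc * m)
  bytes <- as.raw(bits[1, ] + 4L * bits[2, ] + 16L * bits[3, ] + 64L * bits[4, ])
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(bytes, con)

  bim <- data.frame(g$markers$chrom, g$markers$id, 0L, g$markers$pos,
                    g$markers$allele_a, g$markers$allele_b)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(g$samples$population, g$samples$id, 0L, 0L, 0L, -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a PLINK text fileset (PED/MAP)
#'
#' Allele pairs are unordered (`"T A"` and `"A T"` give the same call) and
#' `"0 0"` is missing. The MAP file carries no allele columns, so
#' `allele_a`/`allele_b` are assigned alphabetically from the alleles
#' observed at each marker (`allele_b = "0"` when monomorphic).
#'
#' @param ped_path,map_path file paths.
#' @param autosomes retained chromosome labels (see [genotypes]).
#' @return A [genotypes] object.
#' @export
read_plink_text <- function(ped_path, map_path,
                            autosomes = as.character(1:18)) {
  map <- utils::read.table(map_path, colClasses = "character")
  names(map) <- c("chrom", "id", "cm", "pos")[seq_len(ncol(map))]
  m <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  len <- lengths(toks)
  if (length(unique(len)) > 1L || (length(len) && len[1] != 6L + 2L * m))
    stop("ragged or mis-sized PED lines (expected ", 6L + 2L * m,
         " fields)", call. = FALSE)
  tok <- matrix(unlist(toks), nrow = length(toks), byrow = TRUE)

  n <- nrow(tok)
  al1 <- tok[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  al2 <- tok[, 6L + 2L * seq_len(m), drop = FALSE]
  calls <- matrix(NA_integer_, n, m)
  allele_a <- allele_b <- character(m)
  for (j in seq_len(m)) {
    a <- al1[, j]; b <- al2[, j]
    obs <- sort(setdiff(unique(c(a, b)), "0"))
    if (length(obs) > 2L)
      stop("marker ", map$id[j], " has more than two alleles", call. = FALSE)
    allele_a[j] <- if (length(obs) >= 1) obs[1] else "0"
    allele_b[j] <- if (length(obs) == 2) obs[2] else "0"
    miss <- a == "0" | b == "0"
    calls[!miss, j] <- (a[!miss] == allele_b[j]) + (b[!miss] == allele_b[j])
  }

  samples <- data.frame(id = tok[, 2], population = tok[, 1],
                        stringsAsFactors = FALSE)
  markers <- data.frame(id = map$id, chrom = map$chrom,
                        pos = as.integer(map$pos),
                        allele_a = allele_a, allele_b = allele_b,
                        stringsAsFactors = FALSE)
  genotypes(calls, samples, markers, autosomes = autosomes)
}

#' Write a PLINK text fileset (PED/MAP)
#'
#' @param g a [genotypes] object.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink_text <- function(g, prefix) {
  n <- n_samples(g); m <- n_markers(g)
  a1 <- g$markers$allele_a; a2 <- g$markers$allele_b
  first <- second <- matrix("0", n, m)
  for (j in seq_len(m)) {
    cj <- g$calls[, j]
    first[, j] <- ifelse(is.na(cj), "0", ifelse(cj <= 1L, a1[j], a2[j]))
    second[, j] <- ifelse(is.na(cj), "0", ifelse(cj >= 1L, a2[j], a1[j]))
  }
  geno <- matrix("", n, 2L * m)
  geno[, 2L * seq_len(m) - 1L] <- first
  geno[, 2L * seq_len(m)] <- second
  ped <- cbind(g$samples$population, g$samples$id, "0", "0", "0", "-9", geno)
  utils::write.table(ped, paste0(prefix, ".ped"), quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  map <- data.frame(g$markers$chrom, g$markers$id, 0L, g$markers$pos)
  utils::write.table(map, paste0(prefix, ".map"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a two-column sample-to-population assignment file
#'
#' @param path whitespace-delimited text file with columns sample id and
#'   population label (no header).
#' @return data.frame with columns `id`, `population`.
#' @export
read_population_file <- function(path) {
  df <- utils::read.table(path, colClasses = "character")
  if (ncol(df) < 2L)
    stop("population file needs two columns: sample_id, population",
         call. = FALSE)
  data.frame(id = df[[1]], population = df[[2]], stringsAsFactors = FALSE)
}

#' Read a gene annotation file (BED4 or GFF3)
#'
#' Records are normalised to 1-based inclusive coordinates: BED input
#' (0-based half-open) is shifted on read, GFF3 is taken as is. GFF3 rows
#' are restricted to `type == "gene"` when a type column is present, and
#' the gene name is taken from the first available of `Name`, `gene_name`,
#' `gene_id`, `ID`.
#'
#' @param path file path.
#' @param format `"bed"` or `"gff3"`.
#' @return data.frame with columns `name`, `chrom`, `start_bp`, `end_bp`.
#' @export
read_gene_annotation <- function(path, format = c("bed", "gff3")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown annotation format: ",
                                              format[1], call. = FALSE))
  empty <- data.frame(name = character(), chrom = character(),
                      start_bp = integer(), end_bp = integer(),
                      stringsAsFactors = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(lines) & !startsWith(lines, "#"))) return(empty)

  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  df <- as.data.frame(gr)
  if (format == "gff3" && "type" %in% names(df) && any(df$type == "gene"))
    df <- df[df$type == "gene", , drop = FALSE]
  if (nrow(df) == 0) return(empty)

  nm <- rep(NA_character_, nrow(df))
  for (col in c("name", "Name", "gene_name", "gene_id", "ID"))
    if (col %in% names(df))
      nm <- ifelse(is.na(nm) & !is.na(df[[col]]), as.character(df[[col]]), nm)
  nm[is.na(nm)] <- paste0("gene_", seq_len(nrow(df)))[is.na(nm)]

  out <- data.frame(name = nm, chrom = sub("^chr", "", as.character(df$seqnames)),
                    start_bp = as.integer(df$start), end_bp = as.integer(df$end),
                    stringsAsFactors = FALSE)
  if (any(out$start_bp > out$end_bp))
    stop("gene record with start > end in ", path, call. = FALSE)
  rownames(out) <- NULL
  out
}
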