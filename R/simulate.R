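# Multi-breed SNP-array cohort simulator with known truth. Population
# divergence follows the Balding-Nichols model (per-population allele
# frequencies Beta-distributed around an ancestral frequency, parameterised
# by F). Autozygosity is planted haplotype-free: a tract is overwritten
# with one doubled haplotype sampled from the population frequencies, which
# gives exact control of each individual's true F_ROH at chip scale.
# Island loci give each carrier the full island core plus individually
# varying flanking extent (an island is the shared core of longer ROH), and
# outlier loci receive deterministic contrasting per-population frequencies
# whose parametric Weir-Cockerham theta equals the requested F (a
# Balding-Nichols draw at high F is bimodal — both populations often drift
# to the same boundary — and cannot serve as a per-locus planted truth).

#' Simulation configuration
#'
#' Defaults emulate a three-breed Mangalitsa-style cohort: 23/24/30
#' individuals, 18 autosomes of 126 Mb (~2.27 Gb genome), 36,000 SNPs,
#' ancestral MAF uniform on \[0.05, 0.5\], per-breed Balding-Nichols F of
#' 0.033/0.025/0.157 (pairwise divergence ~0.029/0.091/0.095), per-breed
#' F_ROH targets of 24.1/16.3/20.8% built from 2-24 Mb tracts, one planted
#' ROH island per breed (carrier fractions 0.65/0.50/0.80) and 1%
#' missingness.
#'
#' @param seed integer; fully determines the cohort, truth and file bytes.
#' @param pop_names,n_per_pop population labels and sizes.
#' @param n_chrom,chrom_length_bp autosome count and (common) length.
#' @param n_snps total marker count, spread evenly over chromosomes on a
#'   jittered grid (spacing +/- 30%).
#' @param maf_range ancestral minor-allele-frequency range (uniform).
#' @param divergence_F per-population Balding-Nichols F (0 = identical to
#'   the ancestral pool; must be < 1).
#' @param froh_target,froh_sd per-population mean and SD of the planted
#'   per-individual autozygous genome fraction; `froh_target = 0` plants
#'   nothing.
#' @param tract_length_range planted tract length range in bp (uniform).
#' @param planted_islands `"default"` (one island per breed as above), a
#'   data.frame with columns `population`, `chrom`, `start_bp`, `end_bp`,
#'   `carrier_fraction`, or `NULL` for none. Every carrier is made
#'   autozygous over the full core interval and additionally over a
#'   per-carrier flanking extension on each side (below), so the island is
#'   the shared core of individually longer runs — the way selective-sweep
#'   islands arise in real data.
#' @param island_ext_bp range (uniform) of the per-carrier, per-side
#'   flanking extension beyond the island core, in bp.
#' @param n_outlier_loci,outlier_F number of planted high-divergence loci
#'   and their parametric FST (loci sampled over the map).
#' @param missing_rate,genotype_error_rate per-call rates applied last
#'   (errors reassign a call to one of the other two codes).
#' @param gap_stress drop the markers inside two 1.5 Mb windows per
#'   chromosome, creating >1 Mb map gaps that exercise the ROH gap rule.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       pop_names = c("BM", "RM", "SM"),
                       n_per_pop = c(23L, 24L, 30L),
                       n_chrom = 18L,
                       chrom_length_bp = 126e6,
                       n_snps = 36000L,
                       maf_range = c(0.05, 0.5),
                       divergence_F = c(0.033, 0.025, 0.157),
                       froh_target = c(0.2411, 0.1634, 0.2082),
                       froh_sd = 0.04,
                       tract_length_range = c(2e6, 24e6),
                       planted_islands = "default",
                       island_ext_bp = c(0, 3e6),
                       n_outlier_loci = 0L,
                       outlier_F = 0.5,
                       missing_rate = 0.01,
                       genotype_error_rate = 0,
                       gap_stress = FALSE) {
  k <- length(pop_names)
  stopifnot(length(n_per_pop) == k, all(n_per_pop >= 1),
            n_chrom >= 1, chrom_length_bp > 0, n_snps >= n_chrom,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            missing_rate >= 0, missing_rate < 1,
            genotype_error_rate >= 0, genotype_error_rate < 1)
  divergence_F <- rep_len(divergence_F, k)
  froh_target <- rep_len(froh_target, k)
  if (any(divergence_F < 0) || any(divergence_F >= 1))
    stop("divergence_F must lie in [0, 1)", call. = FALSE)
  if (identical(planted_islands, "default")) {
    planted_islands <- data.frame(
      population = pop_names,
      chrom = as.character(rep_len(c("16", "15", "17"), k)),
      start_bp = rep_len(c(20.5e6, 114e6, 24e6), k),
      end_bp = rep_len(c(22.5e6, 116e6, 26e6), k),
      carrier_fraction = rep_len(c(0.65, 0.50, 0.80), k),
      stringsAsFactors = FALSE)
    planted_islands <- planted_islands[
      planted_islands$chrom %in% as.character(seq_len(n_chrom)) &
        planted_islands$end_bp <= chrom_length_bp, , drop = FALSE]
  }
  if (!is.null(planted_islands)) {
    stopifnot(all(planted_islands$carrier_fraction >= 0),
              all(planted_islands$carrier_fraction <= 1),
              all(planted_islands$start_bp >= 1),
              all(planted_islands$end_bp <= chrom_length_bp))
  }
  structure(list(seed = as.integer(seed), pop_names = pop_names,
                 n_per_pop = as.integer(n_per_pop), n_chrom = as.integer(n_chrom),
                 chrom_length_bp = as.numeric(chrom_length_bp),
                 n_snps = as.integer(n_snps), maf_range = maf_range,
                 divergence_F = divergence_F, froh_target = froh_target,
                 froh_sd = froh_sd, tract_length_range = tract_length_range,
                 planted_islands = planted_islands,
                 island_ext_bp = island_ext_bp,
                 n_outlier_loci = as.integer(n_outlier_loci),
                 outlier_F = outlier_F, missing_rate = missing_rate,
                 genotype_error_rate = genotype_error_rate,
                 gap_stress = gap_stress),
            class = "sim_config")
}

# jittered-grid marker map over equally sized autosomes
sim_marker_map <- function(cfg) {
  per_chrom <- rep(cfg$n_snps %/% cfg$n_chrom, cfg$n_chrom)
  extra <- cfg$n_snps %% cfg$n_chrom
  if (extra) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  maps <- lapply(seq_len(cfg$n_chrom), function(ch) {
    nc <- per_chrom[ch]
    spacing <- cfg$chrom_length_bp / nc
    pos <- round((seq_len(nc) - 0.5) * spacing +
                   stats::runif(nc, -0.3, 0.3) * spacing)
    pos <- pmin(pmax(pos, 1), cfg$chrom_length_bp)
    pos <- as.integer(cummax(pos) + seq_len(nc) - 1L)  # strictly increasing
    data.frame(chrom = as.character(ch), pos = pos, stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, maps)
  if (cfg$gap_stress) {
    drop <- logical(nrow(map))
    for (ch in as.character(seq_len(cfg$n_chrom))) {
      jdx <- which(map$chrom == ch)
      centers <- stats::runif(2, 0.2, 0.8) * cfg$chrom_length_bp
      for (cen in centers)
        drop[jdx[abs(map$pos[jdx] - cen) < 0.75e6]] <- TRUE
    }
    map <- map[!drop, , drop = FALSE]
  }
  base_pairs <- c("A C", "A G", "A T", "C G", "C T", "G T")
  al <- strsplit(sample(base_pairs, nrow(map), replace = TRUE), " ")
  map$allele_a <- vapply(al, `[`, "", 1L)
  map$allele_b <- vapply(al, `[`, "", 2L)
  map$id <- sprintf("SNP%06d", seq_len(nrow(map)))
  map[, c("id", "chrom", "pos", "allele_a", "allele_b")]
}

#' Ancestral and per-population allele frequencies
#'
#' Ancestral frequencies are uniform on `maf_range`; each population's
#' frequency is Beta(`p(1-F)/F`, `(1-p)(1-F)/F`) (exactly `p` when `F = 0`).
#' Planted outlier loci are overwritten with contrasting frequencies
#' `0.5 +/- delta` (alternating across populations) with `delta` solved so
#' the parametric Weir-Cockerham theta at the locus equals `outlier_F`.
#'
#' @param cfg a [sim_config].
#' @param m number of markers.
#' @param outlier_idx marker indices of the planted outlier loci.
#' @return list `(ancestral, pop_freq, delta)`; `pop_freq` is a pops x
#'   markers matrix.
#' @keywords internal
sim_frequencies <- function(cfg, m, outlier_idx = integer()) {
  p <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  k <- length(cfg$pop_names)
  pop_freq <- matrix(0, nrow = k, ncol = m)
  for (i in seq_len(k)) {
    F <- cfg$divergence_F[i]
    if (F == 0) {
      pop_freq[i, ] <- p
    } else {
      shape1 <- p * (1 - F) / F
      shape2 <- (1 - p) * (1 - F) / F
      pop_freq[i, ] <- pmin(pmax(stats::rbeta(m, shape1, shape2), 1e-6),
                            1 - 1e-6)
    }
  }
  delta <- NA_real_
  if (length(outlier_idx)) {
    Fo <- cfg$outlier_F
    e <- rep_len(c(1, -1), k)
    if (k %% 2L == 1L) e[k] <- 0
    n_active <- sum(e != 0)
    s2 <- 0.25 * Fo / (1 - Fo / k)          # large-n theta = s2/(1/4 + s2/k)
    delta <- sqrt(s2 * (k - 1) / n_active)
    for (i in seq_len(k))
      pop_freq[i, outlier_idx] <- 0.5 + e[i] * delta
  }
  list(ancestral = p, pop_freq = pop_freq, delta = delta)
}

# draw tracts for one individual until the merged length reaches the target
sim_tracts_one <- function(target_bp, cfg) {
  empty <- data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), stringsAsFactors = FALSE)
  if (target_bp <= 0) return(empty)
  mean_len <- mean(cfg$tract_length_range)
  tr <- empty
  repeat {
    total <- sum(tr$end_bp - tr$start_bp)
    if (total >= target_bp) break
    k <- max(1L, ceiling((target_bp - total) / mean_len))
    len <- pmin(stats::runif(k, cfg$tract_length_range[1],
                             cfg$tract_length_range[2]),
                cfg$chrom_length_bp - 2)
    ch <- as.character(sample.int(cfg$n_chrom, k, replace = TRUE))
    start <- floor(stats::runif(k, 1, cfg$chrom_length_bp - len))
    tr <- merge_intervals(rbind(tr, data.frame(
      chrom = ch, start_bp = start, end_bp = start + len,
      stringsAsFactors = FALSE)))
  }
  tr
}

# union of possibly overlapping intervals, per chromosome
merge_intervals <- function(tr) {
  if (nrow(tr) < 2L) return(tr)
  ord <- order(tr$chrom, tr$start_bp)
  ch <- tr$chrom[ord]; s <- tr$start_bp[ord]; e <- tr$end_bp[ord]
  n <- length(s)
  cm <- e
  for (i in 2:n) if (ch[i] == ch[i - 1L] && cm[i] < cm[i - 1L])
    cm[i] <- cm[i - 1L]
  new_run <- c(TRUE, ch[-1] != ch[-n] | s[-1] > cm[-n])
  grp <- cumsum(new_run)
  data.frame(chrom = ch[new_run],
             start_bp = s[new_run],
             end_bp = as.numeric(tapply(cm, grp, max)),
             stringsAsFactors = FALSE)
}

# overwrite calls inside [start, end] with a doubled haplotype drawn from
# the population frequencies (zero heterozygotes inside by construction)
plant_tract <- function(calls_row, markers, pop_p, chrom, start, end) {
  jdx <- which(markers$chrom == chrom & markers$pos >= start &
                 markers$pos <= end)
  if (length(jdx))
    calls_row[jdx] <- 2L * stats::rbinom(length(jdx), 1L, pop_p[jdx])
  calls_row
}

#' Simulate a multi-breed cohort with known truth
#'
#' Generation order: baseline calls `Binomial(2, p_pop)` per individual and
#' SNP; planted autozygous tracts overwrite calls with a doubled haplotype;
#' island tracts do the same for the first `ceiling(carrier_fraction * n)`
#' individuals of a seeded permutation of the breed; genotype errors
#' reassign calls; missingness masks calls. Everything is a deterministic
#' function of `cfg$seed`.
#'
#' @param cfg a [sim_config].
#' @return list of class `sim_cohort`: `genotypes` (a [genotypes] object),
#'   `truth` (list of `individuals`, `pairwise_fst`, `islands`,
#'   `outlier_loci` tables), and `config`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  map <- sim_marker_map(cfg)
  m <- nrow(map)
  genome_bp <- cfg$n_chrom * cfg$chrom_length_bp

  outlier_idx <- if (cfg$n_outlier_loci > 0)
    sort(sample.int(m, cfg$n_outlier_loci)) else integer()
  fr <- sim_frequencies(cfg, m, outlier_idx)

  k <- length(cfg$pop_names)
  n_total <- sum(cfg$n_per_pop)
  pop_of <- rep(cfg$pop_names, cfg$n_per_pop)
  ids <- unlist(lapply(seq_len(k), function(i)
    sprintf("%s_%02d", cfg$pop_names[i], seq_len(cfg$n_per_pop[i]))))

  calls <- matrix(NA_integer_, n_total, m)
  for (i in seq_len(k)) {
    rows <- which(pop_of == cfg$pop_names[i])
    pk <- fr$pop_freq[i, ]
    calls[rows, ] <- matrix(
      stats::rbinom(length(rows) * m, 2L, rep(pk, each = length(rows))),
      nrow = length(rows), ncol = m)
  }

  # planted autozygous tracts
  truth_froh <- numeric(n_total)
  all_tracts <- stats::setNames(vector("list", n_total), ids)
  for (s in seq_len(n_total)) {
    i <- match(pop_of[s], cfg$pop_names)
    target_mean <- cfg$froh_target[i]
    target <- if (target_mean <= 0) 0 else
      min(max(stats::rnorm(1, target_mean, cfg$froh_sd), 0), 0.6)
    tr <- sim_tracts_one(target * genome_bp, cfg)
    all_tracts[[s]] <- tr
    if (nrow(tr))
      for (t in seq_len(nrow(tr)))
        calls[s, ] <- plant_tract(calls[s, ], map, fr$pop_freq[i, ],
                                  tr$chrom[t], tr$start_bp[t], tr$end_bp[t])
  }

  # planted island loci: doubled haplotypes for a carrier subset
  islands_truth <- NULL
  if (!is.null(cfg$planted_islands) && nrow(cfg$planted_islands)) {
    isl <- cfg$planted_islands
    isl$n_carriers <- NA_integer_
    for (t in seq_len(nrow(isl))) {
      rows <- which(pop_of == isl$population[t])
      nc <- ceiling(isl$carrier_fraction[t] * length(rows))
      carriers <- rows[sample.int(length(rows))][seq_len(nc)]
      isl$n_carriers[t] <- nc
      i <- match(isl$population[t], cfg$pop_names)
      for (s in carriers) {
        ext <- stats::runif(2, cfg$island_ext_bp[1], cfg$island_ext_bp[2])
        lo <- max(1, isl$start_bp[t] - ext[1])
        hi <- min(cfg$chrom_length_bp, isl$end_bp[t] + ext[2])
        calls[s, ] <- plant_tract(calls[s, ], map, fr$pop_freq[i, ],
                                  as.character(isl$chrom[t]), lo, hi)
        all_tracts[[s]] <- merge_intervals(rbind(
          all_tracts[[s]],
          data.frame(chrom = as.character(isl$chrom[t]),
                     start_bp = lo, end_bp = hi,
                     stringsAsFactors = FALSE)))
      }
    }
    islands_truth <- isl
  }
  truth_froh <- vapply(all_tracts, function(tr)
    if (nrow(tr)) sum(tr$end_bp - tr$start_bp) / genome_bp else 0, numeric(1))

  # genotype errors, then missingness
  if (cfg$genotype_error_rate > 0) {
    idx <- which(stats::runif(length(calls)) < cfg$genotype_error_rate)
    if (length(idx))
      calls[idx] <- (calls[idx] +
                       sample(1:2, length(idx), replace = TRUE)) %% 3L
  }
  if (cfg$missing_rate > 0) {
    idx <- which(stats::runif(length(calls)) < cfg$missing_rate)
    calls[idx] <- NA_integer_
  }

  g <- genotypes(calls,
                 samples = data.frame(id = ids, population = pop_of,
                                      stringsAsFactors = FALSE),
                 markers = map,
                 autosomes = as.character(seq_len(cfg$n_chrom)))

  pair <- if (k >= 2) t(utils::combn(k, 2)) else matrix(integer(), ncol = 2)
  pairwise <- data.frame(
    pop1 = cfg$pop_names[pair[, 1]], pop2 = cfg$pop_names[pair[, 2]],
    expected_fst = (cfg$divergence_F[pair[, 1]] +
                      cfg$divergence_F[pair[, 2]]) / 2,
    stringsAsFactors = FALSE)

  outliers <- if (length(outlier_idx))
    data.frame(snp = map$id[outlier_idx], chrom = map$chrom[outlier_idx],
               pos = map$pos[outlier_idx], theta = cfg$outlier_F,
               stringsAsFactors = FALSE)
  else
    data.frame(snp = character(), chrom = character(), pos = integer(),
               theta = numeric(), stringsAsFactors = FALSE)

  truth <- list(
    individuals = data.frame(sample_id = ids, population = pop_of,
                             planted_froh = truth_froh,
                             stringsAsFactors = FALSE),
    pairwise_fst = pairwise,
    islands = islands_truth,
    outlier_loci = outliers,
    genome_bp = genome_bp)

  structure(list(genotypes = g, truth = truth, config = cfg),
            class = "sim_cohort")
}

#' Write a simulated cohort to disk
#'
#' Emits PLINK text (PED/MAP) and binary (BED/BIM/FAM) filesets, a
#' two-column population file, a synthetic gene annotation (BED4: one gene
#' inside each planted island and outlier locus plus background genes,
#' names `GSYN...`) and the truth tables as TSV.
#'
#' @param sim a `sim_cohort` from [simulate_cohort].
#' @param dir output directory (created if needed).
#' @param prefix fileset prefix.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir, prefix = "cohort") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pfx <- file.path(dir, prefix)
  write_plink_text(sim$genotypes, pfx)
  write_plink_binary(sim$genotypes, pfx)
  utils::write.table(sim$genotypes$samples, file.path(dir, "populations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)

  # synthetic genes: one inside each planted feature + deterministic grid
  genes <- list()
  gid <- 0L
  add_gene <- function(chrom, start1, end1) {
    gid <<- gid + 1L
    data.frame(chrom = chrom, start0 = format(start1 - 1L, scientific = FALSE),
               end0 = format(end1, scientific = FALSE),
               name = sprintf("GSYN%04d", gid), stringsAsFactors = FALSE)
  }
  if (!is.null(sim$truth$islands) && nrow(sim$truth$islands))
    for (t in seq_len(nrow(sim$truth$islands)))
      genes[[length(genes) + 1L]] <- add_gene(
        as.character(sim$truth$islands$chrom[t]),
        as.integer(sim$truth$islands$start_bp[t] + 1e4),
        as.integer(sim$truth$islands$start_bp[t] + 8e4))
  if (nrow(sim$truth$outlier_loci))
    for (t in seq_len(nrow(sim$truth$outlier_loci)))
      genes[[length(genes) + 1L]] <- add_gene(
        sim$truth$outlier_loci$chrom[t],
        max(1L, sim$truth$outlier_loci$pos[t] - 2e4),
        sim$truth$outlier_loci$pos[t] + 2e4)
  for (ch in as.character(seq_len(sim$config$n_chrom)))
    for (s in seq(5e6, sim$config$chrom_length_bp - 5e6, by = 25e6))
      genes[[length(genes) + 1L]] <- add_gene(ch, as.integer(s),
                                              as.integer(s + 5e4))
  utils::write.table(do.call(rbind, genes),
                     file.path(dir, "genes_synthetic.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  tw <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tw(sim$truth$individuals, "truth_individuals.tsv")
  tw(sim$truth$pairwise_fst, "truth_pairwise_fst.tsv")
  if (!is.null(sim$truth$islands)) tw(sim$truth$islands, "truth_islands.tsv")
  tw(sim$truth$outlier_loci, "truth_outlier_loci.tsv")
  invisible(dir)
}
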