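# Config-driven orchestration of the full analysis: input (or simulation),
# per-branch QC, ROH calling + F_ROH, incidence + islands, FST scans,
# diversity, gene annotation, all written as TSV with a run manifest.

tsv_write <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

default_pipeline_config <- function() {
  list(
    output_dir = "rohscan_output",
    seed = 1L,
    simulate = NULL,            # sim_config() arguments, or NULL
    input = NULL,               # list(prefix=, format="binary"|"text")
    population_file = NULL,
    annotation = NULL,          # list(path=, format="bed"|"gff3")
    autosomes = as.character(1:18),
    branches = list(structure = TRUE, roh = TRUE, fst = TRUE),
    roh = list(),               # roh_params() overrides
    islands = list(p_min = 0.999, incidence_floor_pct = 30,
                   fallback = list(p_min = 0.998, incidence_min_pct = 55)),
    fst = list(top_fraction = 0.001),
    flank_bp = 100000)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.data.frame(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the full analysis pipeline
#'
#' Loads genotypes (PLINK text or binary) or simulates a cohort, applies
#' the three QC branches (structure / roh / fst), calls ROH, F_ROH,
#' incidence and islands per breed, runs the multi-population and all
#' pairwise FST scans, computes diversity and the Ho~F_ROH correlation,
#' annotates significant SNPs, and writes every result as TSV plus a run
#' manifest (config hash, seed, package version). Re-running with the same
#' config and seed reproduces the TSVs byte for byte.
#'
#' @param config a config list, or the path of a YAML file holding one;
#'   see the package vignette for the schema. Unset keys fall back to the
#'   defaults.
#' @param verbose emit per-stage log lines with before/after counts.
#' @return The output directory, invisibly; results are also returned in
#'   `attr(, "results")`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    if (!file.exists(cfg_path))
      stop("config file not found: ", cfg_path, call. = FALSE)
    config <- yaml::read_yaml(cfg_path)
  }
  cfg <- merge_config(default_pipeline_config(), config)
  say <- function(...) if (verbose) message(...)

  if (is.null(cfg$simulate) && is.null(cfg$input))
    stop("config must declare either `input` or `simulate`", call. = FALSE)
  if (!is.null(cfg$input)) {
    pfx <- cfg$input$prefix
    fmt <- if (is.null(cfg$input$format)) "binary" else cfg$input$format
    need <- if (fmt == "binary") paste0(pfx, c(".bed", ".bim", ".fam"))
            else paste0(pfx, c(".ped", ".map"))
    missing_files <- need[!file.exists(need)]
    if (length(missing_files))
      stop("missing input file(s): ", paste(missing_files, collapse = ", "),
           call. = FALSE)
  }
  if (!is.null(cfg$population_file) && !file.exists(cfg$population_file))
    stop("population file not found: ", cfg$population_file, call. = FALSE)
  if (!is.null(cfg$annotation) && !file.exists(cfg$annotation$path))
    stop("annotation file not found: ", cfg$annotation$path, call. = FALSE)

  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$output_dir, ...)
  results <- list()

  # ---- input ----
  if (!is.null(cfg$simulate)) {
    say("simulating cohort (seed ", cfg$seed, ")")
    sim_args <- cfg$simulate
    sim_args$seed <- cfg$seed
    sim <- simulate_cohort(do.call(sim_config, sim_args))
    g <- sim$genotypes
    write_cohort(sim, out("simulated"))
  } else {
    g <- if (fmt == "binary")
      read_plink_binary(pfx, autosomes = cfg$autosomes)
    else
      read_plink_text(paste0(pfx, ".ped"), paste0(pfx, ".map"),
                      autosomes = cfg$autosomes)
  }
  if (!is.null(cfg$population_file))
    g <- assign_populations(g, read_population_file(cfg$population_file))
  say("input: ", n_samples(g), " samples x ", n_markers(g), " markers")
  pops <- unique(g$samples$population)

  # ---- structure branch (LD-pruned marker panel for PCA/clustering prep) ----
  if (isTRUE(cfg$branches$structure)) {
    say("structure branch QC")
    qs <- apply_qc(g, qc_profile("structure"), verbose = verbose)
    tsv_write(qs$report, out("qc_report_structure.tsv"))
    tsv_write(qs$genotypes$markers[, c("id", "chrom", "pos")],
              out("structure_pruned_markers.tsv"))
    results$structure <- qs
  }

  # ---- ROH branch: per-breed QC, ROH, F_ROH, incidence, islands ----
  roh_all <- froh_all <- ho_all <- NULL
  if (isTRUE(cfg$branches$roh)) {
    say("ROH branch QC (per breed)")
    qb <- apply_qc_by_population(g, qc_profile("roh"), verbose = verbose)
    qc_rep <- do.call(rbind, lapply(names(qb), function(p)
      cbind(population = p, qb[[p]]$report)))
    tsv_write(qc_rep, out("qc_report_roh.tsv"))

    islands_list <- list()
    members_list <- list()
    for (p in names(qb)) {
      gb <- qb[[p]]$genotypes
      params <- do.call(roh_params, cfg$roh)
      segs <- call_roh(gb, params)
      say("breed ", p, ": ", nrow(segs), " ROH segments (L = ",
          attr(segs, "L"), ")")
      fr <- froh(segs, gb$samples, snp_coverage_bp(gb$markers))
      track <- roh_incidence(segs, gb$markers, gb$samples$id)
      isl <- call_islands(track, p_min = cfg$islands$p_min,
                          incidence_floor_pct = cfg$islands$incidence_floor_pct,
                          fallback = cfg$islands$fallback)
      tsv_write(segs, out(paste0("roh_segments_", p, ".tsv")))
      tsv_write(fr, out(paste0("froh_", p, ".tsv")))
      tsv_write(track, out(paste0("incidence_manhattan_", p, ".tsv")))
      tsv_write(isl, out(paste0("islands_", p, ".tsv")))
      islands_list[[p]] <- isl
      members_list[[p]] <- attr(isl, "members")
      roh_all <- rbind(roh_all, segs)
      froh_all <- rbind(froh_all, fr)
      ho_all <- rbind(ho_all, observed_het(gb))
    }
    results$roh <- list(segments = roh_all, froh = froh_all,
                        islands = islands_list, members = members_list)

    # diversity on the same per-breed ROH marker panels
    div_pairs <- merge(ho_all, froh_all[, c("sample_id", "froh_all")],
                       by = "sample_id")
    tsv_write(div_pairs[, c("sample_id", "population", "ho", "froh_all")],
              out("diversity.tsv"))
    corr <- tryCatch(ho_froh_correlation(ho_all, froh_all),
                     error = function(e) NULL)
    if (!is.null(corr)) {
      tsv_write(data.frame(r = corr$r, p = corr$p, n = corr$n),
                out("ho_froh_correlation.tsv"))
      say(sprintf("Ho ~ F_ROH: r = %.3f (n = %d)", corr$r, corr$n))
    }
    results$diversity <- list(ho = ho_all, correlation = corr)
  }

  # ---- FST branch ----
  fst_sig <- NULL
  if (isTRUE(cfg$branches$fst) && length(pops) >= 2) {
    say("FST branch QC")
    qf <- apply_qc(g, qc_profile("fst"), verbose = verbose)
    tsv_write(qf$report, out("qc_report_fst.tsv"))
    gf <- qf$genotypes
    comparisons <- c(list(pops),
                     if (length(pops) > 2)
                       utils::combn(pops, 2, simplify = FALSE))
    fst_sig <- list()
    fst_tracks <- list()
    for (cmp in comparisons) {
      track <- wc_fst(gf, cmp)
      lab <- attr(track, "comparison")
      sig <- suppressWarnings(fst_outliers(track, cfg$fst$top_fraction))
      say("FST ", lab, ": mean = ",
          sprintf("%.4f", fst_mean(track)), ", ", nrow(sig),
          " outlier SNP(s)")
      tsv_write(fst_manhattan(track),
                out(paste0("fst_manhattan_", lab, ".tsv")))
      tsv_write(sig, out(paste0("fst_significant_", lab, ".tsv")))
      fst_sig[[lab]] <- sig
      fst_tracks[[lab]] <- track
    }
    means <- data.frame(
      comparison = names(fst_tracks),
      mean_fst = vapply(fst_tracks, fst_mean, numeric(1)),
      stringsAsFactors = FALSE)
    tsv_write(means, out("fst_means.tsv"))
    results$fst <- list(tracks = fst_tracks, significant = fst_sig,
                        means = means)
  }

  # ---- annotation ----
  genes <- NULL
  if (!is.null(cfg$annotation)) {
    genes <- read_gene_annotation(cfg$annotation$path, cfg$annotation$format)
  } else if (!is.null(cfg$simulate)) {
    genes <- read_gene_annotation(out("simulated", "genes_synthetic.bed"),
                                  "bed")
  }
  if (!is.null(genes)) {
    members <- if (isTRUE(cfg$branches$roh)) results$roh$members else NULL
    tables <- annotate_tables(fst_sig, members, genes, cfg$flank_bp)
    for (nm in names(tables))
      if (nrow(tables[[nm]]))
        tsv_write(tables[[nm]], out(paste0("annotated_", nm, ".tsv")))
    results$annotation <- tables
  }

  # ---- manifest ----
  # hash the canonical merged config minus the output location, so the same
  # analysis has the same fingerprint wherever it is written
  cfg_for_hash <- cfg
  cfg_for_hash$output_dir <- NULL
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg_for_hash, tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- data.frame(
    key = c("config_hash", "seed", "rohscan_version"),
    value = c(cfg_hash, as.character(cfg$seed),
              as.character(utils::packageVersion("rohscan"))),
    stringsAsFactors = FALSE)
  tsv_write(manifest, out("manifest.tsv"))

  res <- cfg$output_dir
  attr(res, "results") <- results
  invisible(res)
}
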