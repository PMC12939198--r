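# End-to-end orchestration: gate -> compartments -> spatial -> survival,
# with per-stage outputs, structured exclusion logging and a manifest of
# file hashes so that identical configurations provably reproduce
# identical results.

#' Configuration of an end-to-end pipeline run
#'
#' Defaults mirror the analysis parameters of the mIHC study design: a
#' 30-um G-cross radius, 10-um infiltration bands within a 100-um zone,
#' a 10-um interaction radius, and the >= 1500 combined tumour + CD8+
#' cell sample gate.
#'
#' @param gating_thresholds Named per-marker intensity cuts, or `NULL` to
#'   estimate them from the pooled data via
#'   [estimate_gating_thresholds()].
#' @param dilation_radius_um,min_component Tumour-region construction, see
#'   [build_tumor_region()].
#' @param r_max_um,band_width_um,max_dist_um,interaction_radius_um,border_correction
#'   Spatial statistic parameters.
#' @param min_combined Sample QC gate, see [sample_qc()].
#' @param features Phenotypes whose G-cross proximity scores enter the
#'   survival stage.
#' @param covariates Clinical adjustment set for the multivariate Cox
#'   model.
#' @param seed Integer seed echoed into the manifest.
#'
#' @return Object of class `run_config`.
#' @export
run_config <- function(gating_thresholds = NULL,
                       dilation_radius_um = 15, min_component = 5L,
                       r_max_um = 30, band_width_um = 10,
                       max_dist_um = 100, interaction_radius_um = 10,
                       border_correction = FALSE, min_combined = 1500L,
                       features = c("trm_pd1neg", "trm_pd1pos"),
                       covariates = c("age_group", "sex", "tnm_stage"),
                       seed = 1L) {
  structure(list(gating_thresholds = gating_thresholds,
                 dilation_radius_um = dilation_radius_um,
                 min_component = as.integer(min_component),
                 r_max_um = r_max_um, band_width_um = band_width_um,
                 max_dist_um = max_dist_um,
                 interaction_radius_um = interaction_radius_um,
                 border_correction = border_correction,
                 min_combined = as.integer(min_combined),
                 features = features, covariates = covariates,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full spatial-survival pipeline
#'
#' Stages, in order: hierarchical gating of every sample, tumour-region
#' construction and compartment assignment, sample QC and spatial
#' summaries, and survival association (median-split Kaplan-Meier /
#' log-rank plus uni- and multivariate Cox on the standardised G-cross
#' proximity scores). Every stage writes its table under `out_dir` and
#' the manifest records an MD5 hash of each output together with the
#' parameter echo, so a re-run with the same inputs and configuration
#' reproduces bit-identical files.
#'
#' @param inputs Either the result of [simulate_cohort()] (a list with
#'   `samples` and `cohort`) or a list
#'   `list(samples = <list of cell tables>, cohort = <data frame>)`;
#'   samples may also be given as paths to [write_cell_table()] files.
#' @param config A [run_config()].
#' @param out_dir Output directory (created; existing files overwritten).
#'
#' @return Invisibly, a list with `spatial` (per-sample summaries),
#'   `survival` (the merged analysis table and test results),
#'   `exclusions` and `manifest_path`.
#' @export
run_pipeline <- function(inputs, config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  samples <- inputs$samples
  cohort <- inputs$cohort
  if (is.null(samples) || !length(samples))
    stop("inputs$samples is empty", call. = FALSE)
  dir.create(file.path(out_dir, "samples"), recursive = TRUE,
             showWarnings = FALSE)

  get_cells <- function(s) {
    if (is.character(s)) read_cell_table(s)
    else if (is.list(s) && !is.null(s$cells)) s$cells
    else s
  }
  cells_list <- lapply(samples, get_cells)
  names(cells_list) <- vapply(cells_list, function(x) x$sample_id[1L], "")

  # --- stage 1: gating -----------------------------------------------------
  thr <- config$gating_thresholds
  if (is.null(thr)) {
    pooled <- do.call(rbind, lapply(cells_list, function(x)
      x[, intersect(mihc_markers(), names(x)), drop = FALSE]))
    thr <- estimate_gating_thresholds(pooled, seed = config$seed)
  }
  gcfg <- gating_config(thr)
  written <- character(0)
  spatial_rows <- list()
  exclusions <- list()
  for (sid in names(cells_list)) {
    cells <- tryCatch(gate_phenotypes(cells_list[[sid]], gcfg),
                      error = function(e)
                        stop(sprintf("stage 'gate' failed for sample %s: %s",
                                     sid, conditionMessage(e)),
                             call. = FALSE))
    # --- stage 2: compartments --------------------------------------------
    region <- tryCatch({
      reg <- build_tumor_region(cells, config$dilation_radius_um,
                                config$min_component)
      cells <- assign_compartments(cells, reg)
      reg
    }, error = function(e)
      stop(sprintf("stage 'compartments' failed for sample %s: %s",
                   sid, conditionMessage(e)), call. = FALSE))
    f <- file.path(out_dir, "samples", paste0(sid, "_cells.tsv"))
    write_cell_table(cells, f)
    written <- c(written, f)
    # --- stage 3: sample QC + spatial summary ------------------------------
    qc <- sample_qc(cells, config$min_combined)
    if (!qc) {
      exclusions[[sid]] <- data.frame(
        sample_id = sid, stage = "spatial",
        reason = sprintf("combined tumour+CD8 count %d < %d",
                         attr(qc, "n_tumor") + attr(qc, "n_cd8"),
                         config$min_combined), stringsAsFactors = FALSE)
      next
    }
    spatial_rows[[sid]] <- tryCatch(
      spatial_summary(cells, region, phenotypes = cd8_labels(),
                      r_max_um = config$r_max_um,
                      band_width_um = config$band_width_um,
                      max_dist_um = config$max_dist_um,
                      interaction_radius_um = config$interaction_radius_um,
                      border_correction = config$border_correction),
      error = function(e)
        stop(sprintf("stage 'spatial' failed for sample %s: %s",
                     sid, conditionMessage(e)), call. = FALSE))
  }
  spatial <- if (length(spatial_rows)) do.call(rbind, spatial_rows) else
    data.frame()
  rownames(spatial) <- NULL
  f_spatial <- file.path(out_dir, "spatial_summary.tsv")
  write.table(spatial, f_spatial, sep = "\t", quote = FALSE,
              row.names = FALSE)
  excl <- if (length(exclusions)) do.call(rbind, exclusions) else
    data.frame(sample_id = character(0), stage = character(0),
               reason = character(0))
  rownames(excl) <- NULL
  f_excl <- file.path(out_dir, "exclusions.tsv")
  write.table(excl, f_excl, sep = "\t", quote = FALSE, row.names = FALSE)

  # --- stage 4: survival ---------------------------------------------------
  surv_tables <- survival_stage(spatial, cohort, config)
  f_surv <- file.path(out_dir, "survival_results.tsv")
  write.table(surv_tables$results, f_surv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  f_feat <- file.path(out_dir, "survival_features.tsv")
  write.table(surv_tables$analysis, f_feat, sep = "\t", quote = FALSE,
              row.names = FALSE)

  files <- c(written, f_spatial, f_excl, f_surv, f_feat)
  manifest <- list(
    package = "trmspatial",
    version = as.character(packageVersion("trmspatial")),
    seed = config$seed,
    parameters = unclass(config)[setdiff(names(unclass(config)),
                                         "gating_thresholds")],
    gating_thresholds = as.list(thr),
    n_samples = length(cells_list),
    n_excluded = nrow(excl),
    outputs = lapply(files, function(f)
      list(file = sub(paste0("^", out_dir, "/?"), "", f),
           md5 = unname(tools::md5sum(f)))))
  f_manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(spatial = spatial, survival = surv_tables,
                 exclusions = excl, manifest_path = f_manifest))
}

# Merge per-sample proximity scores into the cohort and run KM/log-rank
# and Cox models. Returns empty-but-well-formed tables when no sample
# passed QC.
survival_stage <- function(spatial, cohort, config) {
  empty <- list(
    analysis = data.frame(),
    results = data.frame(feature = character(0), analysis = character(0),
                         term = character(0), estimate = numeric(0),
                         ci_lower = numeric(0), ci_upper = numeric(0),
                         p = numeric(0), note = character(0)))
  if (!nrow(spatial) || is.null(cohort) || !nrow(cohort)) {
    message("survival stage: no samples passed QC; nothing to analyse")
    return(empty)
  }
  feats <- intersect(config$features, unique(spatial$phenotype))
  wide <- cohort
  for (ph in feats) {
    sc <- spatial$gcross_score[spatial$phenotype == ph]
    names(sc) <- spatial$sample_id[spatial$phenotype == ph]
    raw <- sc[wide$sample_id]
    wide[[paste0("gcross_", ph)]] <- unname(raw)
    s <- sd(raw, na.rm = TRUE)
    wide[[paste0("gcross_", ph, "_z")]] <-
      if (is.na(s) || s < 1e-12) 0 else (raw - mean(raw, na.rm = TRUE)) / s
  }
  wide <- wide[!is.na(wide[[paste0("gcross_", feats[1L])]]), , drop = FALSE]
  if (nrow(wide) < 4L) {
    message("survival stage: fewer than 4 scored patients; skipping tests")
    return(list(analysis = wide, results = empty$results))
  }
  rows <- list()
  for (ph in feats) {
    # event-free strata are legitimate in small runs; keep the note, not
    # the warning
    km <- tryCatch(suppressWarnings(km_logrank(wide, paste0("gcross_", ph))),
                   error = function(e) NULL)
    if (!is.null(km))
      rows[[paste0("km_", ph)]] <- data.frame(
        feature = ph, analysis = "logrank_median_split", term = "chisq",
        estimate = km$chisq, ci_lower = NA_real_, ci_upper = NA_real_,
        p = km$p, note = sprintf("cut=%.4g", km$cutpoint),
        stringsAsFactors = FALSE)
    for (mode in c("univariate", "multivariate")) {
      cx <- tryCatch(
        cox_model(wide, paste0("gcross_", ph, "_z"),
                  covariates = config$covariates,
                  multivariate = mode == "multivariate"),
        error = function(e) NULL)
      if (is.null(cx)) next
      rows[[paste0("cox_", mode, "_", ph)]] <- data.frame(
        feature = ph, analysis = paste0("cox_", mode), term = cx$term,
        estimate = cx$hr, ci_lower = cx$ci_lower, ci_upper = cx$ci_upper,
        p = cx$p,
        note = ifelse(cx$fit_failed, "fit failed", "HR per SD of score"),
        stringsAsFactors = FALSE)
    }
  }
  list(analysis = wide,
       results = if (length(rows)) do.call(rbind, c(rows,
                                                    make.row.names = FALSE))
                 else empty$results)
}

#' Assemble machine-readable report tables from a completed run
#'
#' Reads the stage outputs of a [run_pipeline()] directory and writes
#' `report_scores.csv` (one row per passing sample and phenotype) and
#' `report_survival.csv` under `<run_dir>/report`.
#'
#' @param run_dir A completed run directory.
#' @return Invisibly, a list with both report data frames.
#' @export
make_report <- function(run_dir) {
  need <- file.path(run_dir, c("spatial_summary.tsv",
                               "survival_results.tsv", "manifest.json"))
  absent <- need[!file.exists(need)]
  if (length(absent))
    stop(sprintf("missing stage output(s): %s",
                 paste(basename(absent), collapse = ", ")), call. = FALSE)
  spatial <- read.table(need[1L], header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
  surv <- read.table(need[2L], header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  rep_dir <- file.path(run_dir, "report")
  dir.create(rep_dir, showWarnings = FALSE)
  scores <- if (nrow(spatial))
    spatial[, c("sample_id", "phenotype", "density_intra", "density_stroma",
                "fraction_cd8_intra", "fraction_cd8_stroma",
                "mean_nn_dist_um", "interactions_per_tumor_cell",
                "gcross_score")]
  else spatial
  write.csv(scores, file.path(rep_dir, "report_scores.csv"),
            row.names = FALSE)
  write.csv(surv, file.path(rep_dir, "report_survival.csv"),
            row.names = FALSE)
  invisible(list(scores = scores, survival = surv))
}
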