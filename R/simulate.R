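#' Configuration for the synthetic mIHC cohort generator
#'
#' Bundles every tunable of the synthetic-data generator: the observation
#' window, the Thomas cluster process that forms PanCK+ tumour islets, the
#' immune phenotype counts with their attraction-to-tumour parameters, the
#' log-normal marker-intensity mixture, and the proportional-hazards
#' survival model that links a spatial proximity score to outcome.
#'
#' Defaults describe a 1 x 1 mm tissue core: 8 tumour islets of on average
#' 230 cells (Gaussian spread 40 um) plus ~490 CD8+ T cells, so that a
#' default sample comfortably clears the >= 1500 combined tumour + CD8+
#' cell quality gate used before spatial scoring. Marker log-intensities
#' are separated by 6 component standard deviations, and survival times
#' follow an exponential proportional-hazards model with a hazard ratio of
#' 0.5 per standard deviation of the PD-1- T_RM proximity score.
#'
#' @param seed Integer root seed. Per-sample and per-patient streams are
#'   derived from it with fixed offsets, so enlarging a cohort never
#'   reshuffles earlier samples.
#' @param window Numeric length-2, window width and height in micrometres.
#' @param n_islets Number of tumour cluster parents (fixed, not random,
#'   for reproducibility).
#' @param islet_sd_um Gaussian spread of islet offspring (um).
#' @param tumor_per_islet Mean (Poisson) number of tumour cells per islet.
#' @param immune_counts Named integer vector: cells per immune phenotype.
#'   Names must be phenotype labels of the gating vocabulary (see
#'   [default_phenotype_hierarchy()]) or `"other"`.
#' @param proximity_rho Fraction in \[0, 1\] of each immune phenotype placed
#'   near tumour cells rather than uniformly; a scalar is recycled.
#' @param attract_scale_um Mean of the exponential distance kernel used for
#'   attracted cells (um).
#' @param intensity_model Data frame with columns `marker`, `mu_neg`,
#'   `mu_pos`, `sigma`: per-marker log-normal mixture parameters (log
#'   scale).
#' @param label_consistent Logical. If `TRUE` (default) intensity draws are
#'   rejected across the mixture midpoint, so intensities are always
#'   consistent with the cell's ground-truth label and midpoint gating
#'   recovers the truth exactly. Set `FALSE` for plain overlapping
#'   mixtures.
#' @param survival List with `baseline_hazard` (> 0, events per month),
#'   `beta` (named vector, log hazard ratios per standardised spatial
#'   score; names are `score_<phenotype>`), and `censor_time_max` (> 0,
#'   months; censoring is uniform on (0, censor_time_max\]).
#' @param n_patients Cohort size for [simulate_cohort()].
#'
#' @return An object of class `simulation_config` (a validated list).
#' @seealso [simulate_sample()], [simulate_cohort()], [simulate_expression()]
#' @export
#' @examples
#' cfg <- simulation_config(seed = 7, n_islets = 3, tumor_per_islet = 40,
#'                          immune_counts = c(cd8 = 30, trm_pd1neg = 20))
#' sim <- simulate_sample(cfg)
#' head(sim$cells)
simulation_config <- function(seed = 1L,
                              window = c(1000, 1000),
                              n_islets = 8L,
                              islet_sd_um = 40,
                              tumor_per_islet = 230,
                              immune_counts = c(cd8 = 150, trm_pd1neg = 60,
                                                trm_pd1pos = 60, cd8_pd1 = 60,
                                                cd8_cd69 = 40, cd8_tcf1 = 40,
                                                other = 80),
                              proximity_rho = 0.3,
                              attract_scale_um = 20,
                              intensity_model = default_intensity_model(),
                              label_consistent = TRUE,
                              survival = list(baseline_hazard = 0.03,
                                              beta = c(score_trm_pd1neg = log(0.5)),
                                              censor_time_max = 60),
                              n_patients = 61L) {
  if (length(window) != 2L || any(!is.finite(window)) || any(window <= 0))
    stop_config("window must be two positive extents (width_um, height_um)")
  if (n_islets < 0) stop_config("n_islets must be >= 0")
  if (islet_sd_um <= 0) stop_config("islet_sd_um must be > 0")
  if (tumor_per_islet <= 0) stop_config("tumor_per_islet must be > 0")
  if (attract_scale_um <= 0) stop_config("attract_scale_um must be > 0")
  if (is.null(names(immune_counts)) && length(immune_counts))
    stop_config("immune_counts must be named by phenotype")
  if (any(immune_counts < 0)) stop_config("immune_counts must be >= 0")
  vocab <- c(vapply(default_phenotype_hierarchy(), `[[`, "", "name"), "other")
  bad <- setdiff(names(immune_counts), vocab)
  if (length(bad))
    stop_config("unknown immune phenotype(s): %s", paste(bad, collapse = ", "))
  if (length(proximity_rho) == 1L)
    proximity_rho <- setNames(rep(proximity_rho, length(immune_counts)),
                              names(immune_counts))
  if (!all(names(immune_counts) %in% names(proximity_rho)))
    stop_config("proximity_rho must cover every immune phenotype")
  if (any(proximity_rho < 0 | proximity_rho > 1))
    stop_config("proximity_rho must lie in [0, 1]")
  stopifnot(is.data.frame(intensity_model),
            all(c("marker", "mu_neg", "mu_pos", "sigma") %in%
                  names(intensity_model)))
  if (any(intensity_model$sigma <= 0))
    stop_config("intensity sigma must be > 0")
  if (survival$baseline_hazard <= 0)
    stop_config("baseline_hazard must be > 0")
  if (survival$censor_time_max <= 0)
    stop_config("censor_time_max must be > 0")
  if (length(survival$beta)) {
    if (is.null(names(survival$beta)) ||
        !all(grepl("^score_", names(survival$beta))))
      stop_config("survival beta must be named 'score_<phenotype>'")
    ph <- sub("^score_", "", names(survival$beta))
    if (!all(ph %in% vocab))
      stop_config("survival beta names an unknown phenotype: %s",
                  paste(setdiff(ph, vocab), collapse = ", "))
  }
  if (n_patients < 1) stop_config("n_patients must be >= 1")
  structure(list(seed = as.integer(seed), window = as.numeric(window),
                 n_islets = as.integer(n_islets), islet_sd_um = islet_sd_um,
                 tumor_per_islet = tumor_per_islet,
                 immune_counts = immune_counts,
                 proximity_rho = proximity_rho[names(immune_counts)],
                 attract_scale_um = attract_scale_um,
                 intensity_model = intensity_model,
                 label_consistent = isTRUE(label_consistent),
                 survival = survival, n_patients = as.integer(n_patients)),
            class = "simulation_config")
}

#' Default marker intensity mixture
#'
#' Log-normal mixture parameters (log scale) for the six-marker panel:
#' negative component mean 0, positive component mean 2.4, common sigma
#' 0.4, i.e. components separated by 6 standard deviations.
#'
#' @return Data frame with columns `marker`, `mu_neg`, `mu_pos`, `sigma`.
#' @export
default_intensity_model <- function() {
  data.frame(marker = mihc_markers(), mu_neg = 0, mu_pos = 2.4, sigma = 0.4,
             stringsAsFactors = FALSE)
}

# Markers each ground-truth label must be positive for (all others negative).
label_positive_markers <- function() {
  pos <- lapply(default_phenotype_hierarchy(), function(e) e$pos)
  names(pos) <- vapply(default_phenotype_hierarchy(), `[[`, "", "name")
  c(pos, list(other = character(0)))
}

# Draw marker intensities for a vector of true labels.
draw_intensities <- function(labels, model, label_consistent) {
  pos_map <- label_positive_markers()
  out <- matrix(0, nrow = length(labels), ncol = nrow(model),
                dimnames = list(NULL, model$marker))
  for (k in seq_len(nrow(model))) {
    m <- model$marker[k]
    is_pos <- vapply(pos_map[labels], function(p) m %in% p, logical(1))
    meanlog <- ifelse(is_pos, model$mu_pos[k], model$mu_neg[k])
    x <- rlnorm(length(labels), meanlog = meanlog, sdlog = model$sigma[k])
    if (label_consistent) {
      # Reject draws that cross the mixture midpoint, so intensities always
      # agree with the ground-truth label (positivity rule is `>= cut`).
      cut <- exp((model$mu_neg[k] + model$mu_pos[k]) / 2)
      bad <- (is_pos & x < cut) | (!is_pos & x >= cut)
      guard <- 0L
      while (any(bad) && guard < 1000L) {
        x[bad] <- rlnorm(sum(bad), meanlog = meanlog[bad],
                         sdlog = model$sigma[k])
        bad <- (is_pos & x < cut) | (!is_pos & x >= cut)
        guard <- guard + 1L
      }
    }
    out[, k] <- x
  }
  out
}

#' Simulate one mIHC-like sample with known ground truth
#'
#' Tumour cells form a Thomas (Neyman-Scott) cluster process: `n_islets`
#' uniformly placed parents, Poisson(`tumor_per_islet`) offspring per
#' parent with isotropic Gaussian spread, clipped to the window. Each
#' immune cell of phenotype `p` is, with probability `proximity_rho[p]`,
#' placed at an exponential distance (mean `attract_scale_um`) and uniform
#' angle from a uniformly chosen tumour cell (re-drawn while outside the
#' window); otherwise uniformly on the window. Marker intensities are
#' drawn from the per-marker log-normal mixture consistent with the true
#' label.
#'
#' @param config A [simulation_config()].
#' @param sample_index Integer; selects the sample's derived RNG stream
#'   and appears in `sample_id`.
#' @param rho Optional override of `config$proximity_rho` (scalar or named
#'   vector), used by [simulate_cohort()] for per-patient attraction.
#' @param intensities Logical; skip marker-intensity generation (cheaper
#'   when only positions and true labels are needed). Positions and labels
#'   are identical either way because intensities are drawn last.
#'
#' @return A list with `cells` (data frame: `sample_id`, `cell_id`,
#'   `x_um`, `y_um`, one intensity column per marker, `true_label`, window
#'   stored in `attr(, "window")` as `c(xmin, xmax, ymin, ymax)`) and
#'   `truth` (list: `labels`, `rho`, `n_tumor`).
#' @export
simulate_sample <- function(config, sample_index = 1L, rho = NULL,
                            intensities = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_islets * config$tumor_per_islet < 1)
    stop_config("expected tumour cell count n_islets * tumor_per_islet must be >= 1")
  if (!is.null(rho)) {
    if (length(rho) == 1L)
      rho <- setNames(rep(rho, length(config$immune_counts)),
                      names(config$immune_counts))
    if (any(rho < 0 | rho > 1)) stop_config("rho must lie in [0, 1]")
  } else rho <- config$proximity_rho
  W <- config$window[1]; H <- config$window[2]

  with_seed(derive_seed(config$seed, sample_index, stream = 1L), {
    # --- tumour islets (Thomas process, clipped to window) ---
    px <- runif(config$n_islets, 0, W)
    py <- runif(config$n_islets, 0, H)
    n_off <- rpois(config$n_islets, config$tumor_per_islet)
    tx <- rep(px, n_off) + rnorm(sum(n_off), 0, config$islet_sd_um)
    ty <- rep(py, n_off) + rnorm(sum(n_off), 0, config$islet_sd_um)
    keep <- tx >= 0 & tx <= W & ty >= 0 & ty <= H
    tx <- tx[keep]; ty <- ty[keep]
    n_tumor <- length(tx)

    # --- immune phenotypes: attracted vs uniform placement ---
    ix <- iy <- numeric(0)
    ilab <- character(0)
    for (ph in names(config$immune_counts)) {
      n_p <- config$immune_counts[[ph]]
      if (n_p == 0L) next
      attracted <- runif(n_p) < rho[[ph]] & n_tumor > 0L
      x <- runif(n_p, 0, W)
      y <- runif(n_p, 0, H)
      todo <- which(attracted)
      guard <- 0L
      while (length(todo) && guard < 10000L) {
        anchor <- sample.int(n_tumor, length(todo), replace = TRUE)
        d <- rexp(length(todo), rate = 1 / config$attract_scale_um)
        a <- runif(length(todo), 0, 2 * pi)
        nx <- tx[anchor] + d * cos(a)
        ny <- ty[anchor] + d * sin(a)
        ok <- nx >= 0 & nx <= W & ny >= 0 & ny <= H
        x[todo[ok]] <- nx[ok]
        y[todo[ok]] <- ny[ok]
        todo <- todo[!ok]
        guard <- guard + 1L
      }
      ix <- c(ix, x); iy <- c(iy, y)
      ilab <- c(ilab, rep(ph, n_p))
    }

    labels <- c(rep("tumor", n_tumor), ilab)
    cells <- data.frame(
      sample_id = sprintf("S%03d", sample_index),
      cell_id = sprintf("c%05d", seq_along(labels)),
      x_um = c(tx, ix), y_um = c(ty, iy),
      stringsAsFactors = FALSE)
    if (intensities) {
      # Drawn last so that skipping them leaves positions untouched.
      im <- draw_intensities(labels, config$intensity_model,
                             config$label_consistent)
      cells <- cbind(cells, as.data.frame(im))
    }
    cells$true_label <- labels
    attr(cells, "window") <- c(0, W, 0, H)
    list(cells = cells,
         truth = list(labels = labels, rho = rho, n_tumor = n_tumor))
  })
}

#' Simulate a synthetic patient cohort with outcome linked to proximity
#'
#' For each patient a per-patient attraction `rho_i ~ Uniform(0, 1)` is
#' drawn and one sample simulated with it. The designated spatial
#' covariates (G-cross AUC proximity scores of the phenotypes named in
#' `config$survival$beta`, computed from ground-truth labels) are
#' standardised across the cohort, and event times are drawn from an
#' exponential proportional-hazards model,
#' `T_i ~ Exp(baseline_hazard * exp(beta . z_i))`, censored uniformly on
#' `(0, censor_time_max]`. Age, sex and TNM stage are drawn independently
#' of the spatial scores (frequencies matching a resected iCCA cohort:
#' 43% female, 63% aged under 65, stages I-IV 24/34/19/22%).
#'
#' @param config A [simulation_config()].
#' @param keep_cells Logical; if `FALSE`, per-sample cell tables are
#'   dropped (and marker intensities never drawn) to save memory — the
#'   cohort table is identical either way.
#' @param r_max_um Radius bound of the proximity score (um).
#'
#' @return List with `samples` (list of `simulate_sample()` results, or
#'   `NULL`), `cohort` (data frame: `patient_id`, `sample_id`, `os_time`,
#'   `event`, `age`, `age_group`, `sex`, `tnm_stage`, one raw `score_*`
#'   and one standardised `score_*_z` column per scored phenotype) and
#'   `truth` (per-patient `rho` and true linear predictor `lp`).
#' @export
simulate_cohort <- function(config, keep_cells = TRUE, r_max_um = 30) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_patients
  beta <- config$survival$beta
  score_ph <- sub("^score_", "", names(beta))
  if (!length(score_ph)) score_ph <- "trm_pd1neg"

  samples <- if (keep_cells) vector("list", n) else NULL
  rho <- age <- u_event <- u_cens <- numeric(n)
  sex <- stage <- character(n)
  scores <- matrix(NA_real_, n, length(score_ph),
                   dimnames = list(NULL, score_ph))
  sample_ids <- character(n)

  for (i in seq_len(n)) {
    draws <- with_seed(derive_seed(config$seed, i, stream = 2L), {
      list(rho = runif(1), age = round(rnorm(1, 61, 10)),
           sex = sample(c("F", "M"), 1L, prob = c(29, 38)),
           stage = sample(c("I", "II", "III", "IV"), 1L,
                          prob = c(16, 23, 13, 15)),
           u_event = runif(1), u_cens = runif(1))
    })
    rho[i] <- draws$rho; age[i] <- draws$age
    sex[i] <- draws$sex; stage[i] <- draws$stage
    u_event[i] <- draws$u_event; u_cens[i] <- draws$u_cens
    sim <- simulate_sample(config, i, rho = rho[i], intensities = keep_cells)
    sample_ids[i] <- sim$cells$sample_id[1L]
    ph_col <- sim$cells$true_label
    for (ph in score_ph)
      scores[i, ph] <- gcross(sim$cells, phenotype = ph,
                              r_max_um = r_max_um,
                              label_col = "true_label")$score
    if (keep_cells) samples[[i]] <- sim
  }

  z <- scores
  for (ph in score_ph) {
    s <- sd(scores[, ph])
    z[, ph] <- if (s < 1e-12) 0 else (scores[, ph] - mean(scores[, ph])) / s
  }
  lp <- if (length(beta)) drop(z[, score_ph, drop = FALSE] %*%
                                 unname(beta[paste0("score_", score_ph)]))
        else rep(0, n)
  rate <- config$survival$baseline_hazard * exp(lp)
  t_event <- -log(u_event) / rate
  t_cens <- u_cens * config$survival$censor_time_max
  os_time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  cohort <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    sample_id = sample_ids,
    os_time = os_time, event = event, age = age,
    age_group = factor(ifelse(age < 65, "<65", ">=65"),
                       levels = c("<65", ">=65")),
    sex = factor(sex, levels = c("F", "M")),
    tnm_stage = factor(stage, levels = c("I", "II", "III", "IV"),
                       ordered = TRUE),
    stringsAsFactors = FALSE)
  for (ph in score_ph) {
    cohort[[paste0("score_", ph)]] <- scores[, ph]
    cohort[[paste0("score_", ph, "_z")]] <- z[, ph]
  }
  truth <- data.frame(patient_id = cohort$patient_id, rho = rho, lp = lp,
                      stringsAsFactors = FALSE)
  attr(truth, "beta") <- beta
  list(samples = samples, cohort = cohort, truth = truth)
}

#' Simulate a single-cell expression matrix with designed QC violators
#'
#' Generates negative-binomial counts for `n_genes` genes (including the
#' 13 mitochondrial `MT-*` genes and the haemoglobin genes HBA1/HBA2/HBB,
#' so mitochondrial and erythroid fractions are computable) across
#' `n_cells` cells. Baseline cells pass the default QC thresholds; cells
#' named in `qc_violation_spec` are forced to violate exactly the named
#' rule.
#'
#' @param n_cells,n_genes Matrix dimensions. `n_genes` should be at least
#'   ~600 so baseline cells robustly exceed the minimum feature count; a
#'   `features_high` violation additionally requires
#'   `n_genes > thresholds$max_features`.
#' @param qc_violation_spec Named list mapping a rule — one of
#'   `"features_low"`, `"features_high"`, `"mito"`, `"erythroid"` — to the
#'   cell indices forced to violate it. A cell may violate only one rule.
#' @param seed Integer seed.
#' @param thresholds A [qc_thresholds()] the violations are constructed
#'   against.
#'
#' @return List with `counts` (sparse `dgCMatrix`, genes x cells, with
#'   dimnames), `genes`, `cell_ids`, and `truth` (data frame: `cell_id`,
#'   `violation`, `"none"` for clean cells).
#' @export
simulate_expression <- function(n_cells, n_genes = 2000L,
                                qc_violation_spec = list(), seed = 1L,
                                thresholds = qc_thresholds()) {
  if (n_genes < 1) stop_config("n_genes must be >= 1")
  if (n_cells < 0) stop_config("n_cells must be >= 0")
  known <- c("features_low", "features_high", "mito", "erythroid")
  bad <- setdiff(names(qc_violation_spec), known)
  if (length(bad))
    stop_config("unknown QC rule(s) in violation spec: %s",
                paste(bad, collapse = ", "))
  idx_all <- unlist(qc_violation_spec, use.names = FALSE)
  if (length(idx_all)) {
    if (any(idx_all < 1 | idx_all > n_cells))
      stop_config("violator index out of range")
    if (anyDuplicated(idx_all))
      stop_config("a cell may violate only one QC rule")
  }
  if (length(qc_violation_spec$features_high) &&
      n_genes <= thresholds$max_features)
    stop_config("features_high violators require n_genes > max_features")

  mt_genes <- paste0("MT-", c("ND1", "ND2", "CO1", "CO2", "ATP8", "ATP6",
                              "CO3", "ND3", "ND4L", "ND4", "ND5", "ND6",
                              "CYB"))
  hb_genes <- c("HBA1", "HBA2", "HBB")
  n_special <- length(mt_genes) + length(hb_genes)
  if (n_genes < n_special + 50)
    stop_config("n_genes too small (need > %d)", n_special + 50)
  genes <- c(mt_genes, hb_genes,
             sprintf("GENE%05d", seq_len(n_genes - n_special)))
  cell_ids <- if (n_cells) sprintf("cell%04d", seq_len(n_cells)) else character(0)

  with_seed(as.integer(seed), {
    counts <- matrix(0, n_genes, n_cells, dimnames = list(genes, cell_ids))
    if (n_cells > 0) {
      mu <- rlnorm(n_genes, log(0.6), 0.8)
      counts[] <- rnbinom(n_genes * n_cells, mu = rep(mu, n_cells), size = 0.5)
      # mitochondrial genes: always expressed, ~5% of the library
      mt_lambda <- 0.05 * sum(mu) / length(mt_genes)
      counts[mt_genes, ] <- rpois(length(mt_genes) * n_cells, mt_lambda) + 1
      counts[hb_genes, ] <- 0

      is_mt <- genes %in% mt_genes
      is_hb <- genes %in% hb_genes
      for (j in qc_violation_spec$mito) {
        non_mt <- sum(counts[!is_mt, j])
        counts[mt_genes, j] <- counts[mt_genes, j] +
          ceiling(0.25 * non_mt / length(mt_genes))
      }
      for (j in qc_violation_spec$erythroid)
        counts["HBB", j] <- ceiling(0.03 * sum(counts[, j]))
      for (j in qc_violation_spec$features_low) {
        target <- thresholds$min_features - 1L
        nz <- which(counts[, j] > 0 & !is_mt & !is_hb)
        keep <- nz[seq_len(max(0L, target - length(mt_genes)))]
        col <- numeric(n_genes)
        col[keep] <- counts[keep, j]
        col[is_mt] <- 1  # keep mito fraction small after the cut
        counts[, j] <- col
      }
      for (j in qc_violation_spec$features_high) {
        target <- thresholds$max_features + 1L
        zero <- which(counts[, j] == 0 & !is_hb)
        need <- target - sum(counts[, j] > 0)
        if (need > length(zero))
          stop_config("cannot reach %d features with n_genes = %d",
                      target, n_genes)
        if (need > 0) counts[zero[seq_len(need)], j] <- 1
      }
    }
    violation <- rep("none", n_cells)
    for (rule in names(qc_violation_spec))
      violation[qc_violation_spec[[rule]]] <- rule
    list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "CsparseMatrix"),
         genes = genes, cell_ids = cell_ids,
         truth = data.frame(cell_id = cell_ids, violation = violation,
                            stringsAsFactors = FALSE))
  })
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Synthetic mIHC cohort configuration\n")
  cat(sprintf("  window: %g x %g um, %d islets x ~%g tumour cells (sd %g um)\n",
              x$window[1], x$window[2], x$n_islets, x$tumor_per_islet,
              x$islet_sd_um))
  cat(sprintf("  immune cells: %s\n",
              paste(sprintf("%s=%d", names(x$immune_counts),
                            as.integer(x$immune_counts)), collapse = ", ")))
  cat(sprintf("  attraction: rho in [%g, %g], scale %g um\n",
              min(x$proximity_rho), max(x$proximity_rho), x$attract_scale_um))
  cat(sprintf("  survival: h0=%g, beta={%s}, censor<=%g, n=%d patients\n",
              x$survival$baseline_hazard,
              paste(sprintf("%s=%.3f", names(x$survival$beta),
                            x$survival$beta), collapse = ", "),
              x$survival$censor_time_max, x$n_patients))
  invisible(x)
}
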