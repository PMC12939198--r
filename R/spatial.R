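# Spatial quantification of immune-tumour organisation. Reference/target
# orientation is fixed throughout: tumour cells are the reference set,
# immune cells of the requested phenotype the target set (G-cross is
# asymmetric). All radii are closed: distances <= r count.

select_rows <- function(cells, labels, label_col = "phenotype") {
  if (!label_col %in% names(cells))
    stop(sprintf("column '%s' not found; run gate_phenotypes() first",
                 label_col), call. = FALSE)
  cells[[label_col]] %in% labels
}

#' Cross-type nearest-neighbour distribution (G-cross) with AUC score
#'
#' The empirical G-cross function `G(r)` is the fraction of reference
#' tumour cells whose nearest target-phenotype cell lies within distance
#' `r` — the uncorrected empirical CDF of the cross nearest-neighbour
#' distances — evaluated on a uniform grid from 0 to `r_max_um`. The
#' proximity score is the area under the curve (trapezoid rule) divided by
#' `r_max_um`, hence in \[0, 1\]: higher means target cells systematically
#' closer to tumour cells.
#'
#' With `border_correction = TRUE` the reference set is restricted to
#' tumour cells at least `r_max_um` from the window edge (reduced-sample
#' estimator); the default is the uncorrected estimator, matching the
#' plain "probability of occurrence within a radius" reading.
#'
#' If the target phenotype is absent the curve is identically zero and the
#' score 0 with `empty_target = TRUE` (absence of the subset is treated as
#' informative, not missing).
#'
#' @param cells Gated cell table.
#' @param phenotype Target phenotype label (or vector of labels, pooled).
#' @param r_max_um Upper radius in micrometres (> 0); the default 30 um
#'   with `n_r = 61` gives a 0.5-um grid.
#' @param n_r Number of grid points (including 0 and `r_max_um`).
#' @param border_correction Logical, see above.
#' @param window `c(xmin, xmax, ymin, ymax)`; needed only for the border
#'   correction (defaults to `attr(cells, "window")`, else the bounding
#'   box).
#' @param label_col Column holding phenotype labels (the generator's
#'   ground truth may be used via `"true_label"`).
#'
#' @return Object of class `gcross_curve`: `r`, `g`, `n_reference`,
#'   `n_target`, `auc` (um), `score`, `empty_target`.
#' @export
#' @examples
#' cells <- data.frame(x_um = c(0, 10, 3), y_um = c(0, 0, 4),
#'                     phenotype = c("tumor", "tumor", "cd8"))
#' gcross(cells, "cd8")$score
gcross <- function(cells, phenotype, r_max_um = 30, n_r = 61L,
                   border_correction = FALSE, window = NULL,
                   label_col = "phenotype") {
  if (!is.finite(r_max_um) || r_max_um <= 0)
    stop_config("r_max_um must be > 0")
  ref <- select_rows(cells, "tumor", label_col)
  tgt <- select_rows(cells, phenotype, label_col)
  if (!any(ref)) stop("no tumour (reference) cells in sample", call. = FALSE)
  rx <- cells$x_um[ref]; ry <- cells$y_um[ref]
  if (border_correction) {
    window <- window %||% attr(cells, "window") %||%
      c(range(cells$x_um), range(cells$y_um))
    edge <- pmin(rx - window[1], window[2] - rx,
                 ry - window[3], window[4] - ry)
    if (!any(edge >= r_max_um))
      stop("border correction leaves no reference cells", call. = FALSE)
    rx <- rx[edge >= r_max_um]; ry <- ry[edge >= r_max_um]
  }
  r_grid <- seq(0, r_max_um, length.out = n_r)
  n_ref <- length(rx)
  n_tgt <- sum(tgt)
  if (n_tgt == 0L) {
    g <- rep(0, n_r)
  } else {
    nn <- sort(cross_nn_dist(rx, ry, cells$x_um[tgt], cells$y_um[tgt]))
    g <- findInterval(r_grid, nn) / n_ref
  }
  auc <- trapezoid(r_grid, g)
  structure(list(r = r_grid, g = g, n_reference = n_ref, n_target = n_tgt,
                 auc = auc, score = auc / r_max_um,
                 phenotype = paste(phenotype, collapse = "+"),
                 border_correction = border_correction,
                 empty_target = n_tgt == 0L),
            class = "gcross_curve")
}

#' @export
print.gcross_curve <- function(x, ...) {
  cat(sprintf("G-cross: tumour -> %s (%d reference, %d target cells%s)\n",
              x$phenotype, x$n_reference, x$n_target,
              if (x$border_correction) ", border-corrected" else ""))
  cat(sprintf("  AUC[0-%g um] = %.2f um, proximity score = %.3f%s\n",
              max(x$r), x$auc, x$score,
              if (x$empty_target) " (empty target set)" else ""))
  invisible(x)
}

#' @export
plot.gcross_curve <- function(x, ...) {
  plot(x$r, x$g, type = "s", ylim = c(0, 1), xlab = "r (um)",
       ylab = expression(hat(G)(r)),
       main = sprintf("G-cross, tumour -> %s (score %.3f)",
                      x$phenotype, x$score), ...)
  invisible(x)
}

#' Per-compartment density and fraction of the CD8+ population
#'
#' Density is the phenotype count divided by the compartment area in
#' square millimetres; the fraction is the phenotype's share of CD8+
#' T cells in the compartment (`NA` when the compartment holds no CD8+
#' cells).
#'
#' @param cells Gated, compartment-assigned cell table.
#' @param compartment_areas Named numeric, areas in mm^2 (> 0) for each
#'   compartment to summarise, e.g. `c(intra_tumor = ..., stroma = ...)`
#'   from [compartment_areas()].
#' @param phenotype Phenotype label (or vector, pooled).
#'
#' @return Data frame: `compartment`, `n`, `density_cells_per_mm2`,
#'   `fraction_of_cd8`.
#' @export
density_and_fraction <- function(cells, compartment_areas, phenotype) {
  if (is.null(names(compartment_areas)) ||
      any(!is.finite(compartment_areas) | compartment_areas <= 0))
    stop_config("compartment_areas must be named, finite and > 0 (mm^2)")
  if (!"compartment" %in% names(cells))
    stop("compartments not assigned; run assign_compartments()",
         call. = FALSE)
  is_ph <- select_rows(cells, phenotype)
  is_cd8 <- select_rows(cells, cd8_labels())
  out <- lapply(names(compartment_areas), function(cp) {
    in_cp <- cells$compartment == cp
    n <- sum(is_ph & in_cp)
    n_cd8 <- sum(is_cd8 & in_cp)
    data.frame(compartment = cp, n = n,
               density_cells_per_mm2 = n / compartment_areas[[cp]],
               fraction_of_cd8 = if (n_cd8 > 0)
                 sum(is_ph & is_cd8 & in_cp) / n_cd8 else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compartment areas in mm^2 from a tumour region
#'
#' @param region A [build_tumor_region()].
#' @param window Optional window override `c(xmin, xmax, ymin, ymax)`.
#' @return `c(intra_tumor = ..., stroma = ...)` in mm^2.
#' @export
compartment_areas <- function(region, window = NULL) {
  stopifnot(inherits(region, "tumor_region"))
  window <- window %||% region$window
  total <- (window[2] - window[1]) * (window[4] - window[3])
  c(intra_tumor = region$area_um2 / 1e6,
    stroma = (total - region$area_um2) / 1e6)
}

#' Distance-band infiltration profile near the tumour boundary
#'
#' Stromal cells of the phenotype within `max_dist_um` of the tumour
#' boundary are binned into sequential bands of width `band_width_um`
#' (band k covers boundary distances in `((k-1)w, kw]`); each band's
#' proportion is relative to the phenotype count within the whole zone, so
#' the proportions sum to 1 whenever the zone is non-empty.
#'
#' @param cells Gated, compartment-assigned cell table (needs
#'   `boundary_distance_um`).
#' @param phenotype Phenotype label (or vector, pooled).
#' @param band_width_um Band width (default 10 um).
#' @param max_dist_um Zone depth (default 100 um); must be an integer
#'   multiple of `band_width_um`.
#'
#' @return Data frame: `band`, `lower_um`, `upper_um`, `proportion`; the
#'   number of zone cells is in `attr(, "n")`, and `attr(, "empty")` is
#'   `TRUE` for the all-zero profile returned when no cell lies in the
#'   zone.
#' @export
infiltration_profile <- function(cells, phenotype, band_width_um = 10,
                                 max_dist_um = 100) {
  k <- max_dist_um / band_width_um
  if (!is.finite(k) || abs(k - round(k)) > 1e-9 || k < 1)
    stop_config("max_dist_um must be a positive multiple of band_width_um")
  k <- as.integer(round(k))
  if (!"boundary_distance_um" %in% names(cells))
    stop("boundary distances missing; run assign_compartments()",
         call. = FALSE)
  is_ph <- select_rows(cells, phenotype)
  d <- cells$boundary_distance_um
  in_zone <- is_ph & cells$compartment == "stroma" & d > 0 & d <= max_dist_um
  n <- sum(in_zone)
  bands <- data.frame(band = seq_len(k),
                      lower_um = (seq_len(k) - 1) * band_width_um,
                      upper_um = seq_len(k) * band_width_um)
  if (n == 0L) {
    bands$proportion <- 0
    attr(bands, "empty") <- TRUE
    attr(bands, "n") <- 0L
    return(bands)
  }
  idx <- pmin(k, as.integer(ceiling(d[in_zone] / band_width_um)))
  bands$proportion <- tabulate(idx, nbins = k) / n
  attr(bands, "empty") <- FALSE
  attr(bands, "n") <- n
  bands
}

#' Count target cells within an interaction radius of each tumour cell
#'
#' For every reference tumour cell, the number of phenotype cells at
#' Euclidean distance `<= radius_um` (closed ball). Computed in chunks but
#' contractually identical to the all-pairs result.
#'
#' @param cells Gated cell table.
#' @param phenotype Target phenotype label (or vector, pooled).
#' @param radius_um Interaction radius (default 10 um).
#'
#' @return List: `counts` (per tumour cell) and `mean`.
#' @export
interaction_count <- function(cells, phenotype, radius_um = 10) {
  ref <- select_rows(cells, "tumor")
  if (!any(ref))
    stop("no tumour (reference) cells: interaction counts undefined",
         call. = FALSE)
  tgt <- select_rows(cells, phenotype)
  counts <- count_within_radius(cells$x_um[ref], cells$y_um[ref],
                                cells$x_um[tgt], cells$y_um[tgt], radius_um)
  list(counts = counts, mean = mean(counts))
}

#' Mean distance from tumour cells to the nearest phenotype cell
#'
#' Arithmetic mean, over reference tumour cells, of the distance to the
#' nearest cell of the target phenotype (micrometres). With no target
#' cells the value is `NA` and the reason is messaged.
#'
#' @inheritParams interaction_count
#' @return Numeric scalar (um), `NA` if the phenotype is absent.
#' @export
mean_nearest_distance <- function(cells, phenotype) {
  ref <- select_rows(cells, "tumor")
  if (!any(ref)) stop("no tumour (reference) cells", call. = FALSE)
  tgt <- select_rows(cells, phenotype)
  if (!any(tgt)) {
    message(sprintf("mean_nearest_distance: no '%s' cells; returning NA",
                    paste(phenotype, collapse = "+")))
    return(NA_real_)
  }
  mean(cross_nn_dist(cells$x_um[ref], cells$y_um[ref],
                     cells$x_um[tgt], cells$y_um[tgt]))
}

#' Sample-level quality gate on combined tumour + CD8+ cell count
#'
#' A sample passes when its tumour cells plus CD8+ T cells number at least
#' `min_combined` (inclusive); failing samples are excluded from spatial
#' scoring.
#'
#' @param cells Gated cell table.
#' @param min_combined Minimum combined count (default 1500).
#' @return Logical; counts in `attr(, "n_tumor")`, `attr(, "n_cd8")`.
#' @export
sample_qc <- function(cells, min_combined = 1500L) {
  n_tumor <- sum(select_rows(cells, "tumor"))
  n_cd8 <- sum(select_rows(cells, cd8_labels()))
  pass <- (n_tumor + n_cd8) >= min_combined
  attr(pass, "n_tumor") <- n_tumor
  attr(pass, "n_cd8") <- n_cd8
  pass
}

#' Per-sample spatial summary across phenotypes
#'
#' One row per phenotype: intra-tumour and stromal density and
#' CD8-fraction, whole-core mean tumour-to-phenotype nearest distance,
#' mean 10-um interaction count per tumour cell, G-cross proximity score,
#' and the 10-band infiltration profile.
#'
#' @param cells Gated, compartment-assigned cell table.
#' @param region The sample's [build_tumor_region()].
#' @param phenotypes Phenotype labels to summarise (default: all CD8+
#'   subsets).
#' @param r_max_um,band_width_um,max_dist_um,interaction_radius_um,border_correction
#'   Spatial parameters, see the individual statistics.
#'
#' @return Data frame, one row per phenotype.
#' @export
spatial_summary <- function(cells, region,
                            phenotypes = cd8_labels(),
                            r_max_um = 30, band_width_um = 10,
                            max_dist_um = 100, interaction_radius_um = 10,
                            border_correction = FALSE) {
  areas <- compartment_areas(region)
  rows <- lapply(phenotypes, function(ph) {
    df <- density_and_fraction(cells, areas, ph)
    gi <- df$compartment == "intra_tumor"
    gs <- df$compartment == "stroma"
    gc <- gcross(cells, ph, r_max_um = r_max_um,
                 border_correction = border_correction)
    ic <- interaction_count(cells, ph, radius_um = interaction_radius_um)
    nn <- suppressMessages(mean_nearest_distance(cells, ph))
    bands <- infiltration_profile(cells, ph, band_width_um, max_dist_um)
    out <- data.frame(
      sample_id = cells$sample_id[1L] %||% NA_character_,
      phenotype = ph,
      n_intra = df$n[gi], n_stroma = df$n[gs],
      density_intra = df$density_cells_per_mm2[gi],
      density_stroma = df$density_cells_per_mm2[gs],
      fraction_cd8_intra = df$fraction_of_cd8[gi],
      fraction_cd8_stroma = df$fraction_of_cd8[gs],
      mean_nn_dist_um = nn,
      interactions_per_tumor_cell = ic$mean,
      gcross_score = gc$score,
      stringsAsFactors = FALSE)
    bp <- setNames(as.list(bands$proportion),
                   sprintf("band_%02d", bands$band))
    cbind(out, as.data.frame(bp))
  })
  do.call(rbind, rows)
}
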