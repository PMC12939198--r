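# Tumour-region geometry. The intra-tumour compartment is modelled as the
# union of disks of a fixed dilation radius centred on PanCK+ cells. The
# region is kept in exact analytic form: membership is a nearest-centre
# test, the boundary is the set of circle arcs not covered by neighbouring
# disks (closed-form circle-circle intersection), signed boundary
# distances are point-to-arc distances, and the area is a scanline
# integral of the union of per-line chord intervals clipped to the window.

# --- small internal pieces -------------------------------------------------

# Union-find over 1..n given an edge list (two-column matrix).
union_find <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    a <- find(edges[k, 1L]); b <- find(edges[k, 2L])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

# Complement, on one circle, of a set of covered angular intervals.
# `start` in [0, 2*pi), `width` in (0, pi]. Returns a matrix of uncovered
# arcs (a0, a1) with a1 > a0 (a1 may exceed 2*pi for arcs crossing zero).
uncovered_arcs <- function(start, width) {
  two_pi <- 2 * pi
  if (!length(start)) return(cbind(0, two_pi))
  s <- start %% two_pi
  e <- s + width
  # split intervals that wrap past 2*pi
  wrap <- e > two_pi
  if (any(wrap)) {
    s <- c(s[!wrap], s[wrap], rep(0, sum(wrap)))
    e <- c(e[!wrap], rep(two_pi, sum(wrap)), e[wrap] - two_pi)
  }
  o <- order(s)
  s <- s[o]; e <- e[o]
  # merge
  ms <- s[1L]; me <- e[1L]
  merged <- list()
  for (k in seq_along(s)[-1L]) {
    if (s[k] <= me + 1e-12) me <- max(me, e[k])
    else { merged[[length(merged) + 1L]] <- c(ms, me); ms <- s[k]; me <- e[k] }
  }
  merged[[length(merged) + 1L]] <- c(ms, me)
  cov <- do.call(rbind, merged)
  # complement on [0, 2*pi]
  gaps <- list()
  if (cov[1L, 1L] > 1e-12) gaps[[1L]] <- c(0, cov[1L, 1L])
  if (nrow(cov) > 1L) for (k in seq_len(nrow(cov) - 1L)) {
    if (cov[k + 1L, 1L] - cov[k, 2L] > 1e-12)
      gaps[[length(gaps) + 1L]] <- c(cov[k, 2L], cov[k + 1L, 1L])
  }
  if (two_pi - cov[nrow(cov), 2L] > 1e-12)
    gaps[[length(gaps) + 1L]] <- c(cov[nrow(cov), 2L], two_pi)
  if (!length(gaps)) return(matrix(numeric(0), ncol = 2L))
  gaps <- do.call(rbind, gaps)
  # stitch the gap ending at 2*pi to the one starting at 0 (same arc)
  n <- nrow(gaps)
  if (n > 1L && gaps[1L, 1L] <= 1e-12 && two_pi - gaps[n, 2L] <= 1e-12) {
    gaps[n, 2L] <- gaps[1L, 2L] + two_pi
    gaps <- gaps[-1L, , drop = FALSE]
  }
  gaps
}

# Area of (union of equal-radius disks) clipped to the window, by
# midpoint-rule scanlines of unioned chord intervals.
disk_union_area <- function(cx, cy, r, window, dy = 0.25) {
  if (!length(cx)) return(0)
  y0 <- max(window[3], min(cy) - r)
  y1 <- min(window[4], max(cy) + r)
  if (y1 <= y0) return(0)
  ny <- max(1L, ceiling((y1 - y0) / dy))
  h <- (y1 - y0) / ny
  ys <- y0 + (seq_len(ny) - 0.5) * h
  total <- 0
  for (y in ys) {
    dyc <- cy - y
    idx <- which(abs(dyc) < r)
    if (!length(idx)) next
    half <- sqrt(r^2 - dyc[idx]^2)
    a <- pmax(window[1], cx[idx] - half)
    b <- pmin(window[2], cx[idx] + half)
    keep <- b > a
    if (!any(keep)) next
    a <- a[keep]; b <- b[keep]
    o <- order(a)
    a <- a[o]; b <- b[o]
    len <- 0; cs <- a[1L]; ce <- b[1L]
    for (k in seq_along(a)[-1L]) {
      if (a[k] <= ce) ce <- max(ce, b[k])
      else { len <- len + (ce - cs); cs <- a[k]; ce <- b[k] }
    }
    len <- len + (ce - cs)
    total <- total + len * h
  }
  total
}

# --- exported operations ---------------------------------------------------

#' Build the intra-tumour region from gated cell positions
#'
#' The region is the union of disks of radius `dilation_radius_um` centred
#' on the tumour cells, with connected components supported by fewer than
#' `min_component` tumour cells discarded (suppressing isolated PanCK+
#' debris). The region is represented analytically: disk centres plus the
#' uncovered boundary arcs of each circle, so membership tests, signed
#' boundary distances and the (window-clipped) area are computed without
#' polygonal approximation.
#'
#' @param cells Gated cell table (see [gate_phenotypes()]); rows with
#'   `phenotype == "tumor"` define the region.
#' @param dilation_radius_um Disk radius in micrometres (> 0).
#' @param min_component Minimum tumour cells per connected component.
#' @param window Observation window `c(xmin, xmax, ymin, ymax)`; defaults
#'   to `attr(cells, "window")`, else the bounding box of all cells padded
#'   by the radius. Used only to clip the reported area.
#' @param label_col Column holding the phenotype labels.
#'
#' @return Object of class `tumor_region`: centres, radius, per-centre
#'   component id, boundary arcs, `area_um2`, window. An empty region
#'   (no tumour cells, or none surviving `min_component`) has zero area.
#' @export
build_tumor_region <- function(cells, dilation_radius_um = 15,
                               min_component = 5L, window = NULL,
                               label_col = "phenotype") {
  if (!is.finite(dilation_radius_um) || dilation_radius_um <= 0)
    stop_config("dilation_radius_um must be > 0")
  if (!label_col %in% names(cells))
    stop(sprintf("column '%s' not found; run gate_phenotypes() first",
                 label_col), call. = FALSE)
  r <- dilation_radius_um
  window <- window %||% attr(cells, "window") %||%
    c(min(cells$x_um) - r, max(cells$x_um) + r,
      min(cells$y_um) - r, max(cells$y_um) + r)
  tum <- cells[cells[[label_col]] == "tumor", , drop = FALSE]

  empty <- function() structure(
    list(centers = cbind(x = numeric(0), y = numeric(0)), radius = r,
         component = integer(0), support = integer(0),
         arcs = data.frame(circle = integer(0), a0 = numeric(0),
                           a1 = numeric(0)),
         area_um2 = 0, window = window, n_tumor_cells = nrow(tum),
         min_component = as.integer(min_component)),
    class = "tumor_region")
  if (!nrow(tum)) return(empty())

  xy <- cbind(x = tum$x_um, y = tum$y_um)
  dup <- duplicated(xy)
  uc <- xy[!dup, , drop = FALSE]
  # map every tumour cell to its unique centre for component support
  key <- paste(xy[, 1L], xy[, 2L])
  ukey <- key[!dup]
  cell2u <- match(key, ukey)

  m <- nrow(uc)
  if (m > 1L) {
    d2 <- outer(uc[, 1L], uc[, 1L], "-")^2 + outer(uc[, 2L], uc[, 2L], "-")^2
    touch <- which(d2 <= (2 * r)^2 & upper.tri(d2), arr.ind = TRUE)
    comp <- union_find(m, touch)
  } else {
    d2 <- matrix(0, 1L, 1L)
    comp <- 1L
  }
  support <- as.integer(tapply(rep(1L, nrow(tum)), comp[cell2u], sum))
  names(support) <- names(table(comp[cell2u]))
  comp_keep <- as.integer(names(support))[support >= min_component]
  keep <- comp %in% comp_keep
  if (!any(keep)) return(empty())

  uc <- uc[keep, , drop = FALSE]
  comp <- match(comp[keep], comp_keep)  # renumber 1..k
  m <- nrow(uc)

  # boundary arcs: per circle, complement of intervals covered by
  # neighbouring disks (closed-form circle-circle intersection)
  if (m > 1L) {
    d2 <- outer(uc[, 1L], uc[, 1L], "-")^2 + outer(uc[, 2L], uc[, 2L], "-")^2
  } else d2 <- matrix(0, 1L, 1L)
  arcs <- vector("list", m)
  for (i in seq_len(m)) {
    nb <- which(d2[i, ] < (2 * r)^2 & seq_len(m) != i)
    if (!length(nb)) { arcs[[i]] <- cbind(0, 2 * pi); next }
    d <- sqrt(d2[i, nb])
    phi <- atan2(uc[nb, 2L] - uc[i, 2L], uc[nb, 1L] - uc[i, 1L])
    alpha <- acos(pmin(1, d / (2 * r)))
    arcs[[i]] <- uncovered_arcs(phi - alpha, 2 * alpha)
  }
  n_arcs <- vapply(arcs, nrow, integer(1))
  arcs_df <- data.frame(
    circle = rep(seq_len(m), n_arcs),
    a0 = unlist(lapply(arcs, function(a) a[, 1L])),
    a1 = unlist(lapply(arcs, function(a) a[, 2L])))

  area <- disk_union_area(uc[, 1L], uc[, 2L], r, window)
  sup_kept <- as.integer(support[as.character(comp_keep)])
  structure(list(centers = uc, radius = r, component = comp,
                 support = sup_kept, arcs = arcs_df, area_um2 = area,
                 window = window, n_tumor_cells = nrow(tum),
                 min_component = as.integer(min_component)),
            class = "tumor_region")
}

# Signed Euclidean distance from points to the region boundary
# (negative inside; the region is boundary-inclusive). +Inf for an empty
# region.
region_signed_distance <- function(region, x, y) {
  n <- length(x)
  if (!nrow(region$centers)) return(rep(Inf, n))
  cx <- region$centers[, 1L]; cy <- region$centers[, 2L]
  r <- region$radius
  d_centre <- cross_nn_dist(x, y, cx, cy)
  inside <- d_centre <= r
  best <- rep(Inf, n)
  arcs <- region$arcs
  for (ci in unique(arcs$circle)) {
    vx <- x - cx[ci]; vy <- y - cy[ci]
    rho <- sqrt(vx^2 + vy^2)
    psi <- atan2(vy, vx) %% (2 * pi)
    rows <- which(arcs$circle == ci)
    for (k in rows) {
      a0 <- arcs$a0[k]; a1 <- arcs$a1[k]
      in_arc <- (psi >= a0 & psi <= a1) |
        (psi + 2 * pi >= a0 & psi + 2 * pi <= a1)
      d_rad <- abs(rho - r)
      e0x <- cx[ci] + r * cos(a0); e0y <- cy[ci] + r * sin(a0)
      e1x <- cx[ci] + r * cos(a1); e1y <- cy[ci] + r * sin(a1)
      d_end <- pmin(sqrt((x - e0x)^2 + (y - e0y)^2),
                    sqrt((x - e1x)^2 + (y - e1y)^2))
      best <- pmin(best, ifelse(in_arc, d_rad, d_end))
    }
  }
  ifelse(inside, -best, best)
}

#' Assign tumour/stroma compartments and signed boundary distances
#'
#' Every cell inside (or exactly on) the tumour region becomes
#' `intra_tumor`, the rest `stroma`; `boundary_distance_um` is the
#' Euclidean distance to the region boundary, negative inside. With an
#' empty region all cells are stromal with distance `+Inf`.
#'
#' @param cells Cell table with `x_um`, `y_um`.
#' @param region A [build_tumor_region()] result for the same sample.
#'
#' @return `cells` with `compartment` and `boundary_distance_um` columns.
#' @export
assign_compartments <- function(cells, region) {
  stopifnot(inherits(region, "tumor_region"))
  d <- region_signed_distance(region, cells$x_um, cells$y_um)
  cells$compartment <- ifelse(is.finite(d) & d <= 0, "intra_tumor", "stroma")
  cells$boundary_distance_um <- d
  cells
}

#' Export a tumour region boundary as GeoJSON
#'
#' Writes the region's boundary arcs, each sampled as a polyline, as a
#' GeoJSON `MultiLineString` feature (coordinates in micrometres) for
#' inspection in any geometry viewer.
#'
#' @param region A [build_tumor_region()] result.
#' @param path Optional file to write to.
#' @param step_rad Angular sampling step of the arcs (radians).
#'
#' @return The GeoJSON string, invisibly when written to `path`.
#' @export
region_as_geojson <- function(region, path = NULL, step_rad = 0.05) {
  stopifnot(inherits(region, "tumor_region"))
  lines <- lapply(seq_len(nrow(region$arcs)), function(k) {
    ci <- region$arcs$circle[k]
    th <- seq(region$arcs$a0[k], region$arcs$a1[k],
              length.out = max(2L, ceiling((region$arcs$a1[k] -
                                              region$arcs$a0[k]) / step_rad)))
    cbind(region$centers[ci, 1L] + region$radius * cos(th),
          region$centers[ci, 2L] + region$radius * sin(th))
  })
  gj <- list(
    type = "Feature",
    properties = list(radius_um = region$radius,
                      area_um2 = region$area_um2,
                      n_components = length(unique(region$component))),
    geometry = list(type = "MultiLineString", coordinates = lines))
  txt <- jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @export
print.tumor_region <- function(x, ...) {
  cat(sprintf(paste0("Tumour region: %d disk(s) of radius %g um in %d ",
                     "component(s)\n  area %.0f um^2 (%.4f mm^2), built ",
                     "from %d tumour cells (min component %d)\n"),
              nrow(x$centers), x$radius, length(unique(x$component)),
              x$area_um2, x$area_um2 / 1e6, x$n_tumor_cells,
              x$min_component))
  invisible(x)
}

#' @export
plot.tumor_region <- function(x, ...) {
  plot(NA, xlim = x$window[1:2], ylim = x$window[3:4], asp = 1,
       xlab = "x (um)", ylab = "y (um)", ...)
  if (nrow(x$centers))
    points(x$centers, pch = 16, cex = 0.3, col = grey(0.7))
  for (k in seq_len(nrow(x$arcs))) {
    ci <- x$arcs$circle[k]
    th <- seq(x$arcs$a0[k], x$arcs$a1[k], length.out = 32L)
    lines(x$centers[ci, 1L] + x$radius * cos(th),
          x$centers[ci, 2L] + x$radius * sin(th), col = "firebrick")
  }
  invisible(x)
}
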