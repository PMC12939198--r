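# Independent brute-force oracles and tiny fixture builders used across
# the suite. Everything here is deliberately naive (double loops, dense
# scans, closed forms) and shares no code path with the package internals
# it checks.

# all-pairs nearest-neighbour distances, O(n*m)
oracle_nn <- function(qx, qy, rx, ry) {
  vapply(seq_along(qx), function(i) {
    if (!length(rx)) return(Inf)
    min(sqrt((qx[i] - rx)^2 + (qy[i] - ry)^2))
  }, numeric(1))
}

# all-pairs counts within a closed radius
oracle_counts <- function(qx, qy, rx, ry, radius) {
  vapply(seq_along(qx), function(i) {
    if (!length(rx)) return(0L)
    sum(sqrt((qx[i] - rx)^2 + (qy[i] - ry)^2) <= radius)
  }, integer(1))
}

# empirical G-cross on a grid from the all-pairs nn distances
oracle_gcross <- function(qx, qy, rx, ry, r_grid) {
  nn <- oracle_nn(qx, qy, rx, ry)
  vapply(r_grid, function(r) mean(nn <= r), numeric(1))
}

# a minimal gated cell table
make_cells <- function(x, y, phenotype, window = NULL,
                       compartment = NULL, boundary = NULL) {
  cells <- data.frame(sample_id = rep("S001", length(x)),
                      cell_id = sprintf("c%04d", seq_along(x)),
                      x_um = x, y_um = y, phenotype = phenotype,
                      stringsAsFactors = FALSE)
  if (!is.null(compartment)) cells$compartment <- compartment
  if (!is.null(boundary)) cells$boundary_distance_um <- boundary
  if (!is.null(window)) attr(cells, "window") <- window
  cells
}

# midpoint gating thresholds implied by a simulation config
midpoint_thresholds <- function(config) {
  m <- config$intensity_model
  setNames(exp((m$mu_neg + m$mu_pos) / 2), m$marker)
}

gate_with_truth_thresholds <- function(cells, config) {
  gate_phenotypes(cells, gating_config(midpoint_thresholds(config)))
}

# hand-worked two-group log-rank chi-square (hypergeometric moments)
oracle_logrank_chisq <- function(time, event, group1) {
  times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# exact signed distance to the boundary of a union of equal disks,
# independent of the package's arc representation: per circle, either the
# ray-angle point is uncovered (radial distance is exact) or the nearest
# uncovered angle is found by scan + bisection on the coverage predicate.
oracle_signed_dist <- function(centers, r, px, py, n_scan = 4096L) {
  covered <- function(i, theta) {
    bx <- centers[i, 1] + r * cos(theta)
    by <- centers[i, 2] + r * sin(theta)
    others <- setdiff(seq_len(nrow(centers)), i)
    if (!length(others)) return(rep(FALSE, length(theta)))
    vapply(seq_along(theta), function(k) {
      any(sqrt((bx[k] - centers[others, 1])^2 +
                 (by[k] - centers[others, 2])^2) < r - 1e-12)
    }, logical(1))
  }
  dist_pt <- function(i, theta, x, y)
    sqrt((x - centers[i, 1] - r * cos(theta))^2 +
           (y - centers[i, 2] - r * sin(theta))^2)
  vapply(seq_along(px), function(j) {
    x <- px[j]; y <- py[j]
    d_centre <- sqrt((x - centers[, 1])^2 + (y - centers[, 2])^2)
    inside <- any(d_centre <= r)
    best <- Inf
    for (i in seq_len(nrow(centers))) {
      psi <- atan2(y - centers[i, 2], x - centers[i, 1])
      if (!covered(i, psi)) {
        best <- min(best, abs(d_centre[i] - r))
        next
      }
      # nearest uncovered angle in each direction, refined by bisection
      grid <- psi + seq(0, 2 * pi, length.out = n_scan)
      cov <- covered(i, grid)
      if (all(cov)) next
      for (dir in c(1L, -1L)) {
        g <- if (dir == 1L) grid else psi - (grid - psi)
        cv <- if (dir == 1L) cov else covered(i, g)
        k <- which(!cv)[1L]
        if (is.na(k) || k == 1L) next
        lo <- g[k - 1L]; hi <- g[k]  # covered -> uncovered
        for (it in 1:60) {
          mid <- (lo + hi) / 2
          if (covered(i, mid)) lo <- mid else hi <- mid
        }
        best <- min(best, dist_pt(i, hi, x, y))
      }
    }
    if (inside) -best else best
  }, numeric(1))
}
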