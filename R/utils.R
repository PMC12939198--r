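# Internal numeric helpers: chunked cross-distance kernels and seed streams.
# All distances are Euclidean in the plane, coordinates in micrometres.

# Nearest-neighbour distance from each query point to the reference set.
# Chunked so that the n_query x n_ref distance matrix never materialises
# whole; contractually identical to the all-pairs computation.
cross_nn_dist <- function(qx, qy, rx, ry, q_chunk = 1024L, r_chunk = 4096L) {
  nq <- length(qx)
  nr <- length(rx)
  if (nq == 0L) return(numeric(0))
  if (nr == 0L) return(rep(Inf, nq))
  best <- rep(Inf, nq)
  for (q0 in seq(1L, nq, by = q_chunk)) {
    qi <- q0:min(nq, q0 + q_chunk - 1L)
    b <- rep(Inf, length(qi))
    for (r0 in seq(1L, nr, by = r_chunk)) {
      ri <- r0:min(nr, r0 + r_chunk - 1L)
      d2 <- outer(qx[qi], rx[ri], "-")^2 + outer(qy[qi], ry[ri], "-")^2
      j <- max.col(-d2, ties.method = "first")
      b <- pmin(b, d2[cbind(seq_along(qi), j)])
    }
    best[qi] <- b
  }
  sqrt(best)
}

# Number of reference points within (closed) radius of each query point.
count_within_radius <- function(qx, qy, rx, ry, radius,
                                q_chunk = 1024L, r_chunk = 4096L) {
  nq <- length(qx)
  nr <- length(rx)
  if (nq == 0L) return(integer(0))
  if (nr == 0L) return(integer(nq))
  r2 <- radius^2
  counts <- integer(nq)
  for (q0 in seq(1L, nq, by = q_chunk)) {
    qi <- q0:min(nq, q0 + q_chunk - 1L)
    cc <- integer(length(qi))
    for (r0 in seq(1L, nr, by = r_chunk)) {
      ri <- r0:min(nr, r0 + r_chunk - 1L)
      d2 <- outer(qx[qi], rx[ri], "-")^2 + outer(qy[qi], ry[ri], "-")^2
      cc <- cc + as.integer(rowSums(d2 <= r2))
    }
    counts[qi] <- cc
  }
  counts
}

# Derived 32-bit seeds: fixed per-index offsets keep earlier samples of a
# cohort stable when the cohort grows, and separate streams keep patient-
# level draws independent of within-sample draws.
derive_seed <- function(seed, index, stream = 0L) {
  as.integer((as.numeric(seed) + 100003 * as.numeric(index) +
                15485863 * as.numeric(stream)) %% 2147483629)
}

# Evaluate `code` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Trapezoid rule on an ordered grid.
trapezoid <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
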