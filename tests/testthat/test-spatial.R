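# Spatial statistics: closed-form micro-examples, all-pairs oracle
# equivalence, CSR behaviour of the G-cross estimator, and summary
# plumbing.

test_that("gcross saturates with coincident targets and vanishes beyond r_max", {
  n <- 6
  x <- runif(n, 0, 100); y <- runif(n, 0, 100)
  co <- make_cells(c(x, x), c(y, y),
                   c(rep("tumor", n), rep("trm_pd1neg", n)))
  gc <- gcross(co, "trm_pd1neg")
  expect_true(all(gc$g == 1))
  expect_equal(gc$score, 1)

  far <- make_cells(c(0, 500), c(0, 0), c("tumor", "trm_pd1neg"))
  gc2 <- gcross(far, "trm_pd1neg", r_max_um = 30)
  expect_true(all(gc2$g == 0))
  expect_identical(gc2$score, 0)
  expect_false(gc2$empty_target)

  expect_error(gcross(far, "trm_pd1neg", r_max_um = -1), "> 0")
  expect_error(gcross(make_cells(1, 1, "cd8"), "cd8"), "no tumour")
})

test_that("G-cross curve properties hold on random instances", {
  set.seed(42)
  for (i in 1:5) {
    cells <- make_cells(runif(80, 0, 200), runif(80, 0, 200),
                        sample(c("tumor", "trm_pd1neg"), 80, replace = TRUE),
                        window = c(0, 200, 0, 200))
    gc <- gcross(cells, "trm_pd1neg")
    expect_true(all(diff(gc$g) >= 0))        # monotone non-decreasing
    expect_true(all(gc$g >= 0 & gc$g <= 1))
    expect_gte(gc$score, 0); expect_lte(gc$score, 1)
    # rigid motion invariance (rotation + translation)
    th <- runif(1, 0, 2 * pi)
    rot <- make_cells(cos(th) * cells$x_um - sin(th) * cells$y_um + 50,
                      sin(th) * cells$x_um + cos(th) * cells$y_um - 20,
                      cells$phenotype)
    expect_equal(gcross(rot, "trm_pd1neg")$g, gc$g, tolerance = 1e-12)
  }
})

test_that("spatial statistics equal their all-pairs brute-force oracles", {
  set.seed(7)
  for (i in 1:6) {
    nt <- sample(20:60, 1); ni <- sample(20:60, 1)
    cells <- make_cells(c(runif(nt, 0, 300), runif(ni, 0, 300)),
                        c(runif(nt, 0, 300), runif(ni, 0, 300)),
                        c(rep("tumor", nt), rep("cd8", ni)))
    tum <- cells$phenotype == "tumor"
    # mean nearest distance
    expect_equal(mean_nearest_distance(cells, "cd8"),
                 mean(oracle_nn(cells$x_um[tum], cells$y_um[tum],
                                cells$x_um[!tum], cells$y_um[!tum])),
                 tolerance = 1e-9)
    # interaction counts
    ic <- interaction_count(cells, "cd8", radius_um = 25)
    expect_identical(ic$counts,
                     oracle_counts(cells$x_um[tum], cells$y_um[tum],
                                   cells$x_um[!tum], cells$y_um[!tum], 25))
    # G-cross values on the grid
    gc <- gcross(cells, "cd8", r_max_um = 40, n_r = 81)
    expect_equal(gc$g, oracle_gcross(cells$x_um[tum], cells$y_um[tum],
                                     cells$x_um[!tum], cells$y_um[!tum],
                                     gc$r), tolerance = 1e-9)
  }
})

test_that("the 3-4-5 example and coincident-point conventions hold", {
  tri <- make_cells(c(0, 3), c(0, 4), c("tumor", "cd8"))
  expect_equal(mean_nearest_distance(tri, "cd8"), 5, tolerance = 1e-12)
  co <- make_cells(c(10, 10), c(10, 10), c("tumor", "cd8"))
  expect_gte(interaction_count(co, "cd8")$counts[1], 1L)
  far <- make_cells(c(0, 0, 100), c(0, 5, 0),
                    c("tumor", "tumor", "cd8"))
  expect_identical(interaction_count(far, "cd8", 10)$counts, c(0L, 0L))
  expect_error(interaction_count(make_cells(1, 1, "cd8"), "cd8"),
               "no tumour")
})

test_that("density and CD8 fractions follow the counting definitions", {
  # 50 phenotype cells in a 0.5 mm^2 compartment -> 100 cells/mm^2
  cells <- make_cells(runif(80), runif(80),
                      c(rep("trm_pd1neg", 50), rep("cd8", 30)),
                      compartment = rep("intra_tumor", 80))
  df <- density_and_fraction(cells, c(intra_tumor = 0.5), "trm_pd1neg")
  expect_equal(df$density_cells_per_mm2, 100)
  expect_equal(df$fraction_of_cd8, 50 / 80)
  # the whole CD8 population has fraction 1
  all_cd8 <- density_and_fraction(cells, c(intra_tumor = 0.5), cd8_labels())
  expect_equal(all_cd8$fraction_of_cd8, 1)
  # no CD8 cells in the compartment: fraction undefined
  tum_only <- make_cells(1:4, 1:4, rep("tumor", 4),
                         compartment = rep("stroma", 4))
  df2 <- density_and_fraction(tum_only, c(stroma = 1), "trm_pd1neg")
  expect_true(is.na(df2$fraction_of_cd8))
  expect_error(density_and_fraction(cells, c(intra_tumor = 0), "cd8"),
               "> 0")
})

test_that("infiltration bands bin boundary distances as designed", {
  # all cells at 5 um: everything in band 1
  cells <- make_cells(1:10, 1:10, rep("cd8", 10),
                      compartment = rep("stroma", 10),
                      boundary = rep(5, 10))
  bp <- infiltration_profile(cells, "cd8")
  expect_equal(bp$proportion, c(1, rep(0, 9)))
  # hand-binned oracle on known distances; band k is ((k-1)w, kw]
  d <- c(0.5, 10, 10.1, 25, 99.9, 100, 101, -3, 40, 70)
  cp <- c(rep("stroma", 7), "intra_tumor", "stroma", "stroma")
  cells2 <- make_cells(seq_along(d), seq_along(d), rep("cd8", length(d)),
                       compartment = cp, boundary = d)
  bp2 <- infiltration_profile(cells2, "cd8")
  in_zone <- d > 0 & d <= 100 & cp == "stroma"
  oracle <- tabulate(ceiling(d[in_zone] / 10), 10) / sum(in_zone)
  expect_equal(bp2$proportion, oracle)
  expect_equal(sum(bp2$proportion), 1)
  expect_identical(attr(bp2, "n"), sum(in_zone))
  # empty zone: flagged zero profile
  none <- infiltration_profile(cells2, "trm_pd1neg")
  expect_true(attr(none, "empty"))
  expect_true(all(none$proportion == 0))
  expect_error(infiltration_profile(cells2, "cd8", band_width_um = 7),
               "multiple")
})

test_that("uncorrected G-cross matches the CSR closed form away from edges", {
  lambda <- 5e-4
  W <- 1000
  set.seed(99)
  rx <- runif(60, 30, W - 30); ry <- runif(60, 30, W - 30)
  radii <- c(5, 10, 20, 30)
  reps <- 60L
  g_hat <- matrix(NA_real_, reps, length(radii))
  for (b in seq_len(reps)) {
    n <- rpois(1, lambda * W * W)
    cells <- make_cells(c(rx, runif(n, 0, W)), c(ry, runif(n, 0, W)),
                        c(rep("tumor", 60), rep("cd8", n)),
                        window = c(0, W, 0, W))
    gc <- gcross(cells, "cd8", r_max_um = 30)
    g_hat[b, ] <- gc$g[match(radii, gc$r)]
  }
  theory <- 1 - exp(-lambda * pi * radii^2)
  se <- apply(g_hat, 2, sd) / sqrt(reps)
  expect_true(all(abs(colMeans(g_hat) - theory) < 3 * se))
})

test_that("border correction restricts the reference set", {
  set.seed(3)
  W <- 200
  cells <- make_cells(c(5, 100, runif(50, 0, W)),
                      c(5, 100, runif(50, 0, W)),
                      c("tumor", "tumor", rep("cd8", 50)),
                      window = c(0, W, 0, W))
  gc <- gcross(cells, "cd8", r_max_um = 30, border_correction = TRUE)
  expect_identical(gc$n_reference, 1L)  # the corner cell is dropped
  expect_error(gcross(cells[1:10, ][cells$x_um[1:10] < 50, ], "cd8",
                      r_max_um = 300, border_correction = TRUE),
               "no reference")
})

test_that("the sample quality gate applies the inclusive 1500-cell rule", {
  n_t <- 800L; n_c <- 699L
  cells <- make_cells(runif(n_t + n_c), runif(n_t + n_c),
                      c(rep("tumor", n_t), rep("cd8", n_c)))
  expect_false(sample_qc(cells))                  # 1499 combined
  cells2 <- make_cells(runif(n_t + n_c + 1), runif(n_t + n_c + 1),
                       c(rep("tumor", n_t), rep("cd8", n_c + 1L)))
  expect_true(sample_qc(cells2))                  # 1500 combined
  empty <- make_cells(numeric(0), numeric(0), character(0))
  expect_false(sample_qc(empty))
  # 'other' cells do not count towards the gate
  with_other <- make_cells(runif(2000), runif(2000),
                           c(rep("tumor", 700), rep("other", 1300)))
  expect_false(sample_qc(with_other))
})

test_that("spatial_summary aggregates every phenotype consistently", {
  cfg <- simulation_config(seed = 23, window = c(500, 500), n_islets = 3L,
                           tumor_per_islet = 70,
                           immune_counts = c(cd8 = 50, trm_pd1neg = 30,
                                             trm_pd1pos = 30))
  sim <- simulate_sample(cfg)
  g <- gate_with_truth_thresholds(sim$cells, cfg)
  reg <- build_tumor_region(g)
  g <- assign_compartments(g, reg)
  ss <- spatial_summary(g, reg)
  expect_identical(ss$phenotype, cd8_labels())
  # counts recompute from the table
  for (k in seq_len(nrow(ss))) {
    ph <- ss$phenotype[k]
    expect_identical(ss$n_intra[k],
                     sum(g$phenotype == ph & g$compartment == "intra_tumor"))
  }
  bands <- as.matrix(ss[, sprintf("band_%02d", 1:10)])
  sums <- rowSums(bands)
  expect_true(all(abs(sums - 1) < 1e-9 | sums == 0))
  expect_true(all(ss$gcross_score >= 0 & ss$gcross_score <= 1))
})
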