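# Tumour-region geometry: disk-union construction, membership, signed
# boundary distances (against an independent coverage-bisection oracle),
# area, and the monotonicity/invariance properties.

tumor_at <- function(x, y, extra_x = numeric(0), extra_y = numeric(0),
                     window = c(0, 200, 0, 200)) {
  make_cells(c(x, extra_x), c(y, extra_y),
             c(rep("tumor", length(x)), rep("cd8", length(extra_x))),
             window = window)
}

test_that("a single tumour cell yields one disk of the exact area", {
  cells <- tumor_at(100, 100)
  reg <- build_tumor_region(cells, dilation_radius_um = 15,
                            min_component = 1L)
  expect_identical(nrow(reg$centers), 1L)
  expect_lt(abs(reg$area_um2 - pi * 15^2) / (pi * 15^2), 0.005)
  # centre of the disk: inside, boundary distance -r
  ac <- assign_compartments(tumor_at(100, 100, 100, 100), reg)
  expect_identical(ac$compartment[2], "intra_tumor")
  expect_equal(ac$boundary_distance_um[2], -15, tolerance = 1e-9)
  # exactly on the boundary: inclusive, distance 0
  on_b <- assign_compartments(tumor_at(100, 100, 115, 100), reg)
  expect_identical(on_b$compartment[2], "intra_tumor")
  expect_equal(on_b$boundary_distance_um[2], 0, tolerance = 1e-9)
})

test_that("disks merge below and separate above twice the radius", {
  r <- 10
  apart <- build_tumor_region(tumor_at(c(50, 50 + 2 * r + 1), c(50, 50)),
                              r, min_component = 1L)
  expect_identical(length(unique(apart$component)), 2L)
  expect_lt(abs(apart$area_um2 - 2 * pi * r^2) / (2 * pi * r^2), 0.005)
  close_by <- build_tumor_region(tumor_at(c(50, 50 + 2 * r - 1), c(50, 50)),
                                 r, min_component = 1L)
  expect_identical(length(unique(close_by$component)), 1L)
  expect_lt(close_by$area_um2, 2 * pi * r^2)
})

test_that("small components are debris-filtered and empty regions degrade cleanly", {
  # a 6-cell islet plus one isolated cell: only the islet survives
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  cells <- tumor_at(c(50 + 5 * cos(th), 150), c(50 + 5 * sin(th), 150))
  reg <- build_tumor_region(cells, 10, min_component = 5L)
  expect_identical(nrow(reg$centers), 6L)
  ac <- assign_compartments(tumor_at(150, 150), reg)
  expect_identical(ac$compartment, "stroma")  # debris cell now stromal

  none <- make_cells(1, 1, "cd8", window = c(0, 10, 0, 10))
  reg0 <- build_tumor_region(none, 10)
  expect_identical(reg0$area_um2, 0)
  ac0 <- assign_compartments(none, reg0)
  expect_identical(ac0$compartment, "stroma")
  expect_identical(ac0$boundary_distance_um, Inf)

  expect_error(build_tumor_region(none, -5), "> 0")
})

test_that("signed distances match the independent geometric oracle", {
  set.seed(77)
  r <- 12
  for (rep in 1:4) {
    nt <- sample(3:7, 1)
    centers <- cbind(runif(nt, 30, 120), runif(nt, 30, 120))
    cells <- make_cells(centers[, 1], centers[, 2], rep("tumor", nt),
                        window = c(0, 150, 0, 150))
    reg <- build_tumor_region(cells, r, min_component = 1L)
    px <- runif(50, 0, 150); py <- runif(50, 0, 150)
    got <- assign_compartments(make_cells(px, py, rep("cd8", 50)), reg)
    want <- oracle_signed_dist(centers, r, px, py)
    expect_equal(got$boundary_distance_um, want, tolerance = 1e-6)
    expect_identical(got$compartment, ifelse(want <= 0, "intra_tumor",
                                             "stroma"))
  }
})

test_that("every cell is exactly one of intra-tumour or stroma", {
  cfg <- simulation_config(seed = 13, window = c(500, 500), n_islets = 3L,
                           tumor_per_islet = 60,
                           immune_counts = c(cd8 = 60, trm_pd1neg = 40))
  sim <- simulate_sample(cfg)
  g <- gate_with_truth_thresholds(sim$cells, cfg)
  reg <- build_tumor_region(g, min_component = 1L)
  ac <- assign_compartments(g, reg)
  expect_true(all(ac$compartment %in% c("intra_tumor", "stroma")))
  expect_identical(sum(is.na(ac$compartment)), 0L)
  # with no debris filter, every tumour cell lies inside the region
  expect_true(all(ac$boundary_distance_um[ac$phenotype == "tumor"] <= 0))
})

test_that("labels and distances are translation invariant", {
  set.seed(5)
  centers <- cbind(runif(5, 40, 110), runif(5, 40, 110))
  px <- runif(30, 0, 150); py <- runif(30, 0, 150)
  base_cells <- make_cells(centers[, 1], centers[, 2], rep("tumor", 5),
                           window = c(0, 150, 0, 150))
  reg <- build_tumor_region(base_cells, 12, min_component = 1L)
  a <- assign_compartments(make_cells(px, py, rep("cd8", 30)), reg)
  shift <- c(1000, -300)
  shifted <- make_cells(centers[, 1] + shift[1], centers[, 2] + shift[2],
                        rep("tumor", 5),
                        window = c(0 + shift[1], 150 + shift[1],
                                   0 + shift[2], 150 + shift[2]))
  reg2 <- build_tumor_region(shifted, 12, min_component = 1L)
  b <- assign_compartments(make_cells(px + shift[1], py + shift[2],
                                      rep("cd8", 30)), reg2)
  expect_identical(a$compartment, b$compartment)
  expect_equal(a$boundary_distance_um, b$boundary_distance_um,
               tolerance = 1e-9)
  expect_equal(reg$area_um2, reg2$area_um2, tolerance = 1e-6)
})

test_that("growing the dilation radius never shrinks the intra-tumour set", {
  set.seed(21)
  centers <- cbind(runif(8, 30, 170), runif(8, 30, 170))
  cells <- make_cells(centers[, 1], centers[, 2], rep("tumor", 8),
                      window = c(0, 200, 0, 200))
  px <- runif(100, 0, 200); py <- runif(100, 0, 200)
  probes <- make_cells(px, py, rep("cd8", 100))
  prev <- rep(FALSE, 100)
  for (r in c(5, 10, 20, 40)) {
    reg <- build_tumor_region(cells, r, min_component = 1L)
    inside <- assign_compartments(probes, reg)$compartment == "intra_tumor"
    expect_true(all(inside[prev]))
    prev <- inside
  }
})

test_that("region area matches the Monte-Carlo inclusion fraction", {
  cfg <- simulation_config(seed = 19, window = c(500, 500), n_islets = 3L,
                           tumor_per_islet = 60,
                           immune_counts = c(cd8 = 1L))
  sim <- simulate_sample(cfg)
  g <- gate_with_truth_thresholds(sim$cells, cfg)
  reg <- build_tumor_region(g)
  set.seed(31)
  n <- 40000L
  px <- runif(n, 0, 500); py <- runif(n, 0, 500)
  inside <- assign_compartments(make_cells(px, py, rep("cd8", n)),
                                reg)$compartment == "intra_tumor"
  p_hat <- mean(inside)
  p_area <- reg$area_um2 / (500 * 500)
  expect_lt(abs(p_hat - p_area), 3 * sqrt(p_area * (1 - p_area) / n))
})

test_that("the GeoJSON export is valid and describes the boundary", {
  reg <- build_tumor_region(tumor_at(c(50, 60), c(50, 50)), 15,
                            min_component = 1L)
  txt <- region_as_geojson(reg)
  parsed <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  expect_identical(parsed$geometry$type, "MultiLineString")
  pts <- do.call(rbind, lapply(parsed$geometry$coordinates, function(l)
    do.call(rbind, lapply(l, unlist))))
  d <- oracle_signed_dist(reg$centers, 15, pts[, 1], pts[, 2])
  expect_lt(max(abs(d)), 1e-6)  # sampled points lie on the true boundary
})
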