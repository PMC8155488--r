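# Synthetic substrate: IDW interpolation, voltage fields, fibrosis, fibers,
# diffusion calibration.

test_that("IDW is exact at data points, averages constants, matches hand values", {
  pts <- data.frame(x = c(0, 1, 3), y = c(0, 0, 0), value = c(1.7, 0, 8))
  expect_equal(idw_interpolate(pts, list(x = 0, y = 0)), 1.7)
  # all in-radius neighbors share a value
  ptsc <- data.frame(x = c(1, 2, 3), y = c(0, 1, 0), value = rep(4.2, 3))
  expect_equal(idw_interpolate(ptsc, list(x = 2, y = 0.5)), 4.2)
  # a = 2, neighbors at distances 1 and 3 with values 0 and 8:
  # weights 1 and 1/9 -> (0 + 8/9) / (10/9) = 0.8
  pts2 <- data.frame(x = c(1, 3), y = c(0, 0), value = c(0, 8))
  expect_equal(idw_interpolate(pts2, list(x = 0, y = 0), power = 2), 0.8)
  # no point in radius -> missing marker, not zero
  expect_true(is.na(idw_interpolate(pts2, list(x = 50, y = 50), radius = 10)))
  # bounded by neighbor range and invariant to point order
  set.seed(9)
  ptsr <- data.frame(x = runif(30, 0, 10), y = runif(30, 0, 10),
                     value = runif(30, 0, 5))
  q <- list(x = runif(20, 0, 10), y = runif(20, 0, 10))
  v1 <- idw_interpolate(ptsr, q)
  v2 <- idw_interpolate(ptsr[sample(30), ], q)
  expect_equal(v1, v2)
  expect_true(all(v1 >= min(ptsr$value) - 1e-12 &
                    v1 <= max(ptsr$value) + 1e-12, na.rm = TRUE))
})

test_that("synthetic voltage field is seeded and hits the low-voltage fraction", {
  geom <- lattice_geometry(c(25, 25), 0.25)  # ~ 100 x 100 nodes
  f1 <- synth_voltage_field(geom, low_frac = 0.3, seed = 11)
  f2 <- synth_voltage_field(geom, low_frac = 0.3, seed = 11)
  expect_identical(f1$field, f2$field)
  frac <- mean(f1$field < f1$cutoff)
  expect_gte(frac, 0.28); expect_lte(frac, 0.32)
  f0 <- synth_voltage_field(geom, low_frac = 0, seed = 11)
  expect_equal(sum(f0$field < f0$cutoff), 0)
  expect_gte(nrow(f1$points), 500)
  expect_true(all(f1$points$value >= 0))
  expect_error(synth_voltage_field(geom, corr_length = 0.1), "spacing")
})

test_that("fibrosis draws follow the probability-voltage relationship", {
  geom <- lattice_geometry(c(25, 25), 0.25)
  field <- synth_voltage_field(geom, seed = 3)$field
  expect_false(any(fibrosis_from_voltage(field, function(v) 0 * v, seed = 1)))
  expect_true(all(fibrosis_from_voltage(field, function(v) 0 * v + 1, seed = 1)))
  # law of large numbers: half nodes at 0.1 mV, half at 3.0 mV
  f <- fibrosis_logistic(v50 = 0.5, k = 4)
  vmix <- matrix(rep(c(0.1, 3.0), length.out = 10000), 100, 100)
  flags <- fibrosis_from_voltage(vmix, f, seed = 5)
  expect_equal(mean(flags), mean(f(c(0.1, 3.0))), tolerance = 0.02)
  expect_error(fibrosis_from_voltage(field, function(v) pmin(1, v / 5)),
               "monotone")
})

test_that("fiber fields are unit-direction, smooth, and reproducible", {
  geom <- lattice_geometry(c(20, 20), 0.5)
  u <- fiber_field(geom, "uniform", angle = 0.3)
  expect_true(all(u == 0.3))
  # swirl: tangential around the center
  sw <- fiber_field(geom, "swirl")
  cx <- mean(range(geom$x)); cy <- mean(range(geom$y))
  i <- which.min((geom$x - (cx + 5))^2 + (geom$y - cy)^2)
  # at (cx+5, cy) the tangent points along +y
  expect_equal(sin(as.vector(sw)[i]), 1, tolerance = 0.05)
  rs1 <- fiber_field(geom, "random_smooth", seed = 2)
  rs2 <- fiber_field(geom, "random_smooth", seed = 2)
  expect_identical(rs1, rs2)
  # smoothness: neighbor angle differences below 30 degrees
  dx <- abs(diff(rs1))
  expect_lt(max(dx), pi / 6)
})

test_that("substrate generation is a pure function of config and seed", {
  s1 <- cached_substrate()
  s2 <- make_substrate(lattice_geometry(c(20, 20), 0.4), seed = 7,
                       D_L = 0.1, low_frac = 0.25, corr_length = 4)
  expect_identical(s1$voltage, s2$voltage)
  expect_identical(s1$fibrosis, s2$fibrosis)
  expect_identical(s1$theta, s2$theta)
  lm <- s1$landmarks
  expect_length(unique(lm), 2)
  expect_false(any(s1$fibrosis[lm]))
})

test_that("plane-wave CV scales like the square root of D", {
  cvs <- cached_strand_cvs()
  expect_equal(cvs$cv2 / cvs$cv1, sqrt(2), tolerance = 0.05 * sqrt(2))
})

test_that("diffusion calibration reaches the target CV and reports failures", {
  sc <- genotype_baseline("wild_type", "SR")
  cal <- memo("calibration_fine", {
    calibrate_diffusion(sc, target_cv = 0.7, tol = 0.02, spacing = 0.25,
                        dt = 0.02)
  })
  expect_lte(abs(cal$achieved_cv - 0.7), 0.02)
  expect_gt(cal$D_L, 0)
  expect_error(calibrate_diffusion(sc, target_cv = 50, spacing = 0.25,
                                   dt = 0.02),
               "unreachable")
})

test_that("a fibrotic strand conducts slower at equal D (needs larger D to match)", {
  sc <- genotype_baseline("wild_type", "SR")
  nxr <- as.integer(round(30 / 0.4)) + 1L
  rows <- 9L
  set.seed(21)
  mask <- matrix(runif(nxr * rows) < 0.2, nxr, rows)
  mask[, 5] <- FALSE  # keep the measurement row conducting
  cv_clean <- strand_cv(sc, D = 0.15, spacing = 0.4, length_mm = 30,
                        rows = rows, dt = 0.05)
  cv_fib <- strand_cv(sc, D = 0.15, spacing = 0.4, length_mm = 30,
                      rows = rows, mask = mask, dt = 0.05)
  expect_lt(cv_fib, cv_clean)
})

test_that("substrate exports round-trip as plain text", {
  s <- cached_substrate()
  p <- tempfile(fileext = ".vtk")
  write_substrate_vtk(s, p)
  expect_true(file.exists(p))
  expect_match(readLines(p, n = 4)[4], "STRUCTURED_POINTS")
  pp <- tempfile(fileext = ".csv")
  write_voltage_points(s$points, pp)
  back <- read_voltage_points(pp)
  expect_equal(back$value, s$points$value, tolerance = 1e-12)
})
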