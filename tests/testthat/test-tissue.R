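# Monodomain solver: diffusion consistency, isochrone shape, termination
# detection, LAT maps, determinism, convergence.

test_that("uniform resting field stays spatially uniform (zero diffusion)", {
  sc <- genotype_baseline("wild_type", "SR")
  s0 <- crn_steady_state(sc, dt = 0.02, duration = 500)
  n <- 15L; N <- n * n
  r <- afvtrial:::cpp_tissue_run(n, n, 0.5, rep(FALSE, N), rep(0.4, N),
                                 rep(0.1, N), 4, as.numeric(sc),
                                 as.numeric(s0), 0.05, 5,
                                 integer(0), numeric(0), 2, 0,
                                 1, 0, integer(0), 1e6)
  expect_lt(diff(range(r$final_V)), 1e-9)
})

test_that("point-stimulus isochrones are circular in isotropic tissue", {
  sc <- genotype_baseline("wild_type", "SR")
  s0 <- crn_steady_state(sc, dt = 0.02, duration = 1000)
  n <- 51L; N <- n * n; dx <- 0.4
  ctr <- (n %/% 2) * n + (n %/% 2)
  stim <- as.integer(ctr + c(0, 1, -1, n, -n))
  run_iso <- function(ratio, theta = 0) {
    afvtrial:::cpp_tissue_run(n, n, dx, rep(FALSE, N), rep(theta, N),
                              rep(0.12, N), ratio, as.numeric(sc),
                              as.numeric(s0), 0.05, 45,
                              stim, 2, 2, 6000, 1e6, 0, integer(0), 1e6)
  }
  spread <- function(r) {
    act <- data.frame(node = r$act_node, time = r$act_time)
    late <- act[act$time > 25 & act$time < 35, ]
    ix <- late$node %% n; iy <- late$node %/% n
    c(sx = diff(range(ix)), sy = diff(range(iy)))
  }
  iso <- spread(run_iso(1))
  expect_lt(abs(iso["sx"] / iso["sy"] - 1), 0.07)
  # 4:1 diffusion anisotropy along x -> axis ratio ~ 2:1
  ani <- spread(run_iso(4, theta = 0))
  expect_equal(unname(ani["sx"] / ani["sy"]), 2, tolerance = 0.2)
})

test_that("termination detection follows the quiescence-window rule", {
  nx <- 4L; ny <- 3L; N <- nx * ny
  t <- seq(0, 6000, by = 5)
  # all resting: termination at induction end
  fr_rest <- matrix(-80, length(t), N)
  tr <- fake_trace(fr_rest, t, nx, ny, induction_end = 1000)
  expect_equal(detect_termination(tr, window = 500), 1000)
  # persistent 6 Hz oscillation: never terminates
  osc <- -50 + 40 * sin(2 * pi * 6 * t / 1000)
  fr_osc <- matrix(rep(osc, N), ncol = N)
  tr2 <- fake_trace(fr_osc, t, nx, ny, induction_end = 1000)
  expect_true(is.na(detect_termination(tr2, window = 500)))
  # quiescent from 4000 ms: termination at the start of the final quiescent
  # stretch (the last sub-threshold portion of the oscillation runs into it,
  # so the detected time may precede 4000 by up to one cycle)
  fr_mix <- fr_osc
  fr_mix[t >= 4000, ] <- -80
  tr3 <- fake_trace(fr_mix, t, nx, ny, induction_end = 1000)
  term <- detect_termination(tr3, window = 500)
  expect_lte(term, 4000)
  expect_gt(term, 4000 - 1000 / 6)
})

test_that("LAT maps give minimal LAT at the stimulus and missing LAT on fibrosis", {
  sub <- cached_substrate()
  sc <- genotype_baseline("wild_type", "SR")
  tr <- memo("sr_sheet_run", {
    run_tissue(sub, sc, stimulus_protocol("S1_train", 600, counts = 1),
               duration = 250, dt = 0.05, record_dt = 5)
  })
  lat <- lat_map(tr, window = c(0, 250))
  pace <- sub$landmarks[["septal_pacing_site"]]
  expect_true(is.finite(lat[pace]))
  expect_equal(which.min(lat), unname(which(lat == min(lat, na.rm = TRUE)))[1])
  expect_lte(lat[pace], min(lat, na.rm = TRUE) + 2)
  expect_true(all(is.na(lat[sub$fibrosis])))
  # downstream landmark activates later; cv_between is positive and finite
  app <- sub$landmarks[["appendage_roi"]]
  expect_gt(lat[app], lat[pace])
  cv <- cv_between(lat, sub$geom, pace, app)
  expect_gt(cv, 0.05); expect_lt(cv, 2)
})

test_that("identical runs are bit-identical (determinism)", {
  sub <- cached_substrate()
  sc <- genotype_baseline("wild_type", "AF")
  prot <- stimulus_protocol("S1_train", 300, counts = 1)
  r1 <- run_tissue(sub, sc, prot, duration = 150, dt = 0.05)
  r2 <- run_tissue(sub, sc, prot, duration = 150, dt = 0.05)
  expect_identical(r1$frames, r2$frames)
  expect_identical(r1$act, r2$act)
})

test_that("refining the lattice changes plane-wave CV by under 5%", {
  sc <- genotype_baseline("wild_type", "SR")
  cv_coarse <- strand_cv(sc, D = 0.15, spacing = 0.125, length_mm = 30,
                         dt = 0.005)
  cv_fine <- strand_cv(sc, D = 0.15, spacing = 0.0625, length_mm = 30,
                       dt = 0.005)
  expect_lt(abs(cv_fine - cv_coarse) / cv_fine, 0.05)
})

test_that("stimulus protocols validate their cycle-length structure", {
  expect_error(stimulus_protocol("burst_induction", cls = c(150, 200)),
               "non-increasing")
  expect_error(stimulus_protocol("S1_train", cls = c(600, 500)), "single")
  expect_error(stimulus_protocol("S1_train", cls = -5), "positive")
  b <- burst_protocol()
  expect_length(b$times, 20)
  expect_true(all(diff(b$times) <= 200 & diff(b$times) >= 120))
})

test_that("SR pacing propagates to the appendage; unstimulated tissue is silent", {
  tr <- memo("sr_sheet_run", {
    run_tissue(cached_substrate(), genotype_baseline("wild_type", "SR"),
               stimulus_protocol("S1_train", 600, counts = 1),
               duration = 250, dt = 0.05, record_dt = 5)
  })
  app <- cached_substrate()$landmarks[["appendage_roi"]]
  expect_true(app %in% tr$act$node)
  sub <- cached_substrate()
  sc <- genotype_baseline("wild_type", "SR")
  quiet <- run_tissue(sub, sc, stimulus_protocol("S1_train", 600, counts = 1),
                      duration = 100, dt = 0.05, stim_amp = 0)
  expect_equal(nrow(quiet$act), 0)
})
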