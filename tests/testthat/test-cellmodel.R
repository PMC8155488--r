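# CRN cell model: equilibrium, pacing, APD90 measurement, restitution.

test_that("resting CRN state is an equilibrium of the derivatives", {
  d <- crn_derivatives(crn_initial_state(), identity_scales())
  expect_lt(abs(d[["V"]]), 0.01)
  expect_error(crn_derivatives(replace(crn_initial_state(), 1, NaN)),
               "non-finite")
})

test_that("sodium-channel block removes inward upstroke current", {
  s <- crn_initial_state()
  s["V"] <- -45  # above INa activation threshold, h/j still near 1
  d_full <- crn_derivatives(s, identity_scales())
  d_block <- crn_derivatives(s, replace(identity_scales(), "gNa", 0))
  expect_lt(d_block[["V"]], d_full[["V"]])
})

test_that("long unpaced integration settles near -81 mV and stays there", {
  s2 <- crn_steady_state(duration = 2000)
  s10 <- crn_steady_state(duration = 10000)
  expect_lt(abs(s10[["V"]] + 81.2), 1.5)
  expect_lt(abs(s10[["V"]] - s2[["V"]]), 0.5)
  expect_true(all(s10[2:16] >= 0 & s10[2:16] <= 1))
  expect_true(all(s10[17:21] > 0))
})

test_that("pacing captures every beat and flags zero-amplitude stimuli", {
  tr <- cached_apd("wild_type", "SR")$trace
  expect_true(all(tr$captured))
  tr0 <- pace_cell(identity_scales(), cycle_length = 600, n_beats = 2,
                   stim_amp = 0)
  expect_false(any(tr0$captured))
})

test_that("APD90 follows its geometric definition on constructed traces", {
  # square pulse: -80 -> +20 mV for 100 ms, threshold -70 mV
  t <- seq(0, 400, by = 0.1)
  v <- ifelse(t >= 50 & t < 150, 20, -80)
  a <- measure_apd90(list(time = t, V = v))
  expect_equal(a, 100, tolerance = 0.01)
  # linear ramp +20 -> -80 over 200 ms: crossing of -70 at 180 ms
  v2 <- rep(-80, length(t))
  v2[t >= 50 & t < 100] <- 20
  ramp <- t >= 100 & t <= 300
  v2[ramp] <- 20 - 0.5 * (t[ramp] - 100)
  a2 <- measure_apd90(list(time = t, V = v2))
  expect_equal(a2, 50 + 180, tolerance = 0.2)  # upstroke at 50, cross at 280
  # flat trace: no beats
  expect_length(measure_apd90(list(time = t, V = rep(-80, length(t)))), 0)
})

test_that("halving dt changes the last-beat APD90 by less than 1 ms", {
  sc <- genotype_baseline("wild_type", "SR")
  a1 <- measure_apd90(pace_cell(sc, cycle_length = 600, n_beats = 4,
                                dt = 0.02))
  a2 <- measure_apd90(pace_cell(sc, cycle_length = 600, n_beats = 4,
                                dt = 0.01))
  expect_lt(abs(tail(a1[!is.na(a1)], 1) - tail(a2[!is.na(a2)], 1)), 1)
})

test_that("ramp restitution yields decreasing DI and AF-remodeled curves sit lower", {
  rc_af <- cached_smax("wild_type")$samples
  expect_true(all(diff(rc_af$di) < 0))
  expect_true(all(rc_af$di > 0))
  # AF-remodeled cells have shorter APD than SR cells at every common DI:
  # both curves are monotone in DI and the SR curve sits entirely above
  rc_sr <- memo("sr_rest_wt", {
    restitution_protocol(genotype_baseline("wild_type", "SR"),
                         cls = seq(600, 400, by = -50))
  })
  expect_gt(min(rc_sr$apd90), max(rc_af$apd90))
})

test_that("restitution fit recovers parameters and the Smax formula", {
  di <- seq(30, 400, by = 10)
  apd <- 50 + 200 * (1 - exp(-di / 60))
  fit <- fit_restitution(di, apd)
  expect_equal(fit$y0, 50, tolerance = 1e-6)
  expect_equal(fit$A1, 200, tolerance = 1e-6)
  expect_equal(fit$tau1, 60, tolerance = 1e-6)
  expect_equal(fit$smax, (200 / 60) * exp(-30 / 60), tolerance = 1e-6)
  expect_equal(fit$smax, 2.0218, tolerance = 1e-4)
  # Gaussian noise sigma = 5 ms: tau1 recovered within 10%
  set.seed(42)
  fitn <- fit_restitution(di, apd + rnorm(length(di), sd = 5))
  expect_lt(abs(fitn$tau1 - 60) / 60, 0.10)
  # constant APD: flat curve
  fit0 <- fit_restitution(di, rep(150, length(di)))
  expect_lt(fit0$A1, 1e-4)
  expect_lt(fit0$smax, 1e-4)
  # degenerate inputs
  expect_error(fit_restitution(rep(100, 6), rnorm(6, 200)), "degenerate")
  expect_error(fit_restitution(di[1:3], apd[1:3]), "at least 4")
  # Smax decreases when tau1 grows at fixed A1 (evaluated at fixed DI_min)
  smax_tau <- function(tau) (200 / tau) * exp(-30 / tau)
  expect_true(smax_tau(80) < smax_tau(60))
})

test_that("synthetic constant-APD cell gives exact (CL - APD, APD) pairs", {
  cls <- seq(600, 400, by = -50)
  pairs <- data.frame(cl = cls, di = cls - 150, apd90 = 150)
  expect_equal(pairs$di, pairs$cl - pairs$apd90)
})

test_that("genotype and rhythm ordering of APD90 matches the remodeling", {
  wt_sr <- cached_apd("wild_type", "SR")$apd_last
  px_sr <- cached_apd("pitx2_deficient", "SR")$apd_last
  wt_af <- cached_apd("wild_type", "AF")$apd_last
  px_af <- cached_apd("pitx2_deficient", "AF")$apd_last
  expect_lt(wt_af, wt_sr)
  expect_lt(px_af, px_sr)
  expect_lt(px_sr, wt_sr)
})
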