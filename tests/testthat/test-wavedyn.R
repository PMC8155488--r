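# Wave-dynamics metrics: CV, AFCL, dominant frequency, phase, phase
# singularities, Smax maps.

test_that("cv_between divides distance by activation delay", {
  geom <- lattice_geometry(c(35, 1), 0.5)
  a <- 1; b <- geom$nx  # 35 mm apart along x
  lat <- rep(NA_real_, geom$nx * geom$ny)
  lat[a] <- 10; lat[b] <- 60
  expect_equal(cv_between(lat, geom, a, b), 0.7)
  expect_error(cv_between(lat, geom, a, a), "distinct")
  lat[b] <- 5
  expect_error(cv_between(lat, geom, a, b), "downstream")
  # doubling distance at the same delay doubles CV
  geom2 <- lattice_geometry(c(70, 1), 0.5)
  lat2 <- rep(NA_real_, geom2$nx)
  lat2[1] <- 10; lat2[geom2$nx] <- 60
  expect_equal(cv_between(lat2, geom2, 1, geom2$nx), 1.4)
})

test_that("AFCL is the across-node mean of inter-activation intervals", {
  act <- data.frame(node = rep(1, 5), time = seq(0, 668, by = 167))
  expect_equal(afcl(act, c(0, 700)), 167)
  act2 <- data.frame(node = c(1, 1, 1, 2, 2, 2),
                     time = c(0, 150, 310, 0, 170, 350))
  expect_equal(afcl(act2, c(0, 400)), 165)
  expect_true(is.na(afcl(act[0, ], c(0, 1000))))
  expect_true(is.na(afcl(data.frame(node = 1, time = 10), c(0, 1000))))
})

sine_frames <- function(freqs, t, phases = 0) {
  phases <- rep_len(phases, length(freqs))
  sapply(seq_along(freqs), function(j)
    40 * sin(2 * pi * freqs[j] * t / 1000 + phases[j]))
}

test_that("dominant frequency finds the spectral peak per node", {
  t <- seq(0, 4000, by = 5)
  fr <- sine_frames(rep(6, 9), t)
  d <- dominant_frequency(fr, t, band = c(3, 15))
  expect_equal(d$peak, 6, tolerance = 0.15)
  expect_equal(d$mean, 6, tolerance = 0.15)
  # half at 4 Hz, half at 8 Hz
  fr2 <- sine_frames(rep(c(4, 8), each = 5), t)
  d2 <- dominant_frequency(fr2, t, band = c(3, 15))
  expect_equal(d2$peak, 8, tolerance = 0.15)
  expect_equal(d2$mean, 6, tolerance = 0.15)
  # 7 Hz with a weaker 4 Hz component
  fr3 <- cbind(40 * sin(2 * pi * 7 * t / 1000) + 15 * sin(2 * pi * 4 * t / 1000))
  d3 <- dominant_frequency(fr3, t, band = c(3, 15))
  expect_equal(d3$peak, 7, tolerance = 0.15)
  # flat node excluded
  fr4 <- cbind(fr[, 1], 0 * t)
  d4 <- dominant_frequency(fr4, t, band = c(3, 15))
  expect_true(is.na(d4$per_node[2]))
  # peak >= mean by construction
  expect_gte(d2$peak, d2$mean)
})

test_that("analytic-signal phase advances, wraps, and masks flat nodes", {
  t <- seq(0, 2000, by = 5)
  fr <- cbind(sine_frames(6, t), sine_frames(6, t, phases = pi / 2),
              0 * t)
  pf <- phase_field(fr, t)
  ph <- pf$phase[, 1]
  # monotone advance modulo wrap: increments cluster around 2*pi*f*dt
  inc <- diff(ph)
  inc <- inc[abs(inc) < pi]
  expect_equal(median(inc), 2 * pi * 6 * 0.005, tolerance = 0.02)
  # a quarter-period offset shows as ~pi/2 phase difference
  dphi <- atan2(sin(pf$phase[, 1] - pf$phase[, 2]),
                cos(pf$phase[, 1] - pf$phase[, 2]))
  expect_equal(abs(median(dphi[50:300])), pi / 2, tolerance = 0.1)
  expect_true(all(is.na(pf$phase[, 3])))
})

test_that("phase singularities carry the analytic winding number", {
  nx <- ny <- 41
  xs <- seq(-2, 2, length.out = nx)
  grid <- expand.grid(x = xs, y = xs)
  spiral <- atan2(grid$y, grid$x)
  ps <- ps_detect(spiral, nx, ny)
  expect_equal(nrow(ps), 1)
  expect_equal(ps$charge, 1)
  expect_lt(abs(ps$ix - nx / 2), 2); expect_lt(abs(ps$iy - ny / 2), 2)
  ps_neg <- ps_detect(-spiral, nx, ny)
  expect_equal(ps_neg$charge, -1)
  # planar wave: no singularity
  planar <- (2 * grid$x) %% (2 * pi) - pi
  expect_equal(nrow(ps_detect(planar, nx, ny)), 0)
})

test_that("topological charge is quasi-conserved between frames", {
  nx <- ny <- 41
  xs <- seq(-2, 2, length.out = nx)
  grid <- expand.grid(x = xs, y = xs)
  # rotating spiral: total charge constant frame to frame
  totals <- sapply(seq(0, 2 * pi, length.out = 20), function(rot) {
    ph <- atan2(grid$y, grid$x) + rot
    ph <- atan2(sin(ph), cos(ph))
    sum(ps_detect(ph, nx, ny)$charge)
  })
  expect_true(all(abs(diff(totals)) <= 2))
  expect_true(all(totals == 1))
})

test_that("PS tracking counts detections cumulatively and measures lifespans", {
  one_ps <- data.frame(ix = 10, iy = 10, charge = 1L)
  frames <- rep(list(one_ps), 100)
  t <- seq(0, 99)
  tr <- ps_track(frames, t, spacing = 1, max_jump_mm = 5)
  expect_equal(tr$ps_number, 100)
  expect_equal(nrow(tr$tracks), 1)
  expect_equal(tr$mean_lifespan, 99)
  # empty frames
  empty <- data.frame(ix = integer(0), iy = integer(0), charge = integer(0))
  tr0 <- ps_track(rep(list(empty), 10), 1:10)
  expect_equal(tr0$ps_number, 0)
  expect_equal(nrow(tr0$tracks), 0)
  expect_true(is.na(tr0$mean_lifespan))
  # opposite charges crossing paths never swap identities
  fa <- data.frame(ix = c(5, 15), iy = c(10, 10), charge = c(1L, -1L))
  fb <- data.frame(ix = c(10, 10), iy = c(10.2, 9.8), charge = c(1L, -1L))
  fc <- data.frame(ix = c(15, 5), iy = c(10, 10), charge = c(1L, -1L))
  tr2 <- ps_track(list(fa, fb, fc), 1:3, spacing = 1, max_jump_mm = 8)
  expect_equal(nrow(tr2$tracks), 2)
  expect_setequal(tr2$tracks$charge, c(1L, -1L))
  expect_true(all(tr2$tracks$lifespan == 2))
})

test_that("Smax maps fit per node, locate the steepest node, and flag flats", {
  di <- seq(30, 300, by = 30)
  mk <- function(y0, A1, tau) y0 + A1 * (1 - exp(-di / tau))
  samples <- rbind(
    data.frame(node = 1, di = di, apd90 = mk(60, 150, 120)),
    data.frame(node = 2, di = di, apd90 = mk(60, 200, 40)),   # steepest
    data.frame(node = 3, di = di, apd90 = rep(150, length(di))))
  sm <- smax_map(samples)
  expect_equal(sm$argmax_node, 2)
  expect_lt(sm$per_node[["3"]], 1e-4)
  expect_equal(sm$mean_smax, mean(sm$per_node), tolerance = 1e-12)
  # insufficient samples are excluded with a warning past 50%
  sparse <- rbind(data.frame(node = 1, di = di[1:2], apd90 = mk(60, 150, 120)[1:2]),
                  data.frame(node = 2, di = di[1:2], apd90 = mk(60, 150, 120)[1:2]))
  expect_warning(smax_map(sparse), "excluded")
})
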