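# Synthetic atrial substrate: monolayer lattice geometry, spatially
# correlated bipolar-voltage fields, IDW interpolation, voltage-driven
# fibrosis, fiber-orientation fields, and diffusion calibration to a target
# conduction velocity. Stands in for patient CT + electroanatomical maps.

#' Regular 2D lattice geometry for a monolayer sheet
#'
#' @param size_mm Sheet extent `c(width, height)` in mm.
#' @param spacing Node spacing (mm).
#' @return Object of class `af_geometry`: `nx`, `ny`, `spacing`, node
#'   coordinate vectors `x`, `y` (mm; nodes in column-major order, x fastest).
#' @export
lattice_geometry <- function(size_mm = c(50, 50), spacing = 0.25) {
  stopifnot(spacing > 0, all(size_mm > 0))
  nx <- as.integer(round(size_mm[1] / spacing)) + 1L
  ny <- as.integer(round(size_mm[2] / spacing)) + 1L
  xs <- (seq_len(nx) - 1) * spacing
  ys <- (seq_len(ny) - 1) * spacing
  structure(list(nx = nx, ny = ny, spacing = spacing,
                 x = rep(xs, times = ny), y = rep(ys, each = nx)),
            class = "af_geometry")
}

#' Inverse-distance-weighted interpolation
#'
#' Interpolates point samples onto query positions with weights
#' `d^-a` normalized over the known points within `radius` of each query.
#' A query coinciding with a known point returns that point's value exactly;
#' queries with no known point in radius get `NA` (missing-value marker).
#'
#' @param points Data frame with columns `x`, `y` (mm) and `value`.
#' @param query Data frame (or list) with columns `x`, `y`.
#' @param power IDW exponent `a` (> 0), default 2.
#' @param radius Neighborhood radius (mm), default 10.
#' @return Numeric vector of interpolated values at the query positions.
#' @export
idw_interpolate <- function(points, query, power = 2, radius = 10) {
  stopifnot(power > 0, radius > 0, nrow(points) > 0)
  px <- points$x; py <- points$y; pv <- points$value
  qx <- query$x; qy <- query$y
  out <- rep(NA_real_, length(qx))
  for (j in seq_along(qx)) {
    d2 <- (px - qx[j])^2 + (py - qy[j])^2
    near <- which(d2 <= radius^2)
    if (!length(near)) next
    d2n <- d2[near]
    exact <- near[d2n < 1e-18]
    if (length(exact)) { out[j] <- pv[exact[1]]; next }
    w <- d2n^(-power / 2)
    out[j] <- sum(w * pv[near]) / sum(w)
  }
  out
}

# Gaussian-smoothed white noise on the lattice via FFT (periodic smoothing,
# adequate for a correlation-structure stand-in).
smooth_noise <- function(nx, ny, spacing, corr_length) {
  z <- matrix(rnorm(nx * ny), nx, ny)
  kx <- 2 * pi * c(0:floor(nx / 2), -(ceiling(nx / 2) - 1):-1) / (nx * spacing)
  ky <- 2 * pi * c(0:floor(ny / 2), -(ceiling(ny / 2) - 1):-1) / (ny * spacing)
  K <- outer(kx^2, ky^2, `+`)
  filt <- exp(-K * corr_length^2 / 4)
  zs <- Re(stats::fft(stats::fft(z) * filt, inverse = TRUE)) / (nx * ny)
  (zs - mean(zs)) / stats::sd(zs)
}

#' Synthetic bipolar-voltage field with catheter-style point samples
#'
#' Generates a seeded, spatially correlated positive bipolar-voltage field on
#' the lattice whose fraction of nodes below the low-voltage cutoff equals
#' `low_frac` (rank-exact by construction), plus a point subsample emulating
#' the >= 500-point catheter map from which clinical substrates are built.
#'
#' The field is Gaussian-correlated noise rank-mapped onto a lognormal
#' amplitude distribution positioned so that `P(V < cutoff) = low_frac`.
#'
#' @param geom An [lattice_geometry()].
#' @param corr_length Spatial correlation length (mm).
#' @param low_frac Target fraction of nodes below `cutoff`, in `[0, 1]`.
#' @param cutoff Low-voltage cutoff (mV), default 0.5.
#' @param sdlog Lognormal spread of amplitudes.
#' @param n_points Number of sampled points (>= 500 mirrors clinical density).
#' @param seed Integer seed; the whole field is a pure function of
#'   `(config, seed)`.
#' @return List with `field` (nx x ny matrix, mV), `points` (data frame
#'   `x`, `y`, `value`), `cutoff`, `low_frac`.
#' @export
synth_voltage_field <- function(geom, corr_length = 8, low_frac = 0.3,
                                cutoff = 0.5, sdlog = 0.8, n_points = 500,
                                seed = 1) {
  stopifnot(inherits(geom, "af_geometry"))
  if (low_frac < 0 || low_frac > 1) stop("low_frac must be in [0, 1]")
  if (corr_length < geom$spacing)
    stop("correlation length must be >= lattice spacing")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  z <- smooth_noise(geom$nx, geom$ny, geom$spacing, corr_length)
  n <- length(z)
  u <- (rank(z, ties.method = "first") - 0.5) / n
  p <- min(max(low_frac, 1e-12), 1 - 1e-12)
  meanlog <- log(cutoff) - stats::qnorm(p) * sdlog
  v <- matrix(stats::qlnorm(u, meanlog = meanlog, sdlog = sdlog),
              geom$nx, geom$ny)
  idx <- sample.int(n, min(n_points, n))
  pts <- data.frame(x = geom$x[idx], y = geom$y[idx], value = as.vector(v)[idx])
  list(field = v, points = pts, cutoff = cutoff, low_frac = low_frac)
}

# save/restore .Random.seed so seeded generators do not disturb the caller's
# RNG stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Logistic fibrosis-probability curve in bipolar voltage
#'
#' Monotone non-increasing map from bipolar voltage (mV) to fibrosis
#' probability, the injectable stand-in for published probability-voltage
#' relationships.
#'
#' @param v50 Voltage of 50% fibrosis probability (mV).
#' @param k Steepness (1/mV).
#' @return Function `f(voltage) -> probability`.
#' @export
fibrosis_logistic <- function(v50 = 0.5, k = 4) {
  force(v50); force(k)
  function(v) 1 / (1 + exp(k * (v - v50)))
}

#' Draw per-node fibrosis flags from a voltage field
#'
#' Independent Bernoulli draws with `p = prob_fn(voltage)` per node. The
#' probability function must be monotone non-increasing in voltage
#' (low-voltage tissue is more likely fibrotic); this is validated on a grid.
#'
#' @param field Voltage matrix (mV).
#' @param prob_fn Probability function, e.g. [fibrosis_logistic()].
#' @param seed Integer seed.
#' @return Logical matrix of fibrosis flags.
#' @export
fibrosis_from_voltage <- function(field, prob_fn = fibrosis_logistic(),
                                  seed = 1) {
  vs <- seq(0, 10, by = 0.05)
  pv <- prob_fn(vs)
  if (any(pv < -1e-9 | pv > 1 + 1e-9))
    stop("probability function must map into [0, 1]")
  if (any(diff(pv) > 1e-9))
    stop("probability function must be monotone non-increasing in voltage")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  p <- prob_fn(field)
  matrix(stats::runif(length(field)) < p, nrow(field), ncol(field))
}

#' Synthetic myocardial fiber-orientation field
#'
#' @param geom An [lattice_geometry()].
#' @param pattern `"uniform"` (constant angle), `"swirl"` (tangential around
#'   the sheet center), or `"random_smooth"` (seeded smooth angle field).
#' @param angle Base angle (radians) for `"uniform"`.
#' @param amplitude Angular amplitude (radians) for `"random_smooth"`.
#' @param corr_length Smoothness scale (mm) for `"random_smooth"`.
#' @param seed Integer seed.
#' @return Matrix of fiber angles (radians); unit direction is
#'   `(cos(theta), sin(theta))`.
#' @export
fiber_field <- function(geom, pattern = c("uniform", "swirl", "random_smooth"),
                        angle = 0, amplitude = pi / 3, corr_length = 10,
                        seed = 1) {
  pattern <- match.arg(pattern)
  nx <- geom$nx; ny <- geom$ny
  if (pattern == "uniform") return(matrix(angle, nx, ny))
  if (pattern == "swirl") {
    cx <- mean(range(geom$x)); cy <- mean(range(geom$y))
    th <- atan2(geom$y - cy, geom$x - cx) + pi / 2
    return(matrix(th, nx, ny))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  z <- smooth_noise(nx, ny, geom$spacing, corr_length)
  matrix(angle + amplitude * tanh(z / 2), nx, ny)
}

#' Assemble a synthetic substrate
#'
#' Combines geometry, a correlated bipolar-voltage field, voltage-driven
#' fibrosis flags, a fiber field and conduction parameters into one substrate
#' object. Landmarks `septal_pacing_site` and `appendage_roi` are placed at
#' opposite corners (with a small inset) to emulate the high-septum to
#' appendage measurement path. The whole object is a pure function of
#' `(config, seed)`.
#'
#' @param geom An [lattice_geometry()].
#' @param seed Integer seed driving field, fibrosis and fiber draws.
#' @param corr_length Voltage correlation length (mm).
#' @param low_frac Target low-voltage fraction.
#' @param cutoff Low-voltage cutoff (mV).
#' @param prob_fn Fibrosis probability function of voltage.
#' @param fiber_pattern See [fiber_field()].
#' @param D_L Longitudinal diffusion coefficient (mm^2/ms); typically set by
#'   [calibrate_diffusion()].
#' @param aniso_ratio Longitudinal-to-transverse diffusion ratio (>= 1).
#' @param inset_mm Landmark inset from the corners (mm).
#' @param fib_coupling Fibrosis conduction mode: 0 (default) renders fibrotic
#'   nodes non-conducting (zero-flux obstacles); a value in (0, 1] keeps them
#'   excitable but coupled at that fraction of `D_L` (diffuse interstitial
#'   fibrosis).
#' @return Object of class `af_substrate`.
#' @export
make_substrate <- function(geom = lattice_geometry(), seed = 1,
                           corr_length = 8, low_frac = 0.3, cutoff = 0.5,
                           prob_fn = fibrosis_logistic(),
                           fiber_pattern = "random_smooth",
                           D_L = 0.1, aniso_ratio = 4, inset_mm = 2,
                           fib_coupling = 0) {
  vf <- synth_voltage_field(geom, corr_length = corr_length,
                            low_frac = low_frac, cutoff = cutoff, seed = seed)
  fib <- fibrosis_from_voltage(vf$field, prob_fn, seed = seed + 1000L)
  th <- fiber_field(geom, fiber_pattern, seed = seed + 2000L)
  node_at <- function(x, y) {
    which.min((geom$x - x)^2 + (geom$y - y)^2)
  }
  xmax <- max(geom$x); ymax <- max(geom$y)
  lm <- c(septal_pacing_site = node_at(inset_mm, inset_mm),
          appendage_roi = node_at(xmax - inset_mm, ymax - inset_mm))
  # landmarks must be conducting
  fib[lm] <- FALSE
  structure(list(geom = geom, voltage = vf$field, points = vf$points,
                 fibrosis = fib, theta = th, D_L = D_L,
                 aniso_ratio = aniso_ratio, fib_coupling = fib_coupling,
                 landmarks = lm, seed = seed,
                 config = list(corr_length = corr_length, low_frac = low_frac,
                               cutoff = cutoff, fiber_pattern = fiber_pattern,
                               inset_mm = inset_mm,
                               fib_coupling = fib_coupling)),
            class = "af_substrate")
}

#' @export
print.af_substrate <- function(x, ...) {
  g <- x$geom
  cat(sprintf(
    "<af_substrate> %dx%d nodes (%.2f mm), %.1f%% fibrotic, D_L = %.4f mm^2/ms (ratio %g), seed %d\n",
    g$nx, g$ny, g$spacing, 100 * mean(x$fibrosis), x$D_L, x$aniso_ratio, x$seed))
  invisible(x)
}

#' Calibrate the diffusion coefficient to a target conduction velocity
#'
#' Bisection on the longitudinal diffusion coefficient until the plane-wave
#' conduction velocity on a calibration strand matches the target. The strand
#' is a thin strip paced at one end; CV is measured between 25% and 75% of
#' its length along the fiber direction.
#'
#' @param scales Conductance scale vector for the strand's myocytes.
#' @param target_cv Target conduction velocity (m/s).
#' @param tol CV tolerance (m/s).
#' @param spacing Node spacing (mm), should match the substrate.
#' @param length_mm Strand length (mm).
#' @param rows Strip width in nodes.
#' @param mask Optional logical matrix (length nodes x rows) of fibrotic
#'   flags for calibration through fibrotic tissue.
#' @param dt Tissue time step (ms).
#' @param D_range Bisection bracket (mm^2/ms).
#' @param max_iter Maximum bisection iterations.
#' @return List with `D_L`, `achieved_cv` (m/s), `iterations`. Errors when
#'   the target is unreachable within `D_range`, reporting the achieved CV
#'   range.
#' @export
calibrate_diffusion <- function(scales, target_cv = 0.7, tol = 0.02,
                                spacing = 0.25, length_mm = 40, rows = 1,
                                mask = NULL, dt = 0.02,
                                D_range = c(0.0005, 3), max_iter = 40) {
  stopifnot(target_cv > 0)
  scales <- as_scales(scales)
  # keep the bracket inside the explicit-diffusion stability limit
  D_range[2] <- min(D_range[2], 0.2 * spacing^2 / dt)
  cv_lo <- strand_cv(scales, D_range[1], spacing, length_mm, rows, mask, dt)
  cv_hi <- strand_cv(scales, D_range[2], spacing, length_mm, rows, mask, dt)
  if (is.na(cv_lo)) cv_lo <- 0
  if (is.na(cv_hi) || target_cv > cv_hi || target_cv < cv_lo)
    stop(sprintf(
      "target CV %.3f m/s unreachable: achievable range [%.3f, %.3f] m/s",
      target_cv, cv_lo, ifelse(is.na(cv_hi), NA, cv_hi)))
  lo <- D_range[1]; hi <- D_range[2]; it <- 0; cv_mid <- NA
  while (it < max_iter) {
    mid <- sqrt(lo * hi)  # CV ~ sqrt(D): bisect in log-D
    cv_mid <- strand_cv(scales, mid, spacing, length_mm, rows, mask, dt)
    if (!is.na(cv_mid) && abs(cv_mid - target_cv) <= tol)
      return(list(D_L = mid, achieved_cv = cv_mid, iterations = it + 1))
    if (is.na(cv_mid) || cv_mid < target_cv) lo <- mid else hi <- mid
    it <- it + 1
  }
  list(D_L = sqrt(lo * hi), achieved_cv = cv_mid, iterations = it)
}

#' Plane-wave conduction velocity on a calibration strand
#'
#' @inheritParams calibrate_diffusion
#' @param D Longitudinal diffusion coefficient (mm^2/ms).
#' @return CV in m/s, or `NA` if the wave fails to propagate.
#' @export
strand_cv <- function(scales, D, spacing = 0.25, length_mm = 40, rows = 1,
                      mask = NULL, dt = 0.02) {
  scales <- as_scales(scales)
  nx <- as.integer(round(length_mm / spacing)) + 1L
  ny <- as.integer(rows)
  N <- nx * ny
  msk <- if (is.null(mask)) rep(FALSE, N) else as.vector(mask)
  stopifnot(length(msk) == N)
  s0 <- crn_steady_state(scales, dt = min(dt, 0.02), duration = 2000)
  stim_nodes <- as.integer(outer(0:min(3, nx - 1), (0:(ny - 1)) * nx, `+`))
  r <- cpp_tissue_run(nx, ny, spacing, msk, rep(0, N), rep(D, N), 1.0,
                      as.numeric(scales), as.numeric(s0), dt,
                      duration = 60 + length_mm / 0.05, stim_nodes = stim_nodes,
                      stim_times = 5, stim_dur = 2, stim_amp = 4000,
                      record_dt = 1e6, record_start = 0,
                      probe_nodes = integer(0), probe_dt = 1e6)
  mid_row <- (ny %/% 2) * nx
  iA <- mid_row + as.integer(round(0.25 * (nx - 1)))
  iB <- mid_row + as.integer(round(0.75 * (nx - 1)))
  tA <- r$act_time[match(iA, r$act_node)]
  tB <- r$act_time[match(iB, r$act_node)]
  if (is.na(tA) || is.na(tB) || tB <= tA) return(NA_real_)
  dist_mm <- (iB - iA) * spacing
  dist_mm / (tB - tA)  # mm/ms = m/s
}

#' Export a substrate as a legacy-VTK text file
#'
#' Writes the lattice as a structured-points VTK file with point-data arrays
#' `voltage`, `fibrosis` and `fiber_angle`, plus a sidecar JSON manifest with
#' the generating config and seed.
#'
#' @param substrate An `af_substrate`.
#' @param path Output `.vtk` path; the manifest goes to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_substrate_vtk <- function(substrate, path) {
  g <- substrate$geom
  con <- file(path, "w")
  writeLines(c("# vtk DataFile Version 3.0", "afvtrial substrate", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", g$nx, g$ny),
               sprintf("ORIGIN 0 0 0"),
               sprintf("SPACING %g %g 1", g$spacing, g$spacing),
               sprintf("POINT_DATA %d", g$nx * g$ny),
               "SCALARS voltage float 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(signif(as.vector(substrate$voltage), 6)), con)
  writeLines(c("SCALARS fibrosis int 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(as.integer(substrate$fibrosis)), con)
  writeLines(c("SCALARS fiber_angle float 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(signif(as.vector(substrate$theta), 6)), con)
  close(con)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(c(substrate$config,
                           list(seed = substrate$seed, D_L = substrate$D_L,
                                aniso_ratio = substrate$aniso_ratio)),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read / write voltage point sets as delimited text
#'
#' @param points Data frame `x`, `y`, `value`.
#' @param path File path.
#' @return The points data frame (read) or `path` invisibly (write).
#' @export
write_voltage_points <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_voltage_points
#' @export
read_voltage_points <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("x", "y", "value") %in% names(df)))
  if (any(df$value < 0)) stop("bipolar amplitudes must be >= 0")
  df
}
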