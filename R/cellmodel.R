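# Single-cell CRN atrial myocyte: pacing, APD90, restitution and its
# maximal-slope (Smax) fit.

#' Initial (resting) state of the CRN atrial myocyte
#'
#' @return Named numeric vector of the 21 state variables: membrane potential
#'   `V` (mV), 15 gating variables in `[0, 1]`, and intracellular
#'   concentrations (mM).
#' @export
crn_initial_state <- function() cpp_crn_initial_state()

#' Time derivative of the CRN state
#'
#' Exact right-hand side of the scaled CRN ODE system, for verification and
#' equilibrium checks. Errors on non-finite state input.
#'
#' @param state 21-element state vector.
#' @param scales 13-element conductance scale vector ([identity_scales()]).
#' @param i_stim Stimulus current (pA); negative values depolarize.
#' @return Named derivative vector (per ms).
#' @export
crn_derivatives <- function(state, scales = identity_scales(), i_stim = 0) {
  out <- cpp_crn_derivs(as.numeric(state), as.numeric(as_scales(scales)), i_stim)
  names(out) <- names(crn_initial_state())
  out
}

#' Quiescent steady state for a scale vector
#'
#' Integrates the unstimulated cell until (approximate) equilibrium.
#'
#' @param scales Conductance scale vector.
#' @param dt Integration step (ms).
#' @param duration Settling time (ms).
#' @return Named state vector.
#' @export
crn_steady_state <- function(scales = identity_scales(), dt = 0.02,
                             duration = 10000) {
  s <- cpp_cell_steady(as.numeric(as_scales(scales)), dt, duration)
  names(s) <- names(crn_initial_state())
  s
}

#' Diastolic stimulus threshold by bisection
#'
#' Finds the minimum rectangular-pulse amplitude (pA, depolarizing) that
#' captures a single beat from the quiescent steady state.
#'
#' @param scales Conductance scale vector.
#' @param stim_dur Pulse duration (ms).
#' @param dt Integration step (ms).
#' @param lo,hi Bisection bracket (pA).
#' @param tol Amplitude tolerance (pA).
#' @return Threshold amplitude (pA).
#' @export
diastolic_threshold <- function(scales = identity_scales(), stim_dur = 2,
                                dt = 0.02, lo = 100, hi = 6000, tol = 50) {
  scales <- as_scales(scales)
  s0 <- crn_steady_state(scales, dt = dt, duration = 5000)
  captures <- function(amp) {
    r <- tryCatch(
      cpp_cell_run(s0, as.numeric(scales), dt, 400, 10, stim_dur, amp, 1),
      error = function(e) NULL)
    if (is.null(r)) return(TRUE)  # blow-up from excess current: above threshold
    length(r$act_times) > 0 && max(r$V) > 0
  }
  if (!captures(hi)) stop("no capture even at ", hi, " pA")
  if (captures(lo)) return(lo)
  while (hi - lo > tol) {
    mid <- 0.5 * (lo + hi)
    if (captures(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Pace a single cell at a fixed cycle length
#'
#' Applies a train of rectangular stimuli (default 2 ms, twice diastolic
#' threshold) starting from the quiescent steady state of the given scale
#' vector. Deterministic.
#'
#' @param scales Conductance scale vector.
#' @param cycle_length Pacing cycle length (ms).
#' @param n_beats Number of stimuli.
#' @param dt Integration step (ms).
#' @param stim_amp Stimulus amplitude (pA); if `NULL`, `stim_mult` times the
#'   diastolic threshold found by bisection.
#' @param stim_mult Amplitude as a multiple of threshold (used when
#'   `stim_amp` is `NULL`).
#' @param stim_dur Stimulus duration (ms).
#' @param record_dt Trace sampling interval (ms).
#' @param settle_ms Quiescent settling before the first stimulus (ms).
#' @return Object of class `ap_trace`: list with `time`, `V` (mV),
#'   `stim_times`, `act_times` (per-beat time of maximal upstroke dV/dt),
#'   `captured` (logical per stimulus: upstroke above 0 mV within the cycle),
#'   `cycle_length`, `final_state`.
#' @export
pace_cell <- function(scales = identity_scales(), cycle_length = 600,
                      n_beats = 10, dt = 0.02, stim_amp = NULL, stim_mult = 2,
                      stim_dur = 2, record_dt = 0.1, settle_ms = 2000) {
  stopifnot(cycle_length > 0, n_beats >= 1)
  scales <- as_scales(scales)
  if (is.null(stim_amp))
    stim_amp <- stim_mult * diastolic_threshold(scales, stim_dur = stim_dur, dt = dt)
  s0 <- crn_steady_state(scales, dt = dt, duration = settle_ms)
  stim_times <- (seq_len(n_beats) - 1) * cycle_length + 10
  duration <- n_beats * cycle_length + 10
  r <- cpp_cell_run(s0, as.numeric(scales), dt, duration, stim_times, stim_dur,
                    stim_amp, record_dt)
  # per-stimulus capture: an activation with peak above 0 mV within the cycle
  captured <- vapply(stim_times, function(t0) {
    w <- r$time >= t0 & r$time < t0 + cycle_length
    any(r$act_times >= t0 & r$act_times < t0 + cycle_length) && max(r$V[w]) > 0
  }, logical(1))
  structure(list(time = r$time, V = r$V, Ca_i = r$Ca_i,
                 stim_times = stim_times, act_times = r$act_times,
                 act_dvdt = r$act_dvdt, captured = captured,
                 cycle_length = cycle_length, dt = dt, stim_amp = stim_amp,
                 final_state = stats::setNames(r$final_state,
                                               names(crn_initial_state()))),
            class = "ap_trace")
}

#' @export
print.ap_trace <- function(x, ...) {
  cat(sprintf("<ap_trace> %d ms at CL %g ms, %d/%d beats captured\n",
              round(max(x$time)), x$cycle_length, sum(x$captured),
              length(x$captured)))
  invisible(x)
}

#' Action potential duration at 90% repolarization
#'
#' For each beat, APD90 is the time from activation (maximal dV/dt of the
#' upstroke) to the downward crossing of `V_rest + 0.1 * (V_peak - V_rest)`,
#' where `V_rest` is the pre-upstroke minimum of that beat, with linear
#' interpolation between samples. Beats whose repolarization never crosses
#' the threshold within the trace yield `NA` (undefined-APD flag).
#'
#' @param trace An `ap_trace`, or a list/data.frame with numeric `time` (ms)
#'   and `V` (mV).
#' @return Numeric vector of per-beat APD90 (ms); `NA` where undefined.
#'   Length 0 when no beat is found.
#' @export
measure_apd90 <- function(trace) {
  time <- trace$time; V <- trace$V
  stopifnot(length(time) == length(V), length(time) > 2)
  dv <- diff(V) / diff(time)
  # upstroke detection: upward crossings of -40 mV (or, for traces that never
  # rest below -40, of the 10% amplitude level)
  thr_up <- if (min(V) < -40 && max(V) > -30) -40 else
    min(V) + 0.5 * (max(V) - min(V))
  up <- which(V[-length(V)] < thr_up & V[-1] >= thr_up)
  if (!length(up)) return(numeric(0))
  # drop crossings within 30 ms of the previous one (noise guard)
  if (length(up) > 1) {
    keep <- c(TRUE, diff(time[up]) > 30)
    up <- up[keep]
  }
  bounds <- c(1L, up, length(V))
  out <- rep(NA_real_, length(up))
  for (b in seq_along(up)) {
    i0 <- up[b]
    # activation: max dV/dt in the 10 ms following the crossing
    w_act <- which(time >= time[i0] - 1 & time <= time[i0] + 10)
    w_act <- w_act[w_act < length(V)]
    i_act <- w_act[which.max(dv[w_act])]
    t_act <- time[i_act]
    # beat window: to next upstroke (or trace end)
    i_end <- if (b < length(up)) up[b + 1] else length(V)
    # pre-upstroke baseline: minimum between previous beat end and upstroke
    i_prev <- if (b > 1) up[b - 1] else 1L
    v_rest <- min(V[i_prev:i0])
    v_peak <- max(V[i0:i_end])
    thr <- v_rest + 0.1 * (v_peak - v_rest)
    seg <- i_act:(i_end - 1L)
    cross <- seg[V[seg] > thr & V[seg + 1L] <= thr]
    if (length(cross)) {
      i <- cross[1]
      t_cross <- time[i] + (thr - V[i]) * (time[i + 1] - time[i]) / (V[i + 1] - V[i])
      out[b] <- t_cross - t_act
    }
  }
  out
}

#' Library of cell states across one rate-adapted paced cycle
#'
#' Paces a cell down a cycle-length ramp to the target cycle length (direct
#' pacing at fast rates from rest fails to capture because the action
#' potential outlasts the cycle), then samples the full 21-variable state
#' every `sample_ms` across one final cycle. Used to seed tissue with
#' phase-distributed (spiral) initial conditions whose cells are already
#' rate-adapted.
#'
#' @param scales Conductance scale vector.
#' @param cl Target cycle length (ms).
#' @param dt Integration step (ms).
#' @param sample_ms State sampling interval (ms).
#' @return Matrix (21 x n_samples) of states over the cycle, with attributes
#'   `cl` and `captured` (whether the final cycle contained an upstroke).
#' @export
cycle_library <- function(scales, cl = 170, dt = 0.02, sample_ms = 2) {
  scales <- as.numeric(as_scales(scales))
  s <- as.numeric(crn_steady_state(scales, dt, 2000))
  amp <- 2 * diastolic_threshold(scales, dt = dt)
  ramp <- c(rep(300, 4), rep(220, 4), rep(max(170, cl), 5), rep(cl, 8))
  for (b in seq_along(ramp)) {
    r <- cpp_cell_run(s, scales, dt, ramp[b], 0, 2, amp, ramp[b])
    s <- r$final_state
  }
  nsamp <- ceiling(cl / sample_ms)
  states <- matrix(NA_real_, 21, nsamp)
  captured <- FALSE
  tacc <- 0
  for (i in seq_len(nsamp)) {
    seg <- min(sample_ms, cl - tacc)
    r <- cpp_cell_run(s, scales, dt, seg, if (tacc == 0) 0 else 1e9, 2, amp, seg)
    s <- r$final_state
    if (length(r$act_times)) captured <- TRUE
    states[, i] <- s
    tacc <- tacc + seg
  }
  attr(states, "cl") <- cl
  attr(states, "captured") <- captured
  states
}

#' Dynamic (ramp) restitution protocol
#'
#' Paces a single cell through a decreasing staircase of cycle lengths and
#' collects one `(DI, APD90)` pair per stage from its final beat, with
#' `DI = CL - APD90(previous beat)`. Stages whose final beats fail capture
#' are excluded.
#'
#' @param scales Conductance scale vector.
#' @param cls Strictly decreasing cycle lengths (ms); default 600 down to
#'   200 ms in 25 ms decrements.
#' @param beats_per_cl Beats paced at each cycle length.
#' @param dt Integration step (ms).
#' @param stim_amp Stimulus amplitude (pA); default twice diastolic threshold.
#' @return Data frame with columns `cl`, `di`, `apd90` (one row per captured
#'   stage). Errors if no stage captures.
#' @export
restitution_protocol <- function(scales = identity_scales(),
                                 cls = seq(600, 200, by = -25),
                                 beats_per_cl = 8, dt = 0.02,
                                 stim_amp = NULL) {
  if (any(diff(cls) >= 0)) stop("cycle lengths must be strictly decreasing")
  scales <- as_scales(scales)
  if (is.null(stim_amp))
    stim_amp <- 2 * diastolic_threshold(scales, dt = dt)
  s0 <- crn_steady_state(scales, dt = dt, duration = 2000)
  stim_times <- 10 + cumsum(c(0, rep(cls, times = rep(beats_per_cl, length(cls)))))
  stim_times <- stim_times[-length(stim_times)]
  duration <- max(stim_times) + min(cls)
  r <- cpp_cell_run(s0, as.numeric(scales), dt, duration, stim_times, 2,
                    stim_amp, 0.1)
  apd <- measure_apd90(list(time = r$time, V = r$V))
  act <- r$act_times
  rows <- list()
  stage_end <- cumsum(rep(beats_per_cl, length(cls)))
  for (s in seq_along(cls)) {
    # stimuli of this stage
    idx <- (stage_end[s] - beats_per_cl + 1):stage_end[s]
    st <- stim_times[idx]
    # map the last two stimuli of the stage to activations/APDs
    beat_of <- function(t0) {
      k <- which(act >= t0 & act < t0 + cls[s])
      if (length(k)) k[1] else NA_integer_
    }
    b_last <- beat_of(st[length(st)])
    b_prev <- beat_of(st[length(st) - 1])
    if (is.na(b_last) || is.na(b_prev)) next
    if (b_last > length(apd) || b_prev > length(apd)) next
    a_last <- apd[b_last]; a_prev <- apd[b_prev]
    if (is.na(a_last) || is.na(a_prev)) next
    di <- cls[s] - a_prev
    if (di <= 0) next
    rows[[length(rows) + 1]] <- data.frame(cl = cls[s], di = di, apd90 = a_last)
  }
  if (!length(rows)) stop("restitution protocol: no stage captured")
  do.call(rbind, rows)
}

#' Fit the exponential restitution curve and its maximal slope
#'
#' Fits `APD90(DI) = y0 + A1 * (1 - exp(-DI / tau1))` by bounded nonlinear
#' least squares (`A1 >= 0`, `tau1 > 0`) and evaluates the maximal slope over
#' the observed DI range, `Smax = (A1 / tau1) * exp(-DI_min / tau1)`, at the
#' smallest observed diastolic interval (the fitted curve's slope is maximal
#' there because the fit is monotone saturating).
#'
#' @param di Diastolic intervals (ms), or a data frame with columns
#'   `di`/`apd90` (e.g. from [restitution_protocol()]).
#' @param apd90 APD90 values (ms), when `di` is a vector.
#' @return Object of class `restitution_fit`: list with `y0`, `A1`, `tau1`
#'   (ms), `smax` (dimensionless), `di_min`, `samples`, `fallback` (TRUE when
#'   the nonlinear fit failed and a finite-difference slope was reported).
#' @export
fit_restitution <- function(di, apd90 = NULL) {
  if (is.data.frame(di)) { apd90 <- di$apd90; di <- di$di }
  ok <- is.finite(di) & is.finite(apd90)
  di <- di[ok]; apd90 <- apd90[ok]
  if (length(di) < 4) stop("need at least 4 samples")
  if (length(unique(round(di, 6))) < 2) stop("degenerate samples: all DIs equal")
  if (any(di <= 0)) stop("DIs must be positive")
  dat <- data.frame(di = di, apd = apd90)
  if (stats::sd(apd90) < 1e-8) {
    # flat curve: the saturating model degenerates to A1 = 0
    out <- list(y0 = mean(apd90), A1 = 0, tau1 = NA_real_, smax = 0,
                di_min = min(di), samples = dat, fallback = FALSE)
    class(out) <- "restitution_fit"
    return(out)
  }
  spread <- max(apd90) - min(apd90)
  start <- list(y0 = min(apd90), A1 = max(spread, 1e-3),
                tau1 = max(diff(range(di)) / 3, 1))
  fit <- tryCatch(
    minpack.lm::nlsLM(apd ~ y0 + A1 * (1 - exp(-di / tau1)), data = dat,
                      start = start,
                      lower = c(y0 = -Inf, A1 = 0, tau1 = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  di_min <- min(di)
  if (is.null(fit)) {
    # fallback: steepest finite-difference slope, clamped at 0
    o <- order(di)
    sl <- diff(apd90[o]) / diff(di[o])
    smax <- max(c(sl, 0), na.rm = TRUE)
    out <- list(y0 = NA_real_, A1 = NA_real_, tau1 = NA_real_,
                smax = smax, di_min = di_min,
                samples = dat, fallback = TRUE)
  } else {
    p <- coef(fit)
    smax <- (p[["A1"]] / p[["tau1"]]) * exp(-di_min / p[["tau1"]])
    out <- list(y0 = p[["y0"]], A1 = p[["A1"]], tau1 = p[["tau1"]],
                smax = unname(smax), di_min = di_min, samples = dat,
                fallback = FALSE)
  }
  class(out) <- "restitution_fit"
  out
}

#' @export
print.restitution_fit <- function(x, ...) {
  if (x$fallback)
    cat(sprintf("<restitution_fit> fallback finite-difference Smax = %.3f\n", x$smax))
  else
    cat(sprintf("<restitution_fit> y0 = %.1f, A1 = %.1f, tau1 = %.1f ms, Smax = %.3f\n",
                x$y0, x$A1, x$tau1, x$smax))
  invisible(x)
}

#' Predict APD90 from a restitution fit
#'
#' @param object A `restitution_fit`.
#' @param di Diastolic intervals (ms).
#' @param ... Unused.
#' @return Predicted APD90 (ms).
#' @export
predict.restitution_fit <- function(object, di, ...) {
  if (object$fallback) stop("fallback fit has no parametric curve")
  if (object$A1 == 0) return(rep(object$y0, length(di)))
  object$y0 + object$A1 * (1 - exp(-di / object$tau1))
}

#' Export an AP trace as delimited text
#'
#' Two-column text (`time_ms`, `V_mV`).
#'
#' @param trace An `ap_trace`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ap_trace <- function(trace, path) {
  utils::write.csv(data.frame(time_ms = trace$time, V_mV = trace$V),
                   path, row.names = FALSE)
  invisible(path)
}
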