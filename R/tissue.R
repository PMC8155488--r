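# Monodomain tissue simulation over a substrate: stimulus protocols, paced
# and AF-induction runs, termination detection, local activation maps.

#' Define a stimulus protocol
#'
#' @param kind `"S1_train"` (fixed cycle length), `"ramp"` (decreasing cycle
#'   lengths, one beat each unless `counts` given), or `"burst_induction"`
#'   (non-increasing cycle-length burst used to induce AF).
#' @param cls Cycle length(s) in ms. For `S1_train` a single value; for
#'   `ramp`/`burst_induction` the (non-increasing) sequence.
#' @param counts Beats per cycle length (recycled).
#' @param amplitude_mult Stimulus amplitude as a multiple of the single-cell
#'   diastolic threshold.
#' @param duration_ms Stimulus pulse duration (ms).
#' @param start_ms Time of the first stimulus (ms).
#' @return Object of class `stim_protocol`.
#' @export
stimulus_protocol <- function(kind = c("S1_train", "ramp", "burst_induction"),
                              cls, counts = 1, amplitude_mult = 4,
                              duration_ms = 2, start_ms = 10) {
  kind <- match.arg(kind)
  if (any(cls <= 0)) stop("cycle lengths must be positive")
  if (kind == "S1_train" && length(cls) != 1)
    stop("S1_train takes a single cycle length")
  if (kind %in% c("ramp", "burst_induction") && any(diff(cls) > 0))
    stop(kind, " cycle-length sequence must be non-increasing")
  counts <- rep_len(counts, length(cls))
  intervals <- rep(cls, times = counts)
  times <- start_ms + cumsum(c(0, intervals))[seq_along(intervals)]
  structure(list(kind = kind, cls = cls, counts = counts,
                 amplitude_mult = amplitude_mult, duration_ms = duration_ms,
                 times = times,
                 end_ms = times[length(times)] + intervals[length(intervals)]),
            class = "stim_protocol")
}

#' Cross-field AF induction protocol
#'
#' S1 plane wave launched from one sheet edge followed by a premature S2 over
#' one quadrant, timed into the S1 repolarization tail; the broken S2
#' wavefront curls into reentry. This is the standard simulation-lab
#' induction and is much cheaper than burst pacing (a few hundred ms instead
#' of seconds); [burst_protocol()] remains available.
#'
#' @param s2_delay_ms S2 timing after the S1 stimulus (ms).
#' @param amplitude_mult Amplitude multiple of diastolic threshold.
#' @return A `stim_protocol` of kind `"cross_field"`.
#' @export
cross_field_protocol <- function(s2_delay_ms = 230, amplitude_mult = 4) {
  structure(list(kind = "cross_field", cls = numeric(0), counts = integer(0),
                 amplitude_mult = amplitude_mult, duration_ms = 2,
                 times = 5, s2_time = 5 + s2_delay_ms,
                 end_ms = 5 + s2_delay_ms + 150),
            class = "stim_protocol")
}

# stimulus electrode sets for a protocol over a substrate
s1_nodes <- function(substrate, protocol, stim_radius_mm = 2) {
  g <- substrate$geom
  nodes <- if (identical(protocol$kind, "cross_field"))
    which(g$x <= min(g$x) + 2 * g$spacing)
  else
    disc_nodes(g, substrate$landmarks[["septal_pacing_site"]], stim_radius_mm)
  nodes[!substrate$fibrosis[nodes]]
}

s2_nodes <- function(substrate, protocol) {
  if (!identical(protocol$kind, "cross_field")) return(integer(0))
  g <- substrate$geom
  n <- which(g$x <= stats::median(g$x) & g$y <= stats::median(g$y))
  as.integer(n[!substrate$fibrosis[n]] - 1L)
}

s2_times <- function(protocol) {
  if (identical(protocol$kind, "cross_field")) protocol$s2_time else numeric(0)
}

#' Default AF burst-induction protocol
#'
#' 20 stimuli ramping the cycle length from 200 ms down to 120 ms at the
#' pacing site, then free running. The exact clinical induction schedule is
#' a configuration choice and is recorded in every run manifest.
#'
#' @param amplitude_mult Amplitude multiple of diastolic threshold.
#' @return A `stim_protocol`.
#' @export
burst_protocol <- function(amplitude_mult = 6) {
  cls <- round(seq(200, 120, length.out = 20))
  stimulus_protocol("burst_induction", cls = cls, counts = 1,
                    amplitude_mult = amplitude_mult)
}

# nodes within a disc around a center node (indices 1-based)
disc_nodes <- function(geom, center, radius_mm) {
  cx <- geom$x[center]; cy <- geom$y[center]
  which((geom$x - cx)^2 + (geom$y - cy)^2 <= radius_mm^2)
}

#' Run a monodomain tissue simulation
#'
#' Steps the CRN reaction coupled to anisotropic diffusion over the substrate
#' lattice, applying the stimulus protocol at the septal pacing site.
#' Fibrotic nodes are non-conducting (zero-flux). Deterministic given
#' (substrate, scales, protocol, dt).
#'
#' @param substrate An `af_substrate`.
#' @param scales Conductance scale vector.
#' @param protocol A `stim_protocol`.
#' @param duration Total simulated time (ms).
#' @param dt Time step (ms).
#' @param record_dt Frame decimation interval (ms; <= 5 ms for wave-dynamics
#'   analysis).
#' @param record_start Time of the first recorded frame (ms).
#' @param stim_radius_mm Radius of the stimulated disc (mm).
#' @param stim_amp Stimulus amplitude (pA); default
#'   `protocol$amplitude_mult` times a nominal 1000 pA threshold scale.
#' @param probe_nodes Optional node indices recorded at 1 ms.
#' @param periodic Use periodic (toroidal) boundaries instead of the no-flux
#'   sheet default; a desk-scale stand-in for closed-chamber topology.
#' @param state0 Initial state: a 21-vector (broadcast to all nodes; default
#'   the quiescent steady state of `scales`) or a full 21*N field, e.g. from
#'   [spiral_seed_state()].
#' @return Object of class `tissue_trace`: decimated voltage `frames`
#'   (frames x nodes), `frame_times`, activation table `act` (node, time,
#'   dvdt_max), `final_V`, `aborted`, `induction_end` (ms), geometry and
#'   provenance fields.
#' @export
run_tissue <- function(substrate, scales, protocol, duration, dt = 0.05,
                       record_dt = 5, record_start = 0, stim_radius_mm = 2,
                       stim_amp = NULL, probe_nodes = integer(0),
                       periodic = FALSE, state0 = NULL) {
  stopifnot(inherits(substrate, "af_substrate"),
            inherits(protocol, "stim_protocol"))
  scales <- as_scales(scales)
  g <- substrate$geom
  N <- g$nx * g$ny
  if (is.null(stim_amp)) stim_amp <- protocol$amplitude_mult * 1000
  if (is.null(state0)) state0 <- crn_steady_state(scales, dt = 0.02,
                                                  duration = 2000)
  fib <- as.vector(substrate$fibrosis)
  DL <- rep(substrate$D_L, N)
  if (substrate$fib_coupling > 0) {
    DL[fib] <- substrate$D_L * substrate$fib_coupling
    mask <- rep(FALSE, N)
  } else mask <- fib
  stim_nodes <- s1_nodes(substrate, protocol, stim_radius_mm)
  r <- cpp_tissue_run(g$nx, g$ny, g$spacing, mask,
                      as.vector(substrate$theta), DL,
                      substrate$aniso_ratio, as.numeric(scales),
                      as.numeric(state0), dt, duration,
                      as.integer(stim_nodes - 1L), protocol$times,
                      protocol$duration_ms, stim_amp, record_dt, record_start,
                      as.integer(probe_nodes - 1L), 1,
                      s2_nodes(substrate, protocol), s2_times(protocol),
                      periodic)
  act <- data.frame(node = r$act_node + 1L, time = r$act_time,
                    dvdt = r$act_dvdt)
  structure(list(frames = r$frames, frame_times = r$frame_times, act = act,
                 final_V = r$final_V, aborted = r$aborted,
                 probes = r$probes, probe_times = r$probe_times,
                 induction_end = protocol$end_ms, stim_log = list(
                   nodes = stim_nodes, times = protocol$times,
                   amplitude = stim_amp, duration = protocol$duration_ms),
                 nx = g$nx, ny = g$ny, spacing = g$spacing, dt = dt,
                 record_dt = record_dt, mask = mask,
                 scales = scales, protocol_kind = protocol$kind,
                 duration = duration),
            class = "tissue_trace")
}

#' @export
print.tissue_trace <- function(x, ...) {
  cat(sprintf(
    "<tissue_trace> %dx%d nodes, %g ms (%s), %d activations%s\n",
    x$nx, x$ny, x$duration, x$protocol_kind, nrow(x$act),
    if (x$aborted) " [ABORTED]" else ""))
  invisible(x)
}

#' Phase-distributed (spiral) initial state over a substrate
#'
#' Builds a full per-node state field whose cells sit at successive phases of
#' a rate-adapted paced cycle, arranged as an Archimedean spiral around a
#' core. Releasing the tissue from this state starts a rotor directly with
#' rate-adapted (short-APD) myocytes, the standard way to study sustained
#' reentry when the transient induction pathway is fragile.
#'
#' @param substrate An `af_substrate`.
#' @param scales Conductance scale vector (typically AF-remodeled).
#' @param cl Cycle length of the seeded rotation (ms); also the pacing rate
#'   of the underlying [cycle_library()].
#' @param pitch_mm Radial distance of one full phase turn (mm), roughly the
#'   seeded wavelength.
#' @param chirality +1 or -1 rotation sense.
#' @param center Core position `c(x, y)` in mm; default the sheet center.
#' @param lib Optional precomputed [cycle_library()] (shared across seeds).
#' @return Numeric vector of length `21 * N` (variable-major) for
#'   [run_tissue()]'s `state0`.
#' @export
spiral_seed_state <- function(substrate, scales, cl = 170, pitch_mm = 40,
                              chirality = 1, center = NULL, lib = NULL) {
  g <- substrate$geom
  n <- g$nx * g$ny
  scales <- as_scales(scales)
  if (is.null(lib)) lib <- cycle_library(scales, cl = cl)
  if (is.null(center)) center <- c(mean(range(g$x)), mean(range(g$y)))
  th <- atan2(g$y - center[2], g$x - center[1])
  rr <- sqrt((g$x - center[1])^2 + (g$y - center[2])^2)
  p <- (chirality * th / (2 * pi) + rr / pitch_mm) %% 1
  idx <- pmin(ncol(lib), 1L + floor(p * ncol(lib)))
  s0 <- lib[, idx]
  if (substrate$fib_coupling <= 0) {
    rest <- as.numeric(crn_steady_state(scales, 0.02, 2000))
    s0[, as.vector(substrate$fibrosis)] <- rest
  }
  out <- numeric(21 * n)
  for (v in 1:21) out[(v - 1) * n + seq_len(n)] <- s0[v, ]
  out
}

#' Run an AF episode on a substrate
#'
#' Starts fibrillation-like activity with the chosen induction method and
#' lets it run freely. `"spiral_seed"` (default) releases the tissue from a
#' [spiral_seed_state()]; `"burst_induction"` and `"cross_field"` use the
#' stimulus protocols of the same names. When the seeded rotor dies during
#' the settling interval the induction is retried with the opposite
#' chirality (up to `retries` times), mirroring repeated clinical induction
#' attempts; every attempt is recorded.
#'
#' @param substrate Calibrated `af_substrate`.
#' @param scales AF-remodeled conductance scale vector.
#' @param duration Episode length (ms).
#' @param dt Time step (ms).
#' @param induction `"spiral_seed"`, `"burst_induction"` or `"cross_field"`.
#' @param settle_ms Transient excluded from analysis (ms); the trace's
#'   `induction_end` for spiral seeding.
#' @param seed_cl,pitch_mm Spiral-seed parameters.
#' @param lib Optional shared [cycle_library()].
#' @param retries Additional induction attempts when activity dies within
#'   `settle_ms + 200` ms.
#' @param record_dt Frame decimation (ms).
#' @param periodic Toroidal boundaries.
#' @return A `tissue_trace` with an `attempts` field.
#' @export
run_af_induction <- function(substrate, scales, duration = 2600, dt = 0.075,
                             induction = c("spiral_seed", "burst_induction",
                                           "cross_field"),
                             settle_ms = 400, seed_cl = 170, pitch_mm = 40,
                             lib = NULL, retries = 1, record_dt = 5,
                             periodic = FALSE) {
  induction <- match.arg(induction)
  scales <- as_scales(scales)
  if (induction != "spiral_seed") {
    prot <- if (induction == "burst_induction") burst_protocol()
            else cross_field_protocol()
    tr <- run_tissue(substrate, scales, prot, duration = duration, dt = dt,
                     record_dt = record_dt, periodic = periodic)
    tr$attempts <- 1L
    return(tr)
  }
  free_prot <- structure(list(kind = "spiral_seed", cls = numeric(0),
                              counts = integer(0), amplitude_mult = 0,
                              duration_ms = 2, times = numeric(0),
                              end_ms = settle_ms),
                         class = "stim_protocol")
  if (is.null(lib)) lib <- cycle_library(scales, cl = seed_cl)
  attempt <- 0L
  tr <- NULL
  for (chir in c(1, -1, 1, -1)) {
    if (attempt > retries) break
    attempt <- attempt + 1L
    st0 <- spiral_seed_state(substrate, scales, cl = seed_cl,
                             pitch_mm = pitch_mm, chirality = chir,
                             lib = lib)
    tr <- run_tissue(substrate, scales, free_prot, duration = duration,
                     dt = dt, record_dt = record_dt, periodic = periodic,
                     state0 = st0)
    term <- detect_termination(tr)
    if (is.na(term) || term > settle_ms + 200) break
  }
  tr$attempts <- attempt
  tr
}

#' Detect AF termination in a tissue trace
#'
#' Termination is the earliest time after the induction end at which every
#' conducting node stays below the activation threshold for the full
#' quiescence window. Returns `NA` when activity persists to the end of the
#' trace.
#'
#' @param trace A `tissue_trace`.
#' @param threshold Activation threshold (mV).
#' @param window Quiescence window (ms).
#' @return Termination time (ms) or `NA`.
#' @export
detect_termination <- function(trace, threshold = -40, window = 500) {
  ft <- trace$frame_times
  keep <- ft >= trace$induction_end
  if (!any(keep)) stop("no frames after induction end; record more of the run")
  ft <- ft[keep]
  fr <- trace$frames[keep, !trace$mask, drop = FALSE]
  quiet <- apply(fr < threshold, 1, all)
  if (!length(quiet) || !any(quiet)) return(NA_real_)
  # earliest start of a quiescent stretch covering `window`
  run_start <- NA_real_
  for (i in seq_along(quiet)) {
    if (quiet[i]) {
      if (is.na(run_start)) run_start <- ft[i]
      if (ft[i] - run_start >= window) return(run_start)
    } else run_start <- NA_real_
  }
  # quiescent tail shorter than the window: only counts if it reaches the end
  # of the trace and the trace extends at least `window` past run_start
  if (!is.na(run_start) && ft[length(ft)] - run_start >= window) run_start
  else NA_real_
}

#' Local activation time map for one beat
#'
#' LAT per node is the time of maximal upstroke dV/dt within the beat window.
#' Nodes that never activate in the window (including fibrotic nodes) get
#' `NA` (missing-LAT marker).
#'
#' @param trace A `tissue_trace`.
#' @param window `c(t0, t1)` beat window (ms); default the window of the last
#'   stimulus.
#' @return Numeric vector of LATs (ms) per node.
#' @export
lat_map <- function(trace, window = NULL) {
  if (is.null(window)) {
    t0 <- max(trace$stim_log$times)
    window <- c(t0, trace$duration)
  }
  act <- trace$act
  act <- act[act$time >= window[1] & act$time <= window[2], ]
  lat <- rep(NA_real_, trace$nx * trace$ny)
  if (nrow(act)) {
    a <- act[!duplicated(act$node), ]  # events are time-ordered: first = LAT
    lat[a$node] <- a$time
  }
  lat[trace$mask] <- NA_real_
  lat
}

#' Export decimated trace frames as delimited text
#'
#' Writes the frame matrix as CSV (`time_ms` column plus one column per
#' node) together with a JSON sidecar manifest carrying `dt`, spacing,
#' dimensions and the stimulus log.
#'
#' @param trace A `tissue_trace`.
#' @param path Output `.csv` path; the manifest goes to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_trace_frames <- function(trace, path) {
  df <- as.data.frame(trace$frames)
  names(df) <- paste0("node", seq_len(ncol(df)))
  utils::write.csv(cbind(time_ms = trace$frame_times, df), path,
                   row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(nx = trace$nx, ny = trace$ny, spacing = trace$spacing,
           dt = trace$dt, record_dt = trace$record_dt,
           protocol = trace$protocol_kind,
           stim_times = trace$stim_log$times,
           stim_amplitude = trace$stim_log$amplitude,
           induction_end = trace$induction_end, aborted = trace$aborted),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Run one full case: paced SR run plus AF episode
#'
#' The paced run uses the condition's sinus-rhythm scales (APD90 and CV are
#' measured on SR currents); the AF episode uses its AF-remodeled scales
#' (AFCL, DF, PS and termination are measured on AF currents). Drug block is
#' applied on top of both.
#'
#' @param substrate Calibrated `af_substrate`.
#' @param cond An [condition()]; its `rhythm` field is ignored (both rhythm
#'   states are run).
#' @param sr_protocol Pacing protocol for the SR run; `NULL` skips it (APD90
#'   and CV then come out `NA`).
#' @param af_duration AF episode length (ms).
#' @param dt Time step (ms).
#' @param induction AF induction method, see [run_af_induction()].
#' @param lib Optional shared [cycle_library()] for the AF scales.
#' @param table Drug block table.
#' @param seed Case seed, recorded for provenance (the tissue run itself is
#'   deterministic).
#' @return List with `sr` (or `NULL`) and `af` tissue traces, resolved scale
#'   vectors, and the case manifest.
#' @export
run_case <- function(substrate, cond,
                     sr_protocol = stimulus_protocol("S1_train", 600, counts = 2),
                     af_duration = 2600, dt = 0.075,
                     induction = "spiral_seed", lib = NULL,
                     table = drug_block_table(), seed = NA_integer_) {
  sr_scales <- resolve_scales(condition(cond$genotype, "SR", cond$drug,
                                        cond$dose), table)
  af_scales <- resolve_scales(condition(cond$genotype, "AF", cond$drug,
                                        cond$dose), table)
  sr <- if (!is.null(sr_protocol))
    run_tissue(substrate, sr_scales, sr_protocol,
               duration = sr_protocol$end_ms + 500, dt = dt)
  af <- run_af_induction(substrate, af_scales, duration = af_duration,
                         dt = dt, induction = induction, lib = lib)
  list(sr = sr, af = af, sr_scales = sr_scales, af_scales = af_scales,
       manifest = list(condition = format(cond), seed = seed,
                       substrate_seed = substrate$seed, dt = dt,
                       af_duration = af_duration, induction = induction,
                       attempts = af$attempts, D_L = substrate$D_L))
}
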