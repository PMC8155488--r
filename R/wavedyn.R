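# Wave-dynamics metrics: conduction velocity, AF cycle length, dominant
# frequency, phase mapping, phase-singularity detection/tracking, and the
# per-case WaveMetrics summary.

#' Conduction velocity between two landmarks
#'
#' Distance along the sheet between the two nodes divided by their local
#' activation time difference, in m/s (mm/ms).
#'
#' @param lat Per-node LAT vector (ms), e.g. from [lat_map()].
#' @param geom An `af_geometry`.
#' @param from,to Node indices; `from` must activate before `to`.
#' @return CV (m/s).
#' @export
cv_between <- function(lat, geom, from, to) {
  if (from == to) stop("from and to must be distinct nodes")
  tA <- lat[from]; tB <- lat[to]
  if (is.na(tA) || is.na(tB)) stop("both landmarks must have a defined LAT")
  if (tB <= tA) stop("downstream node activates before (or with) the source")
  d <- sqrt((geom$x[from] - geom$x[to])^2 + (geom$y[from] - geom$y[to])^2)
  d / (tB - tA)
}

#' Mean AF cycle length from activation times
#'
#' Mean inter-activation interval per node (successive upstroke events within
#' the analysis window), averaged across nodes with at least two activations.
#'
#' @param act Activation table with columns `node`, `time` (a `tissue_trace`
#'   may be passed directly).
#' @param window `c(t0, t1)` analysis window (ms).
#' @param nodes Optional node subset.
#' @return Mean AFCL (ms); `NA` when fewer than two activations at every
#'   node (undefined flag).
#' @export
afcl <- function(act, window, nodes = NULL) {
  if (inherits(act, "tissue_trace")) act <- act$act
  a <- act[act$time >= window[1] & act$time <= window[2], ]
  if (!is.null(nodes)) a <- a[a$node %in% nodes, ]
  if (!nrow(a)) return(NA_real_)
  per_node <- tapply(a$time, a$node, function(t) {
    if (length(t) < 2) NA_real_ else mean(diff(sort(t)))
  })
  m <- per_node[!is.na(per_node)]
  if (!length(m)) return(NA_real_)
  mean(m)
}

hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

#' Dominant frequency per node and its tissue summaries
#'
#' Per-node DF is the frequency of maximal spectral power within `band`,
#' computed from the mean-subtracted, Hann-tapered periodogram of the
#' decimated voltage. Peak DF is the maximum of per-node DFs, mean DF their
#' mean; flat (non-oscillatory) nodes are excluded.
#'
#' @param frames Voltage frame matrix (frames x nodes) or a `tissue_trace`.
#' @param frame_times Frame times (ms); taken from the trace if given.
#' @param window Optional `c(t0, t1)` analysis window (ms).
#' @param band Frequency band (Hz), default 3-15 Hz.
#' @param min_sd Minimum per-node voltage SD (mV) to count as oscillatory.
#' @param mask Optional logical vector of nodes to exclude.
#' @return List with `per_node` (Hz, `NA` for excluded nodes), `peak`,
#'   `mean`, and the spectral resolution `df_hz`.
#' @export
dominant_frequency <- function(frames, frame_times = NULL, window = NULL,
                               band = c(3, 15), min_sd = 1, mask = NULL) {
  if (inherits(frames, "tissue_trace")) {
    if (is.null(mask)) mask <- frames$mask
    frame_times <- frames$frame_times
    frames <- frames$frames
  }
  stopifnot(!is.null(frame_times), nrow(frames) == length(frame_times))
  if (!is.null(window)) {
    keep <- frame_times >= window[1] & frame_times <= window[2]
    frames <- frames[keep, , drop = FALSE]
    frame_times <- frame_times[keep]
  }
  nT <- nrow(frames)
  if (nT < 16) stop("analysis window too short for spectral analysis")
  fs <- 1000 / stats::median(diff(frame_times))  # Hz
  if ((nT / fs) < 2) warning("window shorter than 2 s: DF resolution > 0.5 Hz")
  nfft <- 2 * stats::nextn(nT, 2)
  freq <- (0:(nfft - 1)) * fs / nfft
  sel <- which(freq >= band[1] & freq <= band[2])
  taper <- hann(nT)
  nnode <- ncol(frames)
  per_node <- rep(NA_real_, nnode)
  use <- if (is.null(mask)) rep(TRUE, nnode) else !mask
  use_idx <- which(use)
  dfs <- rep(NA_real_, length(use_idx))
  # chunked FFT keeps the zero-padded spectrum matrix small
  for (chunk in split(seq_along(use_idx),
                      ceiling(seq_along(use_idx) / 2000))) {
    X <- frames[, use_idx[chunk], drop = FALSE]
    X <- sweep(X, 2, colMeans(X))
    sds <- sqrt(colMeans(X^2))
    X <- X * taper
    X <- rbind(X, matrix(0, nfft - nT, ncol(X)))
    P <- Mod(stats::mvfft(X))^2
    d <- freq[sel][apply(P[sel, , drop = FALSE], 2, which.max)]
    d[sds < min_sd] <- NA_real_
    dfs[chunk] <- d
  }
  per_node[use_idx] <- dfs
  ok <- per_node[!is.na(per_node)]
  list(per_node = per_node,
       peak = if (length(ok)) max(ok) else NA_real_,
       mean = if (length(ok)) mean(ok) else NA_real_,
       df_hz = fs / nfft)
}

# analytic signal via FFT (Hilbert transform embedding)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase field of a tissue trace
#'
#' Per-node phase in `(-pi, pi]` from the analytic signal of the
#' mean-subtracted voltage; one full action-potential cycle traverses 2*pi.
#' Non-oscillatory nodes (SD below `min_sd`) are masked `NA`.
#'
#' @param frames Frame matrix (frames x nodes) or `tissue_trace`.
#' @param frame_times Frame times (ms).
#' @param window Optional analysis window (ms).
#' @param min_sd Oscillation threshold (mV).
#' @param mask Optional node exclusion mask.
#' @return List with `phase` (frames x nodes, radians), `frame_times`.
#' @export
phase_field <- function(frames, frame_times = NULL, window = NULL,
                        min_sd = 1, mask = NULL) {
  if (inherits(frames, "tissue_trace")) {
    if (is.null(mask)) mask <- frames$mask
    frame_times <- frames$frame_times
    frames <- frames$frames
  }
  if (!is.null(window)) {
    keep <- frame_times >= window[1] & frame_times <= window[2]
    frames <- frames[keep, , drop = FALSE]
    frame_times <- frame_times[keep]
  }
  ph <- matrix(NA_real_, nrow(frames), ncol(frames))
  use <- if (is.null(mask)) rep(TRUE, ncol(frames)) else !mask
  for (j in which(use)) {
    x <- frames[, j]
    x <- x - mean(x)
    if (sqrt(mean(x^2)) < min_sd) next
    ph[, j] <- Arg(analytic_signal(x))
  }
  list(phase = ph, frame_times = frame_times)
}

wrap_pi <- function(x) atan2(sin(x), cos(x))

#' Detect phase singularities in one phase frame
#'
#' Topological-charge rule: the line integral of wrapped phase differences
#' around each elementary lattice cell equals +-2*pi at a singularity and 0
#' elsewhere. Cells touching masked (`NA`) nodes are skipped.
#'
#' @param phase Phase values for one frame (length nx*ny, column-major).
#' @param nx,ny Lattice dimensions.
#' @return Data frame with `ix`, `iy` (cell lower-left corner, 1-based),
#'   `x_frac`, `y_frac` (cell-center offsets) and `charge` (+1/-1).
#' @export
ps_detect <- function(phase, nx, ny) {
  P <- matrix(phase, nx, ny)
  p1 <- P[-nx, -ny]; p2 <- P[-1, -ny]; p3 <- P[-1, -1]; p4 <- P[-nx, -1]
  s <- wrap_pi(p2 - p1) + wrap_pi(p3 - p2) + wrap_pi(p4 - p3) + wrap_pi(p1 - p4)
  hit <- which(is.finite(s) & abs(s) > pi)
  if (!length(hit))
    return(data.frame(ix = integer(0), iy = integer(0), charge = integer(0)))
  ix <- ((hit - 1) %% (nx - 1)) + 1L
  iy <- ((hit - 1) %/% (nx - 1)) + 1L
  data.frame(ix = ix, iy = iy, charge = as.integer(sign(s[hit])))
}

#' Track phase singularities across frames
#'
#' Charge-respecting nearest-neighbor association between consecutive
#' frames within a maximum jump distance. The PS number reported is the
#' cumulative count of per-frame detections over the analysis window (the
#' convention that matches fibrillation PS counts of order 1e4-1e5 over tens
#' of seconds); the lifespan is the mean track duration.
#'
#' @param ps_frames List of [ps_detect()] outputs, one per frame.
#' @param frame_times Frame times (ms), equally spaced.
#' @param spacing Lattice spacing (mm).
#' @param max_jump_mm Maximum per-frame displacement (mm).
#' @return List with `tracks` (data frame: id, birth, death, charge,
#'   lifespan), `ps_number` (cumulative detection count), `mean_lifespan`
#'   (ms; `NA` when no tracks).
#' @export
ps_track <- function(ps_frames, frame_times, spacing = 1, max_jump_mm = 5) {
  stopifnot(length(ps_frames) == length(frame_times))
  ps_number <- sum(vapply(ps_frames, nrow, integer(1)))
  tracks <- list()      # finished
  active <- data.frame(id = integer(0), ix = numeric(0), iy = numeric(0),
                       charge = integer(0), birth = numeric(0),
                       last = numeric(0))
  next_id <- 1L
  maxj2 <- (max_jump_mm / spacing)^2
  for (f in seq_along(ps_frames)) {
    t <- frame_times[f]
    cur <- ps_frames[[f]]
    matched_cur <- rep(FALSE, nrow(cur))
    keep <- rep(FALSE, nrow(active))
    if (nrow(active) && nrow(cur)) {
      for (a in seq_len(nrow(active))) {
        cand <- which(!matched_cur & cur$charge == active$charge[a])
        if (length(cand)) {
          d2 <- (cur$ix[cand] - active$ix[a])^2 + (cur$iy[cand] - active$iy[a])^2
          b <- which.min(d2)
          if (d2[b] <= maxj2) {
            k <- cand[b]
            matched_cur[k] <- TRUE
            active$ix[a] <- cur$ix[k]; active$iy[a] <- cur$iy[k]
            active$last[a] <- t
            keep[a] <- TRUE
          }
        }
      }
    }
    # close unmatched active tracks
    if (nrow(active)) {
      dead <- active[!keep, , drop = FALSE]
      for (a in seq_len(nrow(dead)))
        tracks[[length(tracks) + 1]] <-
          data.frame(id = dead$id[a], birth = dead$birth[a],
                     death = dead$last[a], charge = dead$charge[a])
      active <- active[keep, , drop = FALSE]
    }
    # spawn new tracks
    if (any(!matched_cur)) {
      new <- cur[!matched_cur, , drop = FALSE]
      add <- data.frame(id = seq.int(next_id, length.out = nrow(new)),
                        ix = new$ix, iy = new$iy, charge = new$charge,
                        birth = t, last = t)
      next_id <- next_id + nrow(new)
      active <- rbind(active, add)
    }
  }
  for (a in seq_len(nrow(active)))
    tracks[[length(tracks) + 1]] <-
      data.frame(id = active$id[a], birth = active$birth[a],
                 death = active$last[a], charge = active$charge[a])
  tr <- if (length(tracks)) do.call(rbind, tracks) else
    data.frame(id = integer(0), birth = numeric(0), death = numeric(0),
               charge = integer(0))
  tr$lifespan <- tr$death - tr$birth
  list(tracks = tr, ps_number = ps_number,
       mean_lifespan = if (nrow(tr)) mean(tr$lifespan) else NA_real_)
}

#' Per-node restitution fits and the Smax map
#'
#' Fits the exponential restitution curve per node from `(DI, APD90)`
#' samples and summarizes the maximal-slope map: its mean over valid nodes
#' and the location of the steepest node. Nodes with fewer than 4 samples or
#' fewer than 2 distinct DIs are excluded; a warning is raised when more
#' than half the nodes are excluded.
#'
#' @param samples Data frame with columns `node`, `di`, `apd90`.
#' @return List with `per_node` (named Smax values), `mean_smax`,
#'   `argmax_node`, `excluded_fraction`.
#' @export
smax_map <- function(samples) {
  stopifnot(all(c("node", "di", "apd90") %in% names(samples)))
  nodes <- unique(samples$node)
  sm <- rep(NA_real_, length(nodes)); names(sm) <- nodes
  for (i in seq_along(nodes)) {
    s <- samples[samples$node == nodes[i], ]
    if (nrow(s) < 4 || length(unique(round(s$di, 6))) < 2) next
    fit <- tryCatch(fit_restitution(s$di, s$apd90), error = function(e) NULL)
    if (!is.null(fit)) sm[i] <- fit$smax
  }
  excl <- mean(is.na(sm))
  if (excl > 0.5)
    warning(sprintf("%.0f%% of nodes excluded from the Smax map", 100 * excl))
  ok <- which(!is.na(sm))
  list(per_node = sm,
       mean_smax = if (length(ok)) mean(sm[ok]) else NA_real_,
       argmax_node = if (length(ok)) as.integer(names(sm)[ok[which.max(sm[ok])]])
                     else NA_integer_,
       excluded_fraction = excl)
}

#' Wave-dynamics metrics for one case
#'
#' Computes the per-case metric row: APD90 and CV from the paced
#' sinus-rhythm run; AFCL, dominant frequency, phase singularities and
#' termination from the AF-induction run; Smax from a single-cell ramp
#' restitution under the case's AF currents.
#'
#' @param case A [run_case()] result.
#' @param substrate The substrate the case ran on.
#' @param analysis_window `c(t0, t1)` (ms) for the AF metrics; default from
#'   induction end to trace end.
#' @param smax Optional precomputed Smax (e.g. shared across cases of one
#'   condition); when `NULL` it is computed from a cell-level ramp protocol.
#' @param term_window Quiescence window for termination detection (ms).
#' @return One-row data frame with Table-style column names:
#'   `APD90_ms`, `CV_m_per_s`, `mean_Smax`, `mean_AFCL_ms`, `peak_DF_Hz`,
#'   `mean_DF_Hz`, `PS_number`, `PS_lifespan_ms`, `terminated`,
#'   `termination_ms`.
#' @export
wave_metrics <- function(case, substrate, analysis_window = NULL,
                         smax = NULL, term_window = 500, min_window = 1500) {
  g <- substrate$geom
  # SR run: APD90 at the appendage ROI probe, CV septal->appendage
  lmk <- substrate$landmarks
  if (!is.null(case$sr)) {
    lat <- lat_map(case$sr)
    cv <- tryCatch(cv_between(lat, g, lmk[["septal_pacing_site"]],
                              lmk[["appendage_roi"]]),
                   error = function(e) NA_real_)
    apd <- apd90_from_trace_node(case$sr, lmk[["appendage_roi"]])
  } else { cv <- NA_real_; apd <- NA_real_ }
  # AF run metrics over the sustained window only
  af <- case$af
  term <- detect_termination(af, window = term_window)
  terminated <- !is.na(term)
  if (is.null(analysis_window))
    analysis_window <- c(af$induction_end,
                         min(term, max(af$frame_times), na.rm = TRUE))
  enough <- diff(analysis_window) >= min_window
  if (!enough) {
    smax_val <- if (is.null(smax)) NA_real_ else smax
    return(data.frame(APD90_ms = apd, CV_m_per_s = cv, mean_Smax = smax_val,
                      mean_AFCL_ms = NA_real_, peak_DF_Hz = NA_real_,
                      mean_DF_Hz = NA_real_, PS_number = NA_integer_,
                      PS_lifespan_ms = NA_real_, terminated = terminated,
                      termination_ms = term))
  }
  cl <- afcl(af, analysis_window)
  dfres <- tryCatch(dominant_frequency(af, window = analysis_window),
                    error = function(e) list(peak = NA_real_, mean = NA_real_))
  pf <- tryCatch(phase_field(af, window = analysis_window),
                 error = function(e) NULL)
  if (!is.null(pf) && nrow(pf$phase)) {
    psf <- lapply(seq_len(nrow(pf$phase)),
                  function(i) ps_detect(pf$phase[i, ], af$nx, af$ny))
    tr <- ps_track(psf, pf$frame_times, spacing = af$spacing,
                   max_jump_mm = 5)
    psn <- tr$ps_number; psl <- tr$mean_lifespan
  } else { psn <- NA_integer_; psl <- NA_real_ }
  if (is.null(smax)) {
    rc <- tryCatch(restitution_protocol(case$af_scales),
                   error = function(e) NULL)
    smax <- if (is.null(rc) || nrow(rc) < 4) NA_real_ else
      fit_restitution(rc)$smax
  }
  data.frame(APD90_ms = apd, CV_m_per_s = cv, mean_Smax = smax,
             mean_AFCL_ms = cl, peak_DF_Hz = dfres$peak,
             mean_DF_Hz = dfres$mean, PS_number = psn, PS_lifespan_ms = psl,
             terminated = terminated, termination_ms = term)
}

# APD90 of the last paced beat at one node, from the decimated frames
apd90_from_trace_node <- function(trace, node) {
  v <- trace$frames[, node]
  a <- measure_apd90(list(time = trace$frame_times, V = v))
  a <- a[!is.na(a)]
  if (length(a)) a[length(a)] else NA_real_
}
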