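# Shared fixtures and memoised expensive computations. The cache environment
# persists across test files within one test run, so paced-cell traces and
# the ensemble trial are computed once and reused wherever they are asserted.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# last-beat APD90 of a paced single cell for a genotype/rhythm column
cached_apd <- function(genotype, rhythm, cl = 600, n_beats = 10) {
  memo(paste("apd", genotype, rhythm, cl, n_beats, sep = "_"), {
    tr <- pace_cell(genotype_baseline(genotype, rhythm), cycle_length = cl,
                    n_beats = n_beats)
    a <- measure_apd90(tr)
    a <- a[!is.na(a)]
    list(trace = tr, apd_last = a[length(a)], apd_all = a)
  })
}

# last-beat APD90 under a drugged SR condition (single cell)
cached_drug_apd <- function(drug, dose) {
  memo(paste("drugapd", drug, dose, sep = "_"), {
    sc <- resolve_scales(condition("wild_type", "SR", drug, dose))
    tr <- pace_cell(sc, cycle_length = 600, n_beats = 10)
    a <- measure_apd90(tr)
    a <- a[!is.na(a)]
    a[length(a)]
  })
}

# single-cell ramp restitution + Smax for a genotype's AF currents
cached_smax <- function(genotype) {
  memo(paste("smax", genotype, sep = "_"), {
    rc <- restitution_protocol(genotype_baseline(genotype, "AF"))
    list(samples = rc, fit = fit_restitution(rc))
  })
}

# strand conduction velocities at two diffusion coefficients (CV ~ sqrt(D))
cached_strand_cvs <- function() {
  memo("strand_cvs", {
    sc <- genotype_baseline("wild_type", "SR")
    list(cv1 = strand_cv(sc, D = 0.1, spacing = 0.25, length_mm = 40, dt = 0.02),
         cv2 = strand_cv(sc, D = 0.2, spacing = 0.25, length_mm = 40, dt = 0.02))
  })
}

# the scaled-down directional ensemble: wild-type and PITX2 baselines at
# n = 10 substrate seeds, plus a wild-type amiodarone low-dose arm on the
# first 6 seeds (the paired drug-delta assertions need matched pairs, not
# the full seed set)
cached_ensemble <- function() {
  memo("ensemble", {
    des <- trial_design(seeds = 1:10, drugs = "amiodarone")
    keep <- is.na(des$cases$dose) |
      (des$cases$dose == "low" & des$cases$genotype == "wild_type" &
         des$cases$seed <= 6)
    des$cases <- des$cases[keep, ]
    run_trial(des, verbose = FALSE)
  })
}

# a small calibrated substrate for substrate/tissue tests
cached_substrate <- function() {
  memo("substrate_small", {
    geom <- lattice_geometry(c(20, 20), 0.4)
    make_substrate(geom, seed = 7, D_L = 0.1, low_frac = 0.25,
                   corr_length = 4)
  })
}

# fabricate a minimal tissue_trace for analysis-function tests
fake_trace <- function(frames, frame_times, nx, ny,
                       act = data.frame(node = integer(0), time = numeric(0),
                                        dvdt = numeric(0)),
                       induction_end = 0, spacing = 1) {
  structure(list(frames = frames, frame_times = frame_times, act = act,
                 final_V = frames[nrow(frames), ], aborted = FALSE,
                 induction_end = induction_end,
                 stim_log = list(nodes = integer(0), times = numeric(0),
                                 amplitude = 0, duration = 0),
                 nx = nx, ny = ny, spacing = spacing, dt = 1, record_dt = 1,
                 mask = rep(FALSE, nx * ny), scales = identity_scales(),
                 protocol_kind = "fixture", duration = max(frame_times)),
            class = "tissue_trace")
}
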