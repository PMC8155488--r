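# Virtual drug-trial pipeline: case grids over (substrate seed x genotype x
# drug x dose), ensemble statistics, and termination-rate tables.

#' Define a virtual-trial design
#'
#' The case grid is `seeds x genotypes x (drug-dose combinations +
#' baseline)`, mirroring a trial with per-substrate baseline and drug arms.
#'
#' @param seeds Integer substrate seeds (one synthetic "patient" each).
#' @param genotypes Subset of `c("wild_type", "pitx2_deficient")`.
#' @param drugs Drug names to include (each at both doses); `character(0)`
#'   for a baseline-only design.
#' @param profile `"desk"` (scaled-down: smaller sheet, shorter AF window,
#'   flagged `scaled_down`) or `"paper"` (25 substrates, 32-s window).
#' @param af_window_ms AF analysis window length (ms); default by profile.
#' @param sheet_mm,spacing_mm Substrate sheet size and spacing; default by
#'   profile.
#' @param target_cv Conduction-velocity calibration target (m/s); default by
#'   profile (see the methods vignette for the desk-scale rationale).
#' @return Object of class `trial_design` with a `cases` data frame.
#' @export
trial_design <- function(seeds = 1:10,
                         genotypes = c("wild_type", "pitx2_deficient"),
                         drugs = names(drug_registry()),
                         profile = c("desk", "paper"),
                         af_window_ms = NULL, sheet_mm = NULL,
                         spacing_mm = NULL, target_cv = NULL) {
  profile <- match.arg(profile)
  genotypes <- match.arg(genotypes, c("wild_type", "pitx2_deficient"),
                         several.ok = TRUE)
  defaults <- if (profile == "desk")
    list(af_window_ms = 2000, sheet_mm = 40, spacing_mm = 0.4,
         target_cv = 0.45, dt = 0.075, low_frac = 0.25, corr_length = 4,
         fib_coupling = 0.3, settle_ms = 400, sr_runs = FALSE)
  else
    list(af_window_ms = 32000, sheet_mm = 100, spacing_mm = 0.3,
         target_cv = 0.7, dt = 0.05, low_frac = 0.3, corr_length = 8,
         fib_coupling = 0.3, settle_ms = 400, sr_runs = TRUE)
  if (is.null(af_window_ms)) af_window_ms <- defaults$af_window_ms
  if (is.null(sheet_mm)) sheet_mm <- defaults$sheet_mm
  if (is.null(spacing_mm)) spacing_mm <- defaults$spacing_mm
  if (is.null(target_cv)) target_cv <- defaults$target_cv
  arms <- data.frame(drug = "none", dose = NA_character_,
                     stringsAsFactors = FALSE)
  for (d in drugs)
    arms <- rbind(arms, data.frame(drug = d, dose = c("low", "high")))
  cases <- merge(merge(data.frame(seed = seeds),
                       data.frame(genotype = genotypes)), arms)
  cases <- cases[order(cases$seed, cases$genotype, cases$drug, cases$dose), ]
  rownames(cases) <- NULL
  structure(list(cases = cases, seeds = seeds, genotypes = genotypes,
                 drugs = drugs, profile = profile,
                 af_window_ms = af_window_ms, sheet_mm = sheet_mm,
                 spacing_mm = spacing_mm, target_cv = target_cv,
                 dt = defaults$dt, low_frac = defaults$low_frac,
                 corr_length = defaults$corr_length,
                 fib_coupling = defaults$fib_coupling,
                 settle_ms = defaults$settle_ms, sr_runs = defaults$sr_runs,
                 scaled_down = profile == "desk"),
            class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("<trial_design> %d cases (%d seeds x %d genotypes x %d arms), profile '%s'\n",
              nrow(x$cases), length(x$seeds), length(x$genotypes),
              nrow(unique(x$cases[c("drug", "dose")])), x$profile))
  invisible(x)
}

#' Build and calibrate the substrate for one trial seed
#'
#' @param design A `trial_design`.
#' @param seed Substrate seed.
#' @param calibration Optional precomputed `D_L` (mm^2/ms) to skip the
#'   bisection (it depends only on design parameters, not on the seed).
#' @return Calibrated `af_substrate`.
#' @export
trial_substrate <- function(design, seed, calibration = NULL) {
  geom <- lattice_geometry(c(design$sheet_mm, design$sheet_mm),
                           design$spacing_mm)
  if (is.null(calibration)) {
    cal <- calibrate_diffusion(genotype_baseline("wild_type", "SR"),
                               target_cv = design$target_cv,
                               spacing = design$spacing_mm, dt = design$dt)
    calibration <- cal$D_L
  }
  make_substrate(geom, seed = seed, D_L = calibration,
                 low_frac = design$low_frac,
                 corr_length = design$corr_length,
                 fib_coupling = design$fib_coupling)
}

#' Run a virtual drug trial
#'
#' Executes every case of the design: per substrate seed, a baseline and one
#' case per drug-dose arm for each genotype. Per-case results are
#' checkpointed as CSV rows so an interrupted trial resumes where it
#' stopped; simulation and summarization are separated (the report is
#' regenerated from the archive deterministically).
#'
#' @param design A `trial_design`.
#' @param table Drug block table.
#' @param out_dir Directory for per-case checkpoint files (created); `NULL`
#'   disables checkpointing.
#' @param verbose Print per-case progress.
#' @return Data frame of per-case metrics (one row per case) with condition
#'   columns, a `failed` flag for cases that errored, and the resolved AF
#'   scale vector serialized in `af_scales`.
#' @export
run_trial <- function(design, table = drug_block_table(), out_dir = NULL,
                      verbose = interactive()) {
  validate_block_table(table)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  cases <- design$cases
  # per-arm caches: Smax and the cycle library are deterministic functions
  # of the AF scale vector
  smax_cache <- new.env(parent = emptyenv())
  lib_cache <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(cases))
  d_cache <- NULL
  sub_cache <- list()
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    key <- sprintf("s%d_%s_%s_%s", cs$seed, cs$genotype, cs$drug,
                   ifelse(is.na(cs$dose), "base", cs$dose))
    ck <- if (is.null(out_dir)) NULL else file.path(out_dir, paste0(key, ".csv"))
    if (!is.null(ck) && file.exists(ck)) {
      rows[[i]] <- utils::read.csv(ck)
      next
    }
    if (verbose) message("case ", key)
    res <- tryCatch({
      skey <- as.character(cs$seed)
      if (is.null(sub_cache[[skey]])) {
        sub <- trial_substrate(design, cs$seed, calibration = d_cache)
        d_cache <- sub$D_L
        sub_cache[[skey]] <- sub
      }
      sub <- sub_cache[[skey]]
      cond <- condition(cs$genotype, "AF", cs$drug,
                        if (is.na(cs$dose)) NULL else cs$dose)
      akey <- paste(cs$genotype, cs$drug, cs$dose, sep = "|")
      af_scales <- resolve_scales(cond, table)
      if (is.null(lib_cache[[akey]]))
        lib_cache[[akey]] <- cycle_library(af_scales)
      case <- run_case(sub, cond,
                       sr_protocol = if (design$sr_runs)
                         stimulus_protocol("S1_train", 600, counts = 2)
                       else NULL,
                       af_duration = design$settle_ms + design$af_window_ms +
                         200,
                       dt = design$dt, lib = lib_cache[[akey]],
                       table = table)
      if (is.null(smax_cache[[akey]])) {
        rc <- tryCatch(restitution_protocol(case$af_scales),
                       error = function(e) NULL)
        smax_cache[[akey]] <- if (is.null(rc) || nrow(rc) < 4) NA_real_ else
          fit_restitution(rc)$smax
      }
      m <- wave_metrics(case, sub, smax = smax_cache[[akey]])
      cbind(cs, m, failed = FALSE,
            af_scales = paste(signif(case$af_scales, 6), collapse = ";"))
    }, error = function(e) {
      cbind(cs, failed = TRUE, error = conditionMessage(e))
    })
    if (!is.null(ck)) utils::write.csv(res, ck, row.names = FALSE)
    rows[[i]] <- res
  }
  out <- do.call(rbind_fill, list(rows))
  attr(out, "scaled_down") <- design$scaled_down
  out
}

# rbind with union of columns (base-only plyr::rbind.fill equivalent)
rbind_fill <- function(dfs) {
  dfs <- dfs[!vapply(dfs, is.null, logical(1))]
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (c in setdiff(cols, names(d))) d[[c]] <- NA
    d[cols]
  }))
}

#' Cohen's d effect size
#'
#' Absolute standardized mean difference with the (n-1)-weighted pooled
#' standard deviation.
#'
#' @param a,b Numeric samples (each of length >= 2).
#' @return `d`, or `NA` with attribute `flag = "zero-variance"` when the
#'   pooled SD is zero.
#' @export
cohens_d <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each sample needs n >= 2")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) {
    out <- NA_real_; attr(out, "flag") <- "zero-variance"; return(out)
  }
  abs(mean(a) - mean(b)) / sqrt(sp2)
}

#' Student's two-sample and paired t tests
#'
#' Thin wrappers around [stats::t.test()] returning `(t, p)`; the two-sample
#' version is the equal-variance Student test. Degenerate (zero-variance)
#' inputs are flagged rather than erroring.
#'
#' @param a,b Numeric samples; for `paired_t`, `before`/`after` of equal
#'   length.
#' @return List with `t`, `p` (two-sided), and `flag` (`NA` or a degeneracy
#'   note).
#' @export
two_sample_t <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1, flag = "degenerate"))
    return(list(t = Inf * sign(mean(a) - mean(b)), p = 0, flag = "degenerate"))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, flag = NA_character_)
}

#' @rdname two_sample_t
#' @param before,after Paired samples.
#' @export
paired_t <- function(before, after) {
  ok <- is.finite(before) & is.finite(after)
  before <- before[ok]; after <- after[ok]
  if (length(before) < 2) stop("need >= 2 complete pairs")
  d <- after - before
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1, flag = "degenerate"))
    return(list(t = Inf * sign(d[1]), p = 0, flag = "degenerate"))
  }
  ht <- stats::t.test(after, before, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, flag = NA_character_)
}

#' Termination-rate table with class and genotype comparisons
#'
#' Aggregates per-case termination flags into counts, denominators and
#' percentages by drug class, genotype, and drug-dose cell, and compares
#' groups with a two-sided exact test on the 2x2 counts (the package's own
#' comparison; plain percentage arithmetic is used for the rates
#' themselves).
#'
#' @param cases Data frame with columns `genotype`, `drug`, `dose`,
#'   `terminated` (logical), one row per drug case (baseline rows with
#'   `drug == "none"` are ignored).
#' @return List of data frames: `overall` (one row), `by_class`,
#'   `by_class_genotype`, `by_drug_dose`; and `tests` with exact-test
#'   p-values for class IC vs III and, within each class, wild-type vs
#'   PITX2-deficient.
#' @export
termination_table <- function(cases) {
  stopifnot(all(c("genotype", "drug", "dose", "terminated") %in% names(cases)))
  d <- cases[cases$drug != "none", ]
  if (!nrow(d)) stop("no drug cases to tabulate")
  d$class <- drug_class(d$drug)
  rate_row <- function(df, label) {
    k <- sum(df$terminated); n <- nrow(df)
    data.frame(group = label, terminated = k, n = n, pct = 100 * k / n)
  }
  overall <- rate_row(d, "all AADs")
  by_class <- do.call(rbind, lapply(split(d, d$class), function(s)
    rate_row(s, paste0("class ", s$class[1]))))
  by_cg <- do.call(rbind, lapply(
    split(d, list(d$class, d$genotype), drop = TRUE), function(s)
      rate_row(s, paste0("class ", s$class[1], " / ", s$genotype[1]))))
  by_dd <- do.call(rbind, lapply(
    split(d, list(d$drug, d$dose), drop = TRUE), function(s)
      rate_row(s, paste(s$drug[1], s$dose[1]))))
  rownames(by_class) <- rownames(by_cg) <- rownames(by_dd) <- NULL
  exact_p <- function(k1, n1, k2, n2) {
    stats::fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), 2))$p.value
  }
  ic <- d[d$class == "IC", ]; iii <- d[d$class == "III", ]
  tests <- data.frame(
    comparison = c("class IC vs class III",
                   "class IC: wild_type vs pitx2_deficient",
                   "class III: wild_type vs pitx2_deficient",
                   "overall: wild_type vs pitx2_deficient"),
    p = c(
      exact_p(sum(ic$terminated), nrow(ic), sum(iii$terminated), nrow(iii)),
      with_geno_p(ic), with_geno_p(iii), with_geno_p(d)))
  list(overall = overall, by_class = by_class, by_class_genotype = by_cg,
       by_drug_dose = by_dd, tests = tests)
}

with_geno_p <- function(d) {
  w <- d[d$genotype == "wild_type", ]; p <- d[d$genotype == "pitx2_deficient", ]
  if (!nrow(w) || !nrow(p)) return(NA_real_)
  stats::fisher.test(matrix(c(sum(w$terminated), nrow(w) - sum(w$terminated),
                              sum(p$terminated), nrow(p) - sum(p$terminated)),
                            2))$p.value
}

#' Percentages from printed termination counts
#'
#' Plain percentage arithmetic on numerator/denominator rows, the path used
#' to reproduce published termination tables row by row (published tables
#' are not always internally consistent across aggregation levels, so each
#' printed row is reproduced from its own counts).
#'
#' @param counts Data frame with columns `terminated` (count) and `n`
#'   (denominator); other columns pass through.
#' @return The data frame with a `pct` column appended.
#' @export
termination_rates <- function(counts) {
  stopifnot(all(c("terminated", "n") %in% names(counts)),
            all(counts$terminated >= 0), all(counts$terminated <= counts$n))
  counts$pct <- 100 * counts$terminated / counts$n
  counts
}

#' Expand printed termination counts into per-case flags
#'
#' Utility for reproducing published termination tables: given per
#' (drug, dose, genotype) counts of terminated cases out of `n`, builds the
#' per-case data frame [termination_table()] consumes.
#'
#' @param counts Data frame with columns `drug`, `dose`, `genotype`,
#'   `terminated` (count), `n` (denominator).
#' @return Per-case data frame with logical `terminated`.
#' @export
termination_from_counts <- function(counts) {
  stopifnot(all(c("drug", "dose", "genotype", "terminated", "n") %in%
                  names(counts)))
  do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    data.frame(genotype = r$genotype, drug = r$drug, dose = r$dose,
               terminated = rep(c(TRUE, FALSE), c(r$terminated, r$n - r$terminated)))
  }))
}

#' Summarize a trial into group means, deltas and statistics
#'
#' Applies the exclusion rule (cases that terminate before the end of the
#' wave-dynamics window contribute to termination tables but not to
#' wave-dynamics summaries), computes per-group means +- SD, per-case deltas
#' versus the matched (same seed, same genotype) baseline, and the
#' between-genotype comparisons (Student's t, Cohen's d).
#'
#' @param trial Per-case data frame from [run_trial()].
#' @param metrics Metric columns to summarize.
#' @return List with `group_summary`, `deltas` (per-case), `baseline_tests`
#'   (wild-type vs PITX2 at baseline), `termination` (from
#'   [termination_table()]).
#' @export
trial_report <- function(trial,
                         metrics = c("APD90_ms", "CV_m_per_s", "mean_Smax",
                                     "mean_AFCL_ms", "peak_DF_Hz",
                                     "mean_DF_Hz", "PS_number",
                                     "PS_lifespan_ms")) {
  tr <- trial[trial$failed %in% c(FALSE, NA), ]
  tr$arm <- ifelse(tr$drug == "none", "baseline",
                   paste(tr$drug, tr$dose, sep = "_"))
  # exclusion rule for wave-dynamic summaries
  wd <- tr[!tr$terminated | is.na(tr$terminated), ]
  grp <- split(wd, list(wd$genotype, wd$arm), drop = TRUE)
  group_summary <- do.call(rbind, lapply(grp, function(s) {
    out <- data.frame(genotype = s$genotype[1], arm = s$arm[1], n = nrow(s))
    for (m in metrics) {
      out[[paste0(m, "_mean")]] <- mean(s[[m]], na.rm = TRUE)
      out[[paste0(m, "_sd")]] <- stats::sd(s[[m]], na.rm = TRUE)
    }
    out
  }))
  rownames(group_summary) <- NULL
  # per-case deltas vs matched baseline
  base <- wd[wd$arm == "baseline", ]
  drugged <- wd[wd$arm != "baseline", ]
  deltas <- NULL
  if (nrow(drugged)) {
    key <- function(d) paste(d$seed, d$genotype)
    idx <- match(key(drugged), key(base))
    ok <- !is.na(idx)
    deltas <- drugged[ok, c("seed", "genotype", "drug", "dose", "arm")]
    for (m in metrics)
      deltas[[paste0("d_", m)]] <- drugged[[m]][ok] - base[[m]][idx[ok]]
  }
  # baseline genotype comparison
  baseline_tests <- NULL
  if (all(c("wild_type", "pitx2_deficient") %in% base$genotype)) {
    w <- base[base$genotype == "wild_type", ]
    p <- base[base$genotype == "pitx2_deficient", ]
    baseline_tests <- do.call(rbind, lapply(metrics, function(m) {
      aw <- w[[m]][is.finite(w[[m]])]; ap <- p[[m]][is.finite(p[[m]])]
      if (length(aw) < 2 || length(ap) < 2)
        return(data.frame(metric = m, wt_mean = mean(aw), pitx2_mean = mean(ap),
                          t = NA, p = NA, d = NA))
      ht <- two_sample_t(aw, ap)
      data.frame(metric = m, wt_mean = mean(aw), pitx2_mean = mean(ap),
                 t = ht$t, p = ht$p, d = cohens_d(aw, ap))
    }))
  }
  term <- if (any(tr$drug != "none"))
    termination_table(tr[, c("genotype", "drug", "dose", "terminated")])
  else NULL
  list(group_summary = group_summary, deltas = deltas,
       baseline_tests = baseline_tests, termination = term,
       note = "no multiple-testing correction applied")
}
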