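# Trial design, statistics, termination tables, report invariants.

test_that("trial designs enumerate seeds x genotypes x arms", {
  d0 <- trial_design(seeds = 1:2, drugs = character(0))
  expect_equal(nrow(d0$cases), 4)
  d1 <- trial_design(seeds = 1:25)
  # 25 seeds x 2 genotypes x (10 drug-dose arms + baseline) = 550 cases,
  # i.e. 25 baseline + 250 drugged per genotype
  expect_equal(nrow(d1$cases), 550)
  per_geno <- table(d1$cases$genotype, d1$cases$drug == "none")
  expect_true(all(per_geno[, "TRUE"] == 25))
  expect_true(all(per_geno[, "FALSE"] == 250))
})

test_that("Cohen's d matches its definition and flags zero variance", {
  a <- c(1.5, 2.5); b <- c(-0.5, 0.5)  # means 2 vs 0, pooled sd sqrt(0.5)
  expect_equal(cohens_d(a, b), 2 / sqrt(0.5), tolerance = 1e-12)
  expect_equal(cohens_d(c(4, 5, 6), c(4, 5, 6)), 0)
  z <- cohens_d(c(0, 0), c(2, 2))
  expect_true(is.na(z))
  expect_equal(attr(z, "flag"), "zero-variance")
})

test_that("t tests reproduce hand-computed values", {
  ht <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(ht$t, -3.674, tolerance = 1e-3)
  same <- two_sample_t(c(2, 2), c(2, 2))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  # paired shift: small p, sign matches the shift direction
  set.seed(8)
  before <- rnorm(10)
  pt <- paired_t(before, before + 1)
  expect_lt(pt$p, 1e-6)
  expect_gt(pt$t, 0)
})

test_that("termination tables reproduce printed-count arithmetic exactly", {
  counts <- data.frame(
    drug = rep(c("flecainide", "propafenone", "amiodarone", "sotalol",
                 "dronedarone"), each = 4),
    dose = rep(c("low", "low", "high", "high"), 5),
    genotype = rep(c("wild_type", "pitx2_deficient"), 10),
    terminated = c(2, 4, 4, 7,     # flecainide 5/15 uM
                   3, 5, 3, 10,    # propafenone 5/10 uM
                   10, 11, 16, 11, # amiodarone 5/10 uM
                   4, 8, 9, 17,    # sotalol 60 uM / 10 mM
                   11, 11, 16, 7), # dronedarone 3/10 uM
    n = 25)
  cases <- termination_from_counts(counts)
  expect_equal(nrow(cases), 500)
  tab <- termination_table(cases)
  # note: the published drug-dose cells sum to 169, not the 180 of the
  # overall row; every row is therefore reproduced from its own counts
  expect_equal(tab$overall$terminated, sum(counts$terminated))
  ic <- tab$by_class[tab$by_class$group == "class IC", ]
  expect_equal(ic$terminated, 38); expect_equal(ic$n, 200)
  expect_equal(round(ic$pct, 1), 19.0)
  iii <- tab$by_class[tab$by_class$group == "class III", ]
  expect_equal(iii$terminated, 131); expect_equal(iii$n, 300)
  expect_equal(round(iii$pct, 1), 43.7)
  cg <- tab$by_class_genotype
  expect_equal(round(cg$pct[cg$group == "class IC / wild_type"], 1), 12.0)
  expect_equal(round(cg$pct[cg$group == "class IC / pitx2_deficient"], 1), 26.0)
  # exact test on the 12/100 vs 26/100 comparison is significant
  p_ic <- tab$tests$p[tab$tests$comparison ==
                        "class IC: wild_type vs pitx2_deficient"]
  expect_lt(p_ic, 0.05)
  # 0 of n -> 0%
  zero <- termination_table(data.frame(genotype = "wild_type",
                                       drug = "sotalol", dose = "low",
                                       terminated = rep(FALSE, 10)))
  expect_equal(zero$overall$pct, 0)
  # row-level printed counts reproduce their percentages exactly
  rows <- termination_rates(data.frame(
    group = c("all", "IC", "III", "IC wt", "IC pitx2"),
    terminated = c(180, 38, 131, 12, 26),
    n = c(500, 200, 300, 100, 100)))
  expect_equal(round(rows$pct, 1), c(36.0, 19.0, 43.7, 12.0, 26.0))
})

test_that("trial reports exclude terminated cases from wave-dynamic means", {
  base <- expand.grid(seed = 1:4, genotype = c("wild_type", "pitx2_deficient"),
                      drug = "none", dose = NA_character_,
                      stringsAsFactors = FALSE)
  drugged <- base
  drugged$drug <- "sotalol"; drugged$dose <- "low"
  tr <- rbind(base, drugged)
  set.seed(1)
  for (m in c("APD90_ms", "CV_m_per_s", "mean_Smax", "mean_AFCL_ms",
              "peak_DF_Hz", "mean_DF_Hz", "PS_number", "PS_lifespan_ms"))
    tr[[m]] <- rnorm(nrow(tr), 100, 5)
  tr$terminated <- FALSE
  tr$terminated[9] <- TRUE           # one terminated drug case
  tr$termination_ms <- ifelse(tr$terminated, 1200, NA)
  tr$failed <- FALSE
  rep1 <- trial_report(tr)
  # the terminated case is in the termination table ...
  expect_equal(rep1$termination$overall$terminated, 1)
  # ... and absent from the wave-dynamic group summary
  g <- rep1$group_summary
  sot_wt <- g[g$arm == "sotalol_low" & g$genotype == tr$genotype[9], ]
  expect_equal(sot_wt$n, 3)
  # regeneration from the same archive is identical
  rep2 <- trial_report(tr)
  expect_identical(rep1$group_summary, rep2$group_summary)
  expect_identical(rep1$deltas, rep2$deltas)
})
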