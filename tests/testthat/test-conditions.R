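# Genotype/rhythm scaling table, drug block registry, percent-change
# arithmetic and the construction-rule consistency report.

test_that("genotype baselines return the stored table columns", {
  wt_sr <- genotype_baseline("wild_type", "SR")
  expect_equal(unname(wt_sr[c("gNa", "gK1", "gto", "gKr", "gCaL", "gKur",
                              "gKs", "INaCa", "INaK", "Iup", "Krel", "Caup",
                              "ACh")]),
               c(1.11, 0.95, 1.17, 1.20, 1.50, 1.00, 1.60, 1.55, 1.00, 1.00,
                 1.00, 1.25, 1.00))
  wt_af <- genotype_baseline("wild_type", "AF")
  expect_equal(unname(wt_af[["gCaL"]]), 0.30)
  expect_equal(unname(wt_af[["gK1"]]), 2.10)
  px_af <- genotype_baseline("pitx2_deficient", "AF")
  expect_equal(unname(px_af[["gKr"]]), 2.00)
  expect_equal(unname(px_af[["gK1"]]), 1.58)
  # PITX2 SR differs from wild-type SR only in gK1 and gKr
  px_sr <- genotype_baseline("pitx2_deficient", "SR")
  wt_sr <- genotype_baseline("wild_type", "SR")
  diffs <- names(px_sr)[px_sr != wt_sr]
  expect_setequal(diffs, c("gK1", "gKr"))
  expect_equal(unname(px_sr[["gK1"]]), 0.71)
  expect_equal(unname(px_sr[["gKr"]]), 2.40)
  expect_error(genotype_baseline("mouse", "SR"))
})

test_that("percent_change uses half-away-from-zero rounding", {
  expect_identical(percent_change(95, 210), 121L)
  expect_identical(percent_change(160, 100), -38L)   # -37.5 rounds away
  expect_identical(percent_change(100, 100), 0L)
  expect_identical(percent_change(7, 7), 0L)
  expect_error(percent_change(0, 10))
})

test_that("drug block application touches only registered channels", {
  base <- genotype_baseline("wild_type", "AF")
  expect_identical(apply_drug(base, "none"), base)
  sot <- apply_drug(base, "sotalol", "low")
  changed <- names(base)[sot != base]
  expect_true(all(changed %in% c("gNa", "gKr", "gKs")))
  expect_equal(unname(sot[["gK1"]]), 2.10)
  # dose monotonicity on every listed channel, every drug
  for (d in names(drug_registry())) {
    lo <- apply_drug(base, d, "low")
    hi <- apply_drug(base, d, "high")
    expect_true(all(hi <= lo + 1e-12), info = d)
  }
  expect_error(apply_drug(base, "aspirin", "low"))
  # a table touching an unregistered channel fails validation
  bad <- drug_block_table()
  bad$sotalol$low <- c(bad$sotalol$low, gK1 = 0.5)
  expect_error(apply_drug(base, "sotalol", "low", table = bad),
               "outside its registry")
})

test_that("conditions resolve to one scale vector and round-trip", {
  cond <- condition("pitx2_deficient", "AF", "flecainide", "high")
  sc <- resolve_scales(cond)
  expect_length(sc, 13)
  expect_true(all(is.finite(sc) & sc >= 0))
  expect_error(condition("wild_type", "SR", "none", "low"))
  expect_error(condition("wild_type", "SR", "sotalol"))
  # registry serialization is lossless
  skip_if_not_installed("jsonlite")
  p <- tempfile(fileext = ".json")
  write_registry(p)
  back <- read_registry(p)
  expect_equal(back$blocks$amiodarone$low, drug_block_table()$amiodarone$low)
  expect_equal(back$genotype_table$wt_af, genotype_table()$wt_af)
})

test_that("consistency report quantifies the same-percent-change rule", {
  cr <- consistency_report()
  expect_equal(cr$deviation[cr$channel == "gKr"], 0, tolerance = 1e-12)
  expect_equal(cr$deviation[cr$channel == "gto"], 0, tolerance = 1e-12)
  expect_equal(cr$deviation[cr$channel == "gK1"],
               abs(1.58 - 0.71 * (2.10 / 0.95)), tolerance = 1e-10)
  expect_equal(cr$deviation[cr$channel == "gK1"], 0.0105, tolerance = 0.01)
  expect_true(all(cr$deviation[!cr$channel %in% "gK1"] < 1e-9))
})

test_that("drug classes follow the IC/III grouping", {
  expect_equal(drug_class(c("flecainide", "propafenone")), c("IC", "IC"))
  expect_equal(drug_class(c("amiodarone", "sotalol", "dronedarone")),
               c("III", "III", "III"))
  expect_error(drug_class("verapamil"))
})
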