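test_that("age bin assignment: completed years at event, multi-bin patients, 90+", {
  pats <- pat("a", birth = "2000-01-01")
  tagged <- assign_age_bins(drec("a", "d", 0, 5, origin = "2014-06-01"), pats)
  expect_equal(tagged$age, 14L)
  expect_equal(as.character(tagged$age_bin), "10-14")

  # events at ages 64 and 65 put the patient in two bins
  p2 <- pat("b", birth = "1949-06-01")
  ev <- rbind(drec("b", "d", 0, 5, origin = "2014-01-01"),    # age 64
              drec("b", "d", 200, 5, origin = "2014-01-01"))  # age 65
  t2 <- assign_age_bins(ev, p2)
  expect_setequal(as.character(t2$age_bin), c("60-64", "65-69"))

  expect_equal(as.character(assign_age_bins(
    drec("c", "d", 0, 5), pat("c", birth = "1920-06-01"))$age_bin), "90+")

  expect_warning(assign_age_bins(drec("d", "d", 0, 5),
                                 pat("d", birth = "2030-01-01")),
                 "negative age")
})

test_that("prevalence arithmetic: PC, PI, severity strata, PI <= PC", {
  win <- dwin()
  pats <- pat(c("a", "b", "c", "d"), gender = c("W", "W", "M", "M"))
  # a: interacting overlap; b: plain overlap; c,d: single drugs
  recs <- rbind(drec("a", "x", 0, 10), drec("a", "y", 5, 10),
                drec("b", "x", 0, 10), drec("b", "z", 5, 10),
                drec("c", "x", 0, 10), drec("d", "z", 0, 10))
  ddi <- ddi_ref("x", "y", "major")
  runs <- coadmin_runs(recs, ddi, win)
  prev <- compute_prevalence(runs, recs, pats)
  all_row <- prev[gender == "all" & age_bin == "all" & severity == "any"]
  expect_equal(all_row$pc, 0.5)        # 2 of 4 patients co-administer
  expect_equal(all_row$pi, 0.25)       # 1 of 4 has a known DDI
  expect_equal(prev[gender == "all" & age_bin == "all" & severity == "major", pi],
               0.25)
  expect_equal(prev[gender == "all" & age_bin == "all" & severity == "minor", pi], 0)
  expect_true(prev[severity == "any" & n_patients > 0, all(pi <= pc)])

  # no DDI reference entries -> PI = 0 in every stratum
  runs0 <- coadmin_runs(recs, empty_ddi(), win)
  prev0 <- compute_prevalence(runs0, recs, pats)
  expect_true(all(prev0[n_patients > 0, pi] == 0))

  # empty strata carry NA prevalences
  expect_true(all(is.na(prev[n_patients == 0, pc])))
})

test_that("aggregation consistency: stratified margins equal unstratified totals", {
  cfg <- synthetic_config(n_patients = 500, seed = 31)
  pats <- generate_population(cfg)
  recs <- generate_dispensations(pats, cfg)
  ddi <- generate_ddi_reference(cfg)
  runs <- coadmin_runs(recs, ddi, cfg$window)
  full <- compute_prevalence(runs, recs, pats)
  flat <- compute_prevalence(runs, recs, pats, by = "severity")
  expect_equal(full[gender == "all" & age_bin == "all"],
               flat[gender == "all" & age_bin == "all"])
  # PI <= PC in every populated stratum (set inclusion)
  expect_true(full[severity == "any" & n_patients > 0, all(pi <= pc)])
})

test_that("relative risk: printed-prevalence worked example and exact tests", {
  # feeding gender prevalences 14.64% vs 9.49% through the RR formula
  # gives 1.54 at two decimals
  expect_equal(round(rr_from_prevalence(14.64, 9.49), 2), 1.54)

  # equal prevalence with exactly proportional counts: RR = 1, Fisher p = 1
  rr <- relative_risk(10, 100, 20, 200)
  expect_equal(rr$rr_women, 1)
  expect_equal(rr$p_value, 1)

  # 2x2 [[1,0],[0,1]]: both tables with these margins are equiprobable
  expect_equal(relative_risk(1, 1, 0, 1)$p_value, 1)

  # reciprocity wherever finite
  rr2 <- relative_risk(c(5, 9), c(50, 40), c(3, 12), c(60, 45))
  expect_equal(rr2$rr_men, 1 / rr2$rr_women)

  # zero male prevalence: infinite RR for women
  expect_equal(relative_risk(3, 10, 0, 10)$rr_women, Inf)
  expect_error(relative_risk(1, 0, 1, 5), "denominators")
})

test_that("gender relative risks table: RRC/RRI per stratum with correction", {
  cfg <- synthetic_config(n_patients = 800, seed = 37)
  pats <- generate_population(cfg)
  recs <- generate_dispensations(pats, cfg)
  ddi <- generate_ddi_reference(cfg)
  runs <- coadmin_runs(recs, ddi, cfg$window)
  prev <- compute_prevalence(runs, recs, pats, by = c("gender", "severity"))
  rr <- gender_relative_risks(prev)
  expect_true(all(c("coadministration", "interaction") %in% rr$measure))
  fin <- rr[is.finite(rr_women) & rr_women > 0]
  expect_equal(fin$rr_men, 1 / fin$rr_women)
  expect_true(all(rr$p_value >= 0 & rr$p_value <= 1))
  expect_true(all(rr$q_value >= rr$p_value - 1e-12))
  # bonferroni is at least as conservative as BH
  rrb <- gender_relative_risks(prev, correction = "bonferroni")
  expect_true(all(rrb$q_value >= rr$q_value - 1e-12))
})

test_that("fisher test on gender RRI rejects at close to nominal rate under the null", {
  # no gender effects: gender-balanced cohort, no gender-specific drugs
  rejections <- sapply(1:200, function(s) {
    cfg <- synthetic_config(n_patients = 500, gender_ratio = 0.5,
                            gender_specific_fraction = 0, seed = 5000 + s)
    pats <- generate_population(cfg)
    recs <- generate_dispensations(pats, cfg)
    ddi <- generate_ddi_reference(cfg)
    runs <- coadmin_runs(recs, ddi, cfg$window)
    prev <- compute_prevalence(runs, recs, pats, by = "gender")
    rr <- gender_relative_risks(prev)
    rr[measure == "interaction", p_value] < 0.05
  })
  rate <- mean(rejections)
  # 99.9% binomial band around 0.05 at 200 replicates; the exact test is
  # conservative on discrete tables, so only the upper bound is informative
  expect_lt(rate, 0.101)
})
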