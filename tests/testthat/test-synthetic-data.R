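test_that("population generation: forced gender, determinism, binomial fraction", {
  one <- generate_population(synthetic_config(n_patients = 1, gender_ratio = 1))
  expect_equal(nrow(one), 1L)
  expect_equal(one$gender, "W")

  cfg <- synthetic_config(n_patients = 1000, gender_ratio = 0.5, seed = 7)
  expect_identical(generate_population(cfg), generate_population(cfg))

  # n = 10000, ratio 0.6: 99.9% binomial interval is [0.584, 0.616]
  p <- generate_population(synthetic_config(n_patients = 10000, gender_ratio = 0.6,
                                            seed = 1))
  expect_gt(mean(p$gender == "W"), 0.57)
  expect_lt(mean(p$gender == "W"), 0.63)

  # ages land inside the configured range
  cfg2 <- synthetic_config(n_patients = 500, age_range = c(20, 39), seed = 3)
  ages <- age_at(generate_population(cfg2)$birth_date, cfg2$window$start)
  expect_true(all(ages >= 20 & ages <= 39))
})

test_that("invalid config fields are reported by name", {
  expect_error(synthetic_config(gender_ratio = 1.2), "gender_ratio")
  expect_error(synthetic_config(n_patients = 0), "n_patients")
  expect_error(synthetic_config(severity_probs = c(0.5, 0.5, 0.5)), "severity_probs")
  expect_error(synthetic_config(age_range = c(50, 20)), "age_range")
  expect_error(synthetic_config(ddi_fraction = 2), "ddi_fraction")
})

test_that("dispensations: determinism, age-polypharmacy coupling, window containment", {
  cfg <- synthetic_config(n_patients = 300, seed = 5)
  pats <- generate_population(cfg)
  d1 <- generate_dispensations(pats, cfg)
  d2 <- generate_dispensations(pats, cfg)
  expect_identical(d1, d2)
  expect_error(generate_dispensations(pats[0], cfg), "empty")

  # all records inside the study window
  expect_true(all(d1$start >= cfg$window$start))
  expect_true(all(as.integer(d1$start) + d1$duration - 1L <= as.integer(cfg$window$end)))

  # zero slope: age and distinct-drug count uncorrelated (|rho| < 0.05)
  cfg0 <- synthetic_config(n_patients = 10000, polypharmacy_slope = 0, seed = 11)
  p0 <- generate_population(cfg0)
  r0 <- generate_dispensations(p0, cfg0)
  nd <- r0[, .(k = data.table::uniqueN(drug_id)), by = patient_id]
  nd[p0, age := age_at(i.birth_date, cfg0$window$start), on = "patient_id"]
  expect_lt(abs(cor(nd$age, nd$k, method = "spearman")), 0.05)

  # default positive slope: clearly positive correlation
  cfg1 <- synthetic_config(n_patients = 10000, seed = 11)
  r1 <- generate_dispensations(generate_population(cfg1), cfg1)
  nd1 <- r1[, .(k = data.table::uniqueN(drug_id)), by = patient_id]
  nd1[generate_population(cfg1), age := age_at(i.birth_date, cfg1$window$start),
      on = "patient_id"]
  expect_gt(cor(nd1$age, nd1$k, method = "spearman"), 0.2)
})

test_that("gender-specific drugs are dispensed to one gender only", {
  cfg <- synthetic_config(n_patients = 2000, gender_specific_fraction = 0.1, seed = 2)
  pats <- generate_population(cfg)
  recs <- generate_dispensations(pats, cfg)
  gs <- ddiprev:::gender_specific_drugs(cfg)
  recs[pats, gender := i.gender, on = "patient_id"]
  expect_false(any(recs[drug_id %in% gs$W, gender] == "M"))
  expect_false(any(recs[drug_id %in% gs$M, gender] == "W"))
})

test_that("DDI reference generation: fraction, severities, planted pairs", {
  expect_equal(nrow(generate_ddi_reference(synthetic_config(ddi_fraction = 0))), 0L)
  full <- generate_ddi_reference(synthetic_config(n_drugs = 4, ddi_fraction = 1))
  expect_equal(nrow(full), 6L)  # C(4,2)
  maj <- generate_ddi_reference(synthetic_config(n_drugs = 10, ddi_fraction = 0.5,
                                                 severity_probs = c(1, 0, 0)))
  expect_true(all(maj$severity == "major"))
  expect_true(all(maj$drug_a < maj$drug_b))
  expect_equal(anyDuplicated(maj[, .(drug_a, drug_b)]), 0L)

  pe <- planted_effect(c("D0002", "D0001"), "W", risk_multiplier = 2)
  ref <- generate_ddi_reference(synthetic_config(ddi_fraction = 0,
                                                 planted_effects = list(pe)))
  expect_equal(nrow(ref), 1L)
  expect_equal(c(ref$drug_a, ref$drug_b), c("D0001", "D0002"))
})

test_that("drug classes: hub dominates alternatives in interaction partners", {
  cfg <- synthetic_config(n_drugs = 60, ddi_fraction = 0.05, seed = 9)
  ddi <- generate_ddi_reference(cfg)
  cls <- generate_drug_classes(cfg, ddi)
  expect_identical(cls, generate_drug_classes(cfg, ddi))
  hub <- attr(cls, "hub_drug")
  expect_true(hub %in% cls$drug_id)
  expect_gte(nrow(cls), 2L)
  partners <- function(d) nrow(ddi[drug_a == d | drug_b == d])
  for (alt in setdiff(cls$drug_id, hub)) {
    expect_lt(partners(alt), partners(hub))
    # alternatives do not interact with the hub itself
    expect_equal(nrow(ddi[(drug_a == hub & drug_b == alt) |
                            (drug_a == alt & drug_b == hub)]), 0L)
  }
  expect_error(generate_drug_classes(cfg, ddi, n_alternatives = 0), "alternative")
})

test_that("planted multiplier 0 for women removes all overlapping pair dispensations", {
  pe <- planted_effect(c("D0003", "D0007"), "W", risk_multiplier = 0)
  cfg <- synthetic_config(n_patients = 3000, planted_effects = list(pe), seed = 13)
  pats <- generate_population(cfg)
  recs <- generate_dispensations(pats, cfg)
  ep <- detect_pair_episodes(recs, window = cfg$window)
  women <- pats[gender == "W", patient_id]
  expect_equal(nrow(ep[drug_a == "D0003" & drug_b == "D0007" &
                         patient_id %in% women]), 0L)
})

test_that("planted co-dispensation rate is monotone in the risk multiplier", {
  rates <- sapply(c(0, 1, 4), function(m) {
    pe <- planted_effect(c("D0010", "D0020"), "both", risk_multiplier = m)
    cfg <- synthetic_config(n_patients = 10000, planted_effects = list(pe),
                            seed = 17)
    pats <- generate_population(cfg)
    recs <- generate_dispensations(pats, cfg)
    ep <- detect_pair_episodes(recs, window = cfg$window)
    nrow(ep[drug_a == "D0010" & drug_b == "D0020"]) / nrow(pats)
  })
  expect_equal(rates[1], 0)
  expect_true(all(diff(rates) > 0))
})

test_that("daily output converts to a valid monthly table (resolution consistency)", {
  cfg <- synthetic_config(n_patients = 100, seed = 21)
  recs <- generate_dispensations(generate_population(cfg), cfg)
  mwin <- study_window(cfg$window$start, cfg$window$end, "monthly")
  mon <- daily_to_monthly(recs, mwin)
  expect_true(all(c("patient_id", "drug_id", "month") %in% names(mon)))
  # re-canonicalization accepts it unchanged
  expect_equal(as.data.frame(canonicalize_dispensations(mon, mwin)),
               as.data.frame(mon))
  # a record spanning a month boundary covers both months
  one <- daily_to_monthly(drec("a", "d", 25, 10), mwin)  # Jan 26 .. Feb 4
  expect_equal(as.character(one$month), c("2014-01-01", "2014-02-01"))

  # monthly-resolution config produces the converted table directly
  cfgm <- synthetic_config(n_patients = 100, resolution = "monthly", seed = 21)
  expect_identical(generate_dispensations(generate_population(cfgm), cfgm), mon)
})

test_that("synthetic tables written to disk re-read identically", {
  tmp <- withr::local_tempdir()
  cfg <- synthetic_config(n_patients = 50, seed = 23)
  paths <- write_synthetic_tables(cfg, tmp)
  pats <- read_patients(paths$patients)
  expect_equal(nrow(pats), 50L)
  recs <- read_dispensations(paths$dispensations, cfg$window)
  expect_equal(as.data.frame(recs),
               as.data.frame(generate_dispensations(generate_population(cfg), cfg)))
  expect_equal(as.data.frame(read_ddi_reference(paths$ddi)),
               as.data.frame(generate_ddi_reference(cfg)))
})
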