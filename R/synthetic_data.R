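# Synthetic EHR-like data with the statistical structure the analysis
# assumes: age-increasing polypharmacy, heavy-tailed (rank power-law) drug
# popularity, gender-specific drugs, a sparse severity-labelled interaction
# reference, a hub drug with substitutable same-class alternatives, and both
# daily and monthly temporal resolution. Planted effects give selected drug
# pairs a controlled co-dispensation rate in a target gender/age stratum so
# that parameter-recovery tests have a known ground truth.

#' Planted co-dispensation effect
#'
#' Routes a drug pair's co-dispensation through a controlled channel: the
#' generator first removes natural temporal overlaps of the pair, then gives
#' every patient a co-dispensation event (both drugs over one shared
#' interval) with probability `planted_base_rate * risk_multiplier` in the
#' matching gender/age stratum and `planted_base_rate` elsewhere. A
#' multiplier of 0 therefore guarantees the matching stratum has no
#' overlapping dispensations of the pair, and the stratum's relative rate
#' equals the multiplier in expectation.
#'
#' @param drug_pair Character vector of two distinct drug ids.
#' @param gender `"W"`, `"M"` or `"both"`.
#' @param age_bin_range Inclusive range of 5-year bin labels, e.g.
#'   `c("40-44", "40-44")`; defaults to all bins.
#' @param risk_multiplier Non-negative multiplicative boost.
#' @return A `planted_effect` object.
#' @export
planted_effect <- function(drug_pair, gender = c("both", "W", "M"),
                           age_bin_range = c("0-4", "90+"),
                           risk_multiplier = 1) {
  gender <- match.arg(gender)
  abort_if(length(drug_pair) != 2L || drug_pair[1L] == drug_pair[2L],
           "planted_effect: drug_pair must be two distinct drug ids")
  abort_if(!all(age_bin_range %in% age_bin_levels()) || length(age_bin_range) != 2L,
           "planted_effect: age_bin_range must be two valid 5-year bin labels")
  abort_if(!is.numeric(risk_multiplier) || risk_multiplier < 0,
           "planted_effect: risk_multiplier must be >= 0")
  structure(list(drug_pair = as.character(drug_pair), gender = gender,
                 age_bin_range = age_bin_range,
                 risk_multiplier = as.numeric(risk_multiplier)),
            class = "planted_effect")
}

#' Configuration of the synthetic-data generator
#'
#' Defaults emulate an 18-month municipal dispensation registry: a
#' two-gender population with ages spread to 90+, a drug formulary whose
#' popularity follows a rank power law (a few hub drugs dominate),
#' overdispersed per-patient drug counts whose mean grows with age
#' (polypharmacy), month-scale treatment durations with refills, and a
#' sparse interaction reference dominated by moderate-severity pairs.
#'
#' @param n_patients Number of patients (>= 1).
#' @param gender_ratio Fraction of women in `[0, 1]`.
#' @param age_range Completed years `c(min, max)` at the window start.
#' @param n_drugs Formulary size (>= 1).
#' @param popularity_exponent Zipf-like exponent (> 0) of the rank
#'   popularity law.
#' @param mean_drugs Mean distinct drugs per patient at age 0.
#' @param polypharmacy_slope Additional expected distinct drugs per decade
#'   of age (>= 0).
#' @param drug_count_dispersion Negative-binomial size parameter of the
#'   distinct-drug count (smaller = more overdispersed).
#' @param mean_duration_days Mean administration length per dispensation in
#'   days (> 0); durations are geometric.
#' @param mean_dispensations Mean dispensations (refills) per patient-drug
#'   (>= 1).
#' @param ddi_fraction Fraction of unordered drug pairs designated
#'   interacting, in `[0, 1]`.
#' @param severity_probs Probabilities over (major, moderate, minor),
#'   summing to 1.
#' @param gender_specific_fraction Fraction of drugs dispensed to one gender
#'   only (contraceptive-like), split evenly between genders.
#' @param planted_effects List of [planted_effect()] objects.
#' @param planted_base_rate Baseline probability of the controlled
#'   co-dispensation channel (see [planted_effect()]).
#' @param resolution `"daily"` or `"monthly"`.
#' @param study_window Character or Date vector `c(start, end)`.
#' @param seed Integer master seed; all generator randomness flows from it
#'   through named substreams.
#' @return A validated `synthetic_config` object.
#' @export
synthetic_config <- function(n_patients = 10000L,
                             gender_ratio = 0.5,
                             age_range = c(0L, 90L),
                             n_drugs = 200L,
                             popularity_exponent = 1.0,
                             mean_drugs = 3,
                             polypharmacy_slope = 0.4,
                             drug_count_dispersion = 2,
                             mean_duration_days = 30,
                             mean_dispensations = 3,
                             ddi_fraction = 0.015,
                             severity_probs = c(major = 0.25, moderate = 0.55,
                                                minor = 0.20),
                             gender_specific_fraction = 0.02,
                             planted_effects = list(),
                             planted_base_rate = 0.1,
                             resolution = c("daily", "monthly"),
                             study_window = c("2014-01-01", "2015-06-30"),
                             seed = 1L) {
  resolution <- match.arg(resolution)
  chk <- function(ok, field, what) {
    abort_if(!isTRUE(ok), sprintf("invalid config field '%s': %s", field, what))
  }
  chk(is.numeric(n_patients) && n_patients >= 1, "n_patients", "must be >= 1")
  chk(is.numeric(gender_ratio) && gender_ratio >= 0 && gender_ratio <= 1,
      "gender_ratio", "must be in [0, 1]")
  chk(length(age_range) == 2L && age_range[1L] <= age_range[2L] && age_range[1L] >= 0,
      "age_range", "must be c(min, max) with 0 <= min <= max")
  chk(is.numeric(n_drugs) && n_drugs >= 1, "n_drugs", "must be >= 1")
  chk(popularity_exponent > 0, "popularity_exponent", "must be > 0")
  chk(mean_drugs > 0, "mean_drugs", "must be > 0")
  chk(polypharmacy_slope >= 0, "polypharmacy_slope", "must be >= 0")
  chk(drug_count_dispersion > 0, "drug_count_dispersion", "must be > 0")
  chk(mean_duration_days > 0, "mean_duration_days", "must be > 0")
  chk(mean_dispensations >= 1, "mean_dispensations", "must be >= 1")
  chk(ddi_fraction >= 0 && ddi_fraction <= 1, "ddi_fraction", "must be in [0, 1]")
  chk(length(severity_probs) == 3L && all(severity_probs >= 0) &&
        all(severity_probs <= 1) && abs(sum(severity_probs) - 1) < 1e-9,
      "severity_probs", "must be 3 probabilities summing to 1")
  chk(gender_specific_fraction >= 0 && gender_specific_fraction <= 1,
      "gender_specific_fraction", "must be in [0, 1]")
  chk(all(vapply(planted_effects, inherits, TRUE, "planted_effect")),
      "planted_effects", "must be a list of planted_effect objects")
  chk(planted_base_rate >= 0 && planted_base_rate <= 1,
      "planted_base_rate", "must be in [0, 1]")
  chk(is.numeric(seed) && length(seed) == 1L && !is.na(seed), "seed",
      "must be a single integer")
  win <- study_window(study_window[1L], study_window[2L], "daily")
  structure(list(
    n_patients = as.integer(n_patients), gender_ratio = gender_ratio,
    age_range = as.integer(age_range), n_drugs = as.integer(n_drugs),
    popularity_exponent = popularity_exponent, mean_drugs = mean_drugs,
    polypharmacy_slope = polypharmacy_slope,
    drug_count_dispersion = drug_count_dispersion,
    mean_duration_days = mean_duration_days,
    mean_dispensations = mean_dispensations, ddi_fraction = ddi_fraction,
    severity_probs = severity_probs,
    gender_specific_fraction = gender_specific_fraction,
    planted_effects = planted_effects, planted_base_rate = planted_base_rate,
    resolution = resolution, window = win, seed = as.integer(seed)
  ), class = "synthetic_config")
}

drug_ids <- function(config) sprintf("D%04d", seq_len(config$n_drugs))

popularity_weights <- function(config) {
  seq_len(config$n_drugs)^(-config$popularity_exponent)
}

# Drugs restricted to one gender (emulating e.g. contraceptives).
# Deterministic given the config seed.
gender_specific_drugs <- function(config) {
  n <- round(config$gender_specific_fraction * config$n_drugs)
  if (n < 1L) return(list(W = character(), M = character()))
  set.seed(substream_seed(config$seed, "gender_specific"))
  picked <- sample(drug_ids(config), n)
  half <- ceiling(n / 2)
  list(W = picked[seq_len(half)], M = picked[setdiff(seq_len(n), seq_len(half))])
}

#' Generate a synthetic patient population
#'
#' Gender is drawn with probability `gender_ratio` for `W`; completed age at
#' the window start is uniform over `age_range`.
#'
#' @param config A [synthetic_config()].
#' @return `data.table` with columns `patient_id`, `gender`, `birth_date`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(substream_seed(config$seed, "population"))
  n <- config$n_patients
  gender <- ifelse(runif(n) < config$gender_ratio, "W", "M")
  age_days <- runif(n, config$age_range[1L] * 365.25,
                    (config$age_range[2L] + 1) * 365.25)
  birth <- data.table::as.IDate(as.integer(config$window$start) - floor(age_days))
  data.table(patient_id = sprintf("P%06d", seq_len(n)),
             gender = gender, birth_date = birth, key = "patient_id")
}

# all unordered pairs (a < b) over 1..n as integer columns
all_pairs <- function(n) {
  if (n < 2L) return(data.table(a = integer(), b = integer()))
  a <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  b <- sequence((n - 1L):1L) + a
  data.table(a = a, b = b)
}

#' Generate a synthetic DDI reference
#'
#' Marks a fraction `ddi_fraction` of unordered drug pairs as interacting,
#' with severities sampled from `severity_probs`. Pairs named in
#' `planted_effects` are always included (their point is to be interactions
#' with a known planted signal).
#'
#' @param config A [synthetic_config()].
#' @return Canonical DDI reference `data.table` (see [read_ddi_reference()]).
#' @export
generate_ddi_reference <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  abort_if(config$n_drugs < 2L, "invalid config field 'n_drugs': need >= 2 for a DDI reference")
  set.seed(substream_seed(config$seed, "ddi_reference"))
  ids <- drug_ids(config)
  pairs <- all_pairs(config$n_drugs)
  m <- round(config$ddi_fraction * nrow(pairs))
  take <- if (m > 0L) pairs[sort(sample.int(nrow(pairs), m))] else pairs[0L]
  ref <- data.table(drug_a = ids[take$a], drug_b = ids[take$b])
  for (pe in config$planted_effects) {
    cp <- canonical_pair(pe$drug_pair[1L], pe$drug_pair[2L])
    abort_if(!all(unlist(cp) %in% ids), "planted_effect drug ids not in the formulary")
    ref <- unique(rbind(ref, data.table(drug_a = cp$drug_a, drug_b = cp$drug_b)))
  }
  ref[, severity := sample(SEVERITY_LEVELS, .N, replace = TRUE,
                           prob = config$severity_probs)]
  if (nrow(ref) == 0L) ref[, severity := character()]
  as_ddi_reference(ref)
}

#' Generate a drug-class table with a hub drug and safer alternatives
#'
#' Emits one interchangeable therapeutic class containing a hub drug -- the
#' drug with the largest popularity-weighted count of reference interaction
#' partners, i.e. a widely dispensed, interaction-heavy drug of the kind a
#' substitution intervention targets -- plus alternatives chosen among
#' drugs that do not interact with the hub and have strictly fewer
#' interaction partners.
#'
#' @param config A [synthetic_config()].
#' @param ddi DDI reference; defaults to [generate_ddi_reference()] on the
#'   same config, so the pair is consistent.
#' @param n_alternatives Number of alternatives requested (>= 1).
#' @return `data.table` with columns `class_id`, `drug_id`; the hub id is
#'   attached as attribute `"hub_drug"`.
#' @export
generate_drug_classes <- function(config, ddi = generate_ddi_reference(config),
                                  n_alternatives = 4L) {
  stopifnot(inherits(config, "synthetic_config"))
  abort_if(config$n_drugs < 2L, "invalid config field 'n_drugs': need >= 2 for drug classes")
  abort_if(n_alternatives < 1L, "a drug class needs at least one alternative")
  ids <- drug_ids(config)
  partners <- setNames(integer(length(ids)), ids)
  if (nrow(ddi) > 0L) {
    tab <- table(c(ddi$drug_a, ddi$drug_b))
    partners[names(tab)] <- as.integer(tab)
  }
  # hub: popularity-weighted interaction burden, so the designated hub is a
  # widely dispensed drug with many reference interactions (the situation
  # a substitution intervention targets); gender-restricted drugs are not
  # interchangeable-class candidates
  gs <- unlist(gender_specific_drugs(config))
  burden <- popularity_weights(config) * partners
  burden[match(gs, ids)] <- 0
  abort_if(all(burden == 0),
           "no drug has any reference interaction; cannot designate a hub")
  hub <- ids[which.max(burden)]
  hub_partners <- unique(c(ddi[drug_a == hub, drug_b], ddi[drug_b == hub, drug_a]))
  candidates <- setdiff(ids, c(hub, hub_partners, gs))
  candidates <- candidates[partners[candidates] < partners[hub]]
  abort_if(length(candidates) == 0L, "no eligible alternative drug for the hub class")
  set.seed(substream_seed(config$seed, "drug_classes"))
  ord <- order(partners[candidates], candidates)
  alts <- candidates[ord][seq_len(min(n_alternatives, length(candidates)))]
  out <- data.table(class_id = "HUBCLASS", drug_id = c(hub, alts))
  setattr(out, "hub_drug", hub)
  setkey(out, class_id, drug_id)[]
}

#' Generate synthetic dispensation records
#'
#' Per patient, the number of distinct drugs is negative binomial with mean
#' `mean_drugs + polypharmacy_slope * age / 10`; drug identities follow the
#' rank popularity law (restricted by gender for gender-specific drugs);
#' each patient-drug receives `1 + Poisson` dispensations with uniform
#' starts in the window and geometric day durations (clipped to the
#' window). Planted effects are then applied (see [planted_effect()]).
#' At monthly resolution the daily records are mapped to their covered
#' billing months.
#'
#' @param patients Output of [generate_population()].
#' @param config The same [synthetic_config()].
#' @return Canonical dispensation `data.table` in the config's resolution.
#' @export
generate_dispensations <- function(patients, config) {
  stopifnot(inherits(config, "synthetic_config"))
  abort_if(nrow(patients) == 0L, "patients table is empty")
  set.seed(substream_seed(config$seed, "dispensations"))
  win <- config$window
  win_s <- as.integer(win$start); win_e <- as.integer(win$end)
  ids <- drug_ids(config)
  w <- popularity_weights(config)
  gs <- gender_specific_drugs(config)

  pts <- data.table::as.data.table(patients)
  pts[, age := age_at(birth_date, win$start)]
  mu <- pmax(0.3, config$mean_drugs + config$polypharmacy_slope * pts$age / 10)
  d <- rnbinom(nrow(pts), size = config$drug_count_dispersion, mu = mu)

  recs <- vector("list", 2L)
  for (g in c("W", "M")) {
    sel <- which(pts$gender == g)
    if (length(sel) == 0L) next
    wg <- w
    wg[match(gs[[setdiff(c("W", "M"), g)]], ids)] <- 0
    dg <- pmin(d[sel], sum(wg > 0))
    drawn <- .sample_wor_many(as.integer(dg), wg)
    recs[[g]] <- data.table(patient_id = rep(pts$patient_id[sel], dg),
                            drug_id = ids[drawn])
  }
  pd <- data.table::rbindlist(recs)
  if (nrow(pd) > 0L) {
    ndisp <- 1L + rpois(nrow(pd), config$mean_dispensations - 1)
    disp <- pd[rep(seq_len(nrow(pd)), ndisp)]
    disp[, start := win_s + floor(runif(.N) * (win_e - win_s + 1L))]
    disp[, duration := 1L + rgeom(.N, 1 / config$mean_duration_days)]
    disp[, duration := pmin(duration, win_e + 1L - start)]
  } else {
    disp <- data.table(patient_id = character(), drug_id = character(),
                       start = integer(), duration = integer())
  }

  disp <- apply_planted_effects(disp, pts, config)
  disp[, start := data.table::as.IDate(start)]
  out <- canonicalize_dispensations(disp, win)
  if (config$resolution == "monthly") {
    mwin <- study_window(win$start, win$end, "monthly")
    out <- daily_to_monthly(out, mwin)
  }
  out
}

# Controlled co-dispensation channel (see planted_effect): removes the
# pair's natural overlaps, then adds one aligned co-dispensation event with
# stratum-dependent probability. Operates on integer-day records.
apply_planted_effects <- function(disp, pts, config) {
  if (length(config$planted_effects) == 0L) return(disp)
  win_s <- as.integer(config$window$start)
  win_e <- as.integer(config$window$end)
  lev <- age_bin_levels()
  for (k in seq_along(config$planted_effects)) {
    pe <- config$planted_effects[[k]]
    set.seed(substream_seed(config$seed, paste0("planted", k)))
    cp <- canonical_pair(pe$drug_pair[1L], pe$drug_pair[2L])
    a_id <- cp$drug_a; b_id <- cp$drug_b
    # 1. remove natural overlaps: drop B records overlapping any A record
    arec <- disp[drug_id == a_id, .(patient_id, s = start, e = start + duration - 1L)]
    if (nrow(arec) > 0L) {
      bidx <- which(disp$drug_id == b_id)
      brec <- disp[bidx, .(patient_id, s = start, e = start + duration - 1L,
                           idx = bidx)]
      if (nrow(brec) > 0L) {
        setkey(arec, patient_id, s, e)
        ov <- data.table::foverlaps(brec, arec, by.x = c("patient_id", "s", "e"),
                                    nomatch = NULL)
        if (nrow(ov) > 0L) disp <- disp[-unique(ov$idx)]
      }
    }
    # 2. controlled events
    dur <- 1L + rgeom(nrow(pts), 1 / config$mean_duration_days)
    ev_start <- win_s + floor(runif(nrow(pts)) * (win_e - win_s + 1L))
    dur <- pmin(dur, win_e + 1L - ev_start)
    bin <- age_to_bin(age_at(pts$birth_date, data.table::as.IDate(ev_start)))
    bin_lo <- match(pe$age_bin_range[1L], lev)
    bin_hi <- match(pe$age_bin_range[2L], lev)
    in_bins <- !is.na(bin) & match(bin, lev) >= bin_lo & match(bin, lev) <= bin_hi
    matches <- in_bins & (pe$gender == "both" | pts$gender == pe$gender)
    rate <- ifelse(matches, pmin(1, config$planted_base_rate * pe$risk_multiplier),
                   config$planted_base_rate)
    keep <- runif(nrow(pts)) < rate
    if (any(keep)) {
      ev <- data.table(patient_id = rep(pts$patient_id[keep], 2L),
                       drug_id = rep(c(a_id, b_id), each = sum(keep)),
                       start = rep(ev_start[keep], 2L),
                       duration = rep(dur[keep], 2L))
      disp <- rbind(disp, ev)
    }
  }
  disp
}

#' Convert daily records to monthly billing records
#'
#' Each half-open day interval is mapped to the set of calendar months it
#' covers, one record per (patient, drug, month).
#'
#' @param records Canonical daily dispensation table.
#' @param window A monthly-resolution [study_window()].
#' @return Canonical monthly dispensation table.
#' @export
daily_to_monthly <- function(records, window) {
  stopifnot(inherits(window, "study_window"), window$resolution == "monthly")
  dt <- data.table::as.data.table(records)
  if (nrow(dt) == 0L) {
    return(canonicalize_dispensations(
      data.table(patient_id = character(), drug_id = character(),
                 month = data.table::as.IDate(integer())), window))
  }
  last_day <- data.table::as.IDate(as.integer(dt$start) + dt$duration - 1L)
  m0 <- data.table::year(dt$start) * 12L + data.table::month(dt$start) - 1L
  m1 <- data.table::year(last_day) * 12L + data.table::month(last_day) - 1L
  nmon <- m1 - m0 + 1L
  mon <- rep(m0, nmon) + sequence(nmon) - 1L
  out <- data.table(patient_id = rep(dt$patient_id, nmon),
                    drug_id = rep(dt$drug_id, nmon),
                    month = data.table::as.IDate(
                      sprintf("%04d-%02d-01", mon %/% 12L, mon %% 12L + 1L)))
  canonicalize_dispensations(unique(out), window)
}

#' Write the four synthetic tables as delimited text
#'
#' Generates population, dispensations, DDI reference and drug classes from
#' one config and writes them in the [read_patients()] /
#' [read_dispensations()] / [read_ddi_reference()] / [read_drug_classes()]
#' schemas.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Named list of the four file paths, invisibly.
#' @export
write_synthetic_tables <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pats <- generate_population(config)
  disp <- generate_dispensations(pats, config)
  ddi <- generate_ddi_reference(config)
  classes <- generate_drug_classes(config, ddi)
  paths <- list(patients = file.path(dir, "patients.csv"),
                dispensations = file.path(dir, "dispensations.csv"),
                ddi = file.path(dir, "ddi_reference.csv"),
                classes = file.path(dir, "drug_classes.csv"))
  write_table(pats, paths$patients)
  write_table(disp, paths$dispensations)
  write_table(ddi, paths$ddi)
  write_table(classes, paths$classes)
  invisible(paths)
}
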