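# Prevalence of co-administration (PC) and of interaction (PI), stratified
# by gender, 5-year age bin and interaction severity, with exact-test
# relative risks for women vs men.

#' Tag drug events with the patient's age bin at the event date
#'
#' Age is completed years at the event's start date; because the analysis is
#' longitudinal, one patient contributes to every bin in which they have at
#' least one event. Rows with a negative age (event before birth) are
#' rejected with a warning reporting the count.
#'
#' @param dt Table with a `patient_id` column and a date column.
#' @param patients Patient table with `patient_id`, `gender`, `birth_date`.
#' @param date_col Name of the event-date column (default `"start"`, falls
#'   back to `"month"` for monthly tables).
#' @return Copy of `dt` with `gender`, `age` and `age_bin` columns added.
#' @export
assign_age_bins <- function(dt, patients, date_col = NULL) {
  dt <- data.table::as.data.table(dt)
  date_col <- date_col %||% intersect(c("start", "month"), names(dt))[1L]
  abort_if(is.na(date_col) || is.null(date_col), "no event-date column found")
  pts <- data.table::as.data.table(patients)[, .(patient_id, gender, birth_date)]
  out <- pts[dt, on = "patient_id"]
  abort_if(anyNA(out$birth_date), "events reference patient ids missing from the patient table")
  out[, age := age_at(birth_date, get(date_col))]
  neg <- out$age < 0L
  if (any(neg)) {
    warning(sprintf("rejected %d row(s) with negative age at event", sum(neg)),
            call. = FALSE)
    out <- out[!neg]
  }
  out[, age_bin := age_to_bin(age)]
  out[, birth_date := NULL][]
}

SEVERITY_STRATA <- c("any", "major", "moderate", "minor")

# distinct-patient counts over all gender x age-bin margins of a tagged
# event table (patient can appear in several bins, so margins are computed
# by distinct count, never by summing cells)
margin_counts <- function(dt, value_name) {
  bins <- c(age_bin_levels(), "all")
  dt <- dt[, .(patient_id, gender, age_bin = as.character(age_bin))]
  m <- rbind(
    dt[, .(n = data.table::uniqueN(patient_id)), by = .(gender, age_bin)],
    dt[, .(age_bin = "all", n = data.table::uniqueN(patient_id)), by = .(gender)],
    dt[, .(gender = "all", n = data.table::uniqueN(patient_id)), by = .(age_bin)],
    dt[, .(gender = "all", age_bin = "all", n = data.table::uniqueN(patient_id))],
    use.names = TRUE)
  data.table::setnames(m, "n", value_name)[]
}

#' Stratified prevalence of co-administration and interaction
#'
#' For every requested stratum (gender x 5-year age bin x severity): the
#' number of patients with at least one administration (the denominator --
#' the population is defined by drug events, not enrolment), the number with
#' at least one co-administered pair (PC numerator) and the number with at
#' least one co-administered known-interacting pair passing the severity
#' filter (PI numerator). Severity strata are non-exclusive; `"any"` pools
#' all severities. Strata with an empty denominator carry `NA` prevalences.
#'
#' @param runs Run-level co-administration table from [coadmin_runs()]
#'   (annotated with a DDI reference).
#' @param records Canonical dispensation table.
#' @param patients Patient table.
#' @param by Stratification dimensions, a subset of
#'   `c("gender", "age_bin", "severity")`; omitted dimensions are collapsed
#'   to `"all"`/`"any"`.
#' @return `data.table` with columns `gender`, `age_bin`, `severity`,
#'   `n_patients`, `n_coadmin`, `n_interact`, `pc`, `pi`.
#' @export
compute_prevalence <- function(runs, records, patients,
                               by = c("gender", "age_bin", "severity")) {
  by <- match.arg(by, several.ok = TRUE)
  rec_tag <- assign_age_bins(records, patients)
  run_tag <- assign_age_bins(runs, patients)

  denom <- margin_counts(rec_tag, "n_patients")
  coad <- margin_counts(run_tag, "n_coadmin")
  inter <- data.table::rbindlist(lapply(SEVERITY_STRATA, function(sv) {
    sel <- if (sv == "any") run_tag[is_ddi == TRUE] else run_tag[severity == sv]
    cbind(margin_counts(sel, "n_interact"), severity = sv)
  }))

  genders <- if ("gender" %in% by) c("W", "M", "all") else "all"
  bins <- if ("age_bin" %in% by) c(age_bin_levels(), "all") else "all"
  sevs <- if ("severity" %in% by) SEVERITY_STRATA else "any"
  cells <- data.table::CJ(gender = genders, age_bin = bins, severity = sevs,
                          unique = TRUE, sorted = FALSE)
  cells <- denom[cells, on = c("gender", "age_bin")]
  cells <- coad[cells, on = c("gender", "age_bin")]
  cells <- inter[cells, on = c("gender", "age_bin", "severity")]
  for (cc in c("n_patients", "n_coadmin", "n_interact"))
    cells[is.na(get(cc)), (cc) := 0L]
  cells[, `:=`(pc = ifelse(n_patients > 0L, n_coadmin / n_patients, NA_real_),
               pi = ifelse(n_patients > 0L, n_interact / n_patients, NA_real_))]
  cells[, age_bin := factor(age_bin, levels = c(age_bin_levels(), "all"))]
  setorder(cells, gender, age_bin, severity)
  cells[, .(gender, age_bin, severity, n_patients, n_coadmin, n_interact, pc, pi)]
}

#' Relative risk for women from affected counts, with Fisher's exact test
#'
#' `rr_women` is the prevalence of the outcome in women divided by the
#' prevalence in men; `rr_men` is the reciprocal. The p-value is the
#' two-sided Fisher exact test on the 2x2 table of gender by
#' affected/unaffected.
#'
#' @param affected_w,n_w Affected and total women.
#' @param affected_m,n_m Affected and total men.
#' @return `data.table` (vectorized over the inputs) with `prev_w`,
#'   `prev_m`, `rr_women`, `rr_men`, `p_value`. When the men's prevalence is
#'   zero and the women's positive, `rr_women` is `Inf` and `rr_men` 0.
#' @export
relative_risk <- function(affected_w, n_w, affected_m, n_m) {
  abort_if(any(n_w <= 0L) || any(n_m <= 0L),
           "relative_risk requires positive denominators for both genders")
  abort_if(any(affected_w > n_w) || any(affected_m > n_m),
           "affected counts exceed denominators")
  prev_w <- affected_w / n_w
  prev_m <- affected_m / n_m
  p <- vapply(seq_along(prev_w), function(i) {
    tab <- matrix(c(affected_w[i], n_w[i] - affected_w[i],
                    affected_m[i], n_m[i] - affected_m[i]), nrow = 2L)
    stats::fisher.test(tab)$p.value
  }, numeric(1L))
  data.table(prev_w = prev_w, prev_m = prev_m,
             rr_women = prev_w / prev_m, rr_men = prev_m / prev_w,
             p_value = p)
}

#' Relative risk from already-computed prevalences
#'
#' The ratio form used when only prevalence percentages are available (e.g.
#' published report tables): `rr_women = prev_w / prev_m`.
#'
#' @param prev_w,prev_m Gender-specific prevalences (any common scale).
#' @return Numeric vector of relative risks for women.
#' @export
rr_from_prevalence <- function(prev_w, prev_m) prev_w / prev_m

#' Gender relative risks of co-administration (RRC) and interaction (RRI)
#'
#' Compares the W and M rows of a stratified prevalence table within each
#' (age bin, severity) stratum, for both outcomes: co-administration (RRC)
#' and interaction (RRI). Significance is a two-sided Fisher exact test
#' with multiplicity correction across all strata in the report.
#'
#' @param prev Output of [compute_prevalence()] including the gender
#'   dimension.
#' @param correction `"fdr"` (Benjamini-Hochberg, default) or
#'   `"bonferroni"`.
#' @param alpha Significance level after correction (default 0.05).
#' @return `data.table` with columns `age_bin`, `severity`, `measure`
#'   (`"coadministration"`/`"interaction"`), `prev_w`, `prev_m`,
#'   `rr_women`, `rr_men`, `p_value`, `q_value`, `significant`.
#' @export
gender_relative_risks <- function(prev, correction = c("fdr", "bonferroni"),
                                  alpha = 0.05) {
  correction <- match.arg(correction)
  prev <- data.table::as.data.table(prev)
  w <- prev[gender == "W"]
  m <- prev[gender == "M"]
  cells <- merge(w, m, by = c("age_bin", "severity"), suffixes = c("_w", "_m"))
  cells <- cells[n_patients_w > 0L & n_patients_m > 0L]
  if (nrow(cells) == 0L) return(data.table())
  # RRC only varies by age bin; avoid duplicating it across severity strata
  rrc <- cells[severity == if ("any" %in% cells$severity) "any" else cells$severity[1L]]
  out <- rbind(
    cbind(rrc[, .(age_bin, severity = "any", measure = "coadministration")],
          relative_risk(rrc$n_coadmin_w, rrc$n_patients_w,
                        rrc$n_coadmin_m, rrc$n_patients_m)),
    cbind(cells[, .(age_bin, severity, measure = "interaction")],
          relative_risk(cells$n_interact_w, cells$n_patients_w,
                        cells$n_interact_m, cells$n_patients_m)))
  out[, q_value := p.adjust(p_value, method = if (correction == "fdr") "BH" else "bonferroni")]
  out[, significant := q_value <= alpha]
  out[]
}
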