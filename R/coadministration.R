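# Per-patient co-administration detection and the pairwise statistics
# gamma (directed conditional likelihood) and tau (strength of
# co-administration, a normalized temporal overlap).

#' Run-level co-administration intervals
#'
#' Detects, per patient and unordered drug pair, every maximal run of
#' consecutive shared administration days (daily resolution; two drugs are
#' co-administered when their merged day sets overlap by at least one day)
#' or every shared billing month (monthly resolution). This is the
#' event-level table; [detect_pair_episodes()] aggregates it per
#' patient-pair.
#'
#' @param records Canonical dispensation table (see [read_dispensations()]).
#' @param ddi Optional DDI reference ([read_ddi_reference()]); when supplied,
#'   runs are annotated with `is_ddi` and `severity`.
#' @param window A [study_window()] giving the resolution.
#' @return `data.table` with columns `patient_id`, `drug_a`, `drug_b`
#'   (canonical order), `start` (first shared day / the shared month),
#'   `days` (shared time units in the run; always 1 at monthly resolution),
#'   `is_ddi`, `severity`.
#' @export
coadmin_runs <- function(records, ddi = NULL, window) {
  stopifnot(inherits(window, "study_window"))
  if (window$resolution == "daily") {
    ep <- merge_same_drug_intervals(records)
    ep <- ep[, .(patient_id, drug_id, s = as.integer(start),
                 e = as.integer(start) + duration - 1L)]  # inclusive last day
    setkey(ep, patient_id, s, e)
    ov <- data.table::foverlaps(ep, ep, type = "any", nomatch = NULL)
    ov <- ov[drug_id < i.drug_id]
    runs <- ov[, .(patient_id, drug_a = drug_id, drug_b = i.drug_id,
                   start = data.table::as.IDate(pmax(s, i.s)),
                   days = pmin(e, i.e) - pmax(s, i.s) + 1L)]
  } else {
    ep <- unique(data.table::as.data.table(records)[, .(patient_id, drug_id, month)])
    pair <- merge(ep, ep, by = c("patient_id", "month"), allow.cartesian = TRUE,
                  suffixes = c("", ".j"))
    pair <- pair[drug_id < drug_id.j]
    runs <- pair[, .(patient_id, drug_a = drug_id, drug_b = get("drug_id.j"),
                     start = month, days = 1L)]
  }
  runs <- annotate_ddi(runs, ddi)
  setorder(runs, patient_id, drug_a, drug_b, start)
  runs[, .(patient_id, drug_a, drug_b, start, days, is_ddi, severity)]
}

#' Per-patient co-administration episodes of drug pairs
#'
#' Aggregates [coadmin_runs()] per (patient, pair): `alpha_ij` counts the
#' disjoint co-administration runs and `lambda_ij` the total shared time
#' units; `lambda_i`/`lambda_j` are each drug's total administered time
#' units for the patient (distinct days after same-drug merging, or distinct
#' billing months). At monthly resolution `alpha_ij = lambda_ij` (number of
#' shared months).
#'
#' @inheritParams coadmin_runs
#' @return `data.table` with one row per patient and co-administered pair:
#'   `patient_id`, `drug_a`, `drug_b`, `alpha_ij`, `lambda_ij`, `lambda_i`,
#'   `lambda_j`, `tau` (see [tau_patient()]), `first_start`, `is_ddi`,
#'   `severity`.
#' @export
detect_pair_episodes <- function(records, ddi = NULL, window) {
  runs <- coadmin_runs(records, ddi, window)
  if (window$resolution == "daily") {
    per_drug <- merge_same_drug_intervals(records)[
      , .(lambda = sum(duration)), by = .(patient_id, drug_id)]
  } else {
    per_drug <- unique(data.table::as.data.table(records)[
      , .(patient_id, drug_id, month)])[
        , .(lambda = .N), by = .(patient_id, drug_id)]
  }
  ep <- runs[, .(alpha_ij = .N, lambda_ij = sum(days), first_start = min(start),
                 is_ddi = is_ddi[1L], severity = severity[1L]),
             by = .(patient_id, drug_a, drug_b)]
  ep[per_drug, lambda_i := i.lambda, on = c(patient_id = "patient_id", drug_a = "drug_id")]
  ep[per_drug, lambda_j := i.lambda, on = c(patient_id = "patient_id", drug_b = "drug_id")]
  ep[, tau := tau_patient(lambda_ij, lambda_i, lambda_j)]
  setorder(ep, patient_id, drug_a, drug_b)
  ep[, .(patient_id, drug_a, drug_b, alpha_ij, lambda_ij, lambda_i, lambda_j,
         tau, first_start, is_ddi, severity)]
}

#' Strength of co-administration for one patient
#'
#' The normalized co-administration length: shared time units divided by the
#' union of the two drugs' administered time units,
#' `lambda_ij / (lambda_i + lambda_j - lambda_ij)`. It lies in `(0, 1]`,
#' equals 1 exactly when the two administered day sets coincide, and tends
#' to 0 for brief overlaps of long treatments. Symmetric in the pair.
#'
#' @param lambda_ij Shared time units (>= 1).
#' @param lambda_i,lambda_j Each drug's total administered time units.
#' @return Numeric vector in `(0, 1]`.
#' @export
tau_patient <- function(lambda_ij, lambda_i, lambda_j) {
  stopifnot(all(lambda_ij >= 1), all(lambda_ij <= pmin(lambda_i, lambda_j)))
  lambda_ij / (lambda_i + lambda_j - lambda_ij)
}

#' Population-level pair statistics (the co-administration graph)
#'
#' For every co-administered pair: the number of users of each drug
#' (patients with >= 1 administration in the window), the number of
#' co-administering patients, the directed conditional likelihoods
#' `gamma_ij = |U_ij| / |U_i|` and `gamma_ji = |U_ij| / |U_j|`, and the mean
#' strength of co-administration `tau_mean` over the co-administering
#' cohort. Viewed as an undirected weighted edge list this is the
#' co-administration graph.
#'
#' @param episodes Output of [detect_pair_episodes()].
#' @param records The canonical dispensation table the episodes came from
#'   (used for per-drug user counts).
#' @return `data.table` with one row per pair: `drug_a`, `drug_b`,
#'   `n_users_i`, `n_users_j`, `n_coadmin_users`, `gamma_ij`, `gamma_ji`,
#'   `tau_mean`, `is_ddi`, `severity`.
#' @export
pair_population_stats <- function(episodes, records) {
  users <- data.table::as.data.table(records)[
    , .(n_users = data.table::uniqueN(patient_id)), by = drug_id]
  st <- episodes[, .(n_coadmin_users = data.table::uniqueN(patient_id),
                     tau_mean = mean(tau),
                     is_ddi = is_ddi[1L], severity = severity[1L]),
                 by = .(drug_a, drug_b)]
  st[users, n_users_i := i.n_users, on = c(drug_a = "drug_id")]
  st[users, n_users_j := i.n_users, on = c(drug_b = "drug_id")]
  st[, `:=`(gamma_ij = n_coadmin_users / n_users_i,
            gamma_ji = n_coadmin_users / n_users_j)]
  setorder(st, -n_coadmin_users, drug_a, drug_b)
  st[, .(drug_a, drug_b, n_users_i, n_users_j, n_coadmin_users,
         gamma_ij, gamma_ji, tau_mean, is_ddi, severity)]
}
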