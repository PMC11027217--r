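# Fixture builders and brute-force oracles shared across the suite.
library(data.table)

dwin <- function(start = "2014-01-01", end = "2014-12-31", resolution = "daily") {
  study_window(start, end, resolution)
}

# daily records from day offsets relative to a window start; durations in days
drec <- function(patient, drug, day0, dur, origin = "2014-01-01") {
  data.table(patient_id = as.character(patient), drug_id = as.character(drug),
             start = as.IDate(origin) + day0, duration = as.integer(dur))
}

mrec <- function(patient, drug, month) {
  data.table(patient_id = as.character(patient), drug_id = as.character(drug),
             month = month)
}

ddi_ref <- function(a, b, severity = "major") {
  as_ddi_reference(data.table(drug_a = a, drug_b = b, severity = severity))
}

pat <- function(ids, gender = "M", birth = "1970-06-15") {
  data.table(patient_id = as.character(ids), gender = gender,
             birth_date = as.IDate(birth))
}

empty_ddi <- function() {
  as_ddi_reference(data.table(drug_a = character(), drug_b = character(),
                              severity = character()))
}

# ---- brute-force oracle: materialize every (patient, drug, day) ----------

oracle_day_sets <- function(records) {
  dt <- as.data.table(records)
  dt[, .(day = seq(as.integer(start), as.integer(start) + duration - 1L)),
     by = .(patient_id, drug_id, seq_len(nrow(dt)))][
       , .(patient_id, drug_id, day)] |> unique()
}

# per-patient pair statistics from raw day sets: lambda = |intersection|,
# alpha = maximal runs of consecutive shared days
oracle_pair_episodes <- function(records) {
  days <- oracle_day_sets(records)
  out <- list()
  for (p in unique(days$patient_id)) {
    dd <- days[patient_id == p]
    drugs <- sort(unique(dd$drug_id))
    if (length(drugs) < 2L) next
    sets <- lapply(drugs, function(d) sort(dd[drug_id == d, day]))
    names(sets) <- drugs
    for (i in seq_along(drugs)) for (j in seq_along(drugs)) {
      if (i >= j) next
      shared <- intersect(sets[[i]], sets[[j]])
      if (length(shared) == 0L) next
      shared <- sort(shared)
      alpha <- 1L + sum(diff(shared) > 1L)
      out[[length(out) + 1L]] <- data.table(
        patient_id = p, drug_a = drugs[i], drug_b = drugs[j],
        alpha_ij = alpha, lambda_ij = length(shared),
        lambda_i = length(sets[[i]]), lambda_j = length(sets[[j]]))
    }
  }
  if (length(out) == 0L)
    return(data.table(patient_id = character(), drug_a = character(),
                      drug_b = character(), alpha_ij = integer(),
                      lambda_ij = integer(), lambda_i = integer(),
                      lambda_j = integer()))
  rbindlist(out)[order(patient_id, drug_a, drug_b)]
}

# randomized small instance: <= 20 patients, <= 8 drugs, <= 60-day window
random_instance <- function(seed) {
  set.seed(seed)
  np <- sample(1:20, 1)
  nd <- sample(2:8, 1)
  nrec <- sample(1:60, 1)
  drec(patient = sample(sprintf("p%02d", 1:np), nrec, replace = TRUE),
       drug = sample(sprintf("d%d", 1:nd), nrec, replace = TRUE),
       day0 = sample(0:59, nrec, replace = TRUE),
       dur = sample(1:20, nrec, replace = TRUE))
}

inst_window <- function() dwin("2014-01-01", "2014-03-31")
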