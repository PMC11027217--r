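# Age-matched, polypharmacy-preserving null model for the expected
# prevalence of interaction. Within each 5-year age bin, every patient
# "administers" as many distinct drugs as observed, drawn at random from
# the drugs observed in that bin, and as many co-administered pairs as
# observed, drawn from their randomized drug set; the randomized pairs are
# then checked against the interaction reference. Observed vs expected PI
# is compared with odds ratios and Fisher exact tests.

#' Configuration of the null model
#'
#' @param n_reps Number of random replicates (default 100).
#' @param sampling How a patient's randomized drug set is drawn within the
#'   age bin. `"label_shuffle"` (default) permutes the observed
#'   patient-drug occurrences of the bin, preserving each patient's
#'   distinct-drug count and each drug's occurrence total exactly (a drug
#'   label shuffle respecting cohort drug availability).
#'   `"frequency_weighted"` draws each patient's set without replacement
#'   with probabilities proportional to drugs' observed patient counts in
#'   the bin; `"uniform_distinct"` draws uniformly over the bin's distinct
#'   drugs.
#' @param seed Integer seed; replicate `r` draws from an independent
#'   substream so results are reproducible per (seed, rep).
#' @return A `null_model_config` object.
#' @export
null_model_config <- function(n_reps = 100L,
                              sampling = c("label_shuffle", "frequency_weighted",
                                           "uniform_distinct"),
                              seed = 1L) {
  sampling <- match.arg(sampling)
  abort_if(!is.numeric(n_reps) || n_reps < 1, "n_reps must be >= 1")
  structure(list(n_reps = as.integer(n_reps), sampling = sampling,
                 seed = as.integer(seed)), class = "null_model_config")
}

#' Randomize one age bin's patient drug sets
#'
#' Draws, for each patient, the same number of distinct drugs as observed,
#' without replacement from the bin's drug pool. Exposed mainly for
#' inspection and testing; [run_null_model()] performs the same draw in
#' compiled code.
#'
#' @param d_counts Integer vector: observed distinct-drug count per patient.
#' @param pool Character vector of the bin's observed drugs.
#' @param weights Sampling weight per pool drug (e.g. observed patient
#'   counts); uniform when `NULL`.
#' @return List of character vectors, one randomized drug set per patient.
#' @export
randomize_patient_drugs <- function(d_counts, pool, weights = NULL) {
  weights <- weights %||% rep(1, length(pool))
  abort_if(length(weights) != length(pool), "weights must match pool length")
  d_counts <- as.integer(d_counts)
  over <- d_counts > length(pool)
  if (any(over)) {
    message(sprintf("%d patient(s) request more drugs than the bin pool; sampling the full pool",
                    sum(over)))
    d_counts[over] <- length(pool)
  }
  drawn <- .sample_wor_many(d_counts, as.numeric(weights))
  unname(split(pool[drawn], factor(rep(seq_along(d_counts), d_counts),
                                   levels = seq_along(d_counts))))
}

#' Run the polypharmacy-preserving null model
#'
#' @param records Canonical dispensation table.
#' @param patients Patient table.
#' @param ddi DDI reference.
#' @param window A [study_window()].
#' @param config A [null_model_config()].
#' @return A `null_model_result`: list with `summary` (per age bin, plus an
#'   `"all"` row in which the whole cohort is treated as one stratum --
#'   distinct drugs and pairs per patient over the full window, drug pool
#'   the whole formulary observed: `n_patients`, `observed_pi`,
#'   `expected_pi_mean`, `expected_pi_sd`, `odds_ratio` of observed vs
#'   pooled-over-replicates null interaction odds, `p_value`
#'   from Fisher's exact test, `n_reps`), `per_rep` (long table of
#'   `expected_pi` and per-rep odds ratio per bin and replicate), and
#'   `config`.
#' @export
run_null_model <- function(records, patients, ddi, window, config = null_model_config()) {
  stopifnot(inherits(config, "null_model_config"))
  runs <- coadmin_runs(records, ddi, window)
  rec_tag <- assign_age_bins(records, patients)
  run_tag <- assign_age_bins(runs, patients)

  # observed per patient-bin: distinct drugs, distinct co-administered
  # pairs, any-interaction flag; "all" is its own stratum (the whole
  # cohort as one bin) so that the overall comparison counts each
  # patient's distinct pairs exactly once
  rec_tag <- rbind(rec_tag[, .(patient_id, age_bin = as.character(age_bin), drug_id)],
                   rec_tag[, .(patient_id, age_bin = "all", drug_id)])
  run_tag <- rbind(run_tag[, .(patient_id, age_bin = as.character(age_bin),
                               drug_a, drug_b, is_ddi)],
                   run_tag[, .(patient_id, age_bin = "all", drug_a, drug_b, is_ddi)])
  drugs_pb <- unique(rec_tag[, .(patient_id, age_bin, drug_id)])
  d_pb <- drugs_pb[, .(d = .N), by = .(patient_id, age_bin)]
  pairs_pb <- unique(run_tag[, .(patient_id, age_bin, drug_a, drug_b)])
  np_pb <- pairs_pb[, .(npairs = .N), by = .(patient_id, age_bin)]
  int_pb <- unique(run_tag[is_ddi == TRUE, .(patient_id, age_bin)])[, obs_int := TRUE]

  obs <- np_pb[d_pb, on = c("patient_id", "age_bin")]
  obs[is.na(npairs), npairs := 0L]
  obs <- int_pb[obs, on = c("patient_id", "age_bin")]
  obs[is.na(obs_int), obs_int := FALSE]

  capped <- obs[npairs > (d * (d - 1L)) %/% 2L, .N]
  if (capped > 0L)
    message(sprintf("capped observed pair count at C(d,2) for %d patient-bin(s)", capped))
  obs[, npairs := pmin(npairs, (d * (d - 1L)) %/% 2L)]

  rep_seeds <- vapply(seq_len(config$n_reps),
                      function(r) substream_seed(config$seed, paste0("rep", r)),
                      integer(1L))

  bins <- obs[, sort(unique(as.character(age_bin)))]
  per_rep <- vector("list", length(bins))
  summary_rows <- vector("list", length(bins))
  for (bi in seq_along(bins)) {
    b <- bins[bi]
    ob <- obs[as.character(age_bin) == b]
    pool <- drugs_pb[as.character(age_bin) == b,
                     .(w = data.table::uniqueN(patient_id)), by = drug_id]
    setorder(pool, drug_id)
    if (config$sampling == "uniform_distinct") pool[, w := 1]
    K <- nrow(pool)
    keys <- numeric(0)
    if (nrow(ddi) > 0L && K >= 2L) {
      dd <- ddi[drug_a %in% pool$drug_id & drug_b %in% pool$drug_id]
      if (nrow(dd) > 0L) {
        ia <- match(dd$drug_a, pool$drug_id) - 1L
        ib <- match(dd$drug_b, pool$drug_id) - 1L
        keys <- sort(pmin(ia, ib) * as.numeric(K) + pmax(ia, ib))
      }
    }
    d_vec <- pmin(ob$d, K)
    n_bin <- nrow(ob)
    null_int <- integer(config$n_reps)
    if (config$sampling == "label_shuffle") {
      # observed occurrence slots, grouped by patient in ob's order
      db <- drugs_pb[as.character(age_bin) == b]
      db[, pool_idx := match(drug_id, pool$drug_id) - 1L]
      setkey(db, patient_id)
      db <- db[data.table(patient_id = ob$patient_id)]
      slots <- db$pool_idx
      offs <- c(0L, cumsum(ob$d))
    }
    for (r in seq_len(config$n_reps)) {
      set.seed(rep_seeds[r])
      flags <- if (config$sampling == "label_shuffle") {
        .null_rep_shuffle(as.integer(slots), as.integer(offs),
                          as.integer(ob$npairs), keys, K)
      } else {
        .null_rep_interacting(as.integer(d_vec), as.integer(ob$npairs),
                              pool$w, keys)
      }
      null_int[r] <- sum(flags)
    }
    obs_int_n <- sum(ob$obs_int)
    null_total <- n_bin * config$n_reps
    null_int_total <- sum(null_int)
    or <- (obs_int_n / (n_bin - obs_int_n)) /
      (null_int_total / (null_total - null_int_total))
    p <- stats::fisher.test(matrix(c(obs_int_n, n_bin - obs_int_n,
                                     null_int_total, null_total - null_int_total),
                                   nrow = 2L))$p.value
    per_rep[[bi]] <- data.table(
      age_bin = b, rep = seq_len(config$n_reps),
      expected_pi = null_int / n_bin,
      odds_ratio = (obs_int_n / (n_bin - obs_int_n)) /
        (null_int / pmax(n_bin - null_int, 1L)))
    summary_rows[[bi]] <- data.table(
      age_bin = b, n_patients = n_bin, observed_pi = obs_int_n / n_bin,
      expected_pi_mean = mean(null_int) / n_bin,
      expected_pi_sd = stats::sd(null_int / n_bin),
      odds_ratio = or, p_value = p, n_reps = config$n_reps)
  }
  res <- list(summary = data.table::rbindlist(summary_rows),
              per_rep = data.table::rbindlist(per_rep),
              config = config)
  class(res) <- "null_model_result"
  res
}

#' @export
print.null_model_result <- function(x, ...) {
  cat(sprintf("<null_model_result> %d age bin(s), %d replicate(s), %s sampling\n",
              nrow(x$summary), x$config$n_reps, x$config$sampling))
  print(x$summary)
  invisible(x)
}
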