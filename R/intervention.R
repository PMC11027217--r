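# Counterfactual substitution of a target drug (e.g. an over-prescribed
# proton-pump inhibitor) with same-class alternatives that avoid known
# interactions with the patient's concurrently administered drugs, and the
# resulting reduction in interaction prevalence.

# per-episode units of administration: merged day intervals (daily) or
# single months (monthly), as inclusive integer ranges [s, e]
episode_units <- function(records, window) {
  if (window$resolution == "daily") {
    ep <- merge_same_drug_intervals(records)
    ep[, .(patient_id, drug_id, s = as.integer(start),
           e = as.integer(start) + duration - 1L)]
  } else {
    ep <- unique(data.table::as.data.table(records)[, .(patient_id, drug_id, month)])
    ep[, .(patient_id, drug_id, s = as.integer(month), e = as.integer(month))]
  }
}

#' Plan per-episode substitutions of a target drug
#'
#' For every administration episode of the target that overlaps a known
#' interaction partner, selects the first same-class alternative whose
#' reference interactions are disjoint from all drugs the patient
#' administers concurrently with that episode. Alternatives are ranked by
#' ascending total interaction count in the reference (safest first), ties
#' broken lexicographically by drug id. Episodes with no qualifying
#' alternative are kept, recording the blocking drugs; episodes with no
#' interacting partner are untouched.
#'
#' @param records Canonical dispensation table.
#' @param target Target drug id; must belong to exactly one class with at
#'   least one alternative.
#' @param classes Drug-class table ([read_drug_classes()]).
#' @param ddi DDI reference.
#' @param window A [study_window()].
#' @return A `substitution_plan`: list with `target`, `alternatives`
#'   (ranked), and `episodes` (one row per target episode: `patient_id`,
#'   `s`, `e`, `action` in kept/replaced/untouched, `alternative`,
#'   `blocked_by`).
#' @export
plan_substitutions <- function(records, target, classes, ddi, window) {
  classes <- data.table::as.data.table(classes)
  cls <- unique(classes[drug_id == target, class_id])
  abort_if(length(cls) == 0L, sprintf("configuration error: target '%s' not in the class table", target))
  abort_if(length(cls) > 1L, sprintf("target '%s' belongs to multiple classes", target))
  alts <- setdiff(classes[class_id == cls, drug_id], target)
  abort_if(length(alts) == 0L, sprintf("class '%s' has no alternative to '%s'", cls, target))

  n_inter <- setNames(integer(length(alts)), alts)
  if (nrow(ddi) > 0L) {
    tab <- table(c(ddi$drug_a, ddi$drug_b))
    hit <- intersect(names(tab), alts)
    n_inter[hit] <- as.integer(tab[hit])
  }
  alts <- alts[order(n_inter[alts], alts)]
  partners_of <- function(d) {
    unique(c(ddi[drug_a == d, drug_b], ddi[drug_b == d, drug_a]))
  }
  target_partners <- partners_of(target)
  alt_partners <- lapply(alts, partners_of)

  units <- episode_units(records, window)
  tgt <- units[drug_id == target]
  if (nrow(tgt) == 0L) {
    plan <- list(target = target, alternatives = alts,
                 episodes = data.table(patient_id = character(), s = integer(),
                                       e = integer(), action = character(),
                                       alternative = character(),
                                       blocked_by = character()))
    class(plan) <- "substitution_plan"
    return(plan)
  }
  oth <- units[drug_id != target]
  setkey(oth, patient_id, s, e)
  tgt[, episode_id := .I]
  ov <- data.table::foverlaps(tgt, oth, by.x = c("patient_id", "s", "e"),
                              nomatch = NULL)
  concurrent <- ov[, .(drugs = list(unique(drug_id))), by = episode_id]
  tgt[, action := "untouched"]
  tgt[, alternative := NA_character_]
  tgt[, blocked_by := NA_character_]
  for (k in seq_len(nrow(concurrent))) {
    eid <- concurrent$episode_id[k]
    conc <- concurrent$drugs[[k]]
    if (!any(conc %in% target_partners)) next  # no DDI in this episode
    chosen <- NA_character_
    for (a in seq_along(alts)) {
      if (!any(conc %in% alt_partners[[a]])) { chosen <- alts[a]; break }
    }
    if (is.na(chosen)) {
      blockers <- conc[vapply(conc, function(d)
        all(vapply(alt_partners, function(p) d %in% p, logical(1L))), logical(1L))]
      tgt[episode_id == eid,
          `:=`(action = "kept", blocked_by = paste(blockers, collapse = ";"))]
    } else {
      tgt[episode_id == eid, `:=`(action = "replaced", alternative = chosen)]
    }
  }
  plan <- list(target = target, alternatives = alts,
               episodes = tgt[, .(patient_id, s, e, action, alternative, blocked_by)])
  class(plan) <- "substitution_plan"
  plan
}

#' @export
print.substitution_plan <- function(x, ...) {
  cat(sprintf("<substitution_plan> target %s; alternatives %s\n", x$target,
              paste(x$alternatives, collapse = " > ")))
  print(x$episodes[, .N, by = action])
  invisible(x)
}

#' Rewrite dispensation records according to a substitution plan
#'
#' Records of the target drug falling inside a replaced episode get the
#' episode's alternative drug id; dates and durations are unchanged, so
#' each patient's total administered time is conserved. Applying a plan
#' twice equals applying it once.
#'
#' @param records Canonical dispensation table.
#' @param plan A `substitution_plan` from [plan_substitutions()].
#' @param window A [study_window()].
#' @return Rewritten canonical dispensation table.
#' @export
apply_substitutions <- function(records, plan, window) {
  stopifnot(inherits(plan, "substitution_plan"))
  rec <- data.table::copy(data.table::as.data.table(records))
  rep_ep <- plan$episodes[action == "replaced"]
  if (nrow(rep_ep) == 0L) return(rec)
  if (window$resolution == "daily") {
    rec[, `:=`(s = as.integer(start), e = as.integer(start) + duration - 1L)]
  } else {
    rec[, `:=`(s = as.integer(month), e = as.integer(month))]
  }
  rec[, rowid := .I]
  tgt <- rec[drug_id == plan$target]
  setkey(rep_ep, patient_id, s, e)
  hits <- data.table::foverlaps(tgt, rep_ep, by.x = c("patient_id", "s", "e"),
                                nomatch = NULL)
  if (nrow(hits) > 0L) rec[hits$rowid, drug_id := hits$alternative]
  rec[, c("s", "e", "rowid") := NULL]
  canonicalize_dispensations(rec, window)
}

#' Apply a substitution plan and recompute interaction prevalence
#'
#' Rewrites the records, reruns the prevalence stack, and reports, per
#' (gender, severity) stratum, the interaction prevalence before and after
#' and the relative reduction, plus the number of patients freed of all
#' known interactions.
#'
#' @param records Canonical dispensation table.
#' @param patients Patient table.
#' @param ddi DDI reference.
#' @param window A [study_window()].
#' @param plan A `substitution_plan`.
#' @return An `intervention_report`: list with `strata` (`gender`,
#'   `severity`, `n_patients`, `pi_before`, `pi_after`,
#'   `relative_reduction`), `n_patients_freed`, `records_after`, `plan`.
#' @export
apply_and_recompute <- function(records, patients, ddi, window, plan) {
  after <- apply_substitutions(records, plan, window)
  runs_b <- coadmin_runs(records, ddi, window)
  runs_a <- coadmin_runs(after, ddi, window)
  prev_b <- compute_prevalence(runs_b, records, patients, by = c("gender", "severity"))
  prev_a <- compute_prevalence(runs_a, after, patients, by = c("gender", "severity"))
  strata <- merge(prev_b[, .(gender, severity, n_patients, pi_before = pi)],
                  prev_a[, .(gender, severity, pi_after = pi)],
                  by = c("gender", "severity"))
  strata[, relative_reduction := data.table::fifelse(
    pi_before > 0, (pi_before - pi_after) / pi_before, NA_real_)]
  before_int <- unique(runs_b[is_ddi == TRUE, patient_id])
  after_int <- unique(runs_a[is_ddi == TRUE, patient_id])
  res <- list(strata = strata[],
              n_patients_freed = length(setdiff(before_int, after_int)),
              records_after = after, plan = plan)
  class(res) <- "intervention_report"
  res
}

#' @export
print.intervention_report <- function(x, ...) {
  cat(sprintf("<intervention_report> target %s; %d patient(s) freed of all known DDIs\n",
              x$plan$target, x$n_patients_freed))
  print(x$strata)
  invisible(x)
}
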