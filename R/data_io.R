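# Reading, validation and canonicalization of the four input tables.
#
# All tables are delimited text (comma default, tab auto-detected) with a
# header row; dates are ISO-8601 (YYYY-MM-DD), billing months are YYYY-MM.

SEVERITY_LEVELS <- c("major", "moderate", "minor")

#' Define a study window
#'
#' The temporal extent and resolution of an analysis. At daily resolution
#' administration intervals are half-open day ranges `[start, start + duration)`;
#' at monthly resolution each record is one billing month.
#'
#' @param start,end Window limits (`Date` or ISO-8601 strings). At monthly
#'   resolution they are truncated to the first day of their month.
#' @param resolution `"daily"` or `"monthly"`.
#' @return A `study_window` object (list with `start`, `end`, `resolution`).
#' @export
study_window <- function(start, end, resolution = c("daily", "monthly")) {
  resolution <- match.arg(resolution)
  start <- parse_iso_date(start)
  end <- parse_iso_date(end)
  abort_if(is.na(start) || is.na(end), "study window dates must parse as ISO-8601")
  if (resolution == "monthly") {
    start <- first_of_month(start)
    end <- first_of_month(end)
  }
  abort_if(start > end, "study window start must not be after end")
  structure(list(start = start, end = end, resolution = resolution),
            class = "study_window")
}

#' @export
print.study_window <- function(x, ...) {
  cat(sprintf("<study_window> %s .. %s (%s)\n", x$start, x$end, x$resolution))
  invisible(x)
}

first_of_month <- function(d) {
  data.table::as.IDate(sprintf("%04d-%02d-01", data.table::year(d),
                               data.table::month(d)))
}

# ISO-8601 parse that yields NA (not an error) on malformed strings
parse_iso_date <- function(x) {
  if (inherits(x, "Date")) return(data.table::as.IDate(x))
  data.table::as.IDate(as.Date(as.character(x), format = "%Y-%m-%d"))
}

parse_month <- function(x) {
  # accepts YYYY-MM or a full date
  x <- as.character(x)
  ok <- grepl("^\\d{4}-\\d{2}$", x)
  x[ok] <- paste0(x[ok], "-01")
  d <- suppressWarnings(parse_iso_date(x))
  d[!is.na(d)] <- first_of_month(d[!is.na(d)])
  d
}

read_delim_table <- function(path, required) {
  abort_if(!file.exists(path), sprintf("file not found: %s", path))
  dt <- data.table::fread(path, colClasses = "character", na.strings = c("", "NA"))
  missing <- setdiff(required, names(dt))
  abort_if(length(missing) > 0L,
           sprintf("schema error in %s: missing column(s) %s", path,
                   paste(missing, collapse = ", ")))
  dt
}

#' Read a patient demographics table
#'
#' Expects columns `patient_id`, `gender`, `birth_date`. Genders other than
#' `W`/`M` are excluded from analysis (the analysis is two-gender) with a
#' message reporting the count.
#'
#' @param path Delimited text file.
#' @return `data.table` with columns `patient_id` (character), `gender`
#'   (`"W"`/`"M"`), `birth_date` (`IDate`).
#' @export
read_patients <- function(path) {
  dt <- read_delim_table(path, c("patient_id", "gender", "birth_date"))
  dt <- dt[, .(patient_id, gender, birth_date = parse_iso_date(birth_date))]
  bad_date <- which(is.na(dt$birth_date))
  abort_if(length(bad_date) > 0L,
           sprintf("unparsable birth_date in row(s): %s",
                   paste(head(bad_date, 10L), collapse = ", ")))
  n_other <- dt[!gender %chin% c("W", "M"), .N]
  if (n_other > 0L) {
    message(sprintf("excluding %d patient(s) with gender outside {W, M}", n_other))
    dt <- dt[gender %chin% c("W", "M")]
  }
  abort_if(anyDuplicated(dt$patient_id) > 0L, "duplicate patient_id values")
  setkey(dt, patient_id)[]
}

#' Read a dispensation table
#'
#' Daily resolution expects columns `patient_id`, `drug_id`, `start`
#' (ISO-8601 date) and `duration` (positive integer days); records are
#' clipped to the study window. Monthly resolution expects `patient_id`,
#' `drug_id`, `month` (`YYYY-MM`); months outside the window are dropped.
#' Malformed rows are rejected with their row numbers; exact duplicate rows
#' are deduplicated with a message.
#'
#' @param path Delimited text file.
#' @param window A [study_window()].
#' @return Canonical `data.table` of dispensation records. Daily: columns
#'   `patient_id`, `drug_id`, `start` (`IDate`), `duration` (days). Monthly:
#'   `patient_id`, `drug_id`, `month` (`IDate`, first of month).
#' @export
read_dispensations <- function(path, window) {
  stopifnot(inherits(window, "study_window"))
  if (window$resolution == "daily") {
    dt <- read_delim_table(path, c("patient_id", "drug_id", "start", "duration"))
    out <- dt[, .(patient_id, drug_id,
                  start = parse_iso_date(start),
                  duration = suppressWarnings(as.integer(duration)))]
  } else {
    dt <- read_delim_table(path, c("patient_id", "drug_id", "month"))
    out <- dt[, .(patient_id, drug_id, month = parse_month(month))]
  }
  canonicalize_dispensations(out, window)
}

#' Canonicalize an in-memory dispensation table
#'
#' Applies the same validation, window clipping and deduplication as
#' [read_dispensations()] to a table already in R.
#'
#' @param records Data frame with the columns described in
#'   [read_dispensations()].
#' @param window A [study_window()].
#' @return Canonical `data.table` (see [read_dispensations()]).
#' @export
canonicalize_dispensations <- function(records, window) {
  stopifnot(inherits(window, "study_window"))
  out <- data.table::as.data.table(records)
  if (window$resolution == "daily") {
    abort_if(!all(c("patient_id", "drug_id", "start", "duration") %in% names(out)),
             "daily records need columns patient_id, drug_id, start, duration")
    out <- out[, .(patient_id = as.character(patient_id),
                   drug_id = as.character(drug_id),
                   start = parse_iso_date(start),
                   duration = as.integer(duration))]
    bad <- which(is.na(out$start) | is.na(out$duration) | out$duration < 1L |
                   is.na(out$drug_id) | out$drug_id == "" | is.na(out$patient_id))
    if (length(bad) > 0L) {
      stop(sprintf("malformed dispensation row(s): %s%s",
                   paste(head(bad, 10L), collapse = ", "),
                   if (length(bad) > 10L) sprintf(" (+%d more)", length(bad) - 10L) else ""),
           call. = FALSE)
    }
    # clip half-open [start, start+duration) to [window start, window end]
    out[, end := as.integer(start) + duration]                 # exclusive
    win_s <- as.integer(window$start)
    win_e <- as.integer(window$end) + 1L                       # exclusive
    out <- out[end > win_s & as.integer(start) < win_e]
    out[, `:=`(start = data.table::as.IDate(pmax(as.integer(start), win_s)),
               end = pmin(end, win_e))]
    out[, duration := end - as.integer(start)][, end := NULL]
  } else {
    abort_if(!all(c("patient_id", "drug_id", "month") %in% names(out)),
             "monthly records need columns patient_id, drug_id, month")
    out <- out[, .(patient_id = as.character(patient_id),
                   drug_id = as.character(drug_id),
                   month = parse_month(month))]
    bad <- which(is.na(out$month) | is.na(out$drug_id) | out$drug_id == "" |
                   is.na(out$patient_id))
    abort_if(length(bad) > 0L,
             sprintf("malformed dispensation row(s): %s",
                     paste(head(bad, 10L), collapse = ", ")))
    out <- out[month >= window$start & month <= window$end]
  }
  ndup <- nrow(out) - data.table::uniqueN(out)
  if (ndup > 0L) {
    message(sprintf("deduplicated %d exact duplicate dispensation row(s)", ndup))
    out <- unique(out)
  }
  setkey(out, patient_id, drug_id)[]
}

#' Read a drug-drug interaction reference
#'
#' Expects columns `drug_a`, `drug_b`, `severity` with severity one of
#' `major`, `moderate`, `minor`. Pairs are canonically ordered
#' (`drug_a < drug_b`); the same pair listed twice with conflicting severity
#' is an error; self-pairs are rejected.
#'
#' @param path Delimited text file.
#' @return `data.table` with one row per interacting pair, keyed by the pair.
#' @export
read_ddi_reference <- function(path) {
  dt <- read_delim_table(path, c("drug_a", "drug_b", "severity"))
  as_ddi_reference(dt)
}

#' Validate and canonicalize an in-memory DDI reference
#'
#' @param ddi Data frame with columns `drug_a`, `drug_b`, `severity`.
#' @return Canonical `data.table` (see [read_ddi_reference()]).
#' @export
as_ddi_reference <- function(ddi) {
  dt <- data.table::as.data.table(ddi)[, .(drug_a = as.character(drug_a),
                                           drug_b = as.character(drug_b),
                                           severity = as.character(severity))]
  bad_sev <- setdiff(unique(dt$severity), SEVERITY_LEVELS)
  abort_if(length(bad_sev) > 0L,
           sprintf("unknown severity token(s) %s; allowed: %s",
                   paste(bad_sev, collapse = ", "),
                   paste(SEVERITY_LEVELS, collapse = ", ")))
  abort_if(any(dt$drug_a == dt$drug_b), "self-pairs are not allowed in a DDI reference")
  cp <- canonical_pair(dt$drug_a, dt$drug_b)
  dt[, `:=`(drug_a = cp$drug_a, drug_b = cp$drug_b)]
  dt <- unique(dt)
  dup <- dt[, .N, by = .(drug_a, drug_b)][N > 1L]
  abort_if(nrow(dup) > 0L,
           sprintf("conflicting severities for pair(s): %s",
                   paste(dup[, paste0("(", drug_a, ",", drug_b, ")")], collapse = " ")))
  setkey(dt, drug_a, drug_b)[]
}

#' Read a drug-class table
#'
#' Therapeutic classes of interchangeable drugs (e.g. the proton-pump
#' inhibitors); columns `class_id`, `drug_id`. Classes with a single member
#' are rejected: a substitution simulation needs at least one alternative.
#'
#' @param path Delimited text file.
#' @return `data.table` with columns `class_id`, `drug_id`.
#' @export
read_drug_classes <- function(path) {
  dt <- read_delim_table(path, c("class_id", "drug_id"))
  dt <- unique(dt[, .(class_id = as.character(class_id),
                      drug_id = as.character(drug_id))])
  singleton <- dt[, .N, by = class_id][N < 2L]
  abort_if(nrow(singleton) > 0L,
           sprintf("drug class(es) with fewer than 2 members: %s",
                   paste(singleton$class_id, collapse = ", ")))
  setkey(dt, class_id, drug_id)[]
}

#' Write a table as delimited text
#'
#' UTF-8, header row, ISO-8601 dates; companion to the readers so that a
#' write/read round trip is the identity.
#'
#' @param x Data frame.
#' @param path Output file; the delimiter is inferred from the extension
#'   (`.tsv` tab, otherwise comma).
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  data.table::fwrite(data.table::as.data.table(x), path, sep = sep)
  invisible(path)
}

#' Merge overlapping and abutting same-drug intervals
#'
#' Collapses, per patient and drug, day intervals that overlap or abut into
#' maximal administration episodes (a refill continuing an ongoing treatment
#' is one episode). After merging, the number of rows per (patient, drug) is
#' the episode count alpha and the summed durations the distinct
#' administered days lambda.
#'
#' @param records Canonical daily dispensation table
#'   (see [read_dispensations()]).
#' @return `data.table` with columns `patient_id`, `drug_id`, `start`,
#'   `duration`, sorted; idempotent and invariant to input row order.
#' @export
merge_same_drug_intervals <- function(records) {
  dt <- data.table::as.data.table(records)
  abort_if(!"start" %in% names(dt) || !"duration" %in% names(dt),
           "merge_same_drug_intervals requires daily-resolution records")
  dt <- dt[, .(patient_id, drug_id, s = as.integer(start),
               e = as.integer(start) + as.integer(duration))]
  setorder(dt, patient_id, drug_id, s, e)
  # a new episode starts when the interval begins strictly after every
  # previous interval's end (abutting start == end merges)
  dt[, grp := {
    cm <- cummax(e)
    cumsum(s > data.table::shift(cm, fill = s[1L]))
  }, by = .(patient_id, drug_id)]
  out <- dt[, .(s = min(s), e = max(e)), by = .(patient_id, drug_id, grp)]
  out[, .(patient_id, drug_id,
          start = data.table::as.IDate(s),
          duration = e - s)][order(patient_id, drug_id, start)]
}
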