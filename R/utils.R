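# Shared helpers: age arithmetic, 5-year bins, canonical drug pairs.

`%||%` <- function(a, b) if (is.null(a)) b else a

AGE_BIN_BREAKS <- c(seq(0L, 90L, by = 5L), Inf)

#' Labels of the 5-year age bins
#'
#' Bins are `0-4`, `5-9`, ..., `85-89`, `90+`; patient age is completed years
#' at the date of the drug event.
#'
#' @return Character vector of the 19 bin labels, in age order.
#' @export
age_bin_levels <- function() {
  lo <- seq(0L, 85L, by = 5L)
  c(sprintf("%d-%d", lo, lo + 4L), "90+")
}

#' Completed age in years at a given date
#'
#' @param birth_date,date `Date` (or `IDate`) vectors, recycled.
#' @return Integer vector of completed years (calendar arithmetic, not
#'   day-count division).
#' @export
age_at <- function(birth_date, date) {
  birth_date <- data.table::as.IDate(birth_date)
  date <- data.table::as.IDate(date)
  yrs <- data.table::year(date) - data.table::year(birth_date)
  before_birthday <- (data.table::month(date) < data.table::month(birth_date)) |
    (data.table::month(date) == data.table::month(birth_date) &
       data.table::mday(date) < data.table::mday(birth_date))
  as.integer(yrs - before_birthday)
}

#' Map ages to 5-year bins
#'
#' @param age Integer vector of completed years (>= 0).
#' @return Factor with levels [age_bin_levels()].
#' @export
age_to_bin <- function(age) {
  lev <- age_bin_levels()
  idx <- pmin(age %/% 5L, 18L) + 1L
  idx[age < 0L] <- NA_integer_
  factor(lev[idx], levels = lev)
}

# Canonicalize an unordered drug pair: lexicographically smaller id first.
canonical_pair <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  swap <- b < a
  list(drug_a = ifelse(swap, b, a), drug_b = ifelse(swap, a, b))
}

# Internal validator shorthand
abort_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
  invisible(NULL)
}

# Annotate a table holding canonical (drug_a, drug_b) columns with DDI
# status/severity from a reference; absent pairs get is_ddi = FALSE,
# severity = "none".
annotate_ddi <- function(dt, ddi) {
  dt <- data.table::copy(dt)
  if (is.null(ddi) || nrow(ddi) == 0L) {
    dt[, `:=`(is_ddi = FALSE, severity = "none")]
    return(dt)
  }
  ref <- ddi[, .(drug_a, drug_b, severity)]
  for (cc in intersect(c("severity", "is_ddi"), names(dt))) dt[, (cc) := NULL]
  dt <- ref[dt, on = c("drug_a", "drug_b")]
  dt[is.na(severity), severity := "none"]
  dt[, is_ddi := severity != "none"]
  dt[]
}

# Derive a 32-bit substream seed from a master seed and a label, so each
# generator/replicate draws from an independent, reproducible stream.
substream_seed <- function(seed, label) {
  chars <- utf8ToInt(paste0(label, ":"))
  h <- as.double(seed %% 2147483647L)
  for (ch in chars) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}
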