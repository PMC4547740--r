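# Raw per-patient, day-stamped EHR event streams. All three constructors
# return plain data frames so they interoperate with read.delim()/merge();
# the constructors exist to enforce the ingest invariants (integer days,
# de-duplication, interval ordering).

#' Drug administration events
#'
#' One row per (patient, calendar day) on which the study drug was
#' administered. Dose is deliberately absent: episode mining needs only the
#' pure calendar date of each administration. Duplicate (patient, day) pairs
#' are dropped on ingest.
#'
#' @param patient_id Character or factor patient identifiers.
#' @param day Integer calendar-day index of the administration.
#' @return A data frame with columns `patient_id`, `day`, sorted by patient
#'   and day, de-duplicated.
#' @export
#' @examples
#' administration_events(c("p1", "p1", "p1"), c(3, 3, 4))
administration_events <- function(patient_id, day) {
  if (length(patient_id) == 1L) patient_id <- rep_len(patient_id, length(day))
  if (length(patient_id) != length(day)) {
    abort_validation("patient_id and day must have equal length")
  }
  day <- as.integer(day)
  if (anyNA(day)) abort_validation("administration day must be an integer, got NA")
  out <- data.frame(patient_id = as.character(patient_id), day = day,
                    stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$patient_id, out$day), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Laboratory observations
#'
#' One absolute lab value per (patient, parameter, calendar day). Values are
#' reduced to a daily scale: when several values exist for the same
#' (patient, parameter, day), the last one supplied wins and a warning is
#' emitted.
#'
#' @param patient_id,parameter_id Identifiers.
#' @param day Integer calendar-day index of the observation.
#' @param value Absolute lab value, in the parameter's lab units.
#' @return A data frame with columns `patient_id`, `parameter_id`, `day`,
#'   `value`, sorted, at most one row per (patient, parameter, day).
#' @export
lab_observations <- function(patient_id, parameter_id, day, value) {
  n <- length(day)
  if (length(patient_id) == 1L) patient_id <- rep_len(patient_id, n)
  if (length(parameter_id) == 1L) parameter_id <- rep_len(parameter_id, n)
  if (length(patient_id) != n || length(parameter_id) != n || length(value) != n) {
    abort_validation("all lab observation fields must have equal length")
  }
  day <- as.integer(day)
  if (anyNA(day)) abort_validation("observation day must be an integer, got NA")
  value <- as.numeric(value)
  if (anyNA(value)) abort_validation("observation value must be numeric, got NA")
  out <- data.frame(patient_id = as.character(patient_id),
                    parameter_id = as.character(parameter_id),
                    day = day, value = value, stringsAsFactors = FALSE)
  key <- paste(out$patient_id, out$parameter_id, out$day, sep = "\r")
  if (anyDuplicated(key)) {
    n_dup <- sum(duplicated(key))
    warning(n_dup, " duplicate lab observation(s) on the same day; keeping the last value",
            call. = FALSE)
    out <- out[!duplicated(key, fromLast = TRUE), , drop = FALSE]
  }
  out <- out[order(out$patient_id, out$parameter_id, out$day), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Patient-specific reference intervals
#'
#' The per-patient, per-parameter normal range used for normalization: the
#' lower border value maps to 0 and the upper border value to 1.
#'
#' @param patient_id,parameter_id Identifiers.
#' @param lower,upper Lower and upper border values in lab units;
#'   `upper` must be strictly greater than `lower`.
#' @return A data frame with columns `patient_id`, `parameter_id`, `lower`,
#'   `upper`, one row per (patient, parameter).
#' @export
reference_intervals <- function(patient_id, parameter_id, lower, upper) {
  n <- length(lower)
  if (length(patient_id) == 1L) patient_id <- rep_len(patient_id, n)
  if (length(parameter_id) == 1L) parameter_id <- rep_len(parameter_id, n)
  if (length(patient_id) != n || length(parameter_id) != n || length(upper) != n) {
    abort_validation("all reference interval fields must have equal length")
  }
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (anyNA(lower) || anyNA(upper)) abort_validation("reference bounds must be numeric")
  bad <- which(upper <= lower)
  if (length(bad) > 0) {
    abort_validation("reference interval upper bound must exceed lower bound (row ",
                     paste(utils::head(bad, 5), collapse = ", "), ")")
  }
  out <- data.frame(patient_id = as.character(patient_id),
                    parameter_id = as.character(parameter_id),
                    lower = lower, upper = upper, stringsAsFactors = FALSE)
  key <- paste(out$patient_id, out$parameter_id, sep = "\r")
  if (anyDuplicated(key)) {
    abort_validation("duplicate reference interval for the same (patient, parameter)")
  }
  out <- out[order(out$patient_id, out$parameter_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalize an absolute lab value to a patient-specific reference interval
#'
#' Maps an absolute lab value `LV_a` to the dimensionless
#' `LV_n = (LV_a - BV_l) / (BV_u - BV_l)`, where `BV_l` and `BV_u` are the
#' patient-specific lower and upper border values. 0 and 1 mark the
#' reference-interval bounds; values are deliberately not clamped, so
#' results below 0 or above 1 indicate out-of-range lab values.
#'
#' @param value Absolute lab value(s), lab units.
#' @param lower,upper Reference interval bounds (recycled against `value`);
#'   `upper > lower` required.
#' @return Numeric vector of normalized, dimensionless values.
#' @export
#' @examples
#' # reference range 30-120 U/L:
#' normalize_value(c(15, 30, 100, 120, 220), 30, 120)
normalize_value <- function(value, lower, upper) {
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (any(upper <= lower)) {
    abort_validation("degenerate reference interval: upper must exceed lower")
  }
  (as.numeric(value) - lower) / (upper - lower)
}
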