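# The Episode type: one solitary administration run plus its normalized lab
# curve on a relative-day axis (day 0 = first administration day).

#' Construct an episode
#'
#' An episode pairs the relative administration days of one solitary
#' administration run with the normalized lab value curve observed around
#' it. Day 0 is the first administration day; negative relative days precede
#' the episode.
#'
#' @param episode_id Identifier, unique within a corpus.
#' @param administration_days Integer vector of relative administration days;
#'   must contain 0 as its minimum.
#' @param points Data frame with columns `relative_day` (integer) and
#'   `value` (normalized, dimensionless); one point per relative day.
#' @param truth_label Optional logical: whether a drug response was planted
#'   (synthetic data only; `NA` for real data).
#' @param parameter_tag Optional identifier of the underlying lab parameter
#'   (synthetic data only; `NA` for anonymized data).
#' @return An object of class `episode`.
#' @seealso [validate_episode()] for the structural acceptance rules.
#' @export
episode <- function(episode_id, administration_days, points,
                    truth_label = NA, parameter_tag = NA_character_) {
  administration_days <- sort(unique(as.integer(administration_days)))
  if (length(administration_days) == 0) {
    abort_validation("episode ", episode_id, ": no administration days")
  }
  if (!is.data.frame(points) ||
      !all(c("relative_day", "value") %in% names(points))) {
    abort_validation("episode ", episode_id,
                     ": points must be a data frame with relative_day and value")
  }
  points <- data.frame(relative_day = as.integer(points$relative_day),
                       value = as.numeric(points$value),
                       stringsAsFactors = FALSE)
  if (anyDuplicated(points$relative_day)) {
    abort_validation("episode ", episode_id, ": duplicate observation days")
  }
  points <- points[order(points$relative_day), , drop = FALSE]
  rownames(points) <- NULL
  structure(
    list(episode_id = as.character(episode_id),
         administration_days = administration_days,
         points = points,
         truth_label = as.logical(truth_label),
         parameter_tag = as.character(parameter_tag)),
    class = "episode"
  )
}

#' Validate the structural rules of an episode
#'
#' Re-checks, independently of the extraction pipeline, the five structural
#' rules an episode must satisfy: (1) the relative day axis is anchored so
#' that the first administration day is day 0; (2) consecutive
#' administration days are separated by at most `max_internal_gap_days`
#' administration-free days; (3) at least `min_obs_per_phase` observations
#' fall before day 0, within the administration period, and after it;
#' (4) observations before/after the administration period lie within
#' `flank_window_days` of its boundaries; (5) no observation lies outside
#' the union of the three phase windows.
#'
#' @param x An [episode()].
#' @param max_internal_gap_days Maximum administration-free days tolerated
#'   inside a run (default 1).
#' @param min_obs_per_phase Minimum observations per phase (default 5).
#' @param flank_window_days Width, in days, of the pre- and post-episode
#'   observation windows (default 7).
#' @return Character vector of violated rules; `character(0)` if the episode
#'   is valid.
#' @export
validate_episode <- function(x, max_internal_gap_days = 1L,
                             min_obs_per_phase = 5L, flank_window_days = 7L) {
  stopifnot(inherits(x, "episode"))
  bad <- character(0)
  ad <- x$administration_days
  if (min(ad) != 0L) {
    bad <- c(bad, sprintf("first administration day must be relative day 0 (got %d)", min(ad)))
  }
  if (length(ad) > 1 && any(diff(ad) > max_internal_gap_days + 1L)) {
    bad <- c(bad, sprintf("administration gap exceeds %d administration-free day(s)",
                          max_internal_gap_days))
  }
  last <- max(ad)
  rd <- x$points$relative_day
  n_before <- sum(rd < 0L)
  n_during <- sum(rd >= 0L & rd <= last)
  n_after <- sum(rd > last)
  if (n_before < min_obs_per_phase) {
    bad <- c(bad, sprintf("only %d observation(s) before the episode (need %d)",
                          n_before, min_obs_per_phase))
  }
  if (n_during < min_obs_per_phase) {
    bad <- c(bad, sprintf("only %d observation(s) during the episode (need %d)",
                          n_during, min_obs_per_phase))
  }
  if (n_after < min_obs_per_phase) {
    bad <- c(bad, sprintf("only %d observation(s) after the episode (need %d)",
                          n_after, min_obs_per_phase))
  }
  if (any(rd < -flank_window_days)) {
    bad <- c(bad, sprintf("observation earlier than %d day(s) before day 0",
                          flank_window_days))
  }
  if (any(rd > last + flank_window_days)) {
    bad <- c(bad, sprintf("observation later than %d day(s) after the last administration",
                          flank_window_days))
  }
  bad
}

#' @export
print.episode <- function(x, ...) {
  ad <- x$administration_days
  cat(sprintf("<episode %s>\n", x$episode_id))
  cat(sprintf("  administration: relative days %d..%d (%d day(s) administered)\n",
              min(ad), max(ad), length(ad)))
  cat(sprintf("  lab curve: %d points on relative days %d..%d\n",
              nrow(x$points), min(x$points$relative_day), max(x$points$relative_day)))
  if (!is.na(x$truth_label)) {
    cat(sprintf("  planted effect: %s\n", x$truth_label))
  }
  invisible(x)
}
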