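# Aggregation of per-episode rater votes into the ground-truth
# classification: majority call with standoff handling, concordance value,
# and rule-based intricacy.

#' Intricacy rule table
#'
#' Thresholds mapping the number of raters agreeing with the majority call
#' to a difficulty ("intricacy") level: `low` for nearly total concordance,
#' `medium` for high concordance, `high` otherwise. The defaults encode an
#' 11-rater panel: low for 10 or 11 agreeing raters, medium for 8 or 9,
#' high for 7 or fewer.
#'
#' With `mode = "fractional"` the thresholds are derived from `n_raters`
#' instead of taken as absolute counts (low: at least `n_raters - 1` agree;
#' medium: at least `round(8/11 * n_raters)` agree), for reuse with panels
#' of a different size.
#'
#' @param n_raters Panel size (default 11).
#' @param low_min_agree Minimum agreeing raters for `low` intricacy
#'   (default 10).
#' @param medium_min_agree Minimum agreeing raters for `medium` intricacy
#'   (default 8).
#' @param mode `"absolute"` (default) uses the thresholds as given;
#'   `"fractional"` rescales them to `n_raters`.
#' @return An object of class `intricacy_rule`.
#' @export
intricacy_rule <- function(n_raters = 11L, low_min_agree = 10L,
                           medium_min_agree = 8L,
                           mode = c("absolute", "fractional")) {
  mode <- match.arg(mode)
  n_raters <- as.integer(n_raters)
  if (mode == "fractional") {
    low_min_agree <- n_raters - 1L
    medium_min_agree <- as.integer(round(8 / 11 * n_raters))
  }
  low_min_agree <- as.integer(low_min_agree)
  medium_min_agree <- as.integer(medium_min_agree)
  if (!(n_raters >= low_min_agree && low_min_agree > medium_min_agree &&
        medium_min_agree >= 1L)) {
    abort_config("require n_raters >= low_min_agree > medium_min_agree >= 1")
  }
  structure(list(n_raters = n_raters, low_min_agree = low_min_agree,
                 medium_min_agree = medium_min_agree, mode = mode),
            class = "intricacy_rule")
}

#' Intricacy level from an agreement count
#'
#' @param agree_count Integer vector: raters agreeing with the majority call.
#' @param rule An [intricacy_rule()].
#' @return Character vector in `c("low", "medium", "high")`.
#' @export
#' @examples
#' intricacy(c(11, 10, 9, 8, 7, 5))
intricacy <- function(agree_count, rule = intricacy_rule()) {
  stopifnot(inherits(rule, "intricacy_rule"))
  agree_count <- as.integer(agree_count)
  if (any(is.na(agree_count)) || any(agree_count < 1L) ||
      any(agree_count > rule$n_raters)) {
    abort_validation("agree_count must be in 1..", rule$n_raters)
  }
  ifelse(agree_count >= rule$low_min_agree, "low",
         ifelse(agree_count >= rule$medium_min_agree, "medium", "high"))
}

#' Majority call for one episode's votes
#'
#' The call is the unique category with the strictly greatest vote count;
#' its concordance value is that count divided by the total number of
#' raters. If two or more categories tie for the maximum, the episode is a
#' standoff and is called `no_assessment` (with the tied maximum count
#' recorded as the agreement count).
#'
#' @param categories Character vector of one vote per rater.
#' @param n_raters Denominator of the concordance value; defaults to the
#'   number of votes.
#' @return List with elements `call`, `concordance`, `agree_count`,
#'   `n_raters`, `standoff`.
#' @export
#' @examples
#' majority_call(rep(c("temporal_correlation", "no_change", "no_assessment"),
#'                   c(7, 3, 1)))
majority_call <- function(categories, n_raters = length(categories)) {
  if (length(categories) == 0) abort_validation("empty vote set")
  check_category(categories, "vote category")
  counts <- table(factor(categories, levels = assessment_categories()))
  mx <- max(counts)
  winners <- names(counts)[counts == mx]
  standoff <- length(winners) > 1L
  list(call = if (standoff) "no_assessment" else winners,
       concordance = as.numeric(mx) / n_raters,
       agree_count = as.integer(mx),
       n_raters = as.integer(n_raters),
       standoff = standoff)
}

#' Classify all episodes of a vote table
#'
#' Applies [majority_call()] and [intricacy()] to each episode of a long
#' vote table, producing the per-episode ground-truth classification.
#'
#' @param votes Data frame with columns `episode_id`, `rater_id`,
#'   `category` (one row per vote; one vote per rater per episode).
#' @param rule An [intricacy_rule()]; its `n_raters` must match the panel
#'   size found in `votes`.
#' @return Data frame with one row per episode: `episode_id`, `call`,
#'   `concordance`, `agree_count`, `n_raters`, `intricacy`, `standoff`.
#' @export
classify_votes <- function(votes, rule = intricacy_rule()) {
  stopifnot(is.data.frame(votes),
            all(c("episode_id", "rater_id", "category") %in% names(votes)))
  if (nrow(votes) == 0) {
    return(data.frame(episode_id = character(0), call = character(0),
                      concordance = numeric(0), agree_count = integer(0),
                      n_raters = integer(0), intricacy = character(0),
                      standoff = logical(0), stringsAsFactors = FALSE))
  }
  check_category(votes$category, "vote category")
  if (anyDuplicated(paste(votes$episode_id, votes$rater_id, sep = "\r"))) {
    abort_validation("more than one vote from the same rater for the same episode")
  }
  by_ep <- split(votes$category, votes$episode_id)
  rows <- lapply(names(by_ep), function(id) {
    mc <- majority_call(by_ep[[id]])
    data.frame(episode_id = id, call = mc$call, concordance = mc$concordance,
               agree_count = mc$agree_count, n_raters = mc$n_raters,
               intricacy = intricacy(mc$agree_count, rule),
               standoff = mc$standoff, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$episode_id), , drop = FALSE]
}
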