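# The corpus container (episodes + classifications + optional raw votes)
# and the external assessment set compared against it.

#' Construct a ground-truth corpus
#'
#' Bundles episodes with their per-episode classifications (majority call,
#' concordance value, intricacy) and, optionally, the raw rater votes the
#' classifications were aggregated from. Episode and classification ids must
#' match one-to-one.
#'
#' @param episodes List of [episode()] objects.
#' @param classifications Data frame as returned by [classify_votes()]:
#'   columns `episode_id`, `call`, `concordance`, `agree_count`, `n_raters`,
#'   `intricacy`, `standoff`.
#' @param votes Optional data frame of raw votes (`episode_id`, `rater_id`,
#'   `category`).
#' @return An object of class `corpus`.
#' @export
corpus <- function(episodes, classifications, votes = NULL) {
  stopifnot(is.list(episodes))
  if (!all(vapply(episodes, inherits, logical(1), "episode"))) {
    abort_validation("episodes must be a list of episode objects")
  }
  ep_ids <- vapply(episodes, function(e) e$episode_id, character(1))
  if (anyDuplicated(ep_ids)) abort_validation("duplicate episode ids in corpus")
  req <- c("episode_id", "call", "concordance", "agree_count", "n_raters",
           "intricacy", "standoff")
  if (!is.data.frame(classifications) || !all(req %in% names(classifications))) {
    abort_validation("classifications must contain columns: ",
                     paste(req, collapse = ", "))
  }
  if (!setequal(ep_ids, classifications$episode_id) ||
      length(ep_ids) != nrow(classifications)) {
    abort_validation("episode ids and classification ids must match one-to-one")
  }
  check_category(classifications$call, "classification call")
  bad_conc <- which(abs(classifications$concordance -
                          classifications$agree_count / classifications$n_raters) > 1e-9)
  if (length(bad_conc) > 0) {
    abort_validation("classification concordance must equal agree_count/n_raters (episode ",
                     classifications$episode_id[bad_conc[1]], ")")
  }
  bad_stand <- which(classifications$standoff &
                       classifications$call != "no_assessment")
  if (length(bad_stand) > 0) {
    abort_validation("standoff episodes must be called no_assessment (episode ",
                     classifications$episode_id[bad_stand[1]], ")")
  }
  if (!is.null(votes)) {
    stopifnot(is.data.frame(votes),
              all(c("episode_id", "rater_id", "category") %in% names(votes)))
    check_category(votes$category, "vote category")
  }
  # canonical order: by episode id
  ord <- order(ep_ids)
  episodes <- episodes[ord]
  classifications <- classifications[match(ep_ids[ord], classifications$episode_id), ,
                                     drop = FALSE]
  rownames(classifications) <- NULL
  structure(list(episodes = episodes, classifications = classifications,
                 votes = votes),
            class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus: %d episode(s)>\n", length(x$episodes)))
  if (length(x$episodes) > 0) {
    tab <- table(factor(x$classifications$call, levels = assessment_categories()))
    cat("  calls:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    itab <- table(factor(x$classifications$intricacy,
                         levels = c("low", "medium", "high")))
    cat("  intricacy:", paste(sprintf("%s=%d", names(itab), itab), collapse = ", "), "\n")
  }
  if (!is.null(x$votes)) {
    cat(sprintf("  raw votes: %d from %d rater(s)\n", nrow(x$votes),
                length(unique(x$votes$rater_id))))
  }
  invisible(x)
}

#' Construct an external assessment set
#'
#' One assessor's (human or algorithmic) category per episode, to be
#' compared against a corpus' ground-truth classification with
#' [concordance_score()].
#'
#' @param assessor_id Identifier of the external assessor.
#' @param episode_id Episode identifiers (unique).
#' @param category Assigned categories, one of
#'   `r paste(assessment_categories(), collapse = ", ")`.
#' @return An object of class `assessment_set`: list with `assessor_id` and
#'   `entries` (data frame `episode_id`, `category`).
#' @export
assessment_set <- function(assessor_id, episode_id, category) {
  if (length(episode_id) != length(category)) {
    abort_validation("episode_id and category must have equal length")
  }
  episode_id <- as.character(episode_id)
  if (anyDuplicated(episode_id)) {
    abort_validation("duplicate episode id in assessment set: ",
                     episode_id[duplicated(episode_id)][1])
  }
  check_category(category, "assessment category")
  entries <- data.frame(episode_id = episode_id,
                        category = as.character(category),
                        stringsAsFactors = FALSE)
  entries <- entries[order(entries$episode_id), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(assessor_id = as.character(assessor_id), entries = entries),
            class = "assessment_set")
}

#' @export
print.assessment_set <- function(x, ...) {
  cat(sprintf("<assessment_set %s: %d entries>\n", x$assessor_id, nrow(x$entries)))
  invisible(x)
}
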