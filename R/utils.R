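# Internal helpers shared across modules.

#' Assessment categories
#'
#' The three nominal categories used throughout: a lab value change with a
#' reasonable temporal relationship to the administration, no noteworthy
#' change, or no assessment possible. These machine tokens are the category
#' strings used in all files and data frames.
#'
#' @return Character vector of the three category tokens, in canonical order.
#' @export
#' @examples
#' assessment_categories()
assessment_categories <- function() {
  c("temporal_correlation", "no_change", "no_assessment")
}

abort_validation <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("adrcorpus_validation_error", "error", "condition")))
}

abort_config <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("adrcorpus_config_error", "error", "condition")))
}

abort_io <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("adrcorpus_io_error", "error", "condition")))
}

check_category <- function(category, what = "category") {
  bad <- setdiff(unique(as.character(category)), assessment_categories())
  if (length(bad) > 0) {
    abort_validation("invalid ", what, ": ",
                     paste(bad, collapse = ", "),
                     " (expected one of: ",
                     paste(assessment_categories(), collapse = ", "), ")")
  }
  invisible(category)
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Draw one integer uniformly from an inclusive range given as c(min, max).
sample_range <- function(range, n = 1) {
  range <- as.integer(range)
  if (range[1] > range[2]) abort_config("empty integer range")
  range[1] + sample.int(range[2] - range[1] + 1L, n, replace = TRUE) - 1L
}

check_range <- function(x, name) {
  if (length(x) != 2 || any(is.na(x)) || x[1] > x[2]) {
    abort_config(name, " must be c(min, max) with min <= max")
  }
  invisible(x)
}

check_prob <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort_config(name, " must be a probability in [0, 1]")
  }
  invisible(x)
}

fmt_num <- function(x, digits = 6L) {
  sprintf(paste0("%.", digits, "f"), x)
}
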