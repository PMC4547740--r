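# Evaluation statistics: the difficulty-weighted Concordance Score,
# Krippendorff's alpha for nominal data, Pearson chi-squared on 2x2 tables,
# and corpus summary tables.

#' Difficulty-weighted Concordance Score
#'
#' Compares an external assessment against a corpus' ground-truth
#' classification. Plain percent agreement treats every episode alike, but
#' episodes differ in how hard they are to assess; the Concordance Score
#' weights each episode by the concordance value `c_i` of its ground-truth
#' majority call:
#' \deqn{S_C = \sum_i m_i c_i / \sum_i c_i}
#' with `m_i = 1` for a matched assessment and 0 otherwise, so mismatching
#' an episode even the expert panel found hard costs little, while
#' mismatching a unanimous episode costs the full weight.
#'
#' @param external An [assessment_set()] (or a data frame with `episode_id`
#'   and `category`). Must cover every corpus episode unless
#'   `restrict = TRUE`, in which case scoring is restricted to the covered
#'   episodes.
#' @param x A [corpus()].
#' @param restrict Allow partial coverage (default `FALSE`).
#' @return An object of class `concordance_report`: list with `n_compared`,
#'   `n_matched`, `concordance_score`, `percent_agreement`, and
#'   `by_intricacy` (per-level match rates and scores).
#' @export
concordance_score <- function(external, x, restrict = FALSE) {
  stopifnot(inherits(x, "corpus"))
  entries <- if (inherits(external, "assessment_set")) external$entries else external
  stopifnot(is.data.frame(entries),
            all(c("episode_id", "category") %in% names(entries)))
  check_category(entries$category, "external category")
  cls <- x$classifications
  hit <- match(cls$episode_id, entries$episode_id)
  if (anyNA(hit)) {
    missing_ids <- cls$episode_id[is.na(hit)]
    if (!restrict) {
      abort_validation("external assessment does not cover ",
                       length(missing_ids), " episode(s): ",
                       paste(utils::head(missing_ids, 5), collapse = ", "),
                       if (length(missing_ids) > 5) ", ..." else "")
    }
    cls <- cls[!is.na(hit), , drop = FALSE]
    hit <- hit[!is.na(hit)]
  }
  unknown <- setdiff(entries$episode_id, x$classifications$episode_id)
  if (length(unknown) > 0) {
    abort_validation("external assessment references unknown episode(s): ",
                     paste(utils::head(unknown, 5), collapse = ", "))
  }
  m <- as.numeric(entries$category[hit] == cls$call)
  ci <- cls$concordance
  if (sum(ci) == 0 || nrow(cls) == 0) {
    abort_validation("cannot score: no episodes (or zero total concordance)")
  }
  lvl <- factor(cls$intricacy, levels = c("low", "medium", "high"))
  by_int <- do.call(rbind, lapply(levels(lvl), function(l) {
    sel <- lvl == l
    data.frame(intricacy = l, n = sum(sel), n_matched = sum(m[sel]),
               match_rate = if (any(sel)) mean(m[sel]) else NA_real_,
               concordance_score = if (any(sel)) {
                 sum(m[sel] * ci[sel]) / sum(ci[sel])
               } else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(n_compared = nrow(cls),
                 n_matched = as.integer(sum(m)),
                 concordance_score = sum(m * ci) / sum(ci),
                 percent_agreement = mean(m),
                 by_intricacy = by_int),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Concordance Score: %.4f (%d/%d matched, raw agreement %.4f)\n",
              x$concordance_score, x$n_matched, x$n_compared,
              x$percent_agreement))
  print(x$by_intricacy, row.names = FALSE)
  invisible(x)
}

#' Krippendorff's alpha for nominal data
#'
#' Chance-corrected inter-rater agreement for any number of raters, with
#' missing votes permitted, computed from the coincidence-matrix
#' formulation with the nominal difference function:
#' `alpha = 1 - D_o / D_e`, where `D_o` is the observed and `D_e` the
#' expected disagreement. Episodes with fewer than two votes are dropped
#' (they are not pairable). When every pairable vote falls in a single
#' category the expected disagreement is zero and alpha is undefined; this
#' raises an error rather than returning a number.
#'
#' @param votes Long data frame of votes: `episode_id`, `rater_id`,
#'   `category`. Raters may skip episodes.
#' @return Alpha (length-1 numeric); 1 on perfect agreement.
#' @export
krippendorff_alpha <- function(votes) {
  stopifnot(is.data.frame(votes),
            all(c("episode_id", "rater_id", "category") %in% names(votes)))
  check_category(votes$category, "vote category")
  if (length(unique(votes$episode_id)) < 2) {
    abort_validation("need votes on at least two episodes")
  }
  if (length(unique(votes$rater_id)) < 2) {
    abort_validation("need votes from at least two raters")
  }
  # unit x category vote counts, units with >= 2 votes only
  counts <- table(votes$episode_id, factor(votes$category,
                                           levels = assessment_categories()))
  counts <- counts[rowSums(counts) >= 2, , drop = FALSE]
  if (nrow(counts) == 0) abort_validation("no episode has two or more votes")
  m_u <- rowSums(counts)
  # coincidence matrix: o_ck = sum_u n_uc (n_uk - delta_ck) / (m_u - 1)
  o <- crossprod(counts / sqrt(m_u - 1)) -
    diag(colSums(counts / (m_u - 1)), nrow = ncol(counts))
  n_c <- rowSums(o)
  n_tot <- sum(o)
  d_obs <- n_tot - sum(diag(o))
  d_exp <- (sum(n_c)^2 - sum(n_c^2)) / (n_tot - 1)
  if (d_exp <= 0) {
    abort_validation("alpha is undefined: expected disagreement is zero ",
                     "(all pairable votes fall in one category)")
  }
  1 - d_obs / d_exp
}

#' Pearson chi-squared test on a 2x2 contingency table
#'
#' The uncorrected (no continuity correction) closed-form statistic
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on 1 degree of freedom.
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @return List with `statistic`, `df` (always 1), `p_value`, and `n` (total
#'   count).
#' @export
#' @examples
#' pearson_chi2_2x2(matrix(c(63, 11, 44, 127), nrow = 2))
pearson_chi2_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort_validation("table must be 2x2")
  if (any(table < 0) || anyNA(table)) {
    abort_validation("table cells must be non-negative counts")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort_validation("table has a zero margin")
  }
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  n <- sum(table)
  stat <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       n = n)
}

#' Summarize a corpus
#'
#' Tabulates the corpus the way its construction is usually reported:
#' majority-call counts and percentages overall and within each intricacy
#' level, optional per-parameter rows (synthetic corpora carry a parameter
#' tag), and episode-length statistics. Administration length is counted
#' inclusively (a run covering relative days 0..9 is 10 days long). The
#' overall episode length is reported under two definitions, since either is
#' defensible: `fixed_flank` adds the two flank windows to the
#' administration length, `observed_span` measures first to last observed
#' lab day.
#'
#' @param x A [corpus()].
#' @param flank_window_days Flank width used for the fixed-flank overall
#'   length (default 7).
#' @return An object of class `corpus_summary`: list with `n`, `calls`,
#'   `by_intricacy`, `per_parameter` (or `NULL`), and `episode_length`
#'   (mean/sd of the administration length and of both overall-length
#'   definitions).
#' @export
summarize_corpus <- function(x, flank_window_days = 7L) {
  stopifnot(inherits(x, "corpus"))
  cls <- x$classifications
  n <- nrow(cls)
  cats <- assessment_categories()
  call_f <- factor(cls$call, levels = cats)
  int_f <- factor(cls$intricacy, levels = c("low", "medium", "high"))
  calls <- data.frame(call = cats, count = as.integer(table(call_f)),
                      stringsAsFactors = FALSE)
  calls$percent <- if (n > 0) 100 * calls$count / n else NA_real_
  tab <- table(int_f, call_f)
  by_int <- do.call(rbind, lapply(levels(int_f), function(l) {
    row_n <- sum(tab[l, ])
    data.frame(intricacy = l, call = cats, count = as.integer(tab[l, ]),
               percent_total = if (n > 0) 100 * as.integer(tab[l, ]) / n else NA_real_,
               percent_within = if (row_n > 0) {
                 100 * as.integer(tab[l, ]) / row_n
               } else NA_real_,
               stringsAsFactors = FALSE)
  }))
  per_param <- NULL
  tags <- vapply(x$episodes, function(e) e$parameter_tag, character(1))
  if (n > 0 && !all(is.na(tags))) {
    ptab <- table(factor(tags), call_f)
    per_param <- data.frame(parameter = rep(rownames(ptab), ncol(ptab)),
                            call = rep(colnames(ptab), each = nrow(ptab)),
                            count = as.integer(ptab),
                            stringsAsFactors = FALSE)
  }
  admin_len <- vapply(x$episodes, function(e) max(e$administration_days) + 1L,
                      integer(1))
  span_len <- vapply(x$episodes, function(e) {
    as.integer(diff(range(e$points$relative_day)) + 1L)
  }, integer(1))
  msd <- function(v) {
    if (length(v) == 0) c(mean = NA_real_, sd = NA_real_) else {
      c(mean = mean(v), sd = stats::sd(v))
    }
  }
  structure(list(
    n = n, calls = calls, by_intricacy = by_int, per_parameter = per_param,
    episode_length = list(
      administration = msd(admin_len),
      overall_fixed_flank = msd(admin_len + 2L * as.integer(flank_window_days)),
      overall_observed_span = msd(span_len))),
    class = "corpus_summary")
}

#' @export
print.corpus_summary <- function(x, ...) {
  cat(sprintf("Corpus of %d episode(s)\n\nMajority calls:\n", x$n))
  print(transform(x$calls, percent = round(percent, 2)), row.names = FALSE)
  cat("\nCalls by intricacy:\n")
  print(transform(x$by_intricacy,
                  percent_total = round(percent_total, 2),
                  percent_within = round(percent_within, 2)),
        row.names = FALSE)
  el <- x$episode_length
  cat(sprintf("\nEpisode length (days): administration %.2f +/- %.2f; overall %.2f +/- %.2f (fixed flanks) / %.2f +/- %.2f (observed span)\n",
              el$administration["mean"], el$administration["sd"],
              el$overall_fixed_flank["mean"], el$overall_fixed_flank["sd"],
              el$overall_observed_span["mean"], el$overall_observed_span["sd"]))
  invisible(x)
}
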