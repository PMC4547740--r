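# Programmatic fixtures: small, always-valid episodes and corpora.

# A structurally valid episode: administration on relative days 0..(len-1),
# daily observations across both flanks and the run.
make_episode <- function(id = "e1", len = 10L, truth = NA,
                         parameter = NA_character_, values = NULL) {
  days <- c(-7:-1, 0:(len - 1L), len:(len + 6L))
  if (is.null(values)) values <- round(seq(0.1, 1.5, length.out = length(days)), 6)
  episode(id, administration_days = 0:(len - 1L),
          points = data.frame(relative_day = days, value = values),
          truth_label = truth, parameter_tag = parameter)
}

# Vote vector realizing a composition c(n_tc, n_nc, n_na).
make_votes <- function(composition) {
  rep(assessment_categories(), composition)
}

# A corpus of n episodes with unanimous panels voting the given calls.
make_corpus <- function(n = 4L, calls = NULL, n_raters = 11L, with_votes = TRUE) {
  if (is.null(calls)) {
    calls <- rep_len(c("no_change", "temporal_correlation"), n)
  }
  ids <- sprintf("ep%03d", seq_len(n))
  eps <- lapply(seq_len(n), function(i) make_episode(ids[i], len = 5L + (i %% 5L)))
  votes <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(episode_id = ids[i], rater_id = sprintf("r%02d", seq_len(n_raters)),
               category = calls[i], stringsAsFactors = FALSE)
  }))
  corpus(eps, classify_votes(votes, intricacy_rule(n_raters = n_raters)),
         votes = if (with_votes) votes else NULL)
}

# Two-episode corpus with concordance values 1.0 and 0.5 (a two-rater
# standoff), for closed-form Concordance Score arithmetic.
two_episode_corpus <- function() {
  eps <- list(make_episode("e1"), make_episode("e2"))
  cls <- data.frame(
    episode_id = c("e1", "e2"),
    call = c("temporal_correlation", "no_assessment"),
    concordance = c(1.0, 0.5),
    agree_count = c(2L, 1L), n_raters = c(2L, 2L),
    intricacy = c("low", "high"),
    standoff = c(FALSE, TRUE), stringsAsFactors = FALSE)
  corpus(eps, cls)
}

# A corpus with varied panel compositions (and hence varied concordance
# values); uses the caller's RNG stream.
make_corpus_mixed <- function(n = 40L, n_raters = 11L) {
  ids <- sprintf("mx%03d", seq_len(n))
  eps <- lapply(seq_len(n), function(i) make_episode(ids[i], len = 5L + (i %% 7L)))
  votes <- do.call(rbind, lapply(seq_len(n), function(i) {
    comp <- as.integer(rmultinom(1, n_raters, prob = c(0.5, 0.35, 0.15)))
    data.frame(episode_id = ids[i], rater_id = sprintf("r%02d", seq_len(n_raters)),
               category = sample(rep(assessment_categories(), comp)),
               stringsAsFactors = FALSE)
  }))
  corpus(eps, classify_votes(votes, intricacy_rule(n_raters = n_raters)),
         votes = votes)
}

# Random vote table: n_raters votes on n_ep episodes, category probabilities
# prob, optionally with missing votes.
random_votes <- function(n_ep, n_raters = 11L, prob = c(0.4, 0.4, 0.2),
                         p_missing = 0) {
  grid <- expand.grid(episode_id = sprintf("ep%03d", seq_len(n_ep)),
                      rater_id = sprintf("r%02d", seq_len(n_raters)),
                      stringsAsFactors = FALSE)
  grid$category <- sample(assessment_categories(), nrow(grid), replace = TRUE,
                          prob = prob)
  if (p_missing > 0) grid <- grid[runif(nrow(grid)) >= p_missing, , drop = FALSE]
  grid
}
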