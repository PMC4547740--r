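# Brute-force reference implementations, kept deliberately independent of
# the package code paths they check: plain loops, no shared helpers.

# Greedy merge of sorted administration days into runs: start a new run
# whenever more than max_gap administration-free days separate two
# consecutive administration days.
oracle_runs <- function(days, max_gap = 1L) {
  days <- sort(unique(days))
  runs <- list()
  cur <- days[1]
  for (d in days[-1]) {
    if (d - cur[length(cur)] - 1L <= max_gap) {
      cur <- c(cur, d)
    } else {
      runs[[length(runs) + 1L]] <- cur
      cur <- d
    }
  }
  runs[[length(runs) + 1L]] <- cur
  runs
}

# Scan the raw day list: is the run [first, last] free of administrations in
# the iso-day margins on both sides?
oracle_isolated <- function(first, last, all_days, iso = 14L) {
  ok <- TRUE
  for (d in all_days) {
    if (d >= first - iso && d < first) ok <- FALSE
    if (d > last && d <= last + iso) ok <- FALSE
  }
  ok
}

# Window counter for the three phases; returns "accept" or the first
# failing phase.
oracle_phase_decision <- function(obs_days, first, last, flank = 7L, min_obs = 5L) {
  n_before <- 0L; n_during <- 0L; n_after <- 0L
  for (d in obs_days) {
    if (d >= first - flank && d <= first - 1L) n_before <- n_before + 1L
    if (d >= first && d <= last) n_during <- n_during + 1L
    if (d >= last + 1L && d <= last + flank) n_after <- n_after + 1L
  }
  if (n_before < min_obs) return("before")
  if (n_during < min_obs) return("during")
  if (n_after < min_obs) return("after")
  "accept"
}

# Direct pairwise-disagreement estimator of nominal Krippendorff's alpha:
# observed disagreement from all within-unit vote pairs (each unit's pairs
# weighted by 1/(m_u - 1)), expected disagreement from all cross pairs of
# pairable votes.
oracle_alpha <- function(votes) {
  units <- split(as.character(votes$category), votes$episode_id)
  units <- units[lengths(units) >= 2]
  vals <- unlist(units, use.names = FALSE)
  n <- length(vals)
  d_obs <- 0
  for (u in units) {
    m <- length(u)
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (i != j && u[i] != u[j]) d_obs <- d_obs + 1 / (m - 1)
      }
    }
  }
  d_obs <- d_obs / n
  d_exp <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && vals[i] != vals[j]) d_exp <- d_exp + 1
    }
  }
  d_exp <- d_exp / (n * (n - 1))
  1 - d_obs / d_exp
}

# Straight-summation Concordance Score.
oracle_concordance_score <- function(matched, concordance) {
  num <- 0; den <- 0
  for (i in seq_along(matched)) {
    num <- num + matched[i] * concordance[i]
    den <- den + concordance[i]
  }
  num / den
}
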