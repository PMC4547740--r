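# Synthetic EHR generator and simulated rater panel. Generates raw event
# streams with the statistical structure the extraction pipeline assumes
# (solitary administration runs, dense-but-gappy lab sampling, drug-response
# effects of configurable amplitude and lag) plus an in-silico rater panel
# with difficulty-dependent reliability, so the full workflow is testable
# without patient data.

#' Default synthetic lab parameter panel
#'
#' Three common clinical-chemistry style parameters with population
#' reference bounds (lab units) and a between-patient jitter fraction
#' applied to each patient's individual interval.
#'
#' @return Data frame with columns `parameter_id`, `lower`, `upper`,
#'   `jitter`.
#' @export
default_parameters <- function() {
  data.frame(parameter_id = c("alp", "ast", "ldh"),
             lower = c(30, 10, 120),
             upper = c(120, 50, 250),
             jitter = 0.1,
             stringsAsFactors = FALSE)
}

#' Synthetic cohort configuration
#'
#' Study conditions for [generate_cohort()]. Defaults describe the corpus
#' construction scenario the package is designed around: administration
#' episodes of 5-14 days separated by at least 15 administration-free days
#' (guaranteeing the 14-day isolation rule), lab values observed on 90% of
#' days, and a drug response planted in one third of the (episode, lab
#' parameter) curves with an amplitude of 1-2.5 reference-interval widths.
#'
#' @param n_patients Number of patients (default 60).
#' @param span_days Length of each patient's record, days (default 365).
#' @param parameters Lab parameter panel, see [default_parameters()].
#' @param admin_episode_length Inclusive range of administration run lengths,
#'   days (default `c(5, 14)`).
#' @param admin_gap_rate Probability that a run contains one internal
#'   administration-free day (default 0.15).
#' @param inter_episode_gap Inclusive range of administration-free days
#'   between consecutive runs (default `c(15, 40)`; keep the minimum at 15 or
#'   more to guarantee isolation under the default 14-day rule).
#' @param p_obs Per-day probability that a lab parameter is observed
#'   (default 0.9).
#' @param p_effect Probability that an (episode, parameter) curve carries a
#'   drug response (default 0.33).
#' @param effect_amplitude Range of planted effect amplitudes, in units of
#'   the reference-interval width (default `c(1, 2.5)`).
#' @param effect_lag_days Inclusive range of onset lags after day 0, days
#'   (default `c(0, 2)`).
#' @param baseline_ar First-order autocorrelation of the baseline lab
#'   dynamics (default 0.7).
#' @param noise_sd_frac Innovation standard deviation as a fraction of the
#'   reference-interval width (default 0.15).
#' @param effect_ramp_days Days over which a planted effect ramps to full
#'   amplitude (default 2).
#' @param effect_halflife_days Half-life of the exponential decay after the
#'   last administration day (default 3).
#' @param seed Integer seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 60L, span_days = 365L,
                             parameters = default_parameters(),
                             admin_episode_length = c(5L, 14L),
                             admin_gap_rate = 0.15,
                             inter_episode_gap = c(15L, 40L),
                             p_obs = 0.9, p_effect = 0.33,
                             effect_amplitude = c(1.0, 2.5),
                             effect_lag_days = c(0L, 2L),
                             baseline_ar = 0.7, noise_sd_frac = 0.15,
                             effect_ramp_days = 2L,
                             effect_halflife_days = 3,
                             seed = 1L) {
  check_prob(admin_gap_rate, "admin_gap_rate")
  check_prob(p_obs, "p_obs")
  check_prob(p_effect, "p_effect")
  check_range(admin_episode_length, "admin_episode_length")
  check_range(inter_episode_gap, "inter_episode_gap")
  check_range(effect_lag_days, "effect_lag_days")
  if (length(effect_amplitude) != 2 || effect_amplitude[1] > effect_amplitude[2] ||
      effect_amplitude[1] < 0) {
    abort_config("effect_amplitude must be c(min, max) with 0 <= min <= max")
  }
  stopifnot(is.data.frame(parameters),
            all(c("parameter_id", "lower", "upper", "jitter") %in% names(parameters)))
  if (any(parameters$upper <= parameters$lower)) {
    abort_config("parameter upper bounds must exceed lower bounds")
  }
  cfg <- list(n_patients = as.integer(n_patients),
              span_days = as.integer(span_days),
              parameters = parameters,
              admin_episode_length = as.integer(admin_episode_length),
              admin_gap_rate = admin_gap_rate,
              inter_episode_gap = as.integer(inter_episode_gap),
              p_obs = p_obs, p_effect = p_effect,
              effect_amplitude = as.numeric(effect_amplitude),
              effect_lag_days = as.integer(effect_lag_days),
              baseline_ar = baseline_ar, noise_sd_frac = noise_sd_frac,
              effect_ramp_days = as.integer(effect_ramp_days),
              effect_halflife_days = as.numeric(effect_halflife_days),
              seed = as.integer(seed))
  if (cfg$span_days < 2L * 14L + cfg$admin_episode_length[2]) {
    abort_config("span_days too short: need at least 2*14 + the maximum ",
                 "episode length (", 2L * 14L + cfg$admin_episode_length[2], ")")
  }
  structure(cfg, class = "generator_config")
}

# Planted drug-response level on calendar day d for a run [first, last]:
# 0 before onset, linear ramp over ramp_days to 1, plateau until the last
# administration day, then exponential decay with the given half-life.
effect_level <- function(days, first, last, lag, ramp_days, halflife) {
  onset <- first + lag
  lvl <- pmin(1, pmax(0, (days - onset + 1) / max(1L, ramp_days)))
  peak <- min(1, max(0, (last - onset + 1) / max(1L, ramp_days)))
  post <- days > last
  lvl[post] <- peak * 2^(-(days[post] - last) / halflife)
  lvl
}

#' Generate a synthetic EHR cohort
#'
#' Simulates per-patient drug administration runs and lab observation
#' streams. Administration runs have the configured length, may contain one
#' internal administration-free day, and are separated by the configured
#' administration-free gaps. Each patient/parameter lab series wanders
#' around a baseline drawn inside the patient's jittered reference interval
#' with first-order autoregressive noise; where a drug response is planted,
#' the series is shifted by `amplitude x interval width` (random sign)
#' starting `lag` days after day 0, with a short onset ramp and an
#' exponential decay after the last administration day. Fully reproducible
#' under the configured seed.
#'
#' @param config A [generator_config()].
#' @return List with `administrations`, `observations`, `intervals` (event
#'   streams as from [administration_events()] etc.) and `truth`, a data
#'   frame keyed by `episode_id` (`"<patient>:<parameter>:<first_day>"`)
#'   with the planted `effect` flag, `amplitude` (0 when no effect), `sign`,
#'   and `lag` of every (run, parameter) curve.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    pars <- config$parameters
    n_par <- nrow(pars)
    adm_rows <- list()
    obs_rows <- list()
    int_rows <- list()
    truth_rows <- list()
    for (p in seq_len(config$n_patients)) {
      pid <- sprintf("pt%03d", p)
      # patient-specific reference intervals: jitter centre and width
      width0 <- pars$upper - pars$lower
      centre <- (pars$upper + pars$lower) / 2 *
        (1 + stats::runif(n_par, -pars$jitter, pars$jitter))
      width <- width0 * (1 + stats::runif(n_par, -pars$jitter, pars$jitter))
      lo <- centre - width / 2
      up <- centre + width / 2
      int_rows[[p]] <- data.frame(patient_id = pid,
                                  parameter_id = pars$parameter_id,
                                  lower = lo, upper = up,
                                  stringsAsFactors = FALSE)
      # plant administration runs with guaranteed isolation margins
      runs <- list()
      t0 <- config$inter_episode_gap[1] + sample_range(c(1L, 10L))
      repeat {
        len <- sample_range(config$admin_episode_length)
        last <- t0 + len - 1L
        if (last > config$span_days - config$inter_episode_gap[1]) break
        days <- t0:last
        if (len >= 4L && stats::runif(1) < config$admin_gap_rate) {
          days <- setdiff(days, sample(days[2:(len - 1L)], 1L))
        }
        runs[[length(runs) + 1L]] <- list(first = t0, last = last, days = days)
        t0 <- last + 1L + sample_range(config$inter_episode_gap)
      }
      if (length(runs) > 0) {
        adm_rows[[p]] <- data.frame(
          patient_id = pid,
          day = unlist(lapply(runs, `[[`, "days")),
          stringsAsFactors = FALSE)
      }
      # lab series per parameter, with planted responses per (run, parameter)
      all_days <- seq_len(config$span_days)
      for (k in seq_len(n_par)) {
        w <- up[k] - lo[k]
        baseline <- stats::runif(1, lo[k] + 0.2 * w, up[k] - 0.2 * w)
        noise <- as.numeric(stats::filter(
          stats::rnorm(config$span_days, 0, config$noise_sd_frac * w),
          config$baseline_ar, method = "recursive"))
        series <- baseline + noise
        for (r in runs) {
          has_effect <- stats::runif(1) < config$p_effect
          amp <- if (has_effect) {
            stats::runif(1, config$effect_amplitude[1], config$effect_amplitude[2])
          } else 0
          sgn <- sample(c(-1, 1), 1)
          lag <- sample_range(config$effect_lag_days)
          if (has_effect) {
            series <- series + sgn * amp * w *
              effect_level(all_days, r$first, r$last, lag,
                           config$effect_ramp_days, config$effect_halflife_days)
          }
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            episode_id = paste(pid, pars$parameter_id[k], r$first, sep = ":"),
            patient_id = pid, parameter_id = pars$parameter_id[k],
            first_day = r$first, last_day = r$last,
            effect = has_effect, amplitude = amp, sign = sgn, lag = lag,
            stringsAsFactors = FALSE)
        }
        seen <- stats::runif(config$span_days) < config$p_obs
        if (any(seen)) {
          obs_rows[[length(obs_rows) + 1L]] <- data.frame(
            patient_id = pid, parameter_id = pars$parameter_id[k],
            day = all_days[seen], value = series[seen],
            stringsAsFactors = FALSE)
        }
      }
    }
    bind <- function(rows, proto) {
      if (length(rows) == 0) proto else {
        do.call(rbind, c(rows, list(make.row.names = FALSE)))
      }
    }
    adm <- bind(adm_rows, data.frame(patient_id = character(0), day = integer(0)))
    obs <- bind(obs_rows, data.frame(patient_id = character(0),
                                     parameter_id = character(0),
                                     day = integer(0), value = numeric(0)))
    ref <- bind(int_rows, data.frame(patient_id = character(0),
                                     parameter_id = character(0),
                                     lower = numeric(0), upper = numeric(0)))
    truth <- bind(truth_rows,
                  data.frame(episode_id = character(0), patient_id = character(0),
                             parameter_id = character(0), first_day = integer(0),
                             last_day = integer(0), effect = logical(0),
                             amplitude = numeric(0), sign = numeric(0),
                             lag = integer(0)))
    list(administrations = administration_events(adm$patient_id, adm$day),
         observations = lab_observations(obs$patient_id, obs$parameter_id,
                                         obs$day, obs$value),
         intervals = if (nrow(ref) > 0) {
           reference_intervals(ref$patient_id, ref$parameter_id,
                               ref$lower, ref$upper)
         } else ref,
         truth = truth)
  })
}

#' Rater panel profiles
#'
#' @param n_raters Panel size (default 11).
#' @param reliability Per-rater probability scale of voting the correct
#'   substantive category on an unambiguous curve (recycled; default 0.9).
#' @param abstain_propensity Per-rater tendency to vote "no assessment"
#'   when uncertain (recycled; default 0.1).
#' @return Data frame with columns `rater_id`, `reliability`,
#'   `abstain_propensity`.
#' @export
rater_profiles <- function(n_raters = 11L, reliability = 0.9,
                           abstain_propensity = 0.1) {
  n_raters <- as.integer(n_raters)
  reliability <- rep_len(reliability, n_raters)
  abstain_propensity <- rep_len(abstain_propensity, n_raters)
  if (any(reliability < 0 | reliability > 1) ||
      any(abstain_propensity < 0 | abstain_propensity > 1)) {
    abort_config("reliability and abstain_propensity must lie in [0, 1]")
  }
  data.frame(rater_id = sprintf("r%02d", seq_len(n_raters)),
             reliability = reliability,
             abstain_propensity = abstain_propensity,
             stringsAsFactors = FALSE)
}

#' Simulate a rater panel voting on episodes
#'
#' Each rater votes once per episode on the three nominal categories. The
#' correct substantive category is "temporal correlation" where an effect
#' was planted and "no change" otherwise. A logistic difficulty term,
#' decreasing in the planted amplitude and scaled by the rater's
#' unreliability, governs errors:
#' `penalty = min(1, scale * (1 - reliability) * plogis(steep * (mid - evidence)))`,
#' where `evidence` is the planted amplitude for effect curves and
#' `null_evidence` for no-effect curves. A rater votes the correct category
#' with probability `reliability * (1 - penalty)`, abstains ("no
#' assessment") with probability `abstain_propensity * (1 - p_correct)`, and
#' otherwise votes the wrong substantive category. Perfectly reliable raters
#' (reliability 1) therefore always vote correctly, and raters with
#' reliability 0 and abstain propensity 1 always abstain. Small planted
#' amplitudes yield split panels, generating the intricacy spectrum.
#'
#' @param episodes List of [episode()] objects.
#' @param truth Truth table from [generate_cohort()] (columns `episode_id`,
#'   `effect`, `amplitude`); every episode must be covered.
#' @param profiles Rater panel from [rater_profiles()].
#' @param seed Integer seed.
#' @param null_evidence Evidence level assigned to no-effect curves, in
#'   interval widths (default 1.5).
#' @param penalty_mid,penalty_steep,penalty_scale Shape of the difficulty
#'   term (defaults 0.4, 3, 8).
#' @return Long data frame of votes: `episode_id`, `rater_id`, `category`.
#' @export
simulate_raters <- function(episodes, truth, profiles = rater_profiles(),
                            seed = 1L, null_evidence = 1.5,
                            penalty_mid = 0.4, penalty_steep = 3,
                            penalty_scale = 8) {
  stopifnot(is.list(episodes), is.data.frame(profiles), nrow(profiles) >= 1)
  ids <- vapply(episodes, function(e) e$episode_id, character(1))
  hit <- match(ids, truth$episode_id)
  if (anyNA(hit)) {
    abort_validation("no truth entry for episode(s): ",
                     paste(utils::head(ids[is.na(hit)], 5), collapse = ", "))
  }
  effect <- truth$effect[hit]
  evidence <- ifelse(effect, truth$amplitude[hit], null_evidence)
  correct <- ifelse(effect, "temporal_correlation", "no_change")
  wrong <- ifelse(effect, "no_change", "temporal_correlation")
  n_ep <- length(episodes)
  n_rat <- nrow(profiles)
  with_seed(seed, {
    difficulty <- stats::plogis(penalty_steep * (penalty_mid - evidence))
    out <- vector("list", n_rat)
    for (r in seq_len(n_rat)) {
      rel <- profiles$reliability[r]
      ab <- profiles$abstain_propensity[r]
      pen <- pmin(1, penalty_scale * (1 - rel) * difficulty)
      p_correct <- rel * (1 - pen)
      p_abstain <- ab * (1 - p_correct)
      u <- stats::runif(n_ep)
      category <- ifelse(u < p_correct, correct,
                         ifelse(u < p_correct + p_abstain, "no_assessment", wrong))
      out[[r]] <- data.frame(episode_id = ids, rater_id = profiles$rater_id[r],
                             category = category, stringsAsFactors = FALSE)
    }
    votes <- do.call(rbind, c(out, list(make.row.names = FALSE)))
    votes <- votes[order(votes$episode_id, votes$rater_id), , drop = FALSE]
    rownames(votes) <- NULL
    votes
  })
}
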