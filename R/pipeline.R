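# Episode mining: partition administration days into runs, keep the solitary
# (isolated) ones, attach and normalize the lab curves, and sample a corpus.

#' Episode extraction configuration
#'
#' Thresholds of the episode mining pipeline. The defaults encode the study
#' design this package reproduces: a solitary episode needs at least 14
#' administration-free days on both sides, tolerates at most one
#' administration-free day internally, and must carry at least five lab
#' observations before, during, and after the administration period, the
#' flanking ones recorded within seven days of its boundaries.
#'
#' @param isolation_days Administration-free days required before and after
#'   a run (default 14).
#' @param max_internal_gap_days Administration-free days tolerated inside a
#'   run (default 1).
#' @param flank_window_days Width of the pre/post observation windows, days
#'   (default 7).
#' @param min_obs_per_phase Minimum lab observations per phase (default 5).
#' @param sample_size Number of episodes sampled into the corpus
#'   (default 400).
#' @param seed Integer seed for corpus sampling.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(isolation_days = 14L, max_internal_gap_days = 1L,
                            flank_window_days = 7L, min_obs_per_phase = 5L,
                            sample_size = 400L, seed = 1L) {
  cfg <- list(isolation_days = as.integer(isolation_days),
              max_internal_gap_days = as.integer(max_internal_gap_days),
              flank_window_days = as.integer(flank_window_days),
              min_obs_per_phase = as.integer(min_obs_per_phase),
              sample_size = as.integer(sample_size),
              seed = as.integer(seed))
  if (any(vapply(cfg, function(x) is.na(x) || x < 0, logical(1)))) {
    abort_config("all pipeline_config values must be non-negative integers")
  }
  if (cfg$isolation_days < cfg$flank_window_days) {
    abort_config("isolation_days must be >= flank_window_days, otherwise the ",
                 "flanking observation windows could overlap a neighbouring run")
  }
  structure(cfg, class = "pipeline_config")
}

#' Partition administration days into runs
#'
#' Splits each patient's administration days into maximal runs of continuous
#' administration, where consecutive administration days may be separated by
#' at most `max_internal_gap_days` administration-free days. Every
#' administration day belongs to exactly one run; the partition is unique.
#'
#' @param administrations Data frame as from [administration_events()].
#' @param max_internal_gap_days Administration-free days tolerated inside a
#'   run (default 1).
#' @return Data frame with one row per run: `patient_id`, `first_day`,
#'   `last_day`, `n_admin_days`, and a list column `admin_days`.
#' @export
find_administration_runs <- function(administrations, max_internal_gap_days = 1L) {
  adm <- administration_events(administrations$patient_id, administrations$day)
  if (nrow(adm) == 0) {
    return(data.frame(patient_id = character(0), first_day = integer(0),
                      last_day = integer(0), n_admin_days = integer(0),
                      admin_days = I(list()), stringsAsFactors = FALSE))
  }
  max_gap <- as.integer(max_internal_gap_days)
  # a new run starts at a patient change or when the day gap leaves more
  # than max_gap administration-free days
  new_patient <- c(TRUE, adm$patient_id[-1] != adm$patient_id[-nrow(adm)])
  day_gap <- c(0L, diff(adm$day))
  run_id <- cumsum(new_patient | day_gap > max_gap + 1L)
  days_by_run <- split(adm$day, run_id)
  patient_by_run <- vapply(split(adm$patient_id, run_id), `[`, character(1), 1)
  out <- data.frame(
    patient_id = unname(patient_by_run),
    first_day = vapply(days_by_run, min, integer(1), USE.NAMES = FALSE),
    last_day = vapply(days_by_run, max, integer(1), USE.NAMES = FALSE),
    n_admin_days = lengths(days_by_run, use.names = FALSE),
    stringsAsFactors = FALSE)
  out$admin_days <- I(unname(days_by_run))
  out
}

#' Keep only isolated (solitary) administration runs
#'
#' A run is solitary when the same patient has no administration in the
#' `isolation_days` days before its first administration day nor in the
#' `isolation_days` days after its last.
#'
#' @param runs Data frame from [find_administration_runs()].
#' @param administrations The full administration event stream the runs were
#'   mined from.
#' @param isolation_days Required administration-free margin, days
#'   (default 14).
#' @return The subset of `runs` that is isolated, same columns.
#' @export
filter_isolated <- function(runs, administrations, isolation_days = 14L) {
  if (nrow(runs) == 0) return(runs)
  iso <- as.integer(isolation_days)
  adm <- administration_events(administrations$patient_id, administrations$day)
  days_by_patient <- split(adm$day, adm$patient_id)
  keep <- vapply(seq_len(nrow(runs)), function(i) {
    d <- days_by_patient[[runs$patient_id[i]]]
    first <- runs$first_day[i]
    last <- runs$last_day[i]
    !any(d >= first - iso & d < first) && !any(d > last & d <= last + iso)
  }, logical(1))
  out <- runs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach and normalize the lab curve of one run
#'
#' Counts one patient/parameter's lab observations in the three phases
#' around an administration run -- before: the `flank_window_days` days
#' preceding the first administration day; during: first to last
#' administration day; after: the `flank_window_days` days following the
#' last. If every phase holds at least `min_obs_per_phase` observations, the
#' observations inside those windows are normalized to the patient's
#' reference interval and re-anchored to relative days (day 0 = first
#' administration day), yielding an [episode()]. Otherwise an
#' `episode_rejection` naming the first failing phase is returned.
#' Observations outside the three windows are discarded, not grounds for
#' rejection.
#'
#' @param run One-row data frame (or list) with `patient_id`, `first_day`,
#'   `last_day`, `admin_days`.
#' @param observations Lab observations of one (patient, parameter), as from
#'   [lab_observations()].
#' @param interval One-row data frame (or list) with `lower` and `upper`
#'   reference bounds.
#' @param config A [pipeline_config()].
#' @param episode_id Identifier for the accepted episode; defaults to
#'   `"<patient>:<parameter>:<first_day>"`.
#' @return An [episode()], or an object of class `episode_rejection` with
#'   elements `phase` (`"before"`, `"during"` or `"after"`) and `counts`.
#' @export
attach_lab_curve <- function(run, observations, interval,
                             config = pipeline_config(),
                             episode_id = NULL) {
  if (interval$upper <= interval$lower) {
    abort_validation("degenerate reference interval: upper must exceed lower")
  }
  first <- as.integer(run$first_day)
  last <- as.integer(run$last_day)
  admin_days <- as.integer(run$admin_days[[1]])
  flank <- config$flank_window_days
  day <- observations$day
  in_before <- day >= first - flank & day <= first - 1L
  in_during <- day >= first & day <= last
  in_after <- day >= last + 1L & day <= last + flank
  counts <- c(before = sum(in_before), during = sum(in_during),
              after = sum(in_after))
  short <- names(counts)[counts < config$min_obs_per_phase]
  if (length(short) > 0) {
    return(structure(list(patient_id = run$patient_id, first_day = first,
                          phase = short[1], counts = counts),
                     class = "episode_rejection"))
  }
  keep <- in_before | in_during | in_after
  if (is.null(episode_id)) {
    param <- if ("parameter_id" %in% names(observations) && sum(keep) > 0) {
      observations$parameter_id[keep][1]
    } else "NA"
    episode_id <- paste(run$patient_id, param, first, sep = ":")
  }
  episode(
    episode_id = episode_id,
    administration_days = admin_days - first,
    points = data.frame(
      relative_day = day[keep] - first,
      value = normalize_value(observations$value[keep], interval$lower,
                              interval$upper)))
}

#' @export
print.episode_rejection <- function(x, ...) {
  cat(sprintf("<rejected run: patient %s, first day %d; too few observations %s (%s)>\n",
              x$patient_id, x$first_day, x$phase,
              paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", ")))
  invisible(x)
}

#' Mine all episodes from raw event streams
#'
#' Runs the full extraction: de-duplicate administrations, partition them
#' into runs, keep the isolated runs, and attach one normalized lab curve
#' per (run, lab parameter) combination for which the patient has a
#' reference interval. Each accepted (run, parameter) pair becomes one
#' episode with id `"<patient>:<parameter>:<first_day>"`.
#'
#' @param administrations,observations,intervals Event streams as from
#'   [administration_events()], [lab_observations()],
#'   [reference_intervals()].
#' @param config A [pipeline_config()].
#' @param truth Optional truth table (from [generate_cohort()]) with columns
#'   `episode_id`, `effect`; matching episodes get their `truth_label` set.
#' @param verbose Log one line per rejected candidate (default `FALSE`).
#' @return List with `episodes` (list of [episode()]), `rejections` (data
#'   frame: `patient_id`, `parameter_id`, `first_day`, `phase`), and
#'   `counts` (funnel: administration events, runs, isolated runs, candidate
#'   curves, accepted episodes).
#' @export
extract_episodes <- function(administrations, observations, intervals,
                             config = pipeline_config(), truth = NULL,
                             verbose = FALSE) {
  adm <- administration_events(administrations$patient_id, administrations$day)
  obs <- lab_observations(observations$patient_id, observations$parameter_id,
                          observations$day, observations$value)
  ref <- reference_intervals(intervals$patient_id, intervals$parameter_id,
                             intervals$lower, intervals$upper)
  runs <- find_administration_runs(adm, config$max_internal_gap_days)
  isolated <- filter_isolated(runs, adm, config$isolation_days)
  obs_split <- split(obs, paste(obs$patient_id, obs$parameter_id, sep = "\r"))
  episodes <- list()
  rej <- list()
  n_candidates <- 0L
  for (i in seq_len(nrow(isolated))) {
    run <- isolated[i, , drop = FALSE]
    params <- ref[ref$patient_id == run$patient_id, , drop = FALSE]
    for (j in seq_len(nrow(params))) {
      key <- paste(run$patient_id, params$parameter_id[j], sep = "\r")
      po <- obs_split[[key]]
      if (is.null(po)) next
      n_candidates <- n_candidates + 1L
      res <- attach_lab_curve(run, po, params[j, ], config,
                              episode_id = paste(run$patient_id,
                                                 params$parameter_id[j],
                                                 run$first_day, sep = ":"))
      if (inherits(res, "episode_rejection")) {
        if (verbose) {
          message(sprintf("reject %s:%s:%d: <%d observations %s",
                          run$patient_id, params$parameter_id[j],
                          run$first_day, config$min_obs_per_phase, res$phase))
        }
        rej[[length(rej) + 1L]] <- data.frame(
          patient_id = run$patient_id, parameter_id = params$parameter_id[j],
          first_day = run$first_day, phase = res$phase,
          stringsAsFactors = FALSE)
      } else {
        res$parameter_tag <- params$parameter_id[j]
        episodes[[length(episodes) + 1L]] <- res
      }
    }
  }
  if (!is.null(truth)) {
    eff <- truth$effect[match(vapply(episodes, function(e) e$episode_id,
                                     character(1)), truth$episode_id)]
    for (i in seq_along(episodes)) episodes[[i]]$truth_label <- eff[i]
  }
  list(episodes = episodes,
       rejections = if (length(rej) > 0) {
         do.call(rbind, c(rej, list(make.row.names = FALSE)))
       } else {
         data.frame(patient_id = character(0), parameter_id = character(0),
                    first_day = integer(0), phase = character(0),
                    stringsAsFactors = FALSE)
       },
       counts = c(administration_events = nrow(adm), runs = nrow(runs),
                  isolated_runs = nrow(isolated), candidate_curves = n_candidates,
                  accepted_episodes = length(episodes)))
}

#' Sample episodes into a corpus
#'
#' Uniform sample without replacement, reproducible under a fixed seed and
#' independent of the input order (episodes are sorted by id before
#' sampling).
#'
#' @param episodes List of [episode()] objects.
#' @param sample_size Number of episodes to keep; must not exceed the
#'   population size.
#' @param seed Integer seed.
#' @return List of `sample_size` episodes, sorted by episode id.
#' @export
sample_corpus <- function(episodes, sample_size, seed) {
  sample_size <- as.integer(sample_size)
  if (sample_size > length(episodes)) {
    abort_config("sample_size (", sample_size, ") exceeds the number of episodes (",
                 length(episodes), ")")
  }
  ids <- vapply(episodes, function(e) e$episode_id, character(1))
  episodes <- episodes[order(ids)]
  idx <- with_seed(seed, sample.int(length(episodes), sample_size))
  episodes[sort(idx)]
}
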