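test_that("run finding merges across at most one administration-free day", {
  adm <- administration_events(rep("p1", 5), c(0, 1, 2, 4, 5))
  runs <- find_administration_runs(adm, max_internal_gap_days = 1L)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$first_day, 0L)
  expect_equal(runs$last_day, 5L)

  adm <- administration_events(rep("p1", 4), c(0, 1, 5, 6))
  runs <- find_administration_runs(adm, max_internal_gap_days = 1L)
  expect_equal(nrow(runs), 2L)
  expect_equal(runs$first_day, c(0L, 5L))
  expect_equal(runs$last_day, c(1L, 6L))

  expect_equal(nrow(find_administration_runs(
    data.frame(patient_id = character(0), day = integer(0)))), 0L)
})

test_that("every administration day belongs to exactly one run", {
  set.seed(7)
  for (i in 1:20) {
    days <- sort(sample(0:59, sample(5:25, 1)))
    adm <- administration_events(rep("p", length(days)), days)
    runs <- find_administration_runs(adm)
    expect_identical(sort(unlist(runs$admin_days)), days)
    expect_identical(runs$first_day, vapply(runs$admin_days, min, integer(1)))
    expect_identical(runs$last_day, vapply(runs$admin_days, max, integer(1)))
  }
})

test_that("isolation filtering keeps exactly the runs with free margins", {
  # two runs 19 free days apart: both kept
  adm <- administration_events(rep("p1", 4), c(14, 15, 35, 36))
  runs <- find_administration_runs(adm)
  expect_equal(nrow(filter_isolated(runs, adm, 14L)), 2L)

  # 9 free days apart: both rejected
  adm <- administration_events(rep("p1", 4), c(14, 15, 25, 26))
  runs <- find_administration_runs(adm)
  expect_equal(nrow(filter_isolated(runs, adm, 14L)), 0L)

  # isolation is per patient: another patient's administrations don't count
  adm <- administration_events(c("p1", "p1", "p2"), c(14, 15, 20))
  runs <- find_administration_runs(adm)
  expect_equal(nrow(filter_isolated(runs, adm, 14L)), 2L)
})

test_that("lab curve attachment applies the three-phase window rules", {
  run <- find_administration_runs(
    administration_events(rep("p1", 10), 100:109))
  cfg <- pipeline_config()
  interval <- list(lower = 30, upper = 120)

  # 7 before, 6 during, 5 after -> accepted
  days <- c(93:99, seq(100, 109, length.out = 6), 110:114)
  obs <- lab_observations(rep("p1", length(days)), "alp", days,
                          seq(40, 150, length.out = length(days)))
  ep <- attach_lab_curve(run, obs, interval, cfg)
  expect_s3_class(ep, "episode")
  expect_length(validate_episode(ep), 0)
  # re-anchoring: day 0 is the first administration day
  expect_identical(min(ep$administration_days), 0L)
  expect_identical(ep$points$relative_day, as.integer(days) - 100L)
  # Eq-1 normalization applied to every point
  expect_equal(ep$points$value, (seq(40, 150, length.out = length(days)) - 30) / 90)

  # only 4 observations before -> rejection naming the phase
  obs4 <- lab_observations(rep("p1", length(days) - 3), "alp", days[-(1:3)],
                           seq(40, 150, length.out = length(days) - 3))
  rej <- attach_lab_curve(run, obs4, interval, cfg)
  expect_s3_class(rej, "episode_rejection")
  expect_identical(rej$phase, "before")

  # observations outside the windows are discarded, not fatal
  far <- lab_observations(rep("p1", length(days) + 2), "alp", c(50, days, 160),
                          c(0, seq(40, 150, length.out = length(days)), 0))
  ep2 <- attach_lab_curve(run, far, interval, cfg)
  expect_s3_class(ep2, "episode")
  expect_identical(nrow(ep2$points), length(days))

  expect_error(attach_lab_curve(run, obs, list(lower = 120, upper = 30), cfg),
               "degenerate")
})

test_that("mining agrees with brute-force oracles on random event streams", {
  set.seed(101)
  for (i in 1:60) {
    days <- sort(sample(0:59, sample(3:30, 1)))
    adm <- administration_events(rep("p", length(days)), days)
    runs <- find_administration_runs(adm)
    oruns <- oracle_runs(days)
    expect_equal(nrow(runs), length(oruns))
    for (k in seq_along(oruns)) {
      expect_identical(runs$admin_days[[k]], oruns[[k]])
    }
    iso <- filter_isolated(runs, adm, 14L)
    okeep <- vapply(oruns, function(r) {
      oracle_isolated(min(r), max(r), days)
    }, logical(1))
    expect_identical(iso$first_day,
                     vapply(oruns[okeep], min, integer(1)))
    # phase decision for a random observation set around the first run
    first <- runs$first_day[1]; last <- runs$last_day[1]
    pool <- (first - 10):(last + 10)
    obs_days <- sort(sample(pool, sample(8:min(25, length(pool)), 1)))
    obs <- lab_observations(rep("p", length(obs_days)), "x", obs_days,
                            rnorm(length(obs_days), 50, 5))
    res <- attach_lab_curve(runs[1, ], obs, list(lower = 30, upper = 120),
                            pipeline_config())
    odec <- oracle_phase_decision(obs_days, first, last)
    if (odec == "accept") {
      expect_s3_class(res, "episode")
    } else {
      expect_s3_class(res, "episode_rejection")
      expect_identical(res$phase, odec)
    }
  }
})

test_that("extracted episodes pass the independent episode validator", {
  cohort <- generate_cohort(generator_config(n_patients = 6L, seed = 5L))
  ext <- extract_episodes(cohort$administrations, cohort$observations,
                          cohort$intervals, pipeline_config(),
                          truth = cohort$truth)
  expect_gt(length(ext$episodes), 0)
  for (ep in ext$episodes) {
    expect_length(validate_episode(ep), 0)
    last <- max(ep$administration_days)
    rd <- ep$points$relative_day
    # phase windows partition the surviving observations
    in_before <- rd >= -7 & rd <= -1
    in_during <- rd >= 0 & rd <= last
    in_after <- rd >= last + 1 & rd <= last + 7
    expect_true(all(in_before + in_during + in_after == 1L))
  }
  # funnel counts are monotone
  expect_true(all(diff(ext$counts[c("runs", "isolated_runs")]) <= 0))
  expect_lte(ext$counts[["accepted_episodes"]], ext$counts[["candidate_curves"]])
  expect_equal(ext$counts[["accepted_episodes"]] + nrow(ext$rejections),
               ext$counts[["candidate_curves"]])
})

test_that("corpus sampling is uniform, seed-reproducible, and order-independent", {
  eps <- lapply(sprintf("e%02d", 1:20), make_episode)
  s1 <- sample_corpus(eps, 8L, seed = 3L)
  s2 <- sample_corpus(rev(eps), 8L, seed = 3L)
  expect_identical(vapply(s1, function(e) e$episode_id, character(1)),
                   vapply(s2, function(e) e$episode_id, character(1)))
  expect_error(sample_corpus(eps, 21L, seed = 1L), "exceeds")
  expect_length(sample_corpus(eps, 20L, seed = 9L), 20L)

  # inclusion frequency ~ sample_size / population over many seeds
  hits <- integer(20)
  n_rep <- 400L
  for (s in seq_len(n_rep)) {
    ids <- vapply(sample_corpus(eps, 8L, seed = s), function(e) e$episode_id,
                  character(1))
    hits[match(ids, sprintf("e%02d", 1:20))] <- hits[match(ids, sprintf("e%02d", 1:20))] + 1L
  }
  p <- 8 / 20
  se <- sqrt(p * (1 - p) / n_rep)
  expect_true(all(abs(hits / n_rep - p) < 5 * se))
})
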