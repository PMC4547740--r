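test_that("Concordance Score weights matches by ground-truth concordance", {
  corp <- make_corpus(6)
  truth_calls <- corp$classifications$call
  perfect <- assessment_set("self", corp$classifications$episode_id, truth_calls)
  expect_equal(concordance_score(perfect, corp)$concordance_score, 1.0)

  # hand-built two-episode case: c = (1.0, 0.5), only the first matches
  corp2 <- two_episode_corpus()
  ext <- assessment_set("a", c("e1", "e2"),
                        c("temporal_correlation", "no_change"))
  rep <- concordance_score(ext, corp2)
  expect_equal(rep$concordance_score, 1.0 / 1.5)
  expect_equal(rep$n_matched, 1L)

  # when all c_i are equal the score reduces to raw percent agreement
  corp3 <- make_corpus(8)  # unanimous panels: c_i = 1 everywhere
  half <- assessment_set("h", corp3$classifications$episode_id,
                         ifelse(seq_len(8) <= 4, corp3$classifications$call,
                                "no_assessment"))
  rep3 <- concordance_score(half, corp3)
  expect_equal(rep3$concordance_score, rep3$percent_agreement)
})

test_that("Concordance Score matches a straight-summation oracle and is order-invariant", {
  set.seed(23)
  corp <- make_corpus_mixed(40)
  cats <- sample(assessment_categories(), 40, replace = TRUE)
  ids <- corp$classifications$episode_id
  ext <- assessment_set("r", ids, cats)
  got <- concordance_score(ext, corp)$concordance_score
  m <- as.numeric(cats[match(corp$classifications$episode_id, ids)] ==
                    corp$classifications$call)
  expect_equal(got, oracle_concordance_score(m, corp$classifications$concordance),
               tolerance = 1e-12)
  # shuffling the external entries changes nothing
  perm <- sample(40)
  ext2 <- assessment_set("r", ids[perm], cats[perm])
  expect_equal(concordance_score(ext2, corp)$concordance_score, got)

  # flipping any single mismatch to a match strictly increases the score
  miss <- which(m == 0)[1]
  cats2 <- cats
  cats2[miss] <- corp$classifications$call[match(ids[miss], corp$classifications$episode_id)]
  expect_gt(concordance_score(assessment_set("r", ids, cats2), corp)$concordance_score,
            got)
})

test_that("Concordance Score enforces coverage unless restricted", {
  corp <- make_corpus(5)
  ids <- corp$classifications$episode_id
  partial <- assessment_set("p", ids[1:3], corp$classifications$call[1:3])
  expect_error(concordance_score(partial, corp), "does not cover 2")
  rep <- concordance_score(partial, corp, restrict = TRUE)
  expect_equal(rep$n_compared, 3L)
  expect_equal(rep$concordance_score, 1.0)
  stranger <- assessment_set("s", c(ids, "nope"), rep("no_change", 6))
  expect_error(concordance_score(stranger, corp), "unknown episode")
})

test_that("Krippendorff's alpha reproduces closed-form cases", {
  # perfect agreement across two categories -> alpha = 1
  votes <- rbind(
    data.frame(episode_id = "u1", rater_id = c("r1", "r2"),
               category = "no_change"),
    data.frame(episode_id = "u2", rater_id = c("r1", "r2"),
               category = "temporal_correlation"))
  expect_equal(krippendorff_alpha(votes), 1.0)

  # units (a,a), (a,b): observed disagreement equals expected -> alpha = 0
  votes0 <- rbind(
    data.frame(episode_id = "u1", rater_id = c("r1", "r2"),
               category = "no_change"),
    data.frame(episode_id = "u2", rater_id = c("r1", "r2"),
               category = c("no_change", "temporal_correlation")))
  expect_equal(krippendorff_alpha(votes0), 0.0)

  # units (a,a), (b,b), (a,b): D_o = 1/3, D_e = 3/5 -> alpha = 4/9
  votes49 <- rbind(
    data.frame(episode_id = "u1", rater_id = c("r1", "r2"),
               category = "no_change"),
    data.frame(episode_id = "u2", rater_id = c("r1", "r2"),
               category = "temporal_correlation"),
    data.frame(episode_id = "u3", rater_id = c("r1", "r2"),
               category = c("no_change", "temporal_correlation")))
  expect_equal(krippendorff_alpha(votes49), 4 / 9)

  # all votes in one category: expected disagreement 0 -> undefined
  uni <- rbind(
    data.frame(episode_id = "u1", rater_id = c("r1", "r2"), category = "no_change"),
    data.frame(episode_id = "u2", rater_id = c("r1", "r2"), category = "no_change"))
  expect_error(krippendorff_alpha(uni), "undefined")
})

test_that("alpha matches the pairwise oracle on random vote tables", {
  set.seed(31)
  for (i in 1:8) {
    votes <- random_votes(n_ep = 25, n_raters = 11,
                          prob = c(0.45, 0.35, 0.2),
                          p_missing = if (i %% 2 == 0) 0.15 else 0)
    expect_equal(krippendorff_alpha(votes), oracle_alpha(votes),
                 tolerance = 1e-9)
  }
})

test_that("alpha is invariant to rater relabeling and episode duplication", {
  set.seed(37)
  votes <- random_votes(n_ep = 30, n_raters = 6)
  a <- krippendorff_alpha(votes)
  expect_lte(a, 1)
  relabeled <- votes
  relabeled$rater_id <- sample(relabeled$rater_id)
  expect_equal(krippendorff_alpha(relabeled), a)
  # duplicating every episode leaves alpha unchanged up to the estimator's
  # finite-sample correction (the n-1 in the expected disagreement), an
  # O(1/n) effect
  doubled <- rbind(votes,
                   transform(votes, episode_id = paste0(episode_id, "_copy")))
  expect_equal(krippendorff_alpha(doubled), a, tolerance = 0.02)
})

test_that("2x2 chi-squared uses the uncorrected closed form", {
  res <- pearson_chi2_2x2(matrix(c(63, 11, 44, 127), nrow = 2))
  expect_equal(round(res$statistic, 2), 74.09)
  expect_equal(res$df, 1L)
  expect_equal(res$n, 245)
  expect_lt(res$p_value, 0.001)

  # proportional rows -> 0
  expect_equal(pearson_chi2_2x2(matrix(c(10, 20, 10, 20), nrow = 2))$statistic, 0)

  set.seed(41)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 30) + 1, nrow = 2)
    got <- pearson_chi2_2x2(tab)$statistic
    want <- unname(suppressWarnings(
      stats::chisq.test(tab, correct = FALSE)$statistic))
    expect_equal(got, want, tolerance = 1e-9)
    # invariances: transpose; swap both rows and both columns
    expect_equal(pearson_chi2_2x2(t(tab))$statistic, got)
    expect_equal(pearson_chi2_2x2(tab[2:1, 2:1])$statistic, got)
  }
  expect_error(pearson_chi2_2x2(matrix(c(0, 0, 5, 5), nrow = 2)), "margin")
  expect_error(pearson_chi2_2x2(matrix(c(-1, 2, 5, 5), nrow = 2)), "non-negative")
})

test_that("corpus summaries recount calls, intricacy and episode lengths", {
  # degenerate corpus: every episode (no_change, low)
  corp <- make_corpus(5, calls = rep("no_change", 5))
  s <- summarize_corpus(corp)
  expect_equal(s$calls$count, c(0L, 5L, 0L))
  expect_equal(s$calls$percent, c(0, 100, 0))
  expect_equal(sum(s$by_intricacy$count), 5L)
  expect_equal(s$by_intricacy$count[s$by_intricacy$intricacy == "low" &
                                      s$by_intricacy$call == "no_change"], 5L)

  # a 400-episode corpus with calls 220/133/47
  calls <- rep(c("no_change", "temporal_correlation", "no_assessment"),
               c(220, 133, 47))
  corp4 <- make_corpus(400, calls = calls)
  s4 <- summarize_corpus(corp4)
  expect_equal(s4$calls$percent[match(c("no_change", "temporal_correlation",
                                        "no_assessment"), s4$calls$call)],
               c(55.00, 33.25, 11.75))
  expect_equal(sum(s4$calls$count), 400L)

  # counts agree with an independent tally
  tal <- table(factor(corp4$classifications$call, assessment_categories()))
  expect_equal(s4$calls$count, as.integer(tal))

  # length statistics: make_episode(len) has admin length len,
  # observed span len + 14, fixed-flank overall len + 14
  lens <- vapply(corp4$episodes, function(e) max(e$administration_days) + 1L,
                 integer(1))
  expect_equal(s4$episode_length$administration[["mean"]], mean(lens))
  expect_equal(s4$episode_length$administration[["sd"]], sd(lens))
  expect_equal(s4$episode_length$overall_fixed_flank[["mean"]], mean(lens) + 14)
  expect_equal(s4$episode_length$overall_observed_span[["mean"]], mean(lens) + 14)
})
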