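test_that("trial scoring partitions shuttle times at the stated boundaries", {
  # avoidance: shuttle during the 5 s cue, before shock onset
  expect_equal(score_trial(3)$outcome, "avoidance")
  expect_true(is.na(score_trial(3)$escape_latency))
  expect_equal(score_trial(4.999)$outcome, "avoidance")
  # escape: shuttle during the 10 s shock; latency measured from shock onset
  s5 <- score_trial(5)
  expect_equal(s5$outcome, "escape")
  expect_equal(s5$escape_latency, 0)
  expect_equal(score_trial(8)$escape_latency, 3)
  expect_equal(score_trial(14.999)$escape_latency, 9.999)
  # failure: no shuttle within 15 s; censored latency 10 s
  expect_equal(score_trial(NA)$outcome, "failure")
  expect_equal(score_trial(NA)$escape_latency, 10)
  expect_equal(score_trial(15)$outcome, "failure")
  expect_error(score_trial(-1), "non-negative")
})

test_that("session summaries average escape latency over escapes and failures", {
  all_fail <- score_trial(rep(NA_real_, 30))
  expect_equal(summarize_session(all_fail)[, c("mean_escape_latency", "n_failures")],
               data.frame(mean_escape_latency = 10, n_failures = 30L))

  mix <- score_trial(c(rep(7, 15), rep(NA_real_, 15)))   # 15 escapes at 2 s + 15 failures
  sm <- summarize_session(mix)
  expect_equal(sm$mean_escape_latency, (15 * 2 + 15 * 10) / 30)
  expect_equal(sm$n_failures, 15L)

  all_avoid <- score_trial(rep(2, 30))
  expect_equal(summarize_session(all_avoid)$mean_escape_latency, 0)
  expect_equal(summarize_session(all_avoid)$n_failures, 0L)
  # avoidances as 0 s when requested
  half <- score_trial(c(rep(2, 15), rep(9, 15)))
  expect_equal(summarize_session(half)$mean_escape_latency, 4)
  expect_equal(summarize_session(half, avoidance_as_zero = TRUE)$mean_escape_latency, 2)
})

test_that("warm-up trials 1-5 of a full session are not scored", {
  full <- score_trial(c(rep(NA_real_, 5), rep(7, 30)))   # 35-trial session
  sm <- summarize_session(full)
  expect_equal(sm$n_failures, 0L)        # the 5 failures were warm-up
  expect_equal(sm$mean_escape_latency, 2)
  expect_error(summarize_session(score_trial(rep(7, 20))), "30")
  expect_error(summarize_session(score_trial(rep(7, 33))), "30")
})

test_that("k-means recovers well-separated phenotypes and names by failures", {
  sm <- make_separated_summaries(n_per = 50)
  km <- kmeans_phenotypes(sm, seed = 1)
  expect_equal(mean(km$labels == sm$truth), 1)
  expect_gt(km$centers["helpless", "failures"], km$centers["resilient", "failures"])

  # naming depends only on failure means, not initialization
  for (s in 1:10)
    expect_equal(kmeans_phenotypes(sm, seed = s)$labels, km$labels)

  expect_error(kmeans_phenotypes(sm, k = 1), "k must be 2")
  degenerate <- data.frame(mean_escape_latency = rep(2, 5), n_failures = rep(3, 5))
  expect_error(kmeans_phenotypes(degenerate), "degenerate")
})

test_that("published classification functions reproduce printed scores", {
  origin <- data.frame(mean_escape_latency = 0, n_failures = 0)
  r0 <- discriminant_classify(origin)
  expect_equal(r0$R_score, -4.63)
  expect_equal(r0$LH_score, -23.24)
  expect_equal(r0$label, "resilient")

  extreme <- data.frame(mean_escape_latency = 10, n_failures = 30)
  r1 <- discriminant_classify(extreme)
  expect_equal(r1$R_score, 2.57)
  expect_equal(r1$LH_score, 29.36)
  expect_equal(r1$label, "helpless")

  # boundary point: R = LH to 3 decimals at (1.595, 10)
  rb <- discriminant_classify(data.frame(mean_escape_latency = 1.595,
                                         n_failures = 10))
  expect_lt(abs(rb$R_score - rb$LH_score), 1e-3)
})

test_that("classification depends only on the sign of R - LH", {
  set.seed(8)
  grid <- data.frame(mean_escape_latency = runif(2000, 0, 10),
                     n_failures = sample(0:30, 2000, TRUE))
  res <- discriminant_classify(grid)
  # direct evaluation of the score difference implied by the coefficients
  diff <- 18.61 + 2.00 * grid$mean_escape_latency - 2.18 * grid$n_failures
  expect_equal(res$label, ifelse(diff > 0, "resilient", "helpless"))
})

test_that("fitted discriminant matches LDA closed form", {
  set.seed(21)
  n <- 200
  sm <- data.frame(
    mean_escape_latency = c(rnorm(n, 2, 1), rnorm(n, 8, 1)),
    n_failures = c(rnorm(n, 5, 2), rnorm(n, 25, 2)))
  labels <- rep(c("resilient", "helpless"), each = n)
  model <- fit_discriminant(sm, labels)

  # equal priors: the boundary passes through the Mahalanobis midpoint of
  # the class means (score difference zero at the midpoint)
  mid <- data.frame(
    mean_escape_latency = mean(tapply(sm$mean_escape_latency, labels, mean)),
    n_failures = mean(tapply(sm$n_failures, labels, mean)))
  rmid <- discriminant_classify(mid, model)
  expect_lt(abs(rmid$R_score - rmid$LH_score), 1e-8)

  # self-consistency on well-separated training data
  refit <- discriminant_classify(sm, model)
  expect_equal(refit$label, labels)

  # unequal priors shift the score difference by exactly log(p1/p2)
  model_p <- fit_discriminant(sm, labels,
                              prior = c(resilient = 0.78, helpless = 0.22))
  rp <- discriminant_classify(mid, model_p)
  expect_equal((rp$R_score - rp$LH_score) - (rmid$R_score - rmid$LH_score),
               log(0.78) - log(0.22) - (log(0.5) - log(0.5)))

  # agreement with an independent LDA implementation
  skip_if_not_installed("MASS")
  ld <- MASS::lda(cbind(sm$mean_escape_latency, sm$n_failures),
                  grouping = factor(labels))
  pred <- as.character(stats::predict(ld)$class)
  expect_equal(refit$label, pred)

  expect_error(fit_discriminant(sm, rep("helpless", 2 * n)), "both classes")
})

test_that("rat lever-press thresholds classify as printed", {
  expect_equal(classify_rat(12), "resilient")
  expect_equal(classify_rat(3), "helpless")
  expect_equal(classify_rat(7), "excluded")
  expect_equal(classify_rat(c(10, 5, 6, 9, 0, 15)),
               c("resilient", "helpless", "excluded", "excluded",
                 "helpless", "resilient"))
  expect_error(classify_rat(-1), "non-negative")
  expect_error(classify_rat(16), "15 trials")
})

test_that("group comparison matches the exact Mann-Whitney enumeration", {
  # completely separated groups of 3 and 3: exact two-tailed P by
  # enumerating all C(6,3) equally likely rank assignments
  sm <- data.frame(mean_escape_latency = c(9, 8, 7, 2, 1, 3),
                   n_failures = c(28, 27, 26, 1, 2, 3))
  labels <- rep(c("helpless", "resilient"), each = 3)
  res <- compare_groups(sm, labels)

  enum_p <- local({
    vals <- sm$n_failures
    obs <- sum(rank(vals)[1:3]) - 6   # observed W for the helpless group
    ws <- apply(utils::combn(6, 3), 2, function(i) sum(rank(vals)[i]) - 6)
    mean(abs(ws - mean(range(ws))) >= abs(obs - mean(range(ws))))
  })
  expect_equal(enum_p, 0.1)   # 2 extreme assignments of 20
  expect_equal(res["n_failures", "p_value"], enum_p)
  expect_equal(res["mean_escape_latency", "p_value"], enum_p)

  # rank-based: invariant to monotone transforms
  sm2 <- sm
  sm2$mean_escape_latency <- exp(sm2$mean_escape_latency)
  expect_equal(compare_groups(sm2, labels)["mean_escape_latency", "W"],
               res["mean_escape_latency", "W"])

  # identical groups: no evidence of a difference
  sm3 <- data.frame(mean_escape_latency = rep(c(1, 2, 3), 2),
                    n_failures = rep(c(4, 5, 6), 2))
  p3 <- compare_groups(sm3, rep(c("helpless", "resilient"), each = 3))$p_value
  expect_true(all(p3 == 1))
  expect_error(compare_groups(sm, rep("helpless", 6)), "non-empty")
})

test_that("extreme-pair selection picks the behavioral extremes per batch", {
  sm <- data.frame(
    animal_id = paste0("m", 1:8),
    mean_escape_latency = c(1, 9, 2, 8, 1.5, 9.5, 2.5, 8.5),
    n_failures = c(2, 28, 1, 25, 3, 28, 2, 20))
  labels <- rep(c("resilient", "helpless"), 4)
  batch <- rep(c("b1", "b2"), each = 4)
  pairs <- select_extreme_pairs(sm, labels, batch)
  expect_equal(nrow(pairs), 2)
  # b1: helpless max failures = m2 (28); resilient min failures = m3 (1)
  expect_equal(pairs$helpless_id[1], "m2")
  expect_equal(pairs$resilient_id[1], "m3")
  # b2: m6 has 28 failures; resilient tie on failures (m5 3 vs m7 2) -> m7
  expect_equal(pairs$helpless_id[2], "m6")
  expect_equal(pairs$resilient_id[2], "m7")

  # a batch without both phenotypes yields no pair, with a warning per batch
  w <- capture_warnings(p1 <- select_extreme_pairs(sm, rep("resilient", 8), batch))
  expect_match(w, "lacks both phenotypes", all = TRUE)
  expect_length(w, 2)
  expect_equal(nrow(p1), 0)

  # 11 valid batches yield 11 pairs, and a valid design
  sm11 <- do.call(rbind, lapply(1:11, function(b) {
    d <- sm[1:2, ]; d$animal_id <- paste0("b", b, "_", 1:2); d
  }))
  pairs11 <- select_extreme_pairs(sm11, rep(c("resilient", "helpless"), 11),
                                  rep(1:11, each = 2))
  expect_equal(nrow(pairs11), 11)
  design <- pairs_to_design(pairs11)
  expect_equal(nrow(design), 22)
  expect_true(all(table(design$pair_id, design$group) == 1))
})

test_that("k-means, refitted discriminant and published equations agree on separated cohorts", {
  sm <- make_separated_summaries(n_per = 120, seed = 77)
  km <- kmeans_phenotypes(sm, seed = 2)
  model <- fit_discriminant(sm, km$labels)
  relab <- discriminant_classify(sm, model)$label
  expect_gte(mean(relab == km$labels), 0.99)
  pub <- discriminant_classify(sm)$label
  expect_gte(mean(pub == km$labels), 0.99)
})
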