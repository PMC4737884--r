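# Shuttle-box trial scoring and helpless/resilient classification.
#
# Trial timeline: 5 s cue light, then a 10 s escapable shock. Shuttling
# during the cue (< 5 s from cue onset) is an avoidance; shuttling during the
# shock (5-15 s) is an escape with latency measured from shock onset;
# no shuttle within 15 s is a failure, assigned the censored latency 10 s.

#' Score a single shuttle-box trial
#'
#' @param shuttle_time seconds from cue onset to shuttling, or `NA` if the
#'   animal never shuttled.
#' @param trial_index optional 1-based trial ordinal carried through.
#' @return data.frame row with `trial_index`, `shuttle_time`, `outcome`
#'   (avoidance/escape/failure) and `escape_latency` (s from shock onset;
#'   `NA` for avoidances, 10 for failures).
#' @export
score_trial <- function(shuttle_time, trial_index = NA_integer_) {
  n <- length(shuttle_time)
  if (any(shuttle_time < 0, na.rm = TRUE))
    stop("shuttle_time must be non-negative")
  outcome <- ifelse(is.na(shuttle_time) | shuttle_time >= 15, "failure",
                    ifelse(shuttle_time < 5, "avoidance", "escape"))
  lat <- ifelse(outcome == "failure", 10,
                ifelse(outcome == "escape", shuttle_time - 5, NA_real_))
  data.frame(trial_index = rep_len(trial_index, n),
             shuttle_time = shuttle_time,
             outcome = outcome, escape_latency = lat,
             stringsAsFactors = FALSE)
}

#' Summarize a testing session into classification indices
#'
#' Scores the final 30 trials of a session (warm-up trials, during which the
#' animal learns the cue-shock association, are discarded): the failure count
#' and the mean escape latency over escape and failure trials, failures
#' contributing the censored value 10 s. Avoidance trials have no shock and
#' hence no escape latency; by default they are excluded from the mean
#' (`avoidance_as_zero = TRUE` instead counts them as 0 s).
#'
#' @param trials data.frame of scored trials (from [score_trial()]) with at
#'   least `outcome` and `escape_latency`; supply either >= 35 trials (all
#'   but the last 30 discarded) or exactly 30 pre-scored trials.
#' @param animal_id identifier carried into the summary.
#' @param avoidance_as_zero include avoidances as 0 s latencies.
#' @return data.frame row: `animal_id`, `mean_escape_latency`, `n_failures`,
#'   `n_avoidances`.
#' @export
summarize_session <- function(trials, animal_id = NA_character_,
                              avoidance_as_zero = FALSE) {
  n <- nrow(trials)
  if (n < 30) stop("need at least 30 scorable trials, got ", n)
  if (n > 30) {
    if (n < 35) stop("supply exactly 30 pre-scored trials or a full session (>= 35)")
    trials <- trials[6:35, , drop = FALSE]  # warm-up trials 1-5 unscored
  }
  fail <- trials$outcome == "failure"
  avoid <- trials$outcome == "avoidance"
  lat <- trials$escape_latency
  if (avoidance_as_zero) lat[avoid] <- 0
  lat <- lat[!is.na(lat)]
  data.frame(animal_id = animal_id,
             mean_escape_latency = if (length(lat)) mean(lat) else 0,
             n_failures = sum(fail), n_avoidances = sum(avoid),
             stringsAsFactors = FALSE)
}

#' Score and summarize a whole cohort
#'
#' Convenience wrapper applying [score_trial()] and [summarize_session()]
#' per animal to a trial table as produced by [gen_behavior_cohort()].
#'
#' @param trials data.frame with `animal_id`, `trial_index`, `shuttle_time`
#'   (`NA` for failures).
#' @param avoidance_as_zero passed to [summarize_session()].
#' @return data.frame of session summaries, one row per animal.
#' @export
summarize_cohort <- function(trials, avoidance_as_zero = FALSE) {
  out <- lapply(split(trials, trials$animal_id), function(tr) {
    tr <- tr[order(tr$trial_index), ]
    sc <- score_trial(tr$shuttle_time, tr$trial_index)
    summarize_session(sc, animal_id = tr$animal_id[1],
                      avoidance_as_zero = avoidance_as_zero)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cluster session summaries into helpless and resilient phenotypes
#'
#' k-means (k = 2) on the (mean escape latency, failure count) plane, run in
#' raw units with 50 random restarts under a fixed seed; the cluster with the
#' larger mean failure count is labelled helpless.
#'
#' @param summaries data.frame with `mean_escape_latency` and `n_failures`.
#' @param k number of clusters; only 2 is supported (the paradigm defines a
#'   helpless/resilient dichotomy).
#' @param seed RNG seed for the restarts.
#' @param nstart number of random restarts; best within-cluster sum of
#'   squares wins.
#' @return list with `labels` (character vector helpless/resilient) and
#'   `centers` (2x2 matrix, rows named by phenotype).
#' @export
kmeans_phenotypes <- function(summaries, k = 2, seed = 1L, nstart = 50) {
  if (k != 2) stop("k must be 2: the paradigm defines exactly two phenotypes")
  x <- cbind(latency = summaries$mean_escape_latency,
             failures = summaries$n_failures)
  if (nrow(unique(x)) < 2) stop("degenerate clustering: fewer than 2 distinct points")
  set.seed(seed)
  km <- stats::kmeans(x, centers = 2, nstart = nstart)
  helpless_cluster <- which.max(tapply(x[, "failures"], km$cluster, mean))
  labels <- ifelse(km$cluster == helpless_cluster, "helpless", "resilient")
  centers <- km$centers[c(helpless_cluster, 3 - helpless_cluster), , drop = FALSE]
  rownames(centers) <- c("helpless", "resilient")
  list(labels = labels, centers = centers)
}

#' The published linear classification functions
#'
#' Classification-function coefficients obtained from a linear discriminant
#' analysis of the 144-mouse training cohort:
#' `R  = -4.63 + 5.67 * latency - 1.65 * failures` and
#' `LH = -23.24 + 3.67 * latency + 0.53 * failures`.
#' A higher score means a smaller squared Mahalanobis distance to that
#' group's centroid; an animal is resilient iff `R > LH`.
#'
#' @return a `discriminant_model`: list with `coef_R` and `coef_LH`, each
#'   `c(intercept, latency, failures)`.
#' @export
published_discriminant <- function() {
  structure(list(coef_R = c(intercept = -4.63, latency = 5.67, failures = -1.65),
                 coef_LH = c(intercept = -23.24, latency = 3.67, failures = 0.53)),
            class = "discriminant_model")
}

#' Classify animals with linear classification functions
#'
#' @param summaries data.frame with `mean_escape_latency`, `n_failures` and
#'   optionally `animal_id`.
#' @param model a `discriminant_model`; defaults to the published one.
#' @return data.frame: `animal_id`, `R_score`, `LH_score`, `label`
#'   (resilient iff `R_score > LH_score`).
#' @export
discriminant_classify <- function(summaries, model = published_discriminant()) {
  stopifnot(inherits(model, "discriminant_model"))
  lat <- summaries$mean_escape_latency
  f <- summaries$n_failures
  r <- model$coef_R[1] + model$coef_R[2] * lat + model$coef_R[3] * f
  lh <- model$coef_LH[1] + model$coef_LH[2] * lat + model$coef_LH[3] * f
  data.frame(animal_id = if (!is.null(summaries$animal_id))
               summaries$animal_id else NA_character_,
             R_score = unname(r), LH_score = unname(lh),
             label = ifelse(r > lh, "resilient", "helpless"),
             stringsAsFactors = FALSE)
}

#' Fit linear classification functions from labelled summaries
#'
#' Fisher linear discriminant analysis with pooled within-class covariance
#' and empirical class priors, returned as classification-function
#' coefficients on the (latency, failures) scale: for class k,
#' `score_k(x) = mu_k' S^-1 x - mu_k' S^-1 mu_k / 2 + log(pi_k)`.
#' Scores differ from negative half squared Mahalanobis distances only by a
#' term common to both classes, so the induced rule is the Mahalanobis
#' nearest-centroid rule shifted by the log prior ratio.
#'
#' @param summaries data.frame with `mean_escape_latency` and `n_failures`.
#' @param labels character vector, "helpless"/"resilient" per row.
#' @param prior class priors named by label; defaults to empirical
#'   proportions.
#' @return a `discriminant_model` (see [published_discriminant()]).
#' @export
fit_discriminant <- function(summaries, labels, prior = NULL) {
  x <- cbind(latency = summaries$mean_escape_latency,
             failures = summaries$n_failures)
  labels <- as.character(labels)
  cls <- c("resilient", "helpless")
  if (!all(cls %in% labels)) stop("both classes must be present")
  if (is.null(prior)) {
    prior <- prop.table(table(factor(labels, cls)))
  } else prior <- prior[cls] / sum(prior[cls])
  mu <- rbind(colMeans(x[labels == "resilient", , drop = FALSE]),
              colMeans(x[labels == "helpless", , drop = FALSE]))
  # pooled within-class covariance, denominator n - 2
  n <- nrow(x)
  sw <- (crossprod(scale(x[labels == "resilient", , drop = FALSE], scale = FALSE)) +
         crossprod(scale(x[labels == "helpless", , drop = FALSE], scale = FALSE))) / (n - 2)
  si <- tryCatch(solve(sw), error = function(e)
    stop("singular pooled within-class covariance: ", conditionMessage(e)))
  cf <- function(k) {
    w <- drop(si %*% mu[k, ])
    c(intercept = unname(-0.5 * sum(mu[k, ] * w) + log(prior[[k]])),
      latency = unname(w[1]), failures = unname(w[2]))
  }
  structure(list(coef_R = cf(1), coef_LH = cf(2)), class = "discriminant_model")
}

#' Classify rats by lever presses in the escapable-shock test
#'
#' Lever presses terminating the shock, counted only within the first 20 s
#' of shock onset, over a 15-trial session: >= 10 presses is resilient,
#' <= 5 is helpless, an intermediate count (6-9) is excluded from analysis.
#'
#' @param lever_presses integer vector of per-animal counted presses (0-15).
#' @return character vector: resilient / helpless / excluded.
#' @export
classify_rat <- function(lever_presses) {
  if (any(lever_presses < 0)) stop("lever press counts must be non-negative")
  if (any(lever_presses > 15)) stop("at most one counted press per trial (15 trials)")
  ifelse(lever_presses >= 10, "resilient",
         ifelse(lever_presses <= 5, "helpless", "excluded"))
}

#' Compare behavioral indices between phenotype groups
#'
#' Mann-Whitney (Wilcoxon rank-sum) tests of failure count and mean escape
#' latency between helpless and resilient animals; two-tailed by default,
#' exact where sample sizes permit and no ties occur, midranks otherwise.
#'
#' @param summaries data.frame with `mean_escape_latency` and `n_failures`.
#' @param labels character vector, "helpless"/"resilient" per row.
#' @param alternative passed to [stats::wilcox.test()].
#' @return data.frame with rows `n_failures`, `mean_escape_latency`:
#'   columns `index`, `W` (statistic, helpless vs resilient), `p_value`.
#' @export
compare_groups <- function(summaries, labels, alternative = "two.sided") {
  lh <- labels == "helpless"
  if (!any(lh) || all(lh)) stop("both groups must be non-empty")
  one <- function(v, index) {
    wt <- suppressWarnings(
      stats::wilcox.test(v[lh], v[!lh], alternative = alternative))
    data.frame(index = index, W = unname(wt$statistic), p_value = wt$p.value,
               stringsAsFactors = FALSE)
  }
  res <- rbind(one(summaries$n_failures, "n_failures"),
               one(summaries$mean_escape_latency, "mean_escape_latency"))
  rownames(res) <- res$index
  res
}

#' Select extreme helpless/resilient pairs for imaging
#'
#' Within each experimental batch (animals run in parallel), selects the
#' helpless animal with the most extreme phenotype — most failures, then
#' longest latency — and the resilient animal with the least failures, then
#' shortest latency, forming one imaging pair per batch. Batches lacking
#' either phenotype are skipped with a warning.
#'
#' @param summaries data.frame with `animal_id`, `mean_escape_latency`,
#'   `n_failures`.
#' @param labels character vector per row, "helpless"/"resilient".
#' @param batch vector assigning each row to a batch.
#' @return data.frame (a pair design): `pair_id`, `helpless_id`,
#'   `resilient_id`.
#' @export
select_extreme_pairs <- function(summaries, labels, batch) {
  stopifnot(nrow(summaries) == length(labels), length(labels) == length(batch))
  out <- list()
  for (b in unique(batch)) {
    in_b <- batch == b
    hl <- which(in_b & labels == "helpless")
    rs <- which(in_b & labels == "resilient")
    if (!length(hl) || !length(rs)) {
      warning("batch ", b, " lacks both phenotypes; no pair selected")
      next
    }
    hi <- hl[order(-summaries$n_failures[hl], -summaries$mean_escape_latency[hl])][1]
    ri <- rs[order(summaries$n_failures[rs], summaries$mean_escape_latency[rs])][1]
    out[[length(out) + 1L]] <- data.frame(
      pair_id = as.character(b),
      helpless_id = summaries$animal_id[hi],
      resilient_id = summaries$animal_id[ri],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(pair_id = character(), helpless_id = character(),
                      resilient_id = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Long-format pair design from selected pairs
#'
#' @param pairs output of [select_extreme_pairs()].
#' @return data.frame: `animal_id`, `pair_id`, `group` — the blocking/group
#'   design consumed by [region_screen()].
#' @export
pairs_to_design <- function(pairs) {
  data.frame(animal_id = c(rbind(pairs$helpless_id, pairs$resilient_id)),
             pair_id = rep(pairs$pair_id, each = 2),
             group = rep(c("helpless", "resilient"), nrow(pairs)),
             stringsAsFactors = FALSE)
}
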