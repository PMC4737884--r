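# Stereotypy of brain-wide activity profiles.
#
# Each animal contributes a vector of regional activity (c-Fos-positive cell
# counts, or regional PET signal) over a shared region list. Within-group
# similarity is the mean pairwise Pearson correlation; the helpless-minus-
# resilient difference in that mean is tested against a bootstrap null that
# resamples both groups, with replacement, from the pooled animals.

#' Pairwise Pearson correlation matrix of activity vectors
#'
#' @param vectors numeric matrix, animals in rows (rownames = animal ids),
#'   regions in columns; or a data.frame of the same shape.
#' @return symmetric correlation matrix with unit diagonal. Animals with
#'   zero-variance vectors (correlation undefined) are dropped with a
#'   warning.
#' @export
correlation_matrix <- function(vectors) {
  x <- as.matrix(vectors)
  if (nrow(x) < 2) stop("need at least 2 animals")
  v <- apply(x, 1, stats::var)
  if (any(v == 0)) {
    warning("excluding zero-variance animal(s): ",
            paste(rownames(x)[v == 0], collapse = ", "))
    x <- x[v > 0, , drop = FALSE]
    if (nrow(x) < 2) stop("fewer than 2 animals with non-degenerate vectors")
  }
  r <- stats::cor(t(x))
  diag(r) <- 1
  r
}

#' Mean within-group pairwise correlation
#'
#' @param r correlation matrix (or submatrix) for one group.
#' @return mean over the off-diagonal upper triangle.
#' @export
mean_pairwise_cor <- function(r) mean(r[upper.tri(r)])

# mean pairwise correlation of a resampled multiset, via indices into the
# pooled correlation matrix; duplicate draws contribute r = 1 pairs unless
# excluded
resample_mean_cor <- function(M, idx, include_self_pairs = TRUE) {
  m <- length(idx)
  s <- M[idx, idx]
  if (include_self_pairs) return((sum(s) - m) / (m * (m - 1)))
  ut <- s[upper.tri(s)]
  dup <- outer(idx, idx, "==")[upper.tri(s)]
  if (all(dup)) return(NA_real_)   # all pairs are the same animal: undefined
  mean(ut[!dup])
}

# the same statistic for many resamples at once: draws is n_iter x m index
# matrix; returns one mean pairwise correlation per row (NA where no valid
# pair remains)
resample_mean_cor_many <- function(M, draws, include_self_pairs = TRUE) {
  m <- ncol(draws)
  tot <- 0
  if (include_self_pairs) {
    for (a in seq_len(m - 1)) for (bb in (a + 1):m)
      tot <- tot + M[cbind(draws[, a], draws[, bb])]
    return(tot / (m * (m - 1) / 2))
  }
  npair <- 0
  for (a in seq_len(m - 1)) for (bb in (a + 1):m) {
    same <- draws[, a] == draws[, bb]
    tot <- tot + ifelse(same, 0, M[cbind(draws[, a], draws[, bb])])
    npair <- npair + !same
  }
  ifelse(npair == 0, NA_real_, tot / npair)
}

#' Bootstrap configuration for the stereotypy test
#'
#' @param n1 resample size for the null helpless group.
#' @param n2 resample size for the null resilient group.
#' @param n_iter bootstrap iterations (default 100,000).
#' @param seed RNG seed.
#' @param include_self_pairs count duplicate-draw pairs as r = 1 (default
#'   `TRUE`, the literal reading of resampling with replacement); `FALSE`
#'   drops same-animal pairs and redraws iterations where no pair survives.
#' @param p_method `"doubled_tail"` (default): twice the smaller tail
#'   proportion, ties counted as extreme, capped at 1; `"central"`: twice
#'   the smaller of the two placement tails of the observed value in the
#'   null histogram.
#' @return a `bootstrap_config` object.
#' @export
bootstrap_config <- function(n1, n2 = n1, n_iter = 100000L, seed = 1L,
                             include_self_pairs = TRUE,
                             p_method = c("doubled_tail", "central")) {
  if (n1 < 2 || n2 < 2) stop("resample sizes must be >= 2")
  if (n_iter < 1) stop("n_iter must be >= 1")
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2),
                 n_iter = as.integer(n_iter), seed = as.integer(seed),
                 include_self_pairs = include_self_pairs,
                 p_method = match.arg(p_method)),
            class = "bootstrap_config")
}

#' Bootstrap test for the group difference in profile stereotypy
#'
#' Computes the observed difference `mean within-helpless correlation -
#' mean within-resilient correlation`, then builds a null distribution by
#' repeatedly resampling, with replacement, `n1` animals (null helpless
#' group) and `n2` animals (null resilient group) from the pooled animals
#' and recording the same difference. The two-sided P-value is the doubled
#' smaller tail proportion of the null at the observed value.
#'
#' @param lh numeric matrix of helpless animals' activity vectors (animals
#'   in rows).
#' @param r numeric matrix of resilient animals' activity vectors, same
#'   region columns.
#' @param cfg a [bootstrap_config()]; defaults to group sizes as resample
#'   sizes and 100,000 iterations.
#' @return list: `observed_diff`, `null_diffs` (length `n_iter`),
#'   `p_two_sided`, `mean_cor_lh`, `mean_cor_r`, `n_redrawn`, `cfg`.
#' @export
bootstrap_group_diff <- function(lh, r, cfg = NULL) {
  lh <- as.matrix(lh); r <- as.matrix(r)
  stopifnot(ncol(lh) == ncol(r))
  if (is.null(cfg)) cfg <- bootstrap_config(n1 = nrow(lh), n2 = nrow(r))
  stopifnot(inherits(cfg, "bootstrap_config"))
  pool <- rbind(lh, r)
  n <- nrow(pool)
  if (n < 2) stop("pooled sample must contain at least 2 animals")
  M <- correlation_matrix(pool)
  if (nrow(M) != n) stop("zero-variance animals are not allowed in the bootstrap pool")
  obs <- mean_pairwise_cor(M[seq_len(nrow(lh)), seq_len(nrow(lh))]) -
    mean_pairwise_cor(M[nrow(lh) + seq_len(nrow(r)), nrow(lh) + seq_len(nrow(r))])

  set.seed(cfg$seed)
  isp <- cfg$include_self_pairs
  # draws are laid out row-wise (iteration by iteration) so results are
  # identical to drawing n1 then n2 indices sequentially per iteration
  draw_block <- function(k, m) matrix(sample.int(n, k * m, replace = TRUE),
                                      nrow = k, ncol = m, byrow = TRUE)
  d1 <- resample_mean_cor_many(M, draw_block(cfg$n_iter, cfg$n1), isp)
  d2 <- resample_mean_cor_many(M, draw_block(cfg$n_iter, cfg$n2), isp)
  nd <- d1 - d2
  n_redrawn <- 0L
  while (anyNA(nd)) {   # degenerate resamples (no valid pair): redraw
    bad <- which(is.na(nd))
    n_redrawn <- n_redrawn + length(bad)
    if (n_redrawn > 100L * cfg$n_iter) stop("too many degenerate resamples")
    nd[bad] <- resample_mean_cor_many(M, draw_block(length(bad), cfg$n1), isp) -
      resample_mean_cor_many(M, draw_block(length(bad), cfg$n2), isp)
  }
  p <- if (cfg$p_method == "doubled_tail") {
    min(1, 2 * min(sum(nd >= obs), sum(nd <= obs)) / cfg$n_iter)
  } else {
    ec <- stats::ecdf(nd)(obs)
    min(1, 2 * min(ec, 1 - ec) + 2 / cfg$n_iter)
  }
  list(observed_diff = obs, null_diffs = nd,
       p_two_sided = max(p, 1 / cfg$n_iter),
       mean_cor_lh = mean_pairwise_cor(M[seq_len(nrow(lh)), seq_len(nrow(lh))]),
       mean_cor_r = mean_pairwise_cor(M[nrow(lh) + seq_len(nrow(r)),
                                        nrow(lh) + seq_len(nrow(r))]),
       n_redrawn = n_redrawn, cfg = cfg)
}
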