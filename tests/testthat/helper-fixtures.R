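# Shared fixtures built in code.

# canonical 11-pair design used across regionstats/voxelmap tests
make_design <- function(n_pairs = 11) {
  data.frame(
    animal_id = paste0(rep(sprintf("p%02d", seq_len(n_pairs)), each = 2),
                       c("_h", "_r")),
    pair_id = rep(sprintf("p%02d", seq_len(n_pairs)), each = 2),
    group = rep(c("helpless", "resilient"), n_pairs),
    stringsAsFactors = FALSE)
}

# draw one region's paired NB counts under the screen's model
draw_counts <- function(design, baseline = 100, dispersion = 0.2,
                        pair_sd = 0.3, lfc = 0) {
  np <- length(unique(design$pair_id))
  b <- stats::rnorm(np, 0, pair_sd)[match(design$pair_id, unique(design$pair_id))]
  mu <- exp(log(baseline) + b + ifelse(design$group == "resilient", lfc, 0))
  if (dispersion == 0) stats::rpois(nrow(design), mu)
  else stats::rnbinom(nrow(design), size = 1 / dispersion, mu = mu)
}

# two clearly separated behavioral blobs on the (latency, failures) plane
make_separated_summaries <- function(n_per = 50, seed = 42) {
  set.seed(seed)
  data.frame(
    animal_id = sprintf("a%03d", seq_len(2 * n_per)),
    mean_escape_latency = c(stats::rnorm(n_per, 1, 0.4),
                            stats::rnorm(n_per, 9, 0.4)),
    n_failures = c(stats::rbinom(n_per, 30, 0.07),
                   stats::rbinom(n_per, 30, 0.93)),
    truth = rep(c("resilient", "helpless"), each = n_per),
    stringsAsFactors = FALSE)
}
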