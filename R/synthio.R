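# ---- parameter constructors -------------------------------------------------

#' Parameters for a synthetic shuttle-box behavior cohort
#'
#' Defines a two-phenotype mixture of animals run through an escapable-shock
#' testing session. Each animal is helpless with probability `p_helpless`
#' (roughly 22% of animals develop helplessness after inescapable-shock
#' induction); the rest are resilient. Trials are scored on the standard
#' timeline: a 5 s cue precedes a 10 s shock, so a shuttle within 5 s of cue
#' onset is an avoidance, a shuttle between 5 and 15 s is an escape, and no
#' shuttle within 15 s is a failure.
#'
#' Shuttle times are drawn from per-phenotype truncated normals on \[0, 15) s
#' (cue-onset reference); a trial is a failure with per-phenotype probability
#' `failure_rates`, modelling latency censored at the 10 s shock end.
#'
#' @param n_animals number of animals in the cohort.
#' @param p_helpless probability an animal is helpless.
#' @param n_trials trials per session (the first `n_trials - 30` are
#'   unscored warm-up trials; default 35 so trials 6-35 are scored).
#' @param latency_means mean escape latency (s from shock onset) for the
#'   resilient and helpless phenotypes, in \[0, 10\].
#' @param latency_sds standard deviations of the latency draws, same order.
#' @param failure_rates per-trial failure probability per phenotype.
#' @param seed integer RNG seed.
#' @return an object of class `behavior_sim_params`.
#' @export
behavior_sim_params <- function(n_animals,
                                p_helpless = 0.22,
                                n_trials = 35,
                                latency_means = c(resilient = 1.5, helpless = 8),
                                latency_sds = c(resilient = 1.5, helpless = 1.5),
                                failure_rates = c(resilient = 0.05, helpless = 0.75),
                                seed = 1L) {
  stopifnot(length(n_animals) == 1, length(p_helpless) == 1,
            length(n_trials) == 1)
  if (!is.finite(n_animals) || n_animals < 1 || n_animals != round(n_animals))
    stop("n_animals must be a positive integer")
  if (!is.finite(p_helpless) || p_helpless < 0 || p_helpless > 1)
    stop("p_helpless must lie in [0, 1]")
  if (n_trials < 6 || n_trials != round(n_trials))
    stop("n_trials must be an integer >= 6")
  if (any(latency_means < 0) || any(latency_means > 10))
    stop("latency_means must lie in [0, 10] (shock duration)")
  if (any(failure_rates < 0) || any(failure_rates > 1))
    stop("failure_rates must lie in [0, 1]")
  structure(list(n_animals = as.integer(n_animals), p_helpless = p_helpless,
                 n_trials = as.integer(n_trials),
                 latency_means = latency_means, latency_sds = latency_sds,
                 failure_rates = failure_rates, seed = as.integer(seed)),
            class = "behavior_sim_params")
}

#' Parameters for synthetic paired region-count matrices
#'
#' Emulates the paired imaging design: `n_pairs` pairs, each holding one
#' helpless and one resilient animal processed in parallel, with per-region
#' c-Fos-positive cell counts drawn from a negative binomial with
#' `variance = mu + dispersion * mu^2`. A shared pair-level log-normal offset
#' models day/batch nuisance variation (the confound the blocking variable of
#' the regional screen absorbs). Designated signal regions carry a group
#' effect of `log_fold_change` on the log scale; by default resilient animals
#' have the higher mean ("R high"), with per-region sign overrides to model
#' regions more active in helpless animals ("LH high", e.g. the locus
#' coeruleus).
#'
#' @param n_pairs number of helpless/resilient pairs (default 11).
#' @param n_regions number of anatomical regions.
#' @param baseline_mean expected count per region; scalar or length
#'   `n_regions` vector (a region profile).
#' @param profile_sd log-scale SD of a randomly drawn per-region baseline
#'   profile multiplying `baseline_mean` (default 0: all regions share the
#'   baseline). A non-zero value makes animals' brain-wide vectors
#'   correlated through the shared anatomy, which the stereotypy analysis
#'   requires.
#' @param dispersion NB dispersion (0 gives the Poisson limit).
#' @param pair_sd SD of the pair-level log-mean offset.
#' @param signal_regions integer indices of regions carrying a group effect.
#' @param log_fold_change group effect magnitude on the log scale.
#' @param signal_direction per-signal-region direction, `"R_high"` or
#'   `"LH_high"`; recycled.
#' @param stereotypy_sd length-2 named vector: SD of per-animal, per-region
#'   log-normal noise for resilient and helpless animals. Unequal values give
#'   the groups different within-group profile similarity (stereotypy);
#'   default 0 (off).
#' @param seed integer RNG seed.
#' @return an object of class `count_sim_params`.
#' @export
count_sim_params <- function(n_pairs = 11, n_regions,
                             baseline_mean = 100,
                             profile_sd = 0,
                             dispersion = 0.2,
                             pair_sd = 0.3,
                             signal_regions = integer(0),
                             log_fold_change = 0.7,
                             signal_direction = "R_high",
                             stereotypy_sd = c(resilient = 0, helpless = 0),
                             seed = 1L) {
  if (n_pairs < 1 || n_pairs != round(n_pairs)) stop("n_pairs must be a positive integer")
  if (n_regions < 1 || n_regions != round(n_regions)) stop("n_regions must be a positive integer")
  if (any(baseline_mean <= 0)) stop("baseline_mean must be > 0")
  if (!length(baseline_mean) %in% c(1L, n_regions))
    stop("baseline_mean must be scalar or one value per region")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (pair_sd < 0) stop("pair_sd must be >= 0")
  signal_regions <- as.integer(signal_regions)
  if (length(signal_regions) &&
      (any(signal_regions < 1) || any(signal_regions > n_regions)))
    stop("signal_regions must be indices in 1..n_regions")
  if (!all(signal_direction %in% c("R_high", "LH_high")))
    stop("signal_direction must be 'R_high' or 'LH_high'")
  if (any(stereotypy_sd < 0)) stop("stereotypy_sd must be >= 0")
  if (profile_sd < 0) stop("profile_sd must be >= 0")
  structure(list(n_pairs = as.integer(n_pairs), n_regions = as.integer(n_regions),
                 baseline_mean = baseline_mean, profile_sd = profile_sd,
                 dispersion = dispersion,
                 pair_sd = pair_sd, signal_regions = signal_regions,
                 log_fold_change = log_fold_change,
                 signal_direction = rep_len(signal_direction,
                                            length(signal_regions)),
                 stereotypy_sd = stereotypy_sd,
                 seed = as.integer(seed)),
            class = "count_sim_params")
}

#' Parameters for a synthetic cell cloud and toy label atlas
#'
#' Lays out non-overlapping axis-aligned boxes (one per region label) inside
#' a voxel volume; cell centroids are placed uniformly inside each region's
#' box with Poisson-distributed counts. A stand-in for registered whole-brain
#' centroid data plus an anatomical label volume.
#'
#' @param volume_shape integer voxel counts per axis (x, y, z).
#' @param voxel_size micrometres per voxel along each axis (scalar or length 3).
#' @param region_layout named list: label id (coercible to positive integer)
#'   to a 2x3 matrix `rbind(min, max)` of box corners in micrometres.
#' @param cells_per_region expected centroid count per region per animal;
#'   scalar or one value per region.
#' @param seed integer RNG seed.
#' @return an object of class `cloud_sim_params`.
#' @export
cloud_sim_params <- function(volume_shape, voxel_size, region_layout,
                             cells_per_region = 100, seed = 1L) {
  volume_shape <- as.integer(volume_shape)
  stopifnot(length(volume_shape) == 3, all(volume_shape > 0))
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  stopifnot(all(voxel_size > 0))
  labs <- suppressWarnings(as.integer(names(region_layout)))
  if (length(region_layout) == 0 || any(is.na(labs)) || any(labs <= 0))
    stop("region_layout must be a named list with positive-integer labels")
  extent <- volume_shape * voxel_size
  boxes <- lapply(region_layout, function(b) {
    b <- matrix(as.numeric(b), nrow = 2)
    if (ncol(b) != 3 || any(b[1, ] > b[2, ])) stop("each box must be rbind(min, max) over x,y,z")
    if (any(b[1, ] < 0) || any(b[2, ] > extent)) stop("region box lies outside the volume")
    b
  })
  # pairwise overlap check: boxes must not intersect with positive volume
  n <- length(boxes)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      lo <- pmax(boxes[[i]][1, ], boxes[[j]][1, ])
      hi <- pmin(boxes[[i]][2, ], boxes[[j]][2, ])
      if (all(lo < hi)) stop("region boxes overlap: labels ",
                             names(boxes)[i], " and ", names(boxes)[j])
    }
  }
  structure(list(volume_shape = volume_shape, voxel_size = voxel_size,
                 region_layout = boxes,
                 cells_per_region = rep_len(cells_per_region, n),
                 seed = as.integer(seed)),
            class = "cloud_sim_params")
}

# ---- generators -------------------------------------------------------------

#' Generate a synthetic behavior cohort
#'
#' Draws per-animal phenotypes (Bernoulli `p_helpless`) and per-trial shuttle
#' times, returning a tidy trial table plus the ground-truth phenotype of
#' each animal.
#'
#' @param params a [behavior_sim_params()] object.
#' @return list with `trials` (data.frame: animal_id, trial_index,
#'   shuttle_time (NA for failures), failed) and `truth` (data.frame:
#'   animal_id, phenotype).
#' @export
gen_behavior_cohort <- function(params) {
  stopifnot(inherits(params, "behavior_sim_params"))
  set.seed(params$seed)
  n <- params$n_animals
  phen <- ifelse(stats::runif(n) < params$p_helpless, "helpless", "resilient")
  ids <- sprintf("m%03d", seq_len(n))
  nt <- params$n_trials
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- phen[i]
    failed <- stats::runif(nt) < params$failure_rates[[p]]
    # shuttle time from cue onset: 5 s cue + truncated-normal escape latency
    st <- 5 + rtruncnorm(nt, params$latency_means[[p]], params$latency_sds[[p]],
                         lo = -5, hi = 10)   # allows avoidances (< 5 s)
    st[failed] <- NA_real_
    out[[i]] <- data.frame(animal_id = ids[i], trial_index = seq_len(nt),
                           shuttle_time = st, failed = failed,
                           stringsAsFactors = FALSE)
  }
  list(trials = do.call(rbind, out),
       truth = data.frame(animal_id = ids, phenotype = phen,
                          stringsAsFactors = FALSE))
}

# inverse-CDF truncated normal on the absolute interval [lo, hi]
rtruncnorm <- function(n, mean, sd, lo, hi) {
  a <- stats::pnorm((lo - mean) / sd)
  b <- stats::pnorm((hi - mean) / sd)
  pmin(hi, pmax(lo, mean + sd * stats::qnorm(a + stats::runif(n) * (b - a))))
}

#' Generate paired region-count matrices with known signal regions
#'
#' Draws an animals-by-regions matrix of negative-binomial counts under the
#' paired design: `log mu = log(baseline) + pair offset + group effect +
#' animal noise`, with the group effect applied in `signal_regions` only.
#' With the default direction the resilient animal of each pair has the
#' higher mean, so the population mean ratio resilient/helpless is exactly
#' `exp(log_fold_change)` in signal regions.
#'
#' @param params a [count_sim_params()] object.
#' @return list with `counts` (integer matrix, rownames animal ids, colnames
#'   region acronyms `r001`...), `design` (data.frame: animal_id, pair_id,
#'   group) and `truth` (data.frame: region, is_signal, log_fold_change,
#'   direction).
#' @export
gen_region_counts <- function(params) {
  stopifnot(inherits(params, "count_sim_params"))
  set.seed(params$seed)
  np <- params$n_pairs; nr <- params$n_regions
  n <- 2L * np
  regions <- sprintf("r%03d", seq_len(nr))
  group <- rep(c("helpless", "resilient"), np)
  pair <- rep(sprintf("p%02d", seq_len(np)), each = 2)
  ids <- paste0(pair, "_", substr(group, 1, 1))
  base <- rep_len(params$baseline_mean, nr)
  if (params$profile_sd > 0)
    base <- base * exp(stats::rnorm(nr, 0, params$profile_sd))
  b <- rep(stats::rnorm(np, 0, params$pair_sd), each = 2)

  lfc <- numeric(nr)
  if (length(params$signal_regions)) {
    sgn <- ifelse(params$signal_direction == "R_high", 1, -1)
    lfc[params$signal_regions] <- params$log_fold_change * sgn
  }
  # log-mean matrix: animals x regions. The group effect deviates the
  # helpless animal from the shared baseline profile (reduced activation in
  # "R_high" regions, elevated in "LH_high" ones), so the resilient/helpless
  # population mean ratio is exactly exp(lfc) per signal region.
  logmu <- outer(b, log(base), "+")
  hel <- group == "helpless"
  logmu[hel, ] <- logmu[hel, ] - matrix(lfc, sum(hel), nr, byrow = TRUE)
  ssd <- ifelse(hel, params$stereotypy_sd[["helpless"]],
                params$stereotypy_sd[["resilient"]])
  if (any(ssd > 0))
    logmu <- logmu + matrix(stats::rnorm(n * nr, 0, rep(ssd, nr)), n, nr)

  mu <- exp(logmu)
  counts <- if (params$dispersion == 0) {
    matrix(stats::rpois(n * nr, mu), n, nr)
  } else {
    matrix(stats::rnbinom(n * nr, size = 1 / params$dispersion, mu = mu), n, nr)
  }
  dimnames(counts) <- list(ids, regions)
  storage.mode(counts) <- "integer"
  direction <- rep(NA_character_, nr)
  direction[params$signal_regions] <- params$signal_direction
  list(counts = counts,
       design = data.frame(animal_id = ids, pair_id = pair, group = group,
                           stringsAsFactors = FALSE),
       truth = data.frame(region = regions,
                          is_signal = seq_len(nr) %in% params$signal_regions,
                          log_fold_change = lfc, direction = direction,
                          stringsAsFactors = FALSE))
}

#' Generate a synthetic cell cloud and its label atlas
#'
#' Places centroids uniformly inside each region's box with counts
#' `Poisson(cells_per_region * scaling)` and rasterizes the layout into an
#' integer label volume (a voxel gets a region's label when its centre falls
#' inside that region's box; 0 is background).
#'
#' @param params a [cloud_sim_params()] object.
#' @param per_animal_intensity per-region multiplicative scaling of the
#'   expected counts (scalar or one value per region).
#' @return list with `cloud` (data.frame: x_um, y_um, z_um, region label) and
#'   `atlas` (list: labels 3D integer array, spacing, label_map).
#' @export
gen_cell_cloud <- function(params, per_animal_intensity = 1) {
  stopifnot(inherits(params, "cloud_sim_params"))
  set.seed(params$seed)
  boxes <- params$region_layout
  labs <- as.integer(names(boxes))
  scal <- rep_len(per_animal_intensity, length(boxes))
  pts <- vector("list", length(boxes))
  for (i in seq_along(boxes)) {
    m <- stats::rpois(1, params$cells_per_region[i] * scal[i])
    b <- boxes[[i]]
    pts[[i]] <- data.frame(
      x_um = stats::runif(m, b[1, 1], b[2, 1]),
      y_um = stats::runif(m, b[1, 2], b[2, 2]),
      z_um = stats::runif(m, b[1, 3], b[2, 3]),
      region = rep(labs[i], m))
  }
  cloud <- do.call(rbind, pts)
  rownames(cloud) <- NULL

  dims <- params$volume_shape; sp <- params$voxel_size
  vol <- array(0L, dim = dims)
  ctr <- lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * sp[a])
  for (i in seq_along(boxes)) {
    b <- boxes[[i]]
    ix <- which(ctr[[1]] >= b[1, 1] & ctr[[1]] <= b[2, 1])
    iy <- which(ctr[[2]] >= b[1, 2] & ctr[[2]] <= b[2, 2])
    iz <- which(ctr[[3]] >= b[1, 3] & ctr[[3]] <= b[2, 3])
    vol[ix, iy, iz] <- labs[i]
  }
  list(cloud = cloud,
       atlas = label_atlas(vol, sp,
                           stats::setNames(paste0("reg", labs), labs)))
}
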