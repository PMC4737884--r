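test_that("behavior cohort generation is reproducible and honours the mixture", {
  p <- behavior_sim_params(n_animals = 30, p_helpless = 0.3, seed = 7)
  a <- gen_behavior_cohort(p)
  b <- gen_behavior_cohort(p)
  expect_identical(a, b)

  # degenerate mixture
  p0 <- behavior_sim_params(n_animals = 25, p_helpless = 0, seed = 1)
  expect_true(all(gen_behavior_cohort(p0)$truth$phenotype == "resilient"))

  # helpless fraction concentrates near p_helpless
  pbig <- behavior_sim_params(n_animals = 10000, p_helpless = 0.22, seed = 11)
  frac <- mean(gen_behavior_cohort(pbig)$truth$phenotype == "helpless")
  expect_lt(abs(frac - 0.22), 0.01)
})

test_that("behavior trials carry a latency in [0, 15) or a failure flag", {
  coh <- gen_behavior_cohort(behavior_sim_params(n_animals = 20, seed = 3))
  tr <- coh$trials
  expect_equal(nrow(tr), 20 * 35)
  expect_true(all(table(tr$animal_id) == 35))
  ok <- ifelse(tr$failed, is.na(tr$shuttle_time),
               tr$shuttle_time >= 0 & tr$shuttle_time < 15)
  expect_true(all(ok))
})

test_that("behavior_sim_params rejects invalid parameters", {
  expect_error(behavior_sim_params(n_animals = 10, p_helpless = 1.2), "p_helpless")
  expect_error(behavior_sim_params(n_animals = -3), "n_animals")
  expect_error(behavior_sim_params(n_animals = 10, n_trials = 4), "n_trials")
  expect_error(behavior_sim_params(n_animals = 10,
                                   latency_means = c(resilient = 1, helpless = 12)),
               "latency_means")
})

test_that("region counts honour the paired design and are reproducible", {
  p <- count_sim_params(n_pairs = 11, n_regions = 1, baseline_mean = 100, seed = 5)
  sim <- gen_region_counts(p)
  expect_identical(dim(sim$counts), c(22L, 1L))
  expect_identical(sim$counts, gen_region_counts(p)$counts)
  expect_true(all(sim$counts >= 0))
  expect_true(is.integer(sim$counts))
  expect_true(all(table(sim$design$pair_id, sim$design$group) == 1))
})

test_that("generated counts satisfy the NB moment relation", {
  # iid draws (no pair offsets): var ~= mu + dispersion * mu^2
  p <- count_sim_params(n_pairs = 500, n_regions = 100, baseline_mean = 50,
                        dispersion = 0.3, pair_sd = 0, seed = 2)
  y <- as.vector(gen_region_counts(p)$counts)    # 1e5 draws
  mu <- mean(y)
  expect_lt(abs(mu - 50) / 50, 0.02)
  expect_lt(abs(var(y) - (mu + 0.3 * mu^2)) / (mu + 0.3 * mu^2), 0.05)

  # Poisson limit: variance ~= mean
  p0 <- count_sim_params(n_pairs = 500, n_regions = 100, baseline_mean = 50,
                         dispersion = 0, pair_sd = 0, seed = 3)
  y0 <- as.vector(gen_region_counts(p0)$counts)
  expect_lt(abs(var(y0) / mean(y0) - 1), 0.05)
})

test_that("group mean ratio converges to exp(log_fold_change)", {
  # null: ratio -> 1
  p <- count_sim_params(n_pairs = 500, n_regions = 20, log_fold_change = 0,
                        seed = 4)
  sim <- gen_region_counts(p)
  res <- sim$design$group == "resilient"
  ratio <- colMeans(sim$counts[res, ]) / colMeans(sim$counts[!res, ])
  expect_true(all(abs(ratio - 1) < 0.15))

  # signal regions: ratio -> exp(lfc), with per-region sign override
  ps <- count_sim_params(n_pairs = 500, n_regions = 4, signal_regions = 1:2,
                         log_fold_change = 0.7,
                         signal_direction = c("R_high", "LH_high"), seed = 6)
  sims <- gen_region_counts(ps)
  res <- sims$design$group == "resilient"
  ratio <- colMeans(sims$counts[res, ]) / colMeans(sims$counts[!res, ])
  expect_lt(abs(ratio[1] - exp(0.7)) / exp(0.7), 0.15)
  expect_lt(abs(ratio[2] - exp(-0.7)) / exp(-0.7), 0.15)
  expect_identical(sims$truth$is_signal, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(sims$truth$direction[1:2], c("R_high", "LH_high"))
  expect_equal(sims$truth$log_fold_change, c(0.7, -0.7, 0, 0))
})

test_that("cell cloud generation respects layout, scaling and determinism", {
  layout <- list(`1` = rbind(c(100, 100, 50), c(400, 400, 250)),
                 `2` = rbind(c(500, 450, 100), c(900, 800, 280)))
  p <- cloud_sim_params(c(20, 20, 6), 50, layout, cells_per_region = 80, seed = 9)
  cc <- gen_cell_cloud(p)
  expect_identical(cc$cloud, gen_cell_cloud(p)$cloud)

  # constructive property: every centroid inside its region's box
  for (lab in c(1, 2)) {
    b <- layout[[as.character(lab)]]
    pt <- cc$cloud[cc$cloud$region == lab, ]
    expect_true(all(pt$x_um >= b[1, 1] & pt$x_um <= b[2, 1]))
    expect_true(all(pt$y_um >= b[1, 2] & pt$y_um <= b[2, 2]))
    expect_true(all(pt$z_um >= b[1, 3] & pt$z_um <= b[2, 3]))
  }
  # atlas voxels inside box 1 carry label 1
  expect_identical(cc$atlas$labels[4, 4, 3], 1L)   # centre (175, 175, 125)
  expect_identical(cc$atlas$labels[1, 1, 1], 0L)   # background corner

  # empty cloud
  p0 <- cloud_sim_params(c(20, 20, 6), 50, layout, cells_per_region = 0, seed = 1)
  expect_equal(nrow(gen_cell_cloud(p0)$cloud), 0)

  # overlapping boxes rejected
  bad <- list(`1` = rbind(c(0, 0, 0), c(200, 200, 100)),
              `2` = rbind(c(100, 100, 50), c(300, 300, 150)))
  expect_error(cloud_sim_params(c(20, 20, 6), 50, bad), "overlap")
})

test_that("doubling the intensity scaling doubles expected cell counts", {
  layout <- list(`1` = rbind(c(0, 0, 0), c(500, 500, 250)))
  n1 <- n2 <- numeric(500)
  for (i in seq_len(500)) {
    p1 <- cloud_sim_params(c(10, 10, 5), 50, layout, cells_per_region = 20,
                           seed = 1000 + i)
    n1[i] <- nrow(gen_cell_cloud(p1, per_animal_intensity = 1)$cloud)
    n2[i] <- nrow(gen_cell_cloud(p1, per_animal_intensity = 2)$cloud)
  }
  # Poisson means 20 and 40: ratio of averages within MC error
  expect_lt(abs(mean(n2) / mean(n1) - 2), 0.15)
})
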