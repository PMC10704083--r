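test_that("default design matches the measurement protocol", {
  design <- default_design()
  configs <- design$configs
  expect_equal(nrow(configs), 30)
  expect_equal(sum(configs$illumination == "tracheal"), 15)
  expect_equal(sum(configs$illumination == "dermal"), 15)
  expect_equal(design$replicates, 21L)
  expect_equal(design$concentrations, c(0.21, 0.30, 0.50, 1.00))
  expect_false(any(duplicated(configs$config_id)))
  # repeated-position reproducibility pairs share one physical truth
  for (arm in c("tracheal", "dermal")) {
    a <- configs[configs$illumination == arm, ]
    expect_identical(a$truth_key[a$detector_position == 10],
                     a$truth_key[a$detector_position == 11])
    expect_identical(a$truth_key[a$detector_position == 14],
                     a$truth_key[a$detector_position == 15])
    same <- a[a$detector_position %in% c(10, 11),
              c("geometry", "phantom_props", "side")]
    expect_identical(same[1, ], same[2, ])
  }
})

test_that("sampled truth is deterministic, in-support and shared across repeats", {
  design <- default_design()
  t1 <- sample_truth(design, seed = 99)
  t2 <- sample_truth(design, seed = 99)
  expect_identical(t1$true_pathlength_m, t2$true_pathlength_m)
  expect_identical(t1$tissue_transmission, t2$tissue_transmission)
  expect_true(all(t1$true_pathlength_m > 0.01 &
                    t1$true_pathlength_m < 0.20))
  tr <- t1[t1$illumination == "tracheal", ]
  expect_equal(tr$true_pathlength_m[tr$detector_position == 10],
               tr$true_pathlength_m[tr$detector_position == 11])
  # dark configurations sit far below any plausible transmission
  expect_equal(sum(t1$tissue_transmission < 1e-6 &
                     !duplicated(t1$truth_key)), 2)
})

test_that("muscle effective attenuation follows diffusion theory and the phantom table", {
  expect_equal(tissue_mu_eff("muscle", 764), sqrt(3 * 0.20 * (0.20 + 14.1)))
  expect_equal(tissue_mu_eff("muscle", 820), sqrt(3 * 0.20 * (0.20 + 12.8)))
  expect_error(tissue_mu_eff("liver", 764), "unknown")
  props <- tissue_optical_properties()
  expect_equal(nrow(props), 10)
  expect_true(all(props$mu_a > 0 & props$mu_s_prime > 0))
})

test_that("gas-mixing bias follows the carry-over recursion", {
  nominal <- c(0.21, 0.30, 0.50, 1.00)
  expect_identical(apply_mixing_bias(nominal, 0), nominal)
  expect_equal(apply_mixing_bias(nominal, 0.2),
               c(0.21, 0.282, 0.4564, 0.89128), tolerance = 1e-12)
  set.seed(7)
  for (i in 1:5) {
    seq_up <- sort(runif(4, 0.21, 1))
    eff <- apply_mixing_bias(seq_up, runif(1, 0.05, 0.9), anchor = seq_up[1])
    expect_true(all(eff <= seq_up + 1e-12))
  }
})

test_that("noiseless scans carry the exact Beer-Lambert gas imprint", {
  design <- default_design(n_tracheal = 1, n_dermal = 1, replicates = 1,
                           concentrations = 0.30)
  truth <- sample_truth(design, seed = 21, n_dark = 0)
  ds <- simulate_experiment(design, truth, noise_rel = 0, master_seed = 21)
  cond <- ds$params$conditions
  grid <- default_grid()
  for (i in seq_len(nrow(ds$scans))) {
    row <- ds$scans[i, ]
    tr <- truth[truth$config_id == row$config_id, ]
    baseline <- gasmas:::scan_baseline(grid) * tr$tissue_transmission
    mu <- gasmas:::channel_mu_a(row$channel, row$o2_effective, cond,
                                gasmas:::default_lines(), grid)
    expect_equal(log(baseline / row$intensity[[1]]),
                 mu * tr$true_pathlength_m * 100, tolerance = 1e-10)
  }
})

test_that("tissue transmission scales intensity but not line depth", {
  design <- default_design(n_tracheal = 1, n_dermal = 1, replicates = 1,
                           concentrations = 0.21)
  t1 <- sample_truth(design, seed = 3, n_dark = 0)
  t2 <- t1
  t2$tissue_transmission <- t1$tissue_transmission / 10
  d1 <- simulate_experiment(design, t1, noise_rel = 0, master_seed = 3)
  d2 <- simulate_experiment(design, t2, noise_rel = 0, master_seed = 3)
  i1 <- d1$scans$intensity[[1]]
  i2 <- d2$scans$intensity[[1]]
  expect_equal(i1 / i2, rep(10, length(i1)))
  # relative line depth is identical
  expect_equal(min(i1) / max(i1), min(i2) / max(i2), tolerance = 1e-12)
})

test_that("simulation is deterministic and per-record reproducible", {
  h <- tiny_dataset(noise_rel = 1e-5, seed = 31)
  h2 <- tiny_dataset(noise_rel = 1e-5, seed = 31)
  expect_identical(h$dataset$scans$intensity, h2$dataset$scans$intensity)

  scans <- h$dataset$scans
  # replicates differ, as independent detector reattachments must
  a <- scans[scans$replicate == 1 & scans$channel == 820, ]$intensity[[1]]
  b <- scans[scans$replicate == 2 & scans$channel == 820, ]$intensity[[1]]
  expect_false(identical(a, b))

  # any single record regenerates in isolation from its derived seed
  row <- scans[17, ]
  tr <- h$truth[h$truth$config_id == row$config_id, ]
  seed <- record_seed(31, row$config_id, row$replicate, row$o2_nominal,
                      row$channel)
  expect_identical(seed, row$seed_used)
  rec <- simulate_scan(tr, channel = row$channel, replicate = row$replicate,
                       o2_fraction = row$o2_effective, noise_rel = 1e-5,
                       seed = seed)
  expect_identical(rec$intensity[[1]], row$intensity[[1]])
})

test_that("experiment size follows the design arithmetic", {
  h <- tiny_dataset(n_configs = 3, replicates = 2,
                    concentrations = c(0.21, 0.50, 1.00))
  # 6 configs x 2 replicates x 3 concentrations x 2 channels
  expect_equal(nrow(h$dataset$scans), 6 * 2 * 3 * 2)
  # truth sidecar: one row per config x concentration, constant pathlength
  sidecar <- h$dataset$truth
  expect_equal(nrow(sidecar), 6 * 3)
  per_config <- tapply(sidecar$true_pathlength_m, sidecar$config_id,
                       function(v) length(unique(v)))
  expect_true(all(per_config == 1))

  design <- default_design(replicates = 3L)
  truth <- sample_truth(design, seed = 1)
  ds <- simulate_experiment(design, truth, noise_rel = 0, master_seed = 1)
  expect_equal(nrow(ds$scans), 30 * 3 * 4 * 2)
})

test_that("intensities below the floor are clipped and flagged", {
  design <- default_design(n_tracheal = 1, n_dermal = 1, replicates = 1,
                           concentrations = 0.21)
  truth <- sample_truth(design, seed = 5, n_dark = 0)
  truth$tissue_transmission <- 1e-8
  ds <- simulate_experiment(design, truth, noise_rel = 1e-5, master_seed = 5)
  expect_true(all(ds$scans$clipped))
  expect_true(all(vapply(ds$scans$intensity, min, 1) >= 1e-6))
})
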