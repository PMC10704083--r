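cond_default <- ambient_conditions()

make_scan <- function(pathlength_m, channel = 820, o2 = 0.21,
                      transmission = 0.05, noise_rel = 0, seed = 1) {
  truth <- tibble::tibble(config_id = "t_01",
                          true_pathlength_m = pathlength_m,
                          tissue_transmission = transmission)
  simulate_scan(truth, channel = channel, replicate = 1, o2_fraction = o2,
                noise_rel = noise_rel, seed = seed)
}

test_that("absorbance fit recovers a known noiseless absorbance to 1e-6", {
  mu_peak <- peak_water_mu_a(cond_default)
  target_a <- 3.1e-4
  pathlength <- target_a / mu_peak / 100
  scan <- make_scan(pathlength)
  fit <- extract_absorbance(scan, h2o_line_820(), cond_default)
  expect_true(fit$converged)
  expect_lt(abs(fit$peak_absorbance - target_a), 1e-6)
  expect_lt(fit$residual_rms, 1e-12)
  td <- tidy(fit)
  expect_identical(td$term[1], "peak_absorbance")
  expect_equal(nrow(td), 4)
  expect_true(glance(fit)$converged)
})

test_that("zero-gas and baseline-only scans yield near-zero, flagged absorbance", {
  scan0 <- make_scan(0)
  fit0 <- extract_absorbance(scan0, h2o_line_820(), cond_default)
  expect_lt(fit0$peak_absorbance, 1e-8)

  noisy <- make_scan(0, noise_rel = 1e-5, seed = 42)
  fitn <- extract_absorbance(noisy, h2o_line_820(), cond_default)
  expect_lt(fitn$peak_absorbance, 3 * 1e-5)
  expect_lt(fitn$snr, 3)
  expect_false(fitn$detected)
})

test_that("pathlength inversion divides by the humidity reference", {
  mu_peak <- peak_water_mu_a(cond_default)
  expect_equal(estimate_pathlength(mu_peak * 100 * 0.1, cond_default), 0.1)
  expect_equal(estimate_pathlength(0, cond_default), 0)
  a <- 2.5e-4
  expect_equal(estimate_pathlength(2 * a, cond_default),
               2 * estimate_pathlength(a, cond_default))
  dry <- ambient_conditions(relative_humidity = 0)
  expect_error(estimate_pathlength(a, dry), "humidity reference")
  expect_error(estimate_pathlength(-1, cond_default))
})

test_that("oxygen estimate is a shared-pathlength Beer-Lambert division", {
  kappa <- peak_oxygen_mu_a_per_fraction(cond_default)
  l <- 0.08
  a <- 0.21 * kappa * l * 100
  expect_equal(estimate_o2(a, l, cond_default), 0.21)
  expect_equal(estimate_o2(0, l, cond_default), 0)
  expect_equal(estimate_o2(a, l / 2, cond_default), 0.42)
  expect_true(is.na(estimate_o2(a, 0, cond_default)))
})

test_that("record inversion round-trips simulated truth within 1 percent", {
  s764 <- make_scan(0.05, channel = 764, o2 = 0.30)
  s820 <- make_scan(0.05, channel = 820, o2 = 0.30)
  est <- invert_record(s764, s820)
  expect_true(est$valid)
  expect_equal(est$pathlength_m, 0.05, tolerance = 0.01)
  expect_equal(est$o2_fraction, 0.30, tolerance = 0.01)

  other <- make_scan(0.05, channel = 764)
  other$config_id <- "other"
  expect_error(invert_record(other, s820), "config_id")
  expect_error(invert_record(s820, s764), "channel")
})

test_that("a dark 820 channel maps to pathlength zero and an invalid estimate", {
  s764 <- make_scan(0.05, channel = 764, transmission = 1e-8,
                    noise_rel = 1e-5)
  s820 <- make_scan(0.05, channel = 820, transmission = 1e-8,
                    noise_rel = 1e-5)
  est <- invert_record(s764, s820)
  expect_false(est$valid)
  expect_equal(est$pathlength_m, 0)
  expect_true(is.na(est$o2_fraction))
  expect_match(est$failure_reason, "clipped|820")
})

test_that("noiseless recovery holds over the pathlength-concentration grid", {
  mu_peak <- peak_water_mu_a(cond_default)
  for (l in c(0.02, 0.10, 0.20)) {
    for (conc in c(0.21, 1.00)) {
      s764 <- make_scan(l, channel = 764, o2 = conc)
      s820 <- make_scan(l, channel = 820, o2 = conc)
      est <- invert_record(s764, s820)
      expect_lt(abs(est$pathlength_m - l) / l, 0.01)
      expect_lt(abs(est$o2_fraction - conc) / conc, 0.01)
    }
  }
})

test_that("replicate scatter grows as tissue transmission falls", {
  sd_for <- function(transmission, n = 60) {
    ests <- vapply(seq_len(n), function(k) {
      scan <- make_scan(0.08, channel = 820, transmission = transmission,
                        noise_rel = 1e-5, seed = 1000 + k)
      fit <- extract_absorbance(scan, h2o_line_820(), cond_default)
      fit$peak_absorbance
    }, numeric(1))
    stats::sd(ests)
  }
  expect_gt(sd_for(1.2e-4), 1.5 * sd_for(0.15))
})

test_that("dataset-level inversion matches record-level inversion", {
  h <- tiny_dataset(noise_rel = 1e-5, seed = 77)
  est <- invert_scans(h$dataset)
  expect_equal(nrow(est), 4 * 3 * 2)
  row <- h$dataset$scans[h$dataset$scans$config_id == "dermal_01" &
                           h$dataset$scans$replicate == 2 &
                           h$dataset$scans$o2_nominal == 0.21, ]
  single <- invert_record(row[row$channel == 764, ],
                          row[row$channel == 820, ],
                          conditions = h$dataset$params$conditions)
  batch <- est[est$config_id == "dermal_01" & est$replicate == 2 &
                 est$o2_nominal == 0.21, ]
  expect_equal(batch$pathlength_m, single$pathlength_m, tolerance = 1e-12)
  expect_equal(batch$o2_fraction, single$o2_fraction, tolerance = 1e-12)
})
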