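make_estimates <- function(pathlengths, valid = TRUE, o2 = NA_real_,
                           config = "c1") {
  tibble::tibble(
    config_id = config, replicate = seq_along(pathlengths),
    o2_nominal = 0.21, pathlength_m = pathlengths,
    o2_fraction = if (length(o2) == 1) rep(o2, length(pathlengths)) else o2,
    valid = valid, outlier = FALSE, failure_reason = NA_character_
  )
}

test_that("the pathlength outlier rule uses a strict upper bound at 0.23 m", {
  est <- make_estimates(c(0, 0.10, 0.229, 0.230, 0.231))
  flagged <- flag_outliers(est)
  expect_identical(flagged$outlier, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  # idempotent and order-independent
  expect_identical(flag_outliers(flagged)$outlier, flagged$outlier)
  perm <- sample(nrow(est))
  expect_identical(flag_outliers(est[perm, ])$outlier,
                   flagged$outlier[perm])
  # failed inversions are outliers regardless of pathlength
  est2 <- make_estimates(c(0.1, 0.1), valid = c(TRUE, FALSE))
  expect_identical(flag_outliers(est2)$outlier, c(FALSE, TRUE))
})

test_that("replicate aggregation excludes outliers and survives empty cells", {
  est <- make_estimates(rep(0.1, 21))
  s <- aggregate_replicates(flag_outliers(est))
  expect_equal(s$mean_pathlength_m, 0.1)
  expect_equal(s$sd_pathlength_m, 0)
  expect_equal(s$n_used, 21)

  est2 <- flag_outliers(make_estimates(c(0.1, 0.1, 0.25)))
  s2 <- aggregate_replicates(est2)
  expect_equal(s2$n_outliers, 1)
  expect_equal(s2$mean_pathlength_m, 0.1)

  est3 <- flag_outliers(make_estimates(c(0, 0.5)))
  s3 <- aggregate_replicates(est3)
  expect_true(s3$empty)
  expect_true(is.na(s3$mean_pathlength_m))

  # mean stays inside the range of included values
  set.seed(12)
  est4 <- flag_outliers(make_estimates(runif(50, 0, 0.3)))
  s4 <- aggregate_replicates(est4)
  used <- est4$pathlength_m[!est4$outlier]
  expect_gte(s4$mean_pathlength_m, min(used))
  expect_lte(s4$mean_pathlength_m, max(used))
})

test_that("KS statistic handles degenerate and disjoint samples", {
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$d_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$comparable)
  apart <- ks_two_sample(c(1, 2), c(3, 4))
  expect_equal(apart$d_statistic, 1)
  expect_error(ks_two_sample(numeric(0), 1:3), "at least one")
  td <- tidy(apart)
  expect_named(td, c("statistic", "p.value", "n1", "n2", "comparable"))
})

test_that("KS D matches both stats::ks.test and exhaustive enumeration", {
  set.seed(202)
  for (i in 1:15) {
    x <- rnorm(sample(5:25, 1))
    y <- rnorm(sample(5:25, 1), mean = runif(1, 0, 1))
    ours <- ks_two_sample(x, y)
    ref <- suppressWarnings(stats::ks.test(x, y))
    expect_equal(ours$d_statistic, unname(ref$statistic), tolerance = 1e-12)
  }
  for (i in 1:10) {
    x <- runif(sample(3:6, 1))
    y <- runif(sample(3:6, 1))
    ours <- ks_two_sample(x, y)
    oracle <- ks_permutation(x, y)
    expect_equal(ours$d_statistic, oracle$d, tolerance = 1e-12)
  }
})

test_that("KS D is invariant under strictly monotone transforms", {
  set.seed(303)
  x <- rgamma(12, 2)
  y <- rgamma(17, 3)
  base <- ks_two_sample(x, y)$d_statistic
  for (f in list(function(v) 3 * v + 2, exp, function(v) v^3, log1p)) {
    expect_equal(ks_two_sample(f(x), f(y))$d_statistic, base,
                 tolerance = 1e-12)
  }
})

test_that("asymptotic p tracks the exact distribution at replicate-sized samples", {
  set.seed(404)
  for (i in 1:20) {
    x <- rnorm(21)
    y <- rnorm(21, mean = runif(1, 0, 0.8))
    ours <- ks_two_sample(x, y)
    exact <- stats::ks.test(x, y, exact = TRUE)$p.value
    expect_lt(abs(ours$p_value - exact), 0.08)
  }
})

test_that("configuration comparisons separate distinct truths and pass identical ones", {
  set.seed(505)
  n_runs <- 50
  comparable <- logical(n_runs)
  for (i in seq_len(n_runs)) {
    x <- rnorm(21, 0.10, 0.002)
    y <- rnorm(21, 0.10, 0.002)
    comparable[i] <- ks_two_sample(x, y)$comparable
  }
  expect_gte(mean(comparable), 0.9)

  far <- ks_two_sample(rnorm(21, 0.05, 0.002), rnorm(21, 0.15, 0.002))
  expect_false(far$comparable)

  x <- rnorm(21, 0.1, 0.01)
  self <- ks_two_sample(x, x)
  expect_equal(self$p_value, 1)
})

test_that("compare_configurations pairs groups within cells and validates columns", {
  set.seed(606)
  est <- tibble::tibble(
    config_id = rep(c("a", "b"), each = 30),
    o2_nominal = rep(rep(c(0.21, 0.30, 0.50), each = 10), 2),
    pathlength_m = c(rnorm(30, 0.10, 0.003),
                     c(rnorm(10, 0.05, 0.003), rnorm(10, 0.15, 0.003),
                       rnorm(10, 0.15, 0.003)))
  )
  out <- compare_configurations(est, group = o2_nominal,
                                value = pathlength_m, within = config_id)
  expect_equal(nrow(out), 6)  # 3 pairs per config
  a_rows <- out[out$config_id == "a", ]
  expect_true(all(a_rows$comparable))
  b_apart <- out[out$config_id == "b" & out$group1 == 0.21, ]
  expect_true(all(!b_apart$comparable))
  expect_error(compare_configurations(est, group = nope),
               "unknown pairing column")
  # Holm correction never decreases p-values
  holm <- compare_configurations(est, group = o2_nominal,
                                 value = pathlength_m, within = config_id,
                                 p_adjust = "holm")
  expect_true(all(holm$p_adjusted >= out$p_value - 1e-15))
})

test_that("box statistics follow the linear-interpolation quantile convention", {
  single <- concentration_boxes(
    tibble::tibble(o2_fraction = 0.5, o2_nominal = 0.5))
  expect_equal(unlist(single[, c("median", "q1", "q3", "whisker_low",
                                 "whisker_high")], use.names = FALSE),
               rep(0.5, 5))

  hundred <- concentration_boxes(
    tibble::tibble(o2_fraction = as.numeric(1:100), o2_nominal = 1))
  expect_equal(hundred$median, 50.5)
  expect_equal(hundred$q1, 25.75)
  expect_equal(hundred$q3, 75.25)

  with_out <- concentration_boxes(
    tibble::tibble(o2_fraction = c(rnorm(30, 0.5, 0.01), 2), o2_nominal = 1))
  expect_equal(with_out$outlier_values[[1]], 2)
  expect_lte(with_out$whisker_high, with_out$q3 + 1.5 * (with_out$q3 - with_out$q1))
  expect_gte(with_out$whisker_low, with_out$q1 - 1.5 * (with_out$q3 - with_out$q1))
})
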