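# Independent oracles used across test files.

# Voigt profile by brute-force numerical convolution of Gaussian and
# Lorentzian densities (independent of the Faddeeva route).
voigt_by_quadrature <- function(x, gaussian_sigma, lorentz_hwhm) {
  vapply(x, function(xx) {
    stats::integrate(
      function(u) {
        stats::dnorm(u, sd = gaussian_sigma) *
          (lorentz_hwhm / pi) / ((xx - u)^2 + lorentz_hwhm^2)
      },
      -Inf, Inf, rel.tol = 1e-12, abs.tol = 0
    )$value
  }, numeric(1))
}

# Exact two-sample KS permutation distribution by exhaustive enumeration of
# all assignments of the pooled sample.
ks_permutation <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  d_obs <- max(abs(stats::ecdf(x)(sort(pooled)) -
                     stats::ecdf(y)(sort(pooled))))
  idx <- utils::combn(n1 + n2, n1)
  grid <- sort(pooled)
  d_all <- apply(idx, 2, function(ii) {
    max(abs(stats::ecdf(pooled[ii])(grid) - stats::ecdf(pooled[-ii])(grid)))
  })
  list(d = d_obs, p = mean(d_all >= d_obs - 1e-12))
}

# Small simulated dataset shared by inversion/QC tests.
tiny_dataset <- function(n_configs = 2L, replicates = 3L,
                         concentrations = c(0.21, 1.00), noise_rel = 0,
                         seed = 11L, n_dark = 0L, beta = 0) {
  design <- default_design(n_tracheal = n_configs, n_dermal = n_configs,
                           replicates = replicates,
                           concentrations = concentrations)
  truth <- sample_truth(design, seed = seed, n_dark = n_dark)
  dataset <- simulate_experiment(design, truth, noise_rel = noise_rel,
                                 beta = beta, master_seed = seed)
  list(design = design, truth = truth, dataset = dataset)
}
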