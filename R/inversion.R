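# Direct-absorption inversion: peak absorbance -> pathlength -> O2 fraction.
#
# The fit model is a multiplicative polynomial baseline times a Beer-Lambert
# line imprint, I(dv) = B(dv) * exp(-A * psi(dv)), with psi the unit-peak
# Voigt shape implied by the ambient conditions. The absorbance A is profiled
# out by 1-D minimisation: for fixed A the baseline is a linear least-squares
# solve, so the optimiser never sees more than one dimension and cannot
# diverge on noisy data.

#' Fit peak absorbance from one scan
#'
#' Least-squares fit of `I = B(dv) * exp(-A * psi(dv))` with a polynomial
#' baseline `B` (default order 2) and the unit-peak Voigt shape `psi` of the
#' given line at the given conditions. Returns the fitted peak absorbance
#' `A = ln(I0/I)` at line centre together with fit diagnostics. Negative
#' optima beyond a small tolerance are clipped to zero and flagged as
#' non-converged; the function never raises on noisy data.
#'
#' @param scan a one-row scans tibble (list-columns `detuning`, `intensity`)
#'   or a list with `detuning` and `intensity` vectors.
#' @param line the [spectral_line()] scanned by this channel.
#' @param conditions an [ambient_conditions()] object.
#' @param baseline_order polynomial order of the baseline.
#' @param snr_threshold detection threshold on the fitted line depth over the
#'   residual RMS.
#' @return an object of class `absorbance_fit` with elements
#'   `peak_absorbance`, `baseline_coefficients`, `residual_rms`, `snr`,
#'   `converged`, `reason`, `n_points`.
#' @export
extract_absorbance <- function(scan, line, conditions,
                               baseline_order = 2L, snr_threshold = 3) {
  stopifnot(inherits(line, "spectral_line"),
            inherits(conditions, "ambient_conditions"))
  detuning <- if (is.list(scan$detuning)) scan$detuning[[1]] else scan$detuning
  intensity <- if (is.list(scan$intensity)) scan$intensity[[1]] else scan$intensity
  sigma_g <- doppler_sigma(line, conditions$temperature)
  gamma_l <- lorentz_hwhm_at(line, conditions$pressure)
  psi <- voigt_profile(detuning, sigma_g, gamma_l) /
    voigt_peak(sigma_g, gamma_l)
  fit_absorbance_core(detuning, intensity, psi,
                      baseline_order = baseline_order,
                      snr_threshold = snr_threshold)
}

# Core fit on a precomputed unit-peak line shape. Profiles the baseline out:
# for fixed A, minimising ||I * exp(A psi) - X beta||^2 is linear in beta.
fit_absorbance_core <- function(detuning, intensity, psi,
                                baseline_order = 2L, snr_threshold = 3,
                                a_interval = c(-0.05, 0.5),
                                negative_tolerance = 1e-6) {
  stopifnot(length(detuning) == length(intensity),
            length(psi) == length(detuning))
  u <- detuning / max(abs(detuning))
  basis <- outer(u, 0:baseline_order, `^`)
  qx <- qr(basis)
  objective <- function(a) {
    y <- intensity * exp(a * psi)
    sum(qr.resid(qx, y)^2)
  }
  opt <- stats::optimize(objective, interval = a_interval, tol = 1e-10)
  a_hat <- opt$minimum
  converged <- TRUE
  reason <- NA_character_
  if (a_hat < -negative_tolerance) {
    converged <- FALSE
    reason <- "absorbance fit landed negative"
  }
  if (a_hat > a_interval[2] - 1e-3) {
    converged <- FALSE
    reason <- "absorbance fit hit the search bound"
  }
  a_clipped <- max(a_hat, 0)
  beta <- qr.coef(qx, intensity * exp(a_clipped * psi))
  fitted <- as.numeric(basis %*% beta) * exp(-a_clipped * psi)
  residual_rms <- sqrt(mean((intensity - fitted)^2))
  i_center <- which.min(abs(detuning))
  baseline_center <- sum(basis[i_center, ] * beta)
  depth <- baseline_center * (1 - exp(-a_clipped))
  snr <- if (residual_rms == 0) Inf else max(depth, 0) / residual_rms
  structure(
    list(peak_absorbance = a_clipped,
         baseline_coefficients = as.numeric(beta),
         residual_rms = residual_rms, snr = snr,
         converged = converged, reason = reason,
         detected = converged && snr >= snr_threshold,
         n_points = length(detuning)),
    class = "absorbance_fit"
  )
}

#' @export
print.absorbance_fit <- function(x, ...) {
  cat(sprintf(
    "<absorbance_fit> A = %.4g, SNR = %.3g, rms = %.3g, converged = %s\n",
    x$peak_absorbance, x$snr, x$residual_rms, x$converged))
  invisible(x)
}

#' Pathlength from water-vapour absorbance
#'
#' Beer-Lambert inversion against the saturated-water-vapour reference:
#' `l = A / mu_a_peak`, with the peak water absorption coefficient computed
#' from the ambient conditions. Returned in metres.
#'
#' @param absorbance peak absorbance on the 820 nm channel (dimensionless).
#' @param conditions an [ambient_conditions()] object.
#' @param line the H2O reference line.
#' @return gas pathlength in metres.
#' @examples
#' estimate_pathlength(3.1e-4, ambient_conditions(temperature = 293.15))
#' @export
estimate_pathlength <- function(absorbance, conditions,
                                line = h2o_line_820()) {
  stopifnot(all(absorbance >= 0))
  mu_peak <- peak_water_mu_a(conditions, line)
  if (mu_peak <= 0) {
    stop("peak water mu_a is zero (dry gas): the humidity reference is ",
         "absent and no pathlength can be inferred.", call. = FALSE)
  }
  absorbance / mu_peak / 100
}

#' Oxygen fraction from absorbance and pathlength
#'
#' Shared-pathlength Beer-Lambert step: the pathlength inferred on the 820 nm
#' channel is assumed to hold at 764 nm, so
#' `c = A / (l_cm * kappa_O2)` with `kappa_O2` the peak oxygen absorption
#' coefficient per unit mole fraction. The result is deliberately not clipped
#' to \[0, 1\]; out-of-range values are preserved for downstream screening.
#'
#' @param absorbance peak absorbance on the 764 nm channel.
#' @param pathlength gas pathlength in metres (> 0).
#' @param conditions an [ambient_conditions()] object.
#' @param line the O2 line.
#' @return O2 mole fraction (dry-gas basis); `NA` when `pathlength <= 0`.
#' @export
estimate_o2 <- function(absorbance, pathlength, conditions,
                        line = o2_line_764()) {
  stopifnot(all(absorbance >= 0))
  kappa <- peak_oxygen_mu_a_per_fraction(conditions, line)
  out <- absorbance / (pathlength * 100 * kappa)
  out[pathlength <= 0] <- NA_real_
  out
}

#' Invert one matched scan pair
#'
#' Composes the two-step inference for one (configuration, replicate,
#' concentration) cell: absorbance fits on both channels, pathlength from the
#' 820 nm channel, O2 fraction from the 764 nm channel. A failed or
#' undetected 820 nm fit maps to pathlength 0 (the "0 m" outlier class) and
#' an invalid estimate; a failed 764 nm fit leaves the pathlength but
#' invalidates the O2 estimate.
#'
#' @param scan_764,scan_820 one-row scans tibbles for the two channels of the
#'   same configuration and replicate.
#' @param conditions an [ambient_conditions()] object.
#' @param lines list with [spectral_line()] elements `h2o` and `o2`.
#' @param snr_threshold validity threshold on fitted SNR.
#' @param baseline_order polynomial baseline order.
#' @return a one-row tibble: `config_id`, `replicate`, `o2_nominal`,
#'   `pathlength_m`, `o2_fraction`, `snr_764`, `snr_820`, `valid`, `outlier`
#'   (initialised `FALSE`; see [flag_outliers()]), `failure_reason`.
#' @export
invert_record <- function(scan_764, scan_820,
                          conditions = ambient_conditions(),
                          lines = default_lines(), snr_threshold = 3,
                          baseline_order = 2L) {
  if (!identical(scan_764$config_id, scan_820$config_id) ||
      !identical(as.integer(scan_764$replicate),
                 as.integer(scan_820$replicate))) {
    stop("scan pair does not share config_id and replicate.", call. = FALSE)
  }
  if (!identical(as.integer(scan_764$channel), 764L) ||
      !identical(as.integer(scan_820$channel), 820L)) {
    stop("scans passed on the wrong channel arguments.", call. = FALSE)
  }
  fit_764 <- extract_absorbance(scan_764, lines$o2, conditions,
                                baseline_order, snr_threshold)
  fit_820 <- extract_absorbance(scan_820, lines$h2o, conditions,
                                baseline_order, snr_threshold)
  fit_764 <- mark_clipped(fit_764, scan_764)
  fit_820 <- mark_clipped(fit_820, scan_820)
  o2_nominal <- if ("o2_nominal" %in% names(scan_764)) {
    scan_764$o2_nominal
  } else {
    NA_real_
  }
  assemble_estimate(scan_764$config_id, as.integer(scan_764$replicate),
                    o2_nominal = o2_nominal,
                    fit_764, fit_820, conditions, lines)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A record clipped at the detector floor carries no trustworthy line shape:
# the flat clipped stretch can fit arbitrarily well, so the SNR is
# meaningless and the record is treated as undetected.
mark_clipped <- function(fit, scan) {
  clipped <- if ("clipped" %in% names(scan)) scan$clipped else FALSE
  if (isTRUE(clipped[[1]])) {
    fit$detected <- FALSE
    fit$reason <- "intensity clipped at the detector floor"
  }
  fit
}

assemble_estimate <- function(config_id, replicate, o2_nominal,
                              fit_764, fit_820, conditions, lines) {
  valid <- TRUE
  reason <- NA_character_
  if (fit_820$detected) {
    pathlength <- estimate_pathlength(fit_820$peak_absorbance, conditions,
                                      lines$h2o)
  } else {
    pathlength <- 0
    valid <- FALSE
    reason <- fit_820$reason %||% NA_character_
    if (is.na(reason)) reason <- "820 nm line below detection threshold"
  }
  if (valid && fit_764$detected) {
    o2 <- estimate_o2(fit_764$peak_absorbance, pathlength, conditions,
                      lines$o2)
  } else {
    o2 <- NA_real_
    if (valid) {
      valid <- FALSE
      reason <- fit_764$reason %||% NA_character_
      if (is.na(reason)) reason <- "764 nm line below detection threshold"
    }
  }
  tibble::tibble(
    config_id = config_id, replicate = replicate, o2_nominal = o2_nominal,
    pathlength_m = pathlength, o2_fraction = o2,
    snr_764 = fit_764$snr, snr_820 = fit_820$snr,
    valid = valid, outlier = FALSE, failure_reason = reason
  )
}

#' Invert every scan pair of a dataset
#'
#' Pipeline driver: pairs the 764/820 nm records of each (configuration,
#' replicate, concentration) cell and applies [invert_record()]'s logic, with
#' the Voigt line shapes computed once per channel.
#'
#' @param dataset a `gasmas_dataset` from [simulate_experiment()], or its
#'   `scans` tibble.
#' @param conditions an [ambient_conditions()] object; defaults to the
#'   dataset's own.
#' @param lines list with [spectral_line()] elements `h2o` and `o2`.
#' @param snr_threshold validity threshold on fitted SNR.
#' @param baseline_order polynomial baseline order.
#' @return a tibble of per-replicate gas estimates (see [invert_record()]).
#' @export
invert_scans <- function(dataset, conditions = NULL,
                         lines = default_lines(), snr_threshold = 3,
                         baseline_order = 2L) {
  if (inherits(dataset, "gasmas_dataset")) {
    scans <- dataset$scans
    if (is.null(conditions)) conditions <- dataset$params$conditions
  } else {
    scans <- dataset
  }
  if (is.null(conditions)) conditions <- ambient_conditions()
  stopifnot(all(c("config_id", "replicate", "channel", "detuning",
                  "intensity") %in% names(scans)))
  if (!"o2_nominal" %in% names(scans)) scans$o2_nominal <- NA_real_

  psi_for <- function(line, detuning) {
    sigma_g <- doppler_sigma(line, conditions$temperature)
    gamma_l <- lorentz_hwhm_at(line, conditions$pressure)
    voigt_profile(detuning, sigma_g, gamma_l) / voigt_peak(sigma_g, gamma_l)
  }

  keys <- paste(scans$config_id, scans$replicate, scans$o2_nominal, sep = "|")
  split_idx <- split(seq_len(nrow(scans)), keys)
  psi_cache <- new.env(parent = emptyenv())
  out <- vector("list", length(split_idx))
  j <- 0L
  for (idx in split_idx) {
    rows <- scans[idx, ]
    i764 <- which(rows$channel == 764L)
    i820 <- which(rows$channel == 820L)
    if (length(i764) != 1L || length(i820) != 1L) {
      stop("expected exactly one 764 and one 820 record per cell; got ",
           nrow(rows), " rows for ", rows$config_id[1], " replicate ",
           rows$replicate[1], call. = FALSE)
    }
    fits <- list()
    for (side in c("764", "820")) {
      i <- if (side == "764") i764 else i820
      line <- if (side == "764") lines$o2 else lines$h2o
      det <- rows$detuning[[i]]
      key <- sprintf("%s_%d_%.6f_%.6f", side, length(det), det[1],
                     det[length(det)])
      if (is.null(psi_cache[[key]])) {
        psi_cache[[key]] <- psi_for(line, det)
      }
      fits[[side]] <- fit_absorbance_core(
        det, rows$intensity[[i]], psi_cache[[key]],
        baseline_order = baseline_order, snr_threshold = snr_threshold)
      fits[[side]] <- mark_clipped(fits[[side]], rows[i, ])
    }
    j <- j + 1L
    out[[j]] <- assemble_estimate(rows$config_id[1],
                                  as.integer(rows$replicate[1]),
                                  rows$o2_nominal[1],
                                  fits[["764"]], fits[["820"]],
                                  conditions, lines)
  }
  est <- dplyr::bind_rows(out)
  dplyr::arrange(est, .data$config_id, .data$o2_nominal, .data$replicate)
}
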