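# Synthetic dual-laser GASMAS scans over the full phantom experiment design.
#
# The generator emulates a time-multiplexed two-laser instrument scanning one
# absorption line per channel (O2 near 764 nm, H2O near 820 nm) through a
# neonatal-thorax phantom: a mild quadratic injection-current baseline, a
# scalar tissue transmission from diffusion-theory attenuation of an
# effective muscle layer, the Beer-Lambert gas imprint, and detector noise.
# Every record carries a known ground truth and a reproducible seed.

#' Phantom tissue optical properties
#'
#' Absorption and reduced scattering coefficients assigned to the solid
#' tissue-mimicking phantoms at the two laser wavelengths.
#'
#' @return a tibble with columns `tissue`, `wavelength` (nm), `mu_a` (cm^-1),
#'   `mu_s_prime` (cm^-1).
#' @export
tissue_optical_properties <- function() {
  tibble::tribble(
    ~tissue,  ~wavelength, ~mu_a, ~mu_s_prime,
    "skin",   764, 0.03, 24.8,
    "fat",    764, 0.13, 13.9,
    "muscle", 764, 0.20, 14.1,
    "bone",   764, 0.10, 9.30,
    "heart",  764, 0.25, 4.89,
    "skin",   820, 0.03, 22.8,
    "fat",    820, 0.07, 13.2,
    "muscle", 820, 0.20, 12.8,
    "bone",   820, 0.11, 8.40,
    "heart",  820, 0.11, 4.45
  )
}

#' Diffusion-theory effective attenuation coefficient
#'
#' \eqn{\mu_{eff} = \sqrt{3 \mu_a (\mu_a + \mu_s')}} for a tissue row of
#' [tissue_optical_properties()].
#'
#' @param tissue tissue name.
#' @param wavelength 764 or 820 (nm).
#' @return effective attenuation coefficient, cm^-1.
#' @export
tissue_mu_eff <- function(tissue = "muscle", wavelength = 764) {
  props <- tissue_optical_properties()
  row <- props[props$tissue == tissue & props$wavelength == wavelength, ]
  if (nrow(row) != 1L) {
    stop("unknown tissue/wavelength combination: ", tissue, "/", wavelength,
         call. = FALSE)
  }
  sqrt(3 * row$mu_a * (row$mu_a + row$mu_s_prime))
}

#' Default source-detector experiment design
#'
#' Thirty source-detector configurations — 15 with tracheal (internal,
#' transmittance) illumination and 15 with dermal (surface, remittance)
#' illumination — each measured with 21 replicate detector reattachments at
#' four nominal oxygen concentrations. Detector positions 10/11 and 14/15
#' within each illumination arm are deliberate repeats of the same physical
#' position (a reproducibility control) and therefore share one ground truth.
#'
#' Geometry (which of the two thorax anatomies), phantom optical-property set
#' (764 vs 820 nm) and body side are assigned deterministically from the
#' position index so the design is balanced and reproducible.
#'
#' @param n_tracheal,n_dermal number of configurations per illumination arm.
#' @param replicates replicate measurements per configuration and
#'   concentration.
#' @param concentrations nominal O2 mole fractions, in administration order.
#' @return an object of class `gasmas_design`: a list with elements
#'   `configs` (tibble), `replicates`, `concentrations`.
#' @examples
#' d <- default_design()
#' nrow(d$configs)  # 30
#' @export
default_design <- function(n_tracheal = 15L, n_dermal = 15L,
                           replicates = 21L,
                           concentrations = c(0.21, 0.30, 0.50, 1.00)) {
  stopifnot(n_tracheal >= 1L, n_dermal >= 1L, replicates >= 1L,
            all(concentrations > 0), all(concentrations <= 1))
  arm <- function(illumination, n) {
    position <- seq_len(n)
    # repeated-position reproducibility pairs: 11 repeats 10, 15 repeats 14
    pk <- position
    pk[position == 11L] <- 10L
    pk[position == 15L] <- 14L
    tibble::tibble(
      config_id = sprintf("%s_%02d", illumination, position),
      illumination = illumination,
      detector_position = position,
      geometry = ifelse(pk %% 2L == 1L, 1L, 2L),
      phantom_props = ifelse(pk <= ceiling(n / 2), 764L, 820L),
      side = ifelse((pk %/% 2L) %% 2L == 0L, "right", "left"),
      truth_key = sprintf("%s_pos%02d", illumination, pk)
    )
  }
  configs <- dplyr::bind_rows(arm("tracheal", n_tracheal),
                              arm("dermal", n_dermal))
  structure(
    list(configs = configs, replicates = as.integer(replicates),
         concentrations = concentrations),
    class = "gasmas_design"
  )
}

#' @export
print.gasmas_design <- function(x, ...) {
  cat(sprintf(
    "<gasmas_design> %d configurations x %d replicates x %d concentrations\n",
    nrow(x$configs), x$replicates, length(x$concentrations)))
  invisible(x)
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Deterministic per-record seed
#'
#' Stable 31-bit hash of (master seed, configuration, replicate,
#' concentration, channel) so that any single scan record can be regenerated
#' in isolation.
#'
#' @param master_seed integer master seed.
#' @param config_id configuration key.
#' @param replicate replicate index.
#' @param concentration nominal O2 fraction.
#' @param channel 764 or 820.
#' @return integer in \[1, 2^31 - 2\].
#' @export
record_seed <- function(master_seed, config_id, replicate, concentration,
                        channel) {
  key <- sprintf("%s|%d|%.6f|%s", config_id, as.integer(replicate),
                 concentration, as.character(channel))
  h <- as.numeric(master_seed) %% 2147483647
  for (ch in utf8ToInt(key)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h) + 1L
}

#' Draw per-configuration ground truth
#'
#' Each unique physical source-detector position receives one true gas
#' pathlength (uniform on `pathlength_range`, reused across all
#' concentrations) and one scalar tissue transmission
#' \eqn{\exp(-\mu_{eff} d)} from the muscle optical properties of the
#' configuration's phantom wavelength set and a random layer thickness. A
#' small number of configurations (`n_dark`) are assigned a transmission far
#' below the detector noise floor so that their inversions fail, emulating
#' the strongly attenuated placements seen on real thoraces.
#'
#' @param design a [default_design()] object.
#' @param seed integer seed; the draw is fully determined by it.
#' @param conditions gas conditions, attached to the truth as an attribute.
#' @param pathlength_range metres, support of the true pathlength draw.
#' @param thickness_range metres, support of the effective tissue layer
#'   thickness draw.
#' @param n_dark number of configurations forced below the detectability
#'   floor.
#' @param dark_transmission transmission assigned to those configurations.
#' @return a tibble (class `gasmas_truth`) with one row per configuration:
#'   design columns plus `true_pathlength_m`, `thickness_m`, `mu_eff`,
#'   `tissue_transmission`.
#' @export
sample_truth <- function(design, seed,
                         conditions = ambient_conditions(),
                         pathlength_range = c(0.01, 0.20),
                         thickness_range = c(0.005, 0.025),
                         n_dark = 2L,
                         dark_transmission = 1e-7) {
  stopifnot(inherits(design, "gasmas_design"),
            inherits(conditions, "ambient_conditions"),
            length(pathlength_range) == 2L, length(thickness_range) == 2L,
            n_dark >= 0L)
  configs <- design$configs
  keys <- unique(configs$truth_key)
  truth <- with_seed(seed, {
    per_key <- tibble::tibble(
      truth_key = keys,
      true_pathlength_m = stats::runif(length(keys), pathlength_range[1],
                                       pathlength_range[2]),
      thickness_m = stats::runif(length(keys), thickness_range[1],
                                 thickness_range[2])
    )
    out <- dplyr::left_join(configs, per_key, by = "truth_key")
    out$mu_eff <- vapply(out$phantom_props, function(w) {
      tissue_mu_eff("muscle", w)
    }, numeric(1))
    out$tissue_transmission <- exp(-out$mu_eff * out$thickness_m * 100)
    if (n_dark > 0L) {
      dark_keys <- sample(keys, min(n_dark, length(keys)))
      out$tissue_transmission[out$truth_key %in% dark_keys] <-
        dark_transmission
    }
    out
  })
  attr(truth, "conditions") <- conditions
  attr(truth, "seed") <- as.integer(seed)
  class(truth) <- c("gasmas_truth", class(truth))
  truth
}

#' Gas-mixing carry-over bias
#'
#' Imperfect purging of the lung cavities mixes each administered gas with
#' the gas already present: `effective[k] = (1 - beta) * nominal[k] + beta *
#' effective[k - 1]`, with the cavities initially holding air (21\% O2). With
#' `beta = 0` the nominal sequence is returned unchanged; with `beta > 0` an
#' increasing sequence is progressively underestimated, most visibly at the
#' 100\% step.
#'
#' @param nominal nominal O2 fractions in administration order.
#' @param beta carry-over fraction in \[0, 1).
#' @param anchor O2 fraction initially filling the cavities (air).
#' @return effective O2 fractions, same length as `nominal`.
#' @examples
#' apply_mixing_bias(c(0.21, 0.30, 0.50, 1.00), beta = 0.2)
#' @export
apply_mixing_bias <- function(nominal, beta, anchor = 0.21) {
  stopifnot(is.numeric(nominal), length(beta) == 1L, beta >= 0, beta < 1)
  if (beta == 0) {
    return(nominal)
  }
  effective <- numeric(length(nominal))
  prev <- anchor
  for (k in seq_along(nominal)) {
    effective[k] <- (1 - beta) * nominal[k] + beta * prev
    prev <- effective[k]
  }
  effective
}

# Quadratic injection-current baseline shape on the scaled detuning axis.
scan_baseline <- function(grid, coefficients = c(1, 0.15, -0.05),
                          intensity_scale = 1) {
  u <- grid / max(abs(grid))
  intensity_scale *
    (coefficients[1] + coefficients[2] * u + coefficients[3] * u^2)
}

# Gas absorption coefficient profile over the grid for one channel.
channel_mu_a <- function(channel, o2_fraction, conditions, lines, grid) {
  if (channel == 820) {
    n_w <- number_density(water_partial_pressure(conditions),
                          conditions$temperature)
    spec <- absorption_spectrum(lines$h2o, n_w, conditions, grid)
  } else {
    e_w <- water_partial_pressure(conditions)
    n_dry <- number_density(conditions$pressure - e_w,
                            conditions$temperature)
    spec <- absorption_spectrum(lines$o2, n_dry * o2_fraction, conditions,
                                grid)
  }
  spec$mu_a
}

default_lines <- function() {
  list(h2o = h2o_line_820(), o2 = o2_line_764())
}

#' Simulate one scan record
#'
#' Direct-absorption intensity sweep for one configuration, replicate and
#' channel:
#' \deqn{I(\Delta\nu) = I_0 B(\Delta\nu)\, T_{tissue}\,
#'   e^{-\mu_a(\Delta\nu)\, L}}
#' with additive Gaussian detector noise of standard deviation
#' `noise_rel * I0 * B * (T_tissue + dark_frac)` — proportional to the local
#' intensity for ordinary transmissions, with a dark/electronic floor (a
#' fixed fraction `dark_frac` of the incident intensity scale) that dominates
#' for strongly attenuated placements. Post-noise intensities are clipped at
#' a small positive floor and the record flagged when clipping occurred.
#'
#' @param truth one row of a [sample_truth()] table (needs
#'   `config_id`, `true_pathlength_m`, `tissue_transmission`).
#' @param channel 764 (oxygen) or 820 (water vapour).
#' @param replicate replicate index.
#' @param o2_fraction effective O2 mole fraction filling the cavities (used
#'   by the 764 channel).
#' @param noise_rel relative detector noise amplitude.
#' @param seed integer seed for this record's noise draw.
#' @param conditions gas conditions.
#' @param lines list with elements `h2o` and `o2` ([spectral_line()]s).
#' @param grid detuning grid, cm^-1.
#' @param baseline_coefficients quadratic baseline coefficients on the scaled
#'   detuning axis.
#' @param intensity_scale incident intensity I0 in detector units.
#' @param dark_frac detector noise floor as a fraction of incident intensity.
#' @param intensity_floor positive clipping floor as a fraction of incident
#'   intensity.
#' @return a one-row tibble with `config_id`, `replicate`, `channel`,
#'   `o2_fraction`, list-columns `detuning` and `intensity`, `seed_used` and
#'   `clipped`.
#' @export
simulate_scan <- function(truth, channel, replicate, o2_fraction = 0.21,
                          noise_rel = 1e-5, seed = 1L,
                          conditions = ambient_conditions(),
                          lines = default_lines(),
                          grid = default_grid(),
                          baseline_coefficients = c(1, 0.15, -0.05),
                          intensity_scale = 1,
                          dark_frac = 1e-4,
                          intensity_floor = 1e-6) {
  stopifnot(channel %in% c(764, 820), noise_rel >= 0)
  mu <- channel_mu_a(channel, o2_fraction, conditions, lines, grid)
  rec <- simulate_scan_core(
    mu = mu, grid = grid,
    pathlength_m = truth$true_pathlength_m,
    transmission = truth$tissue_transmission,
    noise_rel = noise_rel, seed = seed,
    baseline_coefficients = baseline_coefficients,
    intensity_scale = intensity_scale, dark_frac = dark_frac,
    intensity_floor = intensity_floor
  )
  tibble::tibble(
    config_id = truth$config_id, replicate = as.integer(replicate),
    channel = as.integer(channel), o2_fraction = o2_fraction,
    detuning = list(grid), intensity = list(rec$intensity),
    seed_used = as.integer(seed), clipped = rec$clipped
  )
}

# Intensity synthesis given a precomputed mu_a profile.
simulate_scan_core <- function(mu, grid, pathlength_m, transmission,
                               noise_rel, seed, baseline_coefficients,
                               intensity_scale, dark_frac, intensity_floor) {
  baseline <- scan_baseline(grid, baseline_coefficients, intensity_scale)
  signal <- baseline * transmission * exp(-mu * pathlength_m * 100)
  if (noise_rel > 0) {
    sd <- noise_rel * baseline * (transmission + dark_frac)
    noise <- with_seed(seed, stats::rnorm(length(grid), 0, sd))
    signal <- signal + noise
  }
  floor_value <- intensity_floor * intensity_scale
  clipped <- any(signal < floor_value)
  signal[signal < floor_value] <- floor_value
  list(intensity = signal, clipped = clipped)
}

#' Simulate the full experiment
#'
#' Crosses the design with its concentration list and replicate count and
#' synthesises every scan record (two channels per measurement), with
#' per-record seeds derived deterministically from `master_seed` via
#' [record_seed()]. The truth sidecar records the effective (mixing-biased)
#' concentration actually filling the cavities for every configuration and
#' concentration step.
#'
#' @param design a [default_design()] object.
#' @param truth a [sample_truth()] table for that design.
#' @param noise_rel relative detector noise amplitude.
#' @param beta gas-mixing carry-over fraction (see [apply_mixing_bias()]).
#' @param master_seed integer master seed.
#' @inheritParams simulate_scan
#' @return an object of class `gasmas_dataset`: a list with `scans` (nested
#'   tibble, one row per record), `truth` (sidecar tibble, one row per
#'   configuration x concentration) and `params`.
#' @examples
#' d <- default_design(n_tracheal = 2, n_dermal = 2, replicates = 2,
#'                     concentrations = c(0.21, 1.00))
#' tr <- sample_truth(d, seed = 7, n_dark = 0)
#' ds <- simulate_experiment(d, tr, master_seed = 7)
#' nrow(ds$scans)  # 4 configs x 2 replicates x 2 concentrations x 2 channels
#' @export
simulate_experiment <- function(design, truth, noise_rel = 1e-5, beta = 0,
                                master_seed = 1L,
                                conditions = attr(truth, "conditions"),
                                lines = default_lines(),
                                grid = default_grid(),
                                baseline_coefficients = c(1, 0.15, -0.05),
                                intensity_scale = 1,
                                dark_frac = 1e-4,
                                intensity_floor = 1e-6) {
  stopifnot(inherits(design, "gasmas_design"),
            all(design$configs$config_id %in% truth$config_id))
  if (is.null(conditions)) conditions <- ambient_conditions()
  concentrations <- design$concentrations
  effective <- apply_mixing_bias(concentrations, beta)

  sidecar <- tidyr::crossing(
    truth[, c("config_id", "geometry", "illumination", "detector_position",
              "side", "phantom_props", "truth_key", "true_pathlength_m",
              "tissue_transmission")],
    tibble::tibble(o2_nominal = concentrations, o2_effective = effective)
  )
  sidecar <- dplyr::arrange(sidecar, .data$config_id, .data$o2_nominal)
  sidecar$seed <- as.integer(master_seed)

  # absorption profiles are identical across records of a channel up to the
  # O2 fraction scaling, so compute them once
  mu_820 <- channel_mu_a(820, NA, conditions, lines, grid)
  mu_764_unit <- channel_mu_a(764, 1, conditions, lines, grid)

  cells <- tidyr::crossing(
    truth[, c("config_id", "true_pathlength_m", "tissue_transmission")],
    tibble::tibble(o2_nominal = concentrations, o2_effective = effective),
    tibble::tibble(replicate = seq_len(design$replicates)),
    tibble::tibble(channel = c(764L, 820L))
  )
  n <- nrow(cells)
  intensity <- vector("list", n)
  seeds <- integer(n)
  clipped <- logical(n)
  for (i in seq_len(n)) {
    ch <- cells$channel[i]
    mu <- if (ch == 820L) mu_820 else cells$o2_effective[i] * mu_764_unit
    seeds[i] <- record_seed(master_seed, cells$config_id[i],
                            cells$replicate[i], cells$o2_nominal[i], ch)
    rec <- simulate_scan_core(
      mu = mu, grid = grid,
      pathlength_m = cells$true_pathlength_m[i],
      transmission = cells$tissue_transmission[i],
      noise_rel = noise_rel, seed = seeds[i],
      baseline_coefficients = baseline_coefficients,
      intensity_scale = intensity_scale, dark_frac = dark_frac,
      intensity_floor = intensity_floor
    )
    intensity[[i]] <- rec$intensity
    clipped[i] <- rec$clipped
  }
  scans <- tibble::tibble(
    config_id = cells$config_id, replicate = cells$replicate,
    channel = cells$channel, o2_nominal = cells$o2_nominal,
    o2_effective = cells$o2_effective,
    detuning = rep(list(grid), n), intensity = intensity,
    seed_used = seeds, clipped = clipped
  )
  structure(
    list(
      scans = scans, truth = sidecar,
      params = list(master_seed = as.integer(master_seed),
                    noise_rel = noise_rel, beta = beta,
                    conditions = conditions, lines = lines,
                    baseline_coefficients = baseline_coefficients,
                    intensity_scale = intensity_scale,
                    dark_frac = dark_frac,
                    intensity_floor = intensity_floor)
    ),
    class = "gasmas_dataset"
  )
}

#' @export
print.gasmas_dataset <- function(x, ...) {
  cat(sprintf(
    "<gasmas_dataset> %d scan records (%d configurations), noise_rel = %g, beta = %g\n",
    nrow(x$scans), length(unique(x$scans$config_id)),
    x$params$noise_rel, x$params$beta))
  invisible(x)
}

#' Long-format view of scan records
#'
#' Unnests the per-record detuning/intensity arrays into one row per grid
#' point, the shape used by the CSV export.
#'
#' @param scans the `scans` tibble of a [simulate_experiment()] dataset.
#' @return a long tibble with columns `config_id`, `replicate`, `channel`,
#'   `o2_nominal`, `detuning`, `intensity`.
#' @export
scans_long <- function(scans) {
  tidyr::unnest(
    scans[, c("config_id", "replicate", "channel", "o2_nominal",
              "detuning", "intensity")],
    cols = c("detuning", "intensity")
  )
}
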