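# Gas physics: hygrometry, number densities and absorption coefficients.
#
# Everything downstream (scan synthesis, inversion) talks to gases through
# this layer: Arden Buck saturation vapour pressure -> water partial pressure
# -> ideal-gas number density -> Voigt-shaped absorption coefficient.

# Physical constants (SI)
.kB <- 1.380649e-23        # Boltzmann constant, J/K (exact)
.c_light <- 299792458      # speed of light, m/s (exact)
.amu <- 1.66053906660e-27  # atomic mass unit, kg

#' Ambient gas conditions
#'
#' Temperature, total pressure and relative humidity of the gas filling the
#' cavities. These three numbers drive all gas-physics computations: the
#' water-vapour reference concentration through the Arden Buck equation and
#' the dry-gas density available to oxygen.
#'
#' @param temperature gas temperature in kelvin. Must lie in the 173-373 K
#'   validity window of the Buck fit.
#' @param pressure total ambient pressure in pascal.
#' @param relative_humidity fraction in \[0, 1\].
#' @return an object of class `ambient_conditions`.
#' @examples
#' ambient_conditions()                 # 293 K, 1 atm, saturated
#' ambient_conditions(relative_humidity = 0.5)
#' @export
ambient_conditions <- function(temperature = 293, pressure = 101325,
                               relative_humidity = 1) {
  stopifnot(length(temperature) == 1L, length(pressure) == 1L,
            length(relative_humidity) == 1L)
  if (!is.finite(temperature) || temperature <= 0) {
    stop("temperature must be a positive number of kelvin.", call. = FALSE)
  }
  if (!is.finite(pressure) || pressure <= 0) {
    stop("pressure must be a positive number of pascal.", call. = FALSE)
  }
  if (!is.finite(relative_humidity) || relative_humidity < 0 ||
      relative_humidity > 1) {
    stop("relative_humidity must lie in [0, 1].", call. = FALSE)
  }
  x <- structure(
    list(temperature = temperature, pressure = pressure,
         relative_humidity = relative_humidity),
    class = "ambient_conditions"
  )
  if (water_partial_pressure(x) > pressure) {
    stop("water partial pressure exceeds total pressure; conditions invalid.",
         call. = FALSE)
  }
  x
}

#' @export
print.ambient_conditions <- function(x, ...) {
  cat(sprintf("<ambient_conditions> T = %.2f K, P = %.0f Pa, RH = %.0f%%\n",
              x$temperature, x$pressure, 100 * x$relative_humidity))
  invisible(x)
}

#' Spectroscopic absorption line
#'
#' A single molecular absorption line in HITRAN-style parameterisation:
#' position, integrated strength, air-broadened Lorentzian half width at a
#' reference pressure, and the molar mass that sets the Doppler width.
#'
#' @param species `"H2O"` or `"O2"`.
#' @param center_wavenumber line centre, cm^-1.
#' @param line_strength integrated line strength, cm^-1/(molecule cm^-2).
#' @param lorentz_hwhm Lorentzian half width at half maximum at
#'   `reference_pressure`, cm^-1.
#' @param reference_pressure pressure at which `lorentz_hwhm` applies, Pa.
#' @param molar_mass molecular mass, g/mol.
#' @return an object of class `spectral_line`.
#' @seealso [h2o_line_820()], [o2_line_764()] for the packaged fixtures.
#' @export
spectral_line <- function(species, center_wavenumber, line_strength,
                          lorentz_hwhm, reference_pressure = 101325,
                          molar_mass) {
  species <- match.arg(species, c("H2O", "O2"))
  stopifnot(is.numeric(center_wavenumber), is.numeric(line_strength),
            is.numeric(lorentz_hwhm), is.numeric(molar_mass))
  if (center_wavenumber <= 0) stop("center_wavenumber must be > 0.", call. = FALSE)
  if (line_strength <= 0) stop("line_strength must be > 0.", call. = FALSE)
  if (lorentz_hwhm < 0) stop("lorentz_hwhm must be >= 0.", call. = FALSE)
  if (reference_pressure <= 0) stop("reference_pressure must be > 0.", call. = FALSE)
  if (molar_mass <= 0) stop("molar_mass must be > 0.", call. = FALSE)
  structure(
    list(species = species, center_wavenumber = center_wavenumber,
         line_strength = line_strength, lorentz_hwhm = lorentz_hwhm,
         reference_pressure = reference_pressure, molar_mass = molar_mass),
    class = "spectral_line"
  )
}

#' @export
print.spectral_line <- function(x, ...) {
  cat(sprintf(
    "<spectral_line> %s at %.1f cm-1 (%.2f nm), S = %.3g, gamma = %.3g cm-1\n",
    x$species, x$center_wavenumber, 1e7 / x$center_wavenumber,
    x$line_strength, x$lorentz_hwhm))
  invisible(x)
}

#' Read a spectral-line constants file
#'
#' Parses the plain-text key-value format used for the packaged line fixtures
#' (`<name> <value> <unit>` per line, `#` comments).
#'
#' @param path file path; defaults to the packaged constants file.
#' @return a tibble with columns `name`, `value`, `unit`.
#' @export
read_spectral_lines <- function(path = system.file("extdata",
                                                   "spectral_lines.txt",
                                                   package = "gasmas")) {
  raw <- readLines(path, warn = FALSE)
  raw <- sub("#.*$", "", raw)
  raw <- trimws(raw)
  raw <- raw[nzchar(raw)]
  parts <- strsplit(raw, "[[:space:]]+")
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad) > 0) {
    stop("malformed constants line: ", raw[bad[1]], call. = FALSE)
  }
  tibble::tibble(
    name = vapply(parts, `[[`, "", 1L),
    value = as.numeric(vapply(parts, `[[`, "", 2L)),
    unit = vapply(parts, `[[`, "", 3L)
  )
}

line_from_constants <- function(prefix, species) {
  tab <- read_spectral_lines()
  get <- function(field) {
    v <- tab$value[tab$name == paste0(prefix, ".", field)]
    if (length(v) != 1L) {
      stop("constants file misses ", prefix, ".", field, call. = FALSE)
    }
    v
  }
  spectral_line(
    species = species,
    center_wavenumber = get("center_wavenumber"),
    line_strength = get("line_strength"),
    lorentz_hwhm = get("lorentz_hwhm"),
    reference_pressure = get("reference_pressure"),
    molar_mass = get("molar_mass")
  )
}

#' Packaged water-vapour line near 820 nm
#'
#' Single-line fixture for the humidity-reference channel.
#' @return a [spectral_line()].
#' @export
h2o_line_820 <- function() {
  if (is.null(.gasmas_env$h2o_line)) {
    .gasmas_env$h2o_line <- line_from_constants("h2o", "H2O")
  }
  .gasmas_env$h2o_line
}

#' Packaged oxygen A-band line near 764 nm
#'
#' Single-line fixture for the oxygen channel.
#' @return a [spectral_line()].
#' @export
o2_line_764 <- function() {
  if (is.null(.gasmas_env$o2_line)) {
    .gasmas_env$o2_line <- line_from_constants("o2", "O2")
  }
  .gasmas_env$o2_line
}

#' Saturation vapour pressure of water (Arden Buck)
#'
#' Buck (1996) fit over liquid water,
#' \eqn{e_s = 611.21 \exp\big[(18.678 - t/234.5)\, t/(257.14 + t)\big]} Pa
#' with \eqn{t} in degrees Celsius. No enhancement factor is applied (it is
#' below 0.5\% at ambient pressure).
#'
#' @param temperature kelvin; must lie strictly inside (173, 373) K.
#' @return saturation vapour pressure in pascal.
#' @examples
#' saturation_vapor_pressure(293.15)  # ~2339 Pa at 20 degC
#' @export
saturation_vapor_pressure <- function(temperature) {
  if (any(!is.finite(temperature)) ||
      any(temperature <= 173) || any(temperature >= 373)) {
    stop("temperature outside the Buck validity window (173, 373) K.",
         call. = FALSE)
  }
  t_c <- temperature - 273.15
  611.21 * exp((18.678 - t_c / 234.5) * (t_c / (257.14 + t_c)))
}

#' Partial pressure of water vapour
#'
#' `relative_humidity * saturation_vapor_pressure(temperature)`.
#'
#' @param conditions an [ambient_conditions()] object.
#' @return partial pressure in pascal.
#' @export
water_partial_pressure <- function(conditions) {
  stopifnot(inherits(conditions, "ambient_conditions"))
  conditions$relative_humidity *
    saturation_vapor_pressure(conditions$temperature)
}

#' Ideal-gas number density
#'
#' \eqn{N = p / (k_B T)}, reported per cubic centimetre as used with
#' HITRAN-style line strengths.
#'
#' @param partial_pressure pascal, >= 0.
#' @param temperature kelvin, > 0.
#' @return molecules per cm^3.
#' @examples
#' number_density(2339, 293.15)  # ~5.8e17 cm^-3
#' @export
number_density <- function(partial_pressure, temperature) {
  stopifnot(all(partial_pressure >= 0), all(temperature > 0))
  partial_pressure / (.kB * temperature) * 1e-6
}

#' Doppler width of a line
#'
#' Gaussian standard deviation
#' \eqn{\sigma_G = \nu_0 \sqrt{k_B T / (m c^2)}} in cm^-1.
#'
#' @param line a [spectral_line()].
#' @param temperature kelvin.
#' @return Gaussian sigma, cm^-1.
#' @export
doppler_sigma <- function(line, temperature) {
  stopifnot(inherits(line, "spectral_line"), temperature > 0)
  m <- line$molar_mass * 1e-3 / 6.02214076e23
  line$center_wavenumber * sqrt(.kB * temperature / (m * .c_light^2))
}

#' Pressure-scaled Lorentzian width
#'
#' Linear pressure scaling of the air-broadened half width:
#' `lorentz_hwhm * pressure / reference_pressure`.
#'
#' @param line a [spectral_line()].
#' @param pressure total pressure, Pa.
#' @return Lorentzian HWHM, cm^-1.
#' @export
lorentz_hwhm_at <- function(line, pressure) {
  stopifnot(inherits(line, "spectral_line"), pressure > 0)
  line$lorentz_hwhm * pressure / line$reference_pressure
}

#' Default spectroscopic detuning grid
#'
#' 512 points spanning +/- 0.6 cm^-1 around line centre — wide enough to hold
#' more than ten Voigt widths of either packaged line at ambient pressure.
#'
#' @param n_points number of grid points.
#' @param half_width half span, cm^-1.
#' @return strictly increasing numeric vector of detunings (cm^-1).
#' @export
default_grid <- function(n_points = 512L, half_width = 0.6) {
  seq(-half_width, half_width, length.out = n_points)
}

#' Absorption coefficient spectrum of one line
#'
#' \eqn{\mu_a(\Delta\nu) = N\, S\, \phi_V(\Delta\nu;\ \sigma_G, \gamma_L)},
#' with the Doppler sigma from the gas temperature and the Lorentzian width
#' scaled to the ambient pressure. The profile is area-normalised, so the
#' spectrum integrates to \eqn{N S} when the grid is wide enough; a narrow
#' grid triggers a warning.
#'
#' @param line a [spectral_line()].
#' @param species_density absorber number density, molecules/cm^3.
#' @param conditions an [ambient_conditions()] object.
#' @param grid detuning grid, cm^-1, strictly increasing.
#' @return a tibble of class `absorption_spectrum` with columns `detuning`
#'   and `mu_a` (cm^-1), and attributes `mu_a_peak`, `gaussian_sigma`,
#'   `lorentz_hwhm`.
#' @export
absorption_spectrum <- function(line, species_density, conditions,
                                grid = default_grid()) {
  stopifnot(inherits(line, "spectral_line"),
            inherits(conditions, "ambient_conditions"),
            species_density >= 0)
  if (any(diff(grid) <= 0)) {
    stop("detuning grid must be strictly increasing.", call. = FALSE)
  }
  sigma_g <- doppler_sigma(line, conditions$temperature)
  gamma_l <- lorentz_hwhm_at(line, conditions$pressure)
  width <- voigt_hwhm(sigma_g, gamma_l)
  if (max(grid) < 10 * width || min(grid) > -10 * width) {
    warning("detuning grid narrower than +/-10 line widths; ",
            "integrated checks may be off.", call. = FALSE)
  }
  mu_a <- species_density * line$line_strength *
    voigt_profile(grid, sigma_g, gamma_l)
  out <- tibble::tibble(detuning = grid, mu_a = mu_a)
  attr(out, "mu_a_peak") <- species_density * line$line_strength *
    voigt_peak(sigma_g, gamma_l)
  attr(out, "gaussian_sigma") <- sigma_g
  attr(out, "lorentz_hwhm") <- gamma_l
  class(out) <- c("absorption_spectrum", class(out))
  out
}

#' Peak water-vapour absorption coefficient
#'
#' Line-centre \eqn{\mu_a} of water vapour at the given conditions: Buck
#' partial pressure -> ideal-gas density -> Voigt peak. At room temperature
#' and 100\% RH the packaged 820 nm line gives ~3.1e-5 cm^-1, the
#' humidity-reference constant of the pathlength inversion.
#'
#' @param conditions an [ambient_conditions()] object.
#' @param line an H2O [spectral_line()]; defaults to the packaged fixture.
#' @return peak absorption coefficient, cm^-1.
#' @examples
#' peak_water_mu_a(ambient_conditions())
#' @export
peak_water_mu_a <- function(conditions, line = h2o_line_820()) {
  stopifnot(inherits(conditions, "ambient_conditions"),
            inherits(line, "spectral_line"))
  if (line$species != "H2O") {
    stop("peak_water_mu_a() needs an H2O line.", call. = FALSE)
  }
  n_w <- number_density(water_partial_pressure(conditions),
                        conditions$temperature)
  n_w * line$line_strength *
    voigt_peak(doppler_sigma(line, conditions$temperature),
               lorentz_hwhm_at(line, conditions$pressure))
}

#' Peak oxygen absorption coefficient per unit mole fraction
#'
#' Line-centre \eqn{\mu_a} of oxygen per unit O2 mole fraction on the dry-gas
#' basis: the absorber density available to oxygen is
#' \eqn{N_{dry} = (P - e_w')/(k_B T)}, the total density minus water vapour.
#' Multiply by the O2 fraction of the dry gas to get \eqn{\mu_a}.
#'
#' @param conditions an [ambient_conditions()] object.
#' @param line an O2 [spectral_line()]; defaults to the packaged fixture.
#' @return peak absorption coefficient per unit mole fraction, cm^-1.
#' @examples
#' 0.21 * peak_oxygen_mu_a_per_fraction(ambient_conditions())  # ambient air
#' @export
peak_oxygen_mu_a_per_fraction <- function(conditions, line = o2_line_764()) {
  stopifnot(inherits(conditions, "ambient_conditions"),
            inherits(line, "spectral_line"))
  if (line$species != "O2") {
    stop("peak_oxygen_mu_a_per_fraction() needs an O2 line.", call. = FALSE)
  }
  e_w <- water_partial_pressure(conditions)
  if (e_w >= conditions$pressure) {
    stop("water partial pressure >= total pressure; no dry gas left.",
         call. = FALSE)
  }
  n_dry <- number_density(conditions$pressure - e_w, conditions$temperature)
  n_dry * line$line_strength *
    voigt_peak(doppler_sigma(line, conditions$temperature),
               lorentz_hwhm_at(line, conditions$pressure))
}
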