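#' Specification of a synthetic temperature-dependent spectral set
#'
#' The generated absorbance matrix is exactly bilinear,
#' \code{D[lambda, T] = s(lambda) * c(T) + noise}, with the
#' temperature-domain profile \code{c(T)} a constant offset plus a sum of
#' Boltzmann sigmoids (one per transition) and \code{s(lambda)} a smooth
#' positive turbidity-like spectral profile. Defaults emulate an anionic
#' lipid melting experiment read in the 250-300 nm window: transitions
#' near 51.5 / 53.3 degrees C (the two-step multilamellar profile) with
#' absorbance decreasing on melting.
#'
#' @param transitions list of transitions, each
#'   \code{list(center, width, amplitude)} with center/width in degrees C;
#'   negative amplitudes encode an absorbance drop on melting
#' @param offset baseline absorbance level of \code{c(T)}
#' @param wavelength wavelength grid, nm
#' @param temperature temperature grid, degrees C (strictly increasing)
#' @param noise_sd Gaussian noise SD added to every matrix element
#' @param seed default RNG seed
#' @return object of class \code{melting_spec}
#' @export
melting_spec <- function(transitions = list(
                           list(center = 51.5, width = 0.5, amplitude = -0.4),
                           list(center = 53.3, width = 0.35, amplitude = -0.4)),
                         offset = 1.0,
                         wavelength = seq(250, 300, by = 1),
                         temperature = seq(40, 65, by = 0.25),
                         noise_sd = 0.002, seed = 1L) {
  if (!length(wavelength) || !length(temperature))
    stop("wavelength and temperature grids must be non-empty")
  if (any(diff(temperature) <= 0))
    stop("temperature grid must be strictly increasing")
  for (tr in transitions)
    if (tr$width <= 0) stop("transition widths must be positive")
  structure(list(transitions = transitions, offset = offset,
                 wavelength = wavelength, temperature = temperature,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "melting_spec")
}

# sum-of-Boltzmann profile used both by the generator and the fit oracle
boltzmann_profile <- function(temp, offset, transitions) {
  y <- rep(offset, length(temp))
  for (tr in transitions)
    y <- y + tr$amplitude / (1 + exp((tr$center - temp) / tr$width))
  y
}

#' Generate a synthetic wavelength x temperature absorbance matrix
#'
#' @param spec a [melting_spec()]
#' @param seed RNG seed (defaults to \code{spec$seed})
#' @return a \code{spectra_matrix}: list with \code{wavelength},
#'   \code{temperature} and matrix \code{D} (rows = wavelengths); the
#'   noise-free temperature profile \code{c_true}, spectral profile
#'   \code{s_true} and the generating spec are attached as ground truth
#' @export
make_spectra <- function(spec = melting_spec(), seed = spec$seed) {
  with_seed(seed, {
    c_true <- boltzmann_profile(spec$temperature, spec$offset,
                                spec$transitions)
    # smooth positive turbidity-like wavelength profile (~ lambda^-4 scaled)
    lam <- spec$wavelength
    s_true <- (lam[1] / lam)^4
    D <- outer(s_true, c_true)
    if (spec$noise_sd > 0)
      D <- D + matrix(stats::rnorm(length(D), 0, spec$noise_sd),
                      nrow = nrow(D))
    structure(list(wavelength = lam, temperature = spec$temperature, D = D,
                   c_true = c_true, s_true = s_true, spec = spec),
              class = "spectra_matrix")
  })
}

#' Generate a synthetic DSC thermogram
#'
#' Heat flow is a linear baseline plus a sum of asymmetric two-sided
#' Gaussian endotherms. Each transition is parameterised by its center,
#' its integrated area (the transition enthalpy in the curve's units) and
#' left/right width parameters; the peak height is
#' \code{area / (sqrt(pi/2) * (sd_left + sd_right))} so the integral equals
#' the requested area. Defaults emulate a multilamellar melting curve: a
#' main endotherm at 52.4 degrees C plus a weak protonated-lipid event
#' near 60 degrees C at ~3\% of the main height.
#'
#' @param transitions list of \code{list(center, area, sd_left, sd_right)}
#' @param baseline numeric \code{c(intercept, slope)} of the linear baseline
#' @param temperature temperature grid, degrees C
#' @param noise_sd Gaussian noise SD
#' @param seed RNG seed
#' @return a \code{thermogram}: data.frame with \code{temperature} and
#'   \code{heat_flow}, ground truth attached as attribute \code{"truth"}
#' @export
make_dsc <- function(transitions = list(
                       list(center = 52.4, area = 1.0,
                            sd_left = 0.45, sd_right = 0.65),
                       list(center = 60.0, area = 0.045,
                            sd_left = 0.55, sd_right = 0.55)),
                     baseline = c(0, 0),
                     temperature = seq(40, 65, by = 0.02),
                     noise_sd = 0, seed = 1L) {
  if (any(diff(temperature) <= 0))
    stop("temperature grid must be strictly increasing")
  with_seed(seed, {
    y <- baseline[1] + baseline[2] * temperature
    for (tr in transitions) {
      if (tr$sd_left <= 0 || tr$sd_right <= 0)
        stop("transition widths must be positive")
      h <- tr$area / (sqrt(pi / 2) * (tr$sd_left + tr$sd_right))
      lft <- temperature < tr$center
      y <- y + h * ifelse(lft,
                          exp(-0.5 * ((temperature - tr$center) / tr$sd_left)^2),
                          exp(-0.5 * ((temperature - tr$center) / tr$sd_right)^2))
    }
    if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
    out <- data.frame(temperature = temperature, heat_flow = y)
    class(out) <- c("thermogram", "data.frame")
    attr(out, "truth") <- list(transitions = transitions, baseline = baseline,
                               noise_sd = noise_sd)
    out
  })
}
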