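#' Physical constants and unit converters
#'
#' Internal units are nm, ps, amu and kJ/mol throughout; converters are
#' applied only at the I/O boundary (diffusion coefficients are commonly
#' quoted in cm^2 s^-1, calorimetric quantities per mole).
#'
#' @format A named list with elements:
#' \describe{
#'   \item{R_J}{gas constant, J mol^-1 K^-1}
#'   \item{R_kJ}{gas constant, kJ mol^-1 K^-1}
#'   \item{amu_per_nm3_to_kg_per_m3}{mass-density conversion factor}
#' }
#' @export
unit_constants <- list(
  R_J  = 8.31446261815324,
  R_kJ = 8.31446261815324e-3,
  amu_per_nm3_to_kg_per_m3 = 1.66053906660
)

#' Convert a diffusion coefficient between cm^2/s and nm^2/ps
#'
#' 1 cm^2 s^-1 = 1e14 nm^2 / 1e12 ps = 100 nm^2 ps^-1.
#'
#' @param D diffusion coefficient
#' @return converted value
#' @export
cm2s_to_nm2ps <- function(D) D * 100

#' @rdname cm2s_to_nm2ps
#' @export
nm2ps_to_cm2s <- function(D) D / 100

#' @rdname cm2s_to_nm2ps
#' @export
nm2ps_to_nm2ns <- function(D) D * 1000

# Celsius -> Kelvin
celsius_to_kelvin <- function(t) t + 273.15

# standard atomic masses (amu) for the elements the generator emits
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999,
  P = 30.973762, Na = 22.98977, Cl = 35.45, S = 32.06
)

element_mass <- function(element) {
  m <- .element_masses[element]
  if (anyNA(m)) {
    stop("unknown element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

# evaluate code with a temporary RNG state seeded by `seed`
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# derive a reproducible child seed, kept below 2^31
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}
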