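#' Savitzky-Golay smoothing
#'
#' Least-squares local-polynomial smoothing with a fixed window; at the
#' series ends the window shrinks so every point is fitted with the data
#' actually available. Polynomial inputs of degree <= \code{poly_order}
#' are reproduced exactly. Even window sizes are supported (the window is
#' split as evenly as possible around the centre point).
#'
#' @param y numeric series
#' @param window_points window length in points
#' @param poly_order local polynomial degree (must be < window_points)
#' @return smoothed series of the same length
#' @export
smooth_sg <- function(y, window_points = 10L, poly_order = 3L) {
  n <- length(y)
  if (window_points <= poly_order)
    stop("window_points must exceed poly_order")
  if (window_points > n) stop("window longer than the series")
  hl <- (window_points - 1L) %/% 2L
  hr <- window_points - 1L - hl
  out <- numeric(n)
  x <- seq_len(n)
  for (i in x) {
    lo <- max(1L, i - hl); hi <- min(n, i + hr)
    idx <- lo:hi
    p <- min(poly_order, length(idx) - 1L)
    xi <- idx - i
    X <- outer(xi, 0:p, "^")
    beta <- qr.coef(qr(X), y[idx])
    out[i] <- beta[1]
  }
  out
}

#' Linear or polynomial baseline subtraction
#'
#' Fits a baseline through the anchor regions (index windows assumed free
#' of signal) and subtracts it. Idempotent: correcting a corrected curve
#' changes nothing.
#'
#' @param x abscissa (temperature or wavenumber)
#' @param y signal
#' @param anchors list of length-2 vectors giving abscissa ranges used as
#'   baseline anchors; default: first and last 10\% of the range
#' @param degree baseline polynomial degree (1 = linear, the default)
#' @return corrected signal
#' @export
baseline_correct <- function(x, y, anchors = NULL, degree = 1L) {
  rng <- range(x)
  anchors <- anchors %||% list(
    c(rng[1], rng[1] + 0.1 * diff(rng)),
    c(rng[2] - 0.1 * diff(rng), rng[2]))
  keep <- Reduce(`|`, lapply(anchors, function(a) x >= a[1] & x <= a[2]))
  if (sum(keep) < degree + 1) stop("anchor regions contain too few points")
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE),
                   subset = which(keep))
  unname(y - stats::predict(fit, newdata = data.frame(x = x)))
}

#' Bilinear decomposition of a spectral set (truncated SVD)
#'
#' Factorises the wavelength x temperature absorbance matrix as
#' D = S C' + E with S the wavelength-domain (spectral) profiles and C the
#' temperature-domain (concentration) profiles of the leading components,
#' via truncated singular value decomposition. Signs are fixed so each
#' concentration profile correlates positively with the mean absorbance;
#' singular values are absorbed into C. The explained variance fraction is
#' the ratio of retained to total squared singular values, and the
#' orthogonality of the truncation guarantees
#' ||D||^2 = ||S C'||^2 + ||E||^2.
#'
#' @param D numeric matrix, wavelengths in rows, temperatures in columns
#'   (or a \code{spectra_matrix} from [make_spectra()])
#' @param n_components number of components retained
#' @return list with matrices \code{C} (T x k), \code{S} (lambda x k),
#'   \code{E}, and \code{explained_variance}
#' @export
mca_decompose <- function(D, n_components = 1L) {
  sm <- NULL
  if (inherits(D, "spectra_matrix")) { sm <- D; D <- D$D }
  D <- as.matrix(D)
  if (n_components > min(dim(D)))
    stop("n_components exceeds the matrix rank bound min(dim(D))")
  sv <- svd(D)
  k <- n_components
  S <- sv$u[, seq_len(k), drop = FALSE]
  C <- sv$v[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  # sign convention: C follows the mean absorbance trend
  mcol <- colMeans(D)
  for (j in seq_len(k)) {
    if (stats::cor(C[, j], mcol) < 0) {
      C[, j] <- -C[, j]; S[, j] <- -S[, j]
    }
  }
  E <- D - S %*% t(C)
  out <- list(C = C, S = S, E = E,
              explained_variance = sum(sv$d[seq_len(k)]^2) / sum(sv$d^2))
  if (!is.null(sm)) {
    out$temperature <- sm$temperature
    out$wavelength <- sm$wavelength
  }
  out
}

# model: y0 + sum_i a_i / (1 + exp((T_i - T) / w_i))
boltzmann_model <- function(par, temp, k) {
  y <- rep(par[1], length(temp))
  for (i in seq_len(k)) {
    a <- par[3 * i - 1]; Tc <- par[3 * i]; w <- par[3 * i + 1]
    y <- y + a / (1 + exp((Tc - temp) / w))
  }
  y
}

#' Fit a single or double Boltzmann sigmoid to a melting profile
#'
#' Nonlinear least squares of
#' \code{y(T) = y0 + sum_i a_i / (1 + exp((T_i - T) / w_i))} with
#' multi-start initialisation (centres seeded from derivative extrema and
#' quantiles of the temperature range). Each T_i is the inflection
#' temperature of its transition; amplitudes are negative when the signal
#' drops on melting. Reports R^2, chi^2 as the raw sum of squared
#' residuals in the profile's native units (a reduced form is also
#' included), and per-centre standard errors. Double fits whose centres
#' are closer than \code{2 * max(w) / 5} are flagged unresolved.
#'
#' @param temperature temperature grid, degrees C
#' @param profile melting profile (e.g. a column of \code{C} from
#'   [mca_decompose()])
#' @param n_transitions 1 or 2
#' @return a \code{melting_fit}: list with \code{model}, data.frame
#'   \code{transitions} (center, width, amplitude, center_se), \code{y0},
#'   \code{r_squared}, \code{chi_squared}, \code{chi_squared_reduced},
#'   \code{fitted}, \code{unresolved}
#' @export
fit_boltzmann <- function(temperature, profile, n_transitions = 1L) {
  k <- as.integer(n_transitions)
  if (!k %in% 1:2) stop("n_transitions must be 1 or 2")
  n <- length(temperature)
  if (n < 8 * (k + 1) / 2)
    stop("too few points for a ", k, "-transition fit")
  y <- as.numeric(profile)
  rngT <- range(temperature)
  span <- diff(rngT)
  # derivative-based centre candidates
  sm <- if (n >= 11) smooth_sg(y, min(11L, n), 3L) else y
  dy <- c(NA, diff(sm) / diff(temperature))
  cand <- temperature[which.max(abs(dy))]
  starts <- list()
  if (k == 1) {
    for (Tc in unique(c(cand, rngT[1] + span * c(0.35, 0.5, 0.65))))
      for (w in span * c(0.02, 0.05, 0.1))
        starts[[length(starts) + 1L]] <- c(y[1], y[n] - y[1], Tc, w)
  } else {
    pairs <- list(rngT[1] + span * c(0.35, 0.65),
                  rngT[1] + span * c(0.4, 0.6),
                  rngT[1] + span * c(0.25, 0.75),
                  sort(c(cand, cand + span * 0.1)),
                  sort(c(cand - span * 0.1, cand)))
    for (p in pairs)
      for (w in span * c(0.02, 0.05))
        starts[[length(starts) + 1L]] <-
          c(y[1], (y[n] - y[1]) / 2, p[1], w, (y[n] - y[1]) / 2, p[2], w)
  }
  obj <- function(par) sum((y - boltzmann_model(par, temperature, k))^2)
  lower <- c(-Inf, rep(c(-Inf, rngT[1] - span, 1e-3), k))
  upper <- c(Inf, rep(c(Inf, rngT[2] + span, span), k))
  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      stats::optim(st, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value))
      best <- res
  }
  if (is.null(best))
    stop("Boltzmann fit failed to converge from any start (",
         length(starts), " starts tried)")
  par <- best$par
  sse <- best$value
  # standard errors from the Gauss-Newton approximation at the optimum
  J <- numeric_jacobian(function(p) boltzmann_model(p, temperature, k), par)
  se <- tryCatch({
    sigma2 <- sse / max(1, n - length(par))
    sqrt(diag(sigma2 * solve(crossprod(J))))
  }, error = function(e) rep(NA_real_, length(par)))
  tr <- data.frame(
    center = par[3 * seq_len(k)],
    width = par[3 * seq_len(k) + 1],
    amplitude = par[3 * seq_len(k) - 1],
    center_se = se[3 * seq_len(k)])
  tr <- tr[order(tr$center), , drop = FALSE]
  rownames(tr) <- NULL
  unresolved <- k == 2 &&
    abs(diff(tr$center)) < 2 * max(tr$width) / 5
  sst <- sum((y - mean(y))^2)
  structure(list(model = if (k == 1) "single" else "double",
                 transitions = tr, y0 = par[1],
                 r_squared = 1 - sse / sst,
                 chi_squared = sse,
                 chi_squared_reduced = sse / max(1, n - length(par)),
                 fitted = boltzmann_model(par, temperature, k),
                 temperature = temperature,
                 unresolved = unresolved),
            class = "melting_fit")
}

numeric_jacobian <- function(f, par, eps = 1e-6) {
  f0 <- f(par)
  J <- matrix(NA_real_, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(1, abs(par[j]))
    pj <- par; pj[j] <- pj[j] + h
    J[, j] <- (f(pj) - f0) / h
  }
  J
}

#' @export
print.melting_fit <- function(x, ...) {
  cat(sprintf("<melting_fit> %s Boltzmann, R^2 = %.4f, chi^2 = %.4g%s\n",
              x$model, x$r_squared, x$chi_squared,
              if (isTRUE(x$unresolved)) " (centres unresolved)" else ""))
  print(x$transitions)
  invisible(x)
}

#' Extract melting features from a DSC thermogram
#'
#' The main-peak maximum T_max is refined by parabolic interpolation; the
#' onset T_onset is the intersection of the extrapolated pre-transition
#' baseline (linear fit over the quiet leading region) with the tangent at
#' the leading-edge inflection (steepest ascent). Local maxima outside the
#' main peak whose height above baseline exceeds
#' \code{prominence * main height} are reported as minor events.
#'
#' @param thermogram data.frame with \code{temperature} and
#'   \code{heat_flow} (e.g. from [make_dsc()])
#' @param prominence minor-event height threshold, fraction of main height
#' @param smooth_points Savitzky-Golay window applied before derivative
#'   estimation (0 = no smoothing)
#' @return list with \code{T_max}, \code{T_onset}, \code{height} and
#'   data.frame \code{minor_events} (temperature, height)
#' @export
dsc_features <- function(thermogram, prominence = 0.02,
                         smooth_points = 0L) {
  tt <- thermogram$temperature
  y <- thermogram$heat_flow
  if (smooth_points >= 4) y <- smooth_sg(y, smooth_points, 3L)
  n <- length(y)
  # pre-transition baseline from the quiet leading 15% of the scan
  lead <- seq_len(max(5L, round(0.15 * n)))
  bl <- stats::lm(y[lead] ~ tt[lead])
  base <- stats::coef(bl)[1] + stats::coef(bl)[2] * tt
  excess <- y - base
  imax <- which.max(excess)
  height <- excess[imax]
  # a peak must rise clearly above the leading-region scatter
  floor_h <- 5 * stats::sd(excess[lead]) + 1e-10 * max(1, abs(height))
  if (!is.finite(height) || height <= floor_h)
    stop("no peak above the extrapolated baseline")
  T_max <- parabolic_peak(tt, y, imax)
  # leading-edge inflection: steepest slope on the rising flank
  rise_lo <- max(which(excess[seq_len(imax)] < 0.05 * height), 1L)
  dy <- diff(y) / diff(tt)
  flank <- rise_lo:max(rise_lo, imax - 1L)
  iflex <- flank[which.max(dy[flank])]
  slope <- dy[iflex]
  Tf <- (tt[iflex] + tt[iflex + 1]) / 2
  yf <- (y[iflex] + y[iflex + 1]) / 2
  b0 <- stats::coef(bl)[[1]]; b1 <- stats::coef(bl)[[2]]
  T_onset <- if (abs(slope - b1) < .Machine$double.eps) NA_real_ else
    (b0 - (yf - slope * Tf)) / (slope - b1)
  # minor events: local maxima outside the main peak's footprint
  in_main <- excess > 0.05 * height &
    cumsum(seq_len(n) >= rise_lo) > 0 &
    seq_len(n) <= {
      after <- which(excess[imax:n] < 0.05 * height)
      if (length(after)) imax + after[1] - 1L else n
    }
  loc <- which(diff(sign(diff(excess))) == -2) + 1L
  loc <- loc[!in_main[loc] & excess[loc] > prominence * height]
  minor <- data.frame(
    temperature = vapply(loc, function(i) parabolic_peak(tt, excess, i),
                         numeric(1)),
    height = excess[loc])
  list(T_max = T_max, T_onset = unname(T_onset), height = height,
       minor_events = minor)
}

#' Band maxima of a spectrum
#'
#' Local maxima inside the stated abscissa window after optional smoothing,
#' refined by parabolic sub-grid interpolation. Maxima whose height above
#' the window minimum is below \code{prominence} times the window's signal
#' span are discarded; a flat spectrum yields none.
#'
#' @param x abscissa (e.g. wavenumber, cm^-1)
#' @param y intensities
#' @param window length-2 abscissa window to search (default: all of x)
#' @param smooth_points Savitzky-Golay window (0 = none)
#' @param prominence minimum relative height of a reported maximum
#' @return numeric vector of peak positions, increasing
#' @export
band_maxima <- function(x, y, window = NULL, smooth_points = 0L,
                        prominence = 0.01) {
  window <- window %||% range(x)
  keep <- x >= min(window) & x <= max(window)
  xs <- x[keep]; ys <- y[keep]
  if (length(xs) < 3) return(numeric(0))
  if (smooth_points >= 4 && smooth_points <= length(ys))
    ys <- smooth_sg(ys, smooth_points, 3L)
  span <- diff(range(ys))
  if (span <= 0) return(numeric(0))
  loc <- which(diff(sign(diff(ys))) == -2) + 1L
  loc <- loc[ys[loc] - min(ys) > prominence * span]
  sort(vapply(loc, function(i) parabolic_peak(xs, ys, i), numeric(1)))
}

#' Heat capacity from enthalpy fluctuations
#'
#' c_p = (<H^2> - <H>^2) / (R T^2) with the unbiased sample variance.
#' With H in kJ mol^-1 the result is returned in J mol^-1 K^-1.
#'
#' @param H enthalpy samples, kJ mol^-1
#' @param temperature_K absolute temperature, K
#' @return heat capacity, J mol^-1 K^-1
#' @export
heat_capacity_fluct <- function(H, temperature_K) {
  if (length(H) < 2) stop("need at least 2 samples")
  if (temperature_K <= 0) stop("temperature must be positive (K)")
  stats::var(H) * 1e6 / (unit_constants$R_J * temperature_K^2)
}

#' Isothermal area compressibility from area fluctuations
#'
#' kappa_A^T = (<A^2> - <A>^2) / (<A> R T), unbiased variance. With A in
#' nm^2 and R in J mol^-1 K^-1 the result carries units nm^2 mol J^-1.
#'
#' @param A area samples, nm^2
#' @param temperature_K absolute temperature, K
#' @param R gas constant (default J mol^-1 K^-1)
#' @return area compressibility
#' @export
area_compressibility <- function(A, temperature_K,
                                 R = unit_constants$R_J) {
  if (length(A) < 2) stop("need at least 2 samples")
  if (temperature_K <= 0) stop("temperature must be positive (K)")
  stats::var(A) / (mean(A) * R * temperature_K)
}

#' Bending modulus from thickness and area compressibility
#'
#' K_A = d^2 / (16 kappa_A^T).
#'
#' @param d membrane thickness, nm
#' @param kappa_A area compressibility (> 0)
#' @return bending modulus, in units of nm^2 divided by the units of kappa_A
#' @export
bending_modulus <- function(d, kappa_A) {
  if (kappa_A <= 0)
    stop("kappa_A must be positive (zero gives an infinite modulus)")
  d^2 / (16 * kappa_A)
}
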