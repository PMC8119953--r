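## CDOM absorbance -> absorption, spectral slopes, SUVA254.

#' Construct an absorbance spectrum
#'
#' Container for a decadal absorbance scan from a spectrophotometer.
#' Absorbance is dimensionless (log10 attenuation over the cuvette), measured
#' on a strictly increasing wavelength grid, typically 220--750 nm at 1-nm
#' steps with a 0.05 m (5 cm) pathlength.
#'
#' @param wavelengths numeric vector of wavelengths (nm), strictly increasing.
#' @param absorbance numeric vector of decadal absorbance values, same length.
#' @param pathlength cuvette pathlength in metres (default 0.05).
#' @param replicate_id optional scan label.
#' @param blank_corrected logical; whether a blank has already been subtracted.
#' @return An object of class `"absorbance_spectrum"`.
#' @seealso [absorbance_to_absorption()], [fit_spectral_slope()]
#' @export
absorbance_spectrum <- function(wavelengths, absorbance, pathlength = 0.05,
                                replicate_id = NA_character_, blank_corrected = TRUE) {
  stop_if_not_increasing(wavelengths, "wavelengths")
  if (length(absorbance) != length(wavelengths))
    stop("absorbance and wavelengths must have equal length", call. = FALSE)
  if (!is.numeric(pathlength) || length(pathlength) != 1L || pathlength <= 0)
    stop("pathlength must be a single positive number (metres)", call. = FALSE)
  structure(list(wavelengths = as.numeric(wavelengths),
                 absorbance = as.numeric(absorbance),
                 pathlength = pathlength,
                 replicate_id = replicate_id,
                 blank_corrected = isTRUE(blank_corrected)),
            class = "absorbance_spectrum")
}

#' @export
print.absorbance_spectrum <- function(x, ...) {
  cat(sprintf("<absorbance_spectrum> %d points, %.0f-%.0f nm, pathlength %.3g m\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths), x$pathlength))
  invisible(x)
}

#' Average replicate absorbance scans with robust outlier screening
#'
#' Replicate scans of the same sample are screened before averaging: a scan is
#' dropped when its mean absolute deviation from the pointwise median spectrum
#' (over the screening window, default 250--500 nm) exceeds `k` times the
#' median of those deviations across scans. Retained scans are averaged
#' pointwise.
#'
#' @param spectra list of [absorbance_spectrum()] objects on a common grid.
#' @param k outlier multiplier on the median scan deviation (default 5).
#' @param window numeric length-2 wavelength window (nm) used for screening.
#' @return An `absorbance_spectrum` with attribute `n_retained` and
#'   `dropped` (indices of discarded scans).
#' @export
average_replicates <- function(spectra, k = 5, window = c(250, 500)) {
  if (!length(spectra)) stop("need at least one spectrum", call. = FALSE)
  if (length(spectra) == 1L) {
    out <- spectra[[1L]]
    attr(out, "n_retained") <- 1L
    attr(out, "dropped") <- integer()
    return(out)
  }
  wl <- spectra[[1L]]$wavelengths
  for (s in spectra)
    if (!isTRUE(all.equal(s$wavelengths, wl)))
      stop("all replicate scans must share one wavelength grid", call. = FALSE)
  A <- sapply(spectra, function(s) s$absorbance)   # wl x n
  idx <- wl >= window[1] & wl <= window[2]
  med <- apply(A[idx, , drop = FALSE], 1L, stats::median)
  dev <- colMeans(abs(A[idx, , drop = FALSE] - med))
  ref <- stats::median(dev)
  drop <- if (ref > 0) which(dev > k * ref) else integer()
  keep <- setdiff(seq_along(spectra), drop)
  if (!length(keep)) stop("all replicate scans flagged as outliers", call. = FALSE)
  out <- absorbance_spectrum(wl, rowMeans(A[, keep, drop = FALSE]),
                             pathlength = spectra[[1L]]$pathlength,
                             replicate_id = "mean",
                             blank_corrected = spectra[[1L]]$blank_corrected)
  attr(out, "n_retained") <- length(keep)
  attr(out, "dropped") <- drop
  out
}

#' Convert decadal absorbance to Napierian absorption coefficients
#'
#' Applies a_CDOM(lambda) = 2.303 * A(lambda) / l, with l the pathlength in
#' metres, giving Napierian absorption coefficients in 1/m.
#'
#' @param spec an [absorbance_spectrum()]; must be blank-corrected.
#' @return An object of class `"absorption_spectrum"` with fields
#'   `wavelengths` (nm) and `a_cdom` (1/m).
#' @export
absorbance_to_absorption <- function(spec) {
  stopifnot(inherits(spec, "absorbance_spectrum"))
  if (!isTRUE(spec$blank_corrected))
    stop("absorbance must be blank-corrected before conversion", call. = FALSE)
  if (spec$pathlength <= 0) stop("pathlength must be positive", call. = FALSE)
  structure(list(wavelengths = spec$wavelengths,
                 a_cdom = 2.303 * spec$absorbance / spec$pathlength),
            class = "absorption_spectrum")
}

#' @export
print.absorption_spectrum <- function(x, ...) {
  cat(sprintf("<absorption_spectrum> %d points, %.0f-%.0f nm, a(350) = %.3g 1/m\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              interp_onto(x$wavelengths, x$a_cdom, 350)))
  invisible(x)
}

#' Absorption coefficient at a given wavelength
#'
#' @param a an `absorption_spectrum`.
#' @param lambda wavelength(s) in nm; linearly interpolated onto the grid.
#' @return numeric vector of a_CDOM(lambda) in 1/m.
#' @export
absorption_at <- function(a, lambda) {
  stopifnot(inherits(a, "absorption_spectrum"))
  interp_onto(a$wavelengths, a$a_cdom, lambda)
}

#' Fit an exponential spectral slope to a CDOM absorption spectrum
#'
#' Fits a_CDOM(lambda) = a_CDOM(lambda0) * exp(-S * (lambda - lambda0)) by
#' unweighted nonlinear least squares over a wavelength window, with the
#' reference wavelength lambda0 fixed at the window midpoint (285 nm for
#' 275--295, 375 nm for 350--400). A log-linear regression provides starting
#' values and is available separately as a cross-check
#' ([fit_spectral_slope_loglinear()]).
#'
#' @param a an `absorption_spectrum`.
#' @param range numeric length-2 fit window in nm, e.g. `c(275, 295)`.
#' @return An object of class `"slope_fit"`: list with `S` (1/nm), `a_ref`
#'   (1/m at `lambda0`), `lambda0`, `fit_range`, `rss`, `converged`.
#' @examples
#' wl <- 220:750
#' a <- structure(list(wavelengths = wl, a_cdom = 10 * exp(-0.0175 * (wl - 350))),
#'                class = "absorption_spectrum")
#' fit_spectral_slope(a, c(350, 400))$S
#' @export
fit_spectral_slope <- function(a, range) {
  stopifnot(inherits(a, "absorption_spectrum"), length(range) == 2L)
  range <- sort(range)
  idx <- a$wavelengths >= range[1] & a$wavelengths <= range[2]
  if (sum(idx) < 3L) stop("fit range covers fewer than 3 grid points", call. = FALSE)
  wl <- a$wavelengths[idx]
  y <- a$a_cdom[idx]
  if (any(y <= 0))
    stop("nonpositive absorption inside the fit range; slope fit aborted", call. = FALSE)
  lambda0 <- mean(range)
  # log-linear start (exact when the spectrum is a pure exponential)
  lf <- stats::lm(log(y) ~ I(wl - lambda0))
  start <- list(a0 = exp(unname(stats::coef(lf)[1])), S = -unname(stats::coef(lf)[2]))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a0 * exp(-S * (wl - lambda0)),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(S = start$S, a_ref = start$a0, lambda0 = lambda0, fit_range = range,
                rss = sum((y - start$a0 * exp(-start$S * (wl - lambda0)))^2), converged = FALSE)
  } else {
    cf <- stats::coef(fit)
    out <- list(S = unname(cf["S"]), a_ref = unname(cf["a0"]), lambda0 = lambda0,
                fit_range = range, rss = sum(stats::resid(fit)^2), converged = TRUE)
  }
  class(out) <- "slope_fit"
  out
}

#' Log-linear spectral slope (cross-check)
#'
#' Ordinary least squares of log(a_CDOM) against wavelength over the window;
#' used as an independent check on [fit_spectral_slope()].
#'
#' @inheritParams fit_spectral_slope
#' @return list with `S` (1/nm) and `a_ref` at the window midpoint.
#' @export
fit_spectral_slope_loglinear <- function(a, range) {
  stopifnot(inherits(a, "absorption_spectrum"), length(range) == 2L)
  range <- sort(range)
  idx <- a$wavelengths >= range[1] & a$wavelengths <= range[2]
  wl <- a$wavelengths[idx]; y <- a$a_cdom[idx]
  if (any(y <= 0)) stop("nonpositive absorption inside the fit range", call. = FALSE)
  lambda0 <- mean(range)
  lf <- stats::lm(log(y) ~ I(wl - lambda0))
  list(S = -unname(stats::coef(lf)[2]), a_ref = exp(unname(stats::coef(lf)[1])),
       lambda0 = lambda0)
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("<slope_fit> S = %.6g 1/nm over %g-%g nm (lambda0 = %g), a(lambda0) = %.4g 1/m%s\n",
              x$S, x$fit_range[1], x$fit_range[2], x$lambda0, x$a_ref,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' @export
coef.slope_fit <- function(object, ...) c(S = object$S, a_ref = object$a_ref)

#' Specific UV absorbance at 254 nm (SUVA254)
#'
#' SUVA254 = (A(254) / pathlength_m) / DOC, in L per mg C per m; an
#' aromaticity proxy for dissolved organic matter.
#'
#' @param A254 decadal absorbance at 254 nm (dimensionless).
#' @param pathlength cuvette pathlength in metres.
#' @param doc dissolved organic carbon concentration, mg C per L.
#' @return SUVA254 in L mg-C^-1 m^-1.
#' @export
suva254 <- function(A254, pathlength, doc) {
  if (any(doc <= 0)) stop("DOC must be positive", call. = FALSE)
  if (any(pathlength <= 0)) stop("pathlength must be positive", call. = FALSE)
  (A254 / pathlength) / doc
}
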