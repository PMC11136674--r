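# Spectral containers and band integration.
#
# Every tabulated function of wavelength (surface reflectivity rho_lambda,
# transmissivity tau_lambda, source flux S_lambda, camera response C_lambda)
# is a `crt_spectrum`: a strictly increasing wavelength grid in nm and a
# vector of non-negative values. Band quantities are trapezoidal integrals
# over a waveband, with the band-weighted surface properties
#
#   rho   = int rho_l S_l dl / int S_l dl
#   rho_o = int rho_l C_l S_l dl / int S_l dl
#
# (and likewise for tau). Note the denominator of the camera-weighted
# properties deliberately excludes C_lambda.

#' Wavelength grid shared by the leaf-optics tables
#'
#' The package's common internal wavelength grid: 400--2500 nm at 1-nm
#' spacing (the native range of the leaf optical model). Spectra supplied on
#' other grids are resampled onto grids derived from this one when band
#' properties are computed.
#'
#' @return Integer vector of wavelengths in nm.
#' @export
crt_grid <- function() 400:2500

#' Stefan-Boltzmann constant (W m-2 K-4)
#' @keywords internal
SIGMA_SB <- 5.670374419e-8

#' Create a spectrum
#'
#' @param wavelengths_nm Strictly increasing numeric vector, nm.
#' @param values Non-negative numeric vector, same length. Units depend on
#'   the role of the spectrum: dimensionless for reflectivity,
#'   transmissivity and camera response; W m-2 nm-1 for source fluxes.
#' @return An object of class `crt_spectrum`.
#' @export
spectrum <- function(wavelengths_nm, values) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  values <- as.numeric(values)
  if (length(wavelengths_nm) == 0L) stop("empty wavelength grid")
  if (length(wavelengths_nm) != length(values)) {
    stop("wavelengths and values must have the same length")
  }
  if (any(!is.finite(wavelengths_nm)) || any(!is.finite(values))) {
    stop("non-finite entries in spectrum")
  }
  if (any(diff(wavelengths_nm) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  if (any(values < 0)) stop("spectrum values must be non-negative")
  structure(list(wavelengths_nm = wavelengths_nm, values = values),
            class = "crt_spectrum")
}

#' Constant spectrum over a wavelength range
#'
#' @param value The constant value.
#' @param range Two-element range in nm (default the internal grid range).
#' @param step Grid step in nm.
#' @export
constant_spectrum <- function(value, range = c(400, 2500), step = 1) {
  wl <- seq(range[1], range[2], by = step)
  spectrum(wl, rep(value, length(wl)))
}

#' @export
print.crt_spectrum <- function(x, ...) {
  cat(sprintf("<crt_spectrum> %d points, %.0f-%.0f nm, values in [%.4g, %.4g]\n",
              length(x$wavelengths_nm), min(x$wavelengths_nm),
              max(x$wavelengths_nm), min(x$values), max(x$values)))
  invisible(x)
}

is_spectrum <- function(x) inherits(x, "crt_spectrum")

#' Define a waveband
#'
#' @param label Band name (used to key fluxes, responses and images).
#' @param lambda_min_nm,lambda_max_nm Band bounds in nm.
#' @param longwave Logical; longwave (thermal) bands receive emitted energy
#'   from primitives and the longwave sky rather than from external sources.
#' @export
waveband <- function(label, lambda_min_nm, lambda_max_nm, longwave = FALSE) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!(lambda_min_nm < lambda_max_nm)) stop("lambda_min_nm must be < lambda_max_nm")
  structure(list(label = label, lambda_min_nm = lambda_min_nm,
                 lambda_max_nm = lambda_max_nm, longwave = isTRUE(longwave)),
            class = "crt_waveband")
}

#' @export
print.crt_waveband <- function(x, ...) {
  cat(sprintf("<crt_waveband> %s: %.0f-%.0f nm%s\n", x$label, x$lambda_min_nm,
              x$lambda_max_nm, if (x$longwave) " (longwave)" else ""))
  invisible(x)
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; wavelengths outside the source support evaluate to
#' zero.
#'
#' @param spec A [spectrum()].
#' @param grid Target wavelengths, nm.
#' @return A `crt_spectrum` on `grid`.
#' @export
resample <- function(spec, grid) {
  stopifnot(is_spectrum(spec))
  grid <- as.numeric(grid)
  if (length(grid) == 0L) stop("empty target grid")
  v <- stats::approx(spec$wavelengths_nm, spec$values, xout = grid,
                     method = "linear", rule = 1)$y
  v[is.na(v)] <- 0
  spectrum(grid, v)
}

# Evaluate a spectrum at arbitrary wavelengths (0 outside support).
spec_at <- function(spec, wl) {
  v <- stats::approx(spec$wavelengths_nm, spec$values, xout = wl,
                     method = "linear", rule = 1)$y
  v[is.na(v)] <- 0
  v
}

# Integration grid for a band: union of all knots of `specs` inside the band
# plus the band endpoints (values at the endpoints come from linear
# interpolation, i.e. the band bounds clip the end intervals).
band_knots <- function(band, specs) {
  wl <- sort(unique(unlist(lapply(specs, function(s) s$wavelengths_nm))))
  wl <- wl[wl > band$lambda_min_nm & wl < band$lambda_max_nm]
  sort(unique(c(band$lambda_min_nm, wl, band$lambda_max_nm)))
}

# Integral over the band of the pointwise product of spectra, each linearly
# interpolated (zero outside support). Composite Simpson per union-knot
# interval: between adjacent knots every factor is linear, so the product
# is a polynomial of degree <= 3 and Simpson integrates it exactly.
band_product_integral <- function(band, specs) {
  wl <- band_knots(band, specs)
  if (length(wl) < 2L) return(0)
  mid <- (wl[-1] + wl[-length(wl)]) / 2
  fa <- rep(1, length(wl)); fm <- rep(1, length(mid))
  for (s in specs) {
    fa <- fa * spec_at(s, wl)
    fm <- fm * spec_at(s, mid)
  }
  h <- diff(wl)
  sum(h / 6 * (fa[-length(fa)] + 4 * fm + fa[-1]))
}

#' Integrate a source spectrum over a band
#'
#' Quadrature of S_lambda over the band on the spectrum's knot grid (exact
#' for the linear interpolant); the band bounds clip the end intervals by
#' linear interpolation.
#'
#' @param S Source spectrum (W m-2 nm-1).
#' @param band A [waveband()].
#' @return Band flux in W m-2. Zero (with a warning) when the band does not
#'   overlap the support of `S`.
#' @export
band_integrate_source <- function(S, band) {
  stopifnot(is_spectrum(S), inherits(band, "crt_waveband"))
  if (band$lambda_max_nm <= min(S$wavelengths_nm) ||
      band$lambda_min_nm >= max(S$wavelengths_nm)) {
    warning(sprintf("band %s does not overlap source support; flux is 0", band$label))
    return(0)
  }
  band_product_integral(band, list(S))
}

#' Band-integrated surface properties (source-weighted means)
#'
#' The band reflectivity and transmissivity used for scattering between
#' objects: source-weighted means of the spectral properties over the band,
#' i.e. the camera-weighted property with C_lambda identically 1.
#'
#' @param rho,tau Reflectivity / transmissivity spectra (dimensionless).
#' @param S Source spectrum (W m-2 nm-1).
#' @param band A [waveband()].
#' @return `list(rho=, tau=)`.
#' @export
band_surface_props <- function(rho, tau, S, band) {
  p <- band_camera_props(rho, tau, C = NULL, S = S, band = band)
  list(rho = p$rho_o, tau = p$tau_o)
}

#' Camera-weighted band surface properties
#'
#' Per-band reflectivity and transmissivity as sensed through a camera
#' channel with normalized spectral response C_lambda:
#' `rho_o = int rho_l C_l S_l dl / int S_l dl` (and likewise `tau_o`). The
#' denominator excludes C_lambda, so `rho_o <= rho` whenever
#' `C_lambda <= 1`.
#'
#' @param rho,tau Reflectivity / transmissivity spectra.
#' @param C Camera response spectrum (values in `[0,1]`), or `NULL` for a
#'   response of exactly 1 everywhere (which reduces to
#'   [band_surface_props()]).
#' @param S Source spectrum.
#' @param band A [waveband()].
#' @return `list(rho_o=, tau_o=)`.
#' @export
band_camera_props <- function(rho, tau, C, S, band) {
  stopifnot(is_spectrum(rho), is_spectrum(tau), is_spectrum(S),
            inherits(band, "crt_waveband"))
  Cs <- if (is.null(C)) list() else {
    stopifnot(is_spectrum(C))
    if (any(C$values > 1 + 1e-12)) stop("camera response C must be <= 1")
    list(C)
  }
  denom <- band_product_integral(band, list(S))
  if (denom <= 0) stop(sprintf("source has zero energy in band %s", band$label))
  list(rho_o = band_product_integral(band, c(list(rho, S), Cs)) / denom,
       tau_o = band_product_integral(band, c(list(tau, S), Cs)) / denom)
}

#' Black-body emitted flux (Stefan-Boltzmann law)
#'
#' @param temperature_k Temperature in kelvin (>= 0).
#' @param emissivity Dimensionless emissivity in `[0,1]`.
#' @return Emitted flux, W m-2.
#' @export
stefan_boltzmann_flux <- function(temperature_k, emissivity = 1) {
  if (any(temperature_k < 0)) stop("temperature must be >= 0 K")
  if (any(emissivity < 0 | emissivity > 1)) stop("emissivity must be in [0,1]")
  emissivity * SIGMA_SB * temperature_k^4
}

#' Read / write a spectrum as two-column delimited text
#'
#' Column 1 is wavelength in nm, column 2 the value; `#` comments allowed.
#'
#' @param path File path.
#' @return [read_spectrum()] returns a `crt_spectrum`.
#' @export
read_spectrum <- function(path) {
  d <- utils::read.table(path, header = FALSE, comment.char = "#")
  if (ncol(d) < 2L) stop("expected two columns: wavelength_nm, value")
  spectrum(d[[1]], d[[2]])
}

#' @param spec A `crt_spectrum`.
#' @rdname read_spectrum
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(is_spectrum(spec))
  utils::write.table(
    data.frame(wavelength_nm = spec$wavelengths_nm, value = spec$values),
    path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
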