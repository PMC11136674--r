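# Radiation sources.
#
# External sources (collimated sun, sun sphere, terrestrial sphere / disk /
# rectangle, diffuse sky) carry per-band fluxes or powers plus a spectral
# distribution used for band-integrating surface properties. Longwave
# sources (sky, and emission from the primitives themselves) are specified
# by temperature; their flux follows the Stefan-Boltzmann law and no
# explicit spectral distribution is used.

new_source <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "crt_source")
}

check_fluxes <- function(fluxes) {
  if (is.null(names(fluxes)) || any(!nzchar(names(fluxes)))) {
    stop("band fluxes must be a named vector keyed by band label")
  }
  if (any(fluxes < 0)) stop("fluxes must be >= 0")
  fluxes
}

#' Collimated (sun-like) source
#'
#' @param direction Length-3 vector pointing from the scene toward the
#'   source (normalized internally).
#' @param fluxes Named numeric: flux per band on a plane perpendicular to
#'   the beam, W m-2.
#' @param spectrum Spectral distribution `S_lambda` (W m-2 nm-1, relative
#'   scale is sufficient: band weighting normalizes it out).
#' @return A `crt_source`.
#' @export
source_collimated <- function(direction = c(0, 0, 1), fluxes,
                              spectrum = constant_spectrum(1)) {
  new_source("collimated", direction = normalize3(direction),
             fluxes = check_fluxes(fluxes), spectrum = spectrum)
}

#' Sun-sphere source (finite angular size)
#'
#' Collimated sun broadened to a disk of angular radius
#' `angular_radius_deg` (default the solar value, 0.266 deg), producing
#' penumbral shadow edges. The collimated source is its zero-width limit.
#'
#' @inheritParams source_collimated
#' @param angular_radius_deg Angular radius of the solar disk, degrees.
#' @export
source_sun_sphere <- function(direction = c(0, 0, 1), fluxes,
                              spectrum = constant_spectrum(1),
                              angular_radius_deg = 0.266) {
  new_source("sun_sphere", direction = normalize3(direction),
             fluxes = check_fluxes(fluxes), spectrum = spectrum,
             angular_radius_deg = angular_radius_deg)
}

#' Terrestrial spherical source (e.g. a light bulb)
#'
#' Isotropic Lambertian sphere emitting total radiant power `power[band]`
#' watts per band.
#'
#' @param position Sphere center, m.
#' @param radius Sphere radius, m.
#' @param power Named numeric: radiant power per band, W.
#' @inheritParams source_collimated
#' @export
source_sphere <- function(position, radius, power,
                          spectrum = constant_spectrum(1)) {
  if (radius <= 0) stop("radius must be > 0")
  new_source("sphere", position = as.numeric(position), radius = radius,
             power = check_fluxes(power), spectrum = spectrum)
}

#' Terrestrial disk source emitting from one side (e.g. halogen lamp)
#'
#' One-sided cosine (Lambertian) emitter of total power `power[band]` W.
#'
#' @param position Disk center, m.
#' @param normal Emitting-side normal.
#' @param radius Disk radius, m.
#' @inheritParams source_sphere
#' @export
source_disk <- function(position, normal, radius, power,
                        spectrum = constant_spectrum(1)) {
  if (radius <= 0) stop("radius must be > 0")
  new_source("disk", position = as.numeric(position),
             normal = normalize3(normal), radius = radius,
             power = check_fluxes(power), spectrum = spectrum)
}

#' Terrestrial rectangular source emitting from one side (e.g. LED array)
#'
#' @param size Length-2 `(width, height)`, m.
#' @inheritParams source_disk
#' @export
source_rectangle <- function(position, normal, size, power,
                             spectrum = constant_spectrum(1)) {
  if (any(size <= 0)) stop("size must be > 0")
  new_source("rectangle", position = as.numeric(position),
             normal = normalize3(normal), size = as.numeric(size),
             power = check_fluxes(power), spectrum = spectrum)
}

#' Diffuse (sky) shortwave source
#'
#' Isotropic sky radiance supplying `fluxes[band]` W m-2 on an
#' unobstructed horizontal surface.
#'
#' @inheritParams source_collimated
#' @export
source_diffuse_sky <- function(fluxes, spectrum = constant_spectrum(1)) {
  new_source("diffuse_sky", fluxes = check_fluxes(fluxes), spectrum = spectrum)
}

#' Diffuse longwave sky source
#'
#' Supplies `sigma * T_sky^4` W m-2 in every longwave band on an
#' unobstructed horizontal surface.
#'
#' @param temperature_k Effective sky temperature, K.
#' @export
source_longwave_sky <- function(temperature_k) {
  if (temperature_k < 0) stop("temperature must be >= 0 K")
  new_source("longwave_sky", temperature_k = temperature_k)
}

is_external_source <- function(s) {
  s$kind %in% c("collimated", "sun_sphere", "sphere", "disk", "rectangle")
}

source_band_flux <- function(s, label) {
  f <- if (!is.null(s$fluxes)) s$fluxes else s$power
  if (is.null(f) || is.na(f[label])) 0 else unname(f[label])
}

#' @export
print.crt_source <- function(x, ...) {
  cat(sprintf("<crt_source> %s\n", x$kind))
  invisible(x)
}
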