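# Canonical test scenes with analytically known expectations.
#
# These fixtures make the package testable with no external data: each one
# returns a scene (plus bands, camera, sources) together with an
# `expected` record of closed-form values derived from the geometry.

#' Generate a canonical fixture scene
#'
#' * `single_plate`: a horizontal 1 m2 plate (rho = 0.3, tau = 0.2) under a
#'   collimated zenith source of 1000 W m-2 with a nadir camera. Expected:
#'   absorbed flux `(1 - rho - tau) * S * cos(theta) = 500` W m-2 and
#'   interior pixel value `rho_o * S = 300` W m-2.
#' * `occlusion_pair`: two stacked horizontal plates under a nadir camera;
#'   the smaller front plate occludes the center of the larger back plate.
#'   Expected: front uid and depth in the covered region.
#' * `mini_canopy`: a tiled ground plus a seeded cloud of leaf patches
#'   with spectral optics, a collimated sun at 30 deg zenith and a diffuse
#'   sky, in two bands (red, NIR).
#' * `color_board`: the synthetic 18-patch color target, a flat illuminant,
#'   RGB channel bands and a smooth in-span "true" camera response, with
#'   the corresponding noise-free measured patch values.
#'
#' @param name Fixture name.
#' @param seed Seed for the randomized fixtures.
#' @return A list with components depending on the fixture (`scene`,
#'   `bands`, `camera`, `cfg`, `expected`, ...).
#' @export
generate_fixture <- function(name = c("single_plate", "occlusion_pair",
                                      "mini_canopy", "color_board"),
                             seed = 1L) {
  name <- match.arg(name)
  switch(name,
         single_plate = fixture_single_plate(),
         occlusion_pair = fixture_occlusion_pair(),
         mini_canopy = fixture_mini_canopy(seed),
         color_board = fixture_color_board(seed))
}

fixture_single_plate <- function(zenith_deg = 0, flux = 1000,
                                 rho = 0.3, tau = 0.2) {
  z <- zenith_deg * pi / 180
  dir <- c(sin(z), 0, cos(z))
  band <- waveband("sw", 400, 700)
  plate <- make_patch(center = c(0, 0, 0), size = c(1, 1),
                      optics_front = optics(rho = rho, tau = tau),
                      data = list(plate_id = 1L, temperature = 300))
  src <- source_collimated(direction = dir, fluxes = c(sw = flux))
  sc <- scene(list(plate), sources = list(src))
  cam <- camera_rig(
    camera_intrinsics(hfov = 20 * pi / 180, resolution = c(32L, 32L),
                      lens_diameter = 0, focal_plane_distance = 2,
                      samples_per_pixel = 4L),
    camera_pose(position = c(0, 0, 2), lookat = c(0, 0, 0)),
    label = "nadir")
  list(scene = sc, bands = list(band), camera = cam,
       expected = list(absorbed = (1 - rho - tau) * flux * cos(z),
                       pixel = rho * flux * cos(z)))
}

fixture_occlusion_pair <- function() {
  band <- waveband("sw", 400, 700)
  front <- make_patch(center = c(0, 0, 1), size = c(0.5, 0.5),
                      optics_front = optics(rho = 0.4),
                      data = list(plate_id = 1L, temperature = 300))
  back <- make_patch(center = c(0, 0, 0), size = c(2, 2),
                     optics_front = optics(rho = 0.2),
                     data = list(plate_id = 2L, temperature = 310))
  src <- source_collimated(direction = c(0, 0, 1), fluxes = c(sw = 1000))
  sc <- scene(list(front, back), sources = list(src))
  cam <- camera_rig(
    camera_intrinsics(hfov = 30 * pi / 180, resolution = c(32L, 32L),
                      lens_diameter = 0, focal_plane_distance = 5,
                      samples_per_pixel = 2L),
    camera_pose(position = c(0, 0, 5), lookat = c(0, 0, 0)),
    label = "nadir")
  list(scene = sc, bands = list(band), camera = cam,
       expected = list(front_uid = sc$primitives[[1]]$uid,
                       front_depth = 4, back_depth = 5,
                       front_temperature = 300, back_temperature = 310))
}

#' @keywords internal
leaf_demo_spectra <- function() {
  wl <- seq(400, 1000, by = 5)
  rho <- 0.06 + 0.04 * exp(-((wl - 550) / 40)^2) +
    0.40 / (1 + exp(-(wl - 720) / 15))
  tau <- 0.04 + 0.02 * exp(-((wl - 550) / 45)^2) +
    0.38 / (1 + exp(-(wl - 722) / 16))
  list(rho = spectrum(wl, pmin(rho, 1)), tau = spectrum(wl, pmin(tau, 1)))
}

fixture_mini_canopy <- function(seed = 1L, n_leaves = 120L) {
  bands <- list(waveband("red", 600, 700), waveband("nir", 750, 900))
  ls <- leaf_demo_spectra()
  leaf_opt <- optics(rho = ls$rho, tau = ls$tau)
  ground <- build_ground(extent = c(2, 2), tiles = c(2, 2),
                         optics_front = optics(rho = 0.2),
                         data = list(class = 0L, temperature = 305))
  leaves <- with_seed(seed, {
    lapply(seq_len(n_leaves), function(i) {
      make_patch(center = c(stats::runif(1, -0.9, 0.9),
                            stats::runif(1, -0.9, 0.9),
                            stats::runif(1, 0.1, 0.8)),
                 size = c(0.12, 0.12),
                 rotation = c(stats::runif(1, 0, 0.9),
                              stats::runif(1, 0, 0.9),
                              stats::runif(1, 0, 2 * pi)),
                 optics_front = leaf_opt,
                 data = list(class = 1L, leaf_id = i, temperature = 298))
    })
  })
  src_sun <- source_collimated(
    direction = c(sin(pi / 6), 0, cos(pi / 6)),
    fluxes = c(red = 400, nir = 350))
  src_sky <- source_diffuse_sky(fluxes = c(red = 60, nir = 50))
  sc <- scene(c(ground, leaves), sources = list(src_sun, src_sky))
  cam <- camera_rig(
    camera_intrinsics(hfov = 60 * pi / 180, resolution = c(48L, 48L),
                      lens_diameter = 0, focal_plane_distance = 2.5,
                      samples_per_pixel = 2L),
    camera_pose(position = c(0, 0, 2.5), lookat = c(0, 0, 0)),
    label = "nadir")
  list(scene = sc, bands = bands, camera = cam,
       expected = list(n_primitives = length(sc$primitives)))
}

fixture_color_board <- function(seed = 42L) {
  target <- synthetic_color_board(seed)
  S <- constant_spectrum(1, range = c(380, 780), step = 2)
  bands <- list(R = waveband("R", 560, 700), G = waveband("G", 480, 600),
                B = waveband("B", 400, 520))
  model <- response_model(n_basis = 12L, range = c(400, 750))
  # smooth in-span "true" responses shaped like RGB channel sensitivities
  shape <- function(center) {
    cf <- exp(-((model$centers - center) / 60)^2)
    0.9 * cf / max(cf)
  }
  true_coef <- list(R = shape(610), G = shape(540), B = shape(460))
  responses <- lapply(true_coef, function(cf) response_from_coef(model, cf))
  measured <- predict_patch_values(target, S, responses, bands)
  list(target = target, illuminant = S, bands = bands, model = model,
       true_coef = true_coef, true_responses = responses,
       expected = list(measured = measured))
}
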