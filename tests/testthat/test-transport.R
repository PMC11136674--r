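sw <- waveband("sw", 400, 700)

flat_plate_scene <- function(zenith_deg = 0, rho = 0.3, tau = 0.2,
                             flux = 1000) {
  z <- zenith_deg * pi / 180
  plate <- make_patch(size = c(1, 1), optics_front = optics(rho, tau))
  scene(list(plate),
        sources = list(source_collimated(c(sin(z), 0, cos(z)),
                                         fluxes = c(sw = flux))))
}

test_that("collimated flux on a flat plate follows the cosine law", {
  f0 <- run_transport(flat_plate_scene(0), list(sw),
                      cfg = transport_config(seed = 3))
  expect_equal(absorbed_flux(f0, 1), 500, tolerance = 1e-12)
  expect_equal(f0$incident[1, 1, 1], 1000, tolerance = 1e-12)
  expect_equal(f0$incident[1, 1, 2], 0)

  f60 <- run_transport(flat_plate_scene(60), list(sw),
                       cfg = transport_config(seed = 3))
  expect_equal(absorbed_flux(f60, 1), 250, tolerance = 1e-9)

  # fully shadowed by an opaque plate above
  shadowed <- scene(list(make_patch(size = c(1, 1)),
                         make_patch(center = c(0, 0, 1), size = c(3, 3),
                                    optics_front = optics(rho = 0))),
                    sources = list(source_collimated(c(0, 0, 1),
                                                     fluxes = c(sw = 1000))))
  fs <- run_transport(shadowed, list(sw), cfg = transport_config(seed = 3))
  expect_equal(fs$incident[1, 1, 1], 0)
})

test_that("finite sources reproduce inverse-square and cosine emission", {
  # small sphere source far above a plate: E = P cos(0) / (4 pi D^2)
  P <- 1000; D <- 10
  sc <- scene(list(make_patch(size = c(0.2, 0.2))),
              sources = list(source_sphere(c(0, 0, D), radius = 0.2,
                                           power = c(sw = P))))
  f <- run_transport(sc, list(sw),
                     cfg = transport_config(rays_per_primitive_direct = 4000,
                                            seed = 5))
  expect_equal(f$incident[1, 1, 1], P / (4 * pi * D^2), tolerance = 0.05)

  # disk source facing the plate: E = P cos cos / (pi d^2) in the far field
  sc2 <- scene(list(make_patch(size = c(0.2, 0.2))),
               sources = list(source_disk(c(0, 0, D), normal = c(0, 0, -1),
                                          radius = 0.3, power = c(sw = P))))
  f2 <- run_transport(sc2, list(sw),
                      cfg = transport_config(rays_per_primitive_direct = 4000,
                                             seed = 5))
  expect_equal(f2$incident[1, 1, 1], P / (pi * D^2), tolerance = 0.05)

  # rectangle source tilted 60 deg away: cosine emission halves the flux
  nrm <- c(0, sin(pi / 3), -cos(pi / 3))
  sc3 <- scene(list(make_patch(size = c(0.2, 0.2))),
               sources = list(source_rectangle(c(0, 0, D), normal = nrm,
                                               size = c(0.5, 0.5),
                                               power = c(sw = P))))
  f3 <- run_transport(sc3, list(sw),
                      cfg = transport_config(rays_per_primitive_direct = 4000,
                                             seed = 5))
  expect_equal(f3$incident[1, 1, 1], P * cos(pi / 3) / (pi * D^2),
               tolerance = 0.07)
})

test_that("diffuse sky flux scales with the visible sky fraction", {
  D <- 200
  sky <- source_diffuse_sky(fluxes = c(sw = D))
  open <- scene(list(make_patch(size = c(1, 1))), sources = list(sky))
  cfg <- transport_config(rays_per_primitive_diffuse = 2000, seed = 11)
  fo <- run_transport(open, list(sw), cfg = cfg)
  expect_equal(fo$incident[1, 1, 1], D, tolerance = 1e-9)  # full sky view

  # huge opaque overhang directly above: no sky at all
  closed <- scene(list(make_patch(size = c(1, 1)),
                       make_patch(center = c(0, 0, 0.01), size = c(500, 500),
                                  optics_front = optics(rho = 0))),
                  sources = list(sky))
  fc <- run_transport(closed, list(sw), cfg = cfg)
  expect_equal(fc$incident[1, 1, 1], 0, tolerance = 1e-9)

  # half-plane overhang blocks half the cosine-weighted sky
  half <- scene(list(make_patch(size = c(0.01, 0.01)),
                     make_patch(center = c(250, 0, 0.02), size = c(500, 500),
                                optics_front = optics(rho = 0))),
                sources = list(sky))
  fh <- run_transport(half, list(sw), cfg = cfg)
  se <- D * 0.5 / sqrt(2000)   # binomial MC error scale
  expect_lt(abs(fh$incident[1, 1, 1] - D / 2), 3 * se)
})

test_that("longwave emission follows the Stefan-Boltzmann law and exchanges between plates", {
  lw <- waveband("lw", 8000, 14000, longwave = TRUE)
  lone <- scene(list(make_patch(size = c(1, 1), emissivity = 1,
                                data = list(temperature = 300))),
                sources = list())
  f <- run_transport(lone, list(lw), cfg = transport_config(seed = 2))
  sb300 <- stefan_boltzmann_flux(300)
  expect_equal(f$injected_per_band[1], 2 * sb300, tolerance = 1e-12)
  expect_equal(sum(f$escaped_per_band), 2 * sb300, tolerance = 1e-9)

  # cold plates at 0 K emit nothing
  cold <- scene(list(make_patch(size = c(1, 1), emissivity = 1,
                                data = list(temperature = 0))))
  f0 <- run_transport(cold, list(lw), cfg = transport_config(seed = 2))
  expect_equal(sum(abs(f0$absorbed)) + sum(f0$injected_per_band), 0)

  expect_error(run_transport(scene(list(make_patch())), list(lw),
                             cfg = transport_config(seed = 2)),
               "temperature")

  # two large close facing black plates: the cold plate absorbs ~ sigma T_hot^4
  hot <- make_patch(center = c(0, 0, 0.02), size = c(2, 2), emissivity = 1,
                    optics_front = optics(rho = 0),
                    data = list(temperature = 400))
  cold2 <- make_patch(center = c(0, 0, 0), size = c(2, 2), emissivity = 1,
                      optics_front = optics(rho = 0),
                      data = list(temperature = 0))
  pair <- scene(list(hot, cold2))
  fp <- run_transport(pair, list(lw),
                      cfg = transport_config(rays_per_primitive_diffuse = 800,
                                             seed = 4))
  sb400 <- stefan_boltzmann_flux(400)
  # cold top face sees the hot bottom face with view factor ~ 1
  expect_equal(fp$absorbed[2, 1, 1], sb400, tolerance = 0.04)
})

test_that("multiple reflections between facing plates match the geometric series", {
  lw <- waveband("lw", 8000, 14000, longwave = TRUE)
  # emitter (ray-black, emissivity 1) faces a rho = 0.5 mirror pair:
  # both plates rho = 0.5, emitter at T, receiver at 0 K.
  # Emitted flux E bounces: receiver absorbs E(1-rho)(1 + rho^2 + ...) =
  # E * 0.5 / (1 - 0.25) = (2/3) E for view factor ~ 1.
  em <- make_patch(center = c(0, 0, 0.01), size = c(4, 4), emissivity = 1,
                   optics_front = optics(rho = 0.5),
                   data = list(temperature = 400))
  rec <- make_patch(center = c(0, 0, 0), size = c(4, 4), emissivity = 1,
                    optics_front = optics(rho = 0.5),
                    data = list(temperature = 0))
  sc <- scene(list(em, rec))
  f <- run_transport(sc, list(lw),
                     cfg = transport_config(rays_per_primitive_diffuse = 500,
                                            max_scattering_iterations = 40,
                                            residual_fraction_tol = 1e-4,
                                            seed = 6))
  E <- stefan_boltzmann_flux(400)
  expect_equal(f$absorbed[2, 1, 1], E * 0.5 / (1 - 0.25), tolerance = 0.05)
  # the emitter's cavity-facing (back) side re-absorbs the odd bounces:
  # E * rho * (1-rho) / (1-rho^2)
  expect_equal(f$absorbed[1, 1, 2], E * 0.5 * 0.5 / (1 - 0.25),
               tolerance = 0.06)
})

test_that("the energy ledger closes and the residual contracts geometrically", {
  fx <- generate_fixture("mini_canopy", seed = 3)
  f <- run_transport(fx$scene, fx$bands, cfg = transport_config(seed = 5))
  led <- f$ledger[nrow(f$ledger), ]
  expect_equal(led$absorbed + led$escaped + led$residual, led$injected,
               tolerance = 1e-9)
  # residual after k iterations <= (max rho+tau)^k * initial scattered energy
  scat_max <- max(f$props$rho + f$props$tau)
  r0 <- f$ledger$residual[1]
  for (k in seq_len(nrow(f$ledger) - 1)) {
    expect_lte(f$ledger$residual[k + 1], scat_max^k * r0 * (1 + 1e-9))
  }
  expect_lte(led$residual, 0.005 * led$injected)
})

test_that("black scenes stop scattering after one iteration", {
  sc <- scene(list(make_patch(size = c(1, 1), optics_front = optics(0, 0)),
                   make_patch(center = c(0.1, 0, 0.5),
                              optics_front = optics(0, 0))),
              sources = list(source_collimated(c(0, 0, 1),
                                               fluxes = c(sw = 100))))
  f <- run_transport(sc, list(sw), cfg = transport_config(seed = 1))
  expect_equal(f$n_iterations, 0)
  expect_equal(f$ledger$residual[1], 0)
})

test_that("transport is deterministic and invariant to primitive order", {
  fx <- generate_fixture("mini_canopy", seed = 9)
  cfg <- transport_config(rays_per_primitive_direct = 20,
                          rays_per_primitive_diffuse = 10, seed = 123)
  f1 <- run_transport(fx$scene, fx$bands, cfg = cfg)
  f2 <- run_transport(fx$scene, fx$bands, cfg = cfg)
  expect_identical(f1$absorbed, f2$absorbed)

  perm <- rev(seq_along(fx$scene$primitives))
  sc_r <- scene(fx$scene$primitives[perm], sources = fx$scene$sources)
  f3 <- run_transport(sc_r, fx$bands, cfg = cfg)
  expect_equal(f3$absorbed[perm, , ], f1$absorbed[, , ], tolerance = 1e-12)
})

test_that("doubling the ray count shrinks the Monte Carlo error by ~ sqrt(2)", {
  # partially occluded plate: the visibility estimate is binomial with
  # sd ~ 1/sqrt(n); estimate the sd over seeds at n and 2n
  blocker <- make_patch(center = c(0.35, 0, 1), size = c(1.4, 1.4),
                        optics_front = optics(rho = 0))
  plate <- make_patch(size = c(1, 1))
  sc <- scene(list(plate, blocker),
              sources = list(source_collimated(c(0, 0, 1),
                                               fluxes = c(sw = 1000))))
  est <- function(n, seed) {
    f <- run_transport(sc, list(sw),
                       cfg = transport_config(rays_per_primitive_direct = n,
                                              seed = seed))
    f$incident[1, 1, 1]
  }
  s1 <- sd(vapply(1:40, function(s) est(50, s), numeric(1)))
  s2 <- sd(vapply(1:40, function(s) est(100, s), numeric(1)))
  expect_gt(s1 / s2, 1.15)
  expect_lt(s1 / s2, 1.80)
})
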