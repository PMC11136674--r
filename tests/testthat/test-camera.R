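test_that("image-plane distance follows the HFOV geometry", {
  intr <- camera_intrinsics(hfov = pi / 2, sensor_size = c(0.036, 0.024))
  expect_equal(image_plane_distance(intr), 0.018)
  # round trip: d * tan(hfov/2) * 2 = sensor width
  intr2 <- camera_intrinsics(hfov = 0.61, sensor_size = c(0.05, 0.03))
  expect_equal(2 * image_plane_distance(intr2) * tan(0.61 / 2), 0.05)
  # telephoto limit: d grows without bound as hfov -> 0
  d_narrow <- image_plane_distance(camera_intrinsics(hfov = 1e-4))
  expect_gt(d_narrow, 100)
  expect_error(camera_intrinsics(hfov = pi), "hfov")
})

test_that("pixel rays respect the thin-lens construction", {
  pose <- camera_pose(position = c(1, 2, 3), view_direction = c(0, 1, 0),
                      up = c(0, 0, 1))
  pin <- camera_intrinsics(hfov = 0.8, resolution = c(33L, 33L),
                           lens_diameter = 0, focal_plane_distance = 4)
  r <- sample_pixel_rays(pin, pose, pixel = c(17, 17), n = 8, seed = 2)
  # pinhole: all origins at the lens center
  expect_equal(r$origins, matrix(c(1, 2, 3), 8, 3, byrow = TRUE))
  # center pixel of an odd grid: mean direction is the view direction
  ctr <- sample_pixel_rays(pin, pose, pixel = c(17, 17), n = 500, seed = 2)
  expect_equal(colMeans(ctr$directions), c(0, 1, 0), tolerance = 2e-3)

  # thin lens: the focal point lies on the line through the image-plane
  # pixel point and the lens center (collinearity residual ~ 0)
  lens <- camera_intrinsics(hfov = 0.8, resolution = c(33L, 33L),
                            lens_diameter = 0.03, focal_plane_distance = 4)
  rr <- sample_pixel_rays(lens, pose, pixel = c(5, 28), n = 16, seed = 7)
  pin_rr <- sample_pixel_rays(pin, pose, pixel = c(5, 28), n = 16, seed = 7)
  for (i in 1:16) {
    q <- rr$focal_points[i, ]
    # focal points live on the focal plane
    expect_equal(sum((q - pose$position) * pose$forward),
                 lens$focal_plane_distance, tolerance = 1e-12)
    # the ray from the lens-disk origin passes through the focal point
    expect_equal(cross3_test(q - rr$origins[i, ], rr$directions[i, ]),
                 c(0, 0, 0), tolerance = 1e-12)
    # pinhole ray through the same pixel point passes through the lens
    # center and its own focal point: collinearity of (q - lens center)
    qp <- pin_rr$focal_points[i, ]
    expect_equal(cross3_test(qp - pose$position, pin_rr$directions[i, ]),
                 c(0, 0, 0), tolerance = 1e-12)
  }
  expect_error(sample_pixel_rays(pin, pose, pixel = c(40, 1)), "pixel")
})

test_that("the camera pass reproduces the flat-plate closed form and black scenes", {
  fx <- generate_fixture("single_plate")
  f <- run_transport(fx$scene, fx$bands, cameras = list(fx$camera),
                     cfg = transport_config(seed = 7))
  img <- camera_pass(fx$scene, f, fx$camera, seed = 7)$sw
  interior <- img[9:24, 9:24]
  se <- stats::sd(interior) / sqrt(length(interior)) + 1e-9
  expect_lt(abs(mean(interior) - fx$expected$pixel), 3 * se + 1e-6)

  black <- scene(list(make_patch(size = c(5, 5), optics_front = optics(0, 0))),
                 sources = list(source_collimated(c(0, 0, 1),
                                                  fluxes = c(sw = 1000))))
  fb <- run_transport(black, fx$bands, cameras = list(fx$camera),
                      cfg = transport_config(seed = 7))
  imgb <- camera_pass(black, fb, fx$camera, seed = 7)$sw
  expect_true(all(imgb == 0))
})

test_that("rendering is bitwise deterministic under a fixed seed", {
  fx <- generate_fixture("mini_canopy", seed = 4)
  cfg <- transport_config(rays_per_primitive_direct = 20,
                          rays_per_primitive_diffuse = 10, seed = 77)
  r1 <- render(fx$scene, fx$camera, fx$bands, cfg = cfg)
  r2 <- render(fx$scene, fx$camera, fx$bands, cfg = cfg)
  expect_identical(r1$images, r2$images)
})

test_that("defocus blur grows with lens diameter and vanishes for a pinhole", {
  sw <- waveband("sw", 400, 700)
  plate <- make_patch(center = c(-0.1, 0, 1.5), size = c(0.2, 0.5),
                      optics_front = optics(rho = 0.5))
  sc <- scene(list(plate),
              sources = list(source_collimated(c(0, 0, 1),
                                               fluxes = c(sw = 1000))))
  widths <- vapply(c(1e-6, 0.005, 0.02), function(L) {
    cam <- camera_rig(
      camera_intrinsics(hfov = 20 * pi / 180, resolution = c(96L, 96L),
                        lens_diameter = L, focal_plane_distance = 3,
                        samples_per_pixel = 48L),
      camera_pose(position = c(0, 0, 2), view_direction = c(0, 0, -1),
                  up = c(0, 1, 0)))
    f <- run_transport(sc, list(sw), cameras = list(cam),
                       cfg = transport_config(seed = 2))
    img <- camera_pass(sc, f, cam, seed = 2)$sw
    edge_transition_width(colMeans(img[40:60, ]))
  }, numeric(1))
  expect_lte(widths[1], 1)
  expect_lt(widths[1], widths[2])
  expect_lt(widths[2], widths[3])
})

test_that("annotation, depth and thermal maps equal the center-ray oracle", {
  fx <- generate_fixture("occlusion_pair")
  sc <- fx$scene; cam <- fx$camera
  lab <- annotate(sc, cam, "plate_id", background = 0)
  uidm <- annotate(sc, cam, "uid", background = 0)
  dep <- depth_image(sc, cam)
  th <- thermal_image(sc, cam, "temperature")
  the <- thermal_image(sc, cam, "emitted_flux")

  cr <- canopyrt:::camera_center_rays(cam$intrinsics, cam$pose)
  exp_lab <- lab; exp_uid <- uidm; exp_dep <- dep; exp_th <- th; exp_the <- the
  for (k in seq_along(cr$row)) {
    ref <- brute_intersect(sc, cr$origins[k, ], cr$directions[k, ])
    i <- cr$row[k]; j <- cr$col[k]
    if (is.null(ref)) {
      exp_lab[i, j] <- 0; exp_uid[i, j] <- 0
      exp_dep[i, j] <- Inf; exp_th[i, j] <- 0; exp_the[i, j] <- 0
    } else {
      p <- sc$primitives[[ref$prim]]
      exp_uid[i, j] <- ref$uid
      exp_lab[i, j] <- p$data$plate_id
      exp_dep[i, j] <- ref$dist
      exp_th[i, j] <- p$data$temperature
      exp_the[i, j] <- stefan_boltzmann_flux(p$data$temperature, p$emissivity)
    }
  }
  expect_equal(lab, exp_lab)
  expect_equal(uidm, exp_uid)
  expect_equal(dep, exp_dep, tolerance = 1e-12)
  expect_lt(max(abs(dep[is.finite(dep)] - exp_dep[is.finite(exp_dep)])), 1e-9)
  expect_equal(th, exp_th)
  expect_equal(the, exp_the)
  # nearest primitive wins where the plates overlap
  expect_equal(lab[16, 16], 1)
  expect_equal(dep[16, 16] < 4.01, TRUE)

  empty_cam_map <- annotate(scene(list(make_patch(center = c(100, 100, 0)))),
                            cam, "uid", background = -1)
  expect_true(all(empty_cam_map == -1))
  expect_warning(annotate(sc, cam, "no_such_key", background = 0), "lack")
})

test_that("oblique depth follows the ray-plane closed form", {
  # plate tilted 30 deg about x, camera on the z axis looking down
  tilt <- pi / 6
  plate <- make_patch(center = c(0, 0, 0), size = c(4, 4),
                      rotation = c(tilt, 0, 0))
  sc <- scene(list(plate))
  cam <- camera_rig(
    camera_intrinsics(hfov = 25 * pi / 180, resolution = c(21L, 21L),
                      focal_plane_distance = 5),
    camera_pose(position = c(0, 0, 5), view_direction = c(0, 0, -1),
                up = c(0, 1, 0)))
  dep <- depth_image(sc, cam)
  cr <- canopyrt:::camera_center_rays(cam$intrinsics, cam$pose)
  n <- plate$normal
  t_exp <- as.numeric(((0 - cr$origins) %*% n) / (cr$directions %*% n))
  expect_equal(dep[cbind(cr$row, cr$col)], t_exp, tolerance = 1e-12)
})

test_that("distortion remapping matches the displacement formula", {
  img <- matrix(runif_det(64 * 64, 0, 1), 64, 64)
  expect_identical(apply_distortion(img, distortion_coefficients()), img)

  # spot values of the displacement model
  co <- distortion_coefficients(p1 = 1e-6)
  sh <- distortion_shift(100, 0, co)
  expect_equal(sh$du, 1.0)
  expect_equal(sh$dv, 0.0)
  expect_equal(distortion_shift(0, 0, distortion_coefficients(1, 2, 3, 4))$du, 0)
  tang <- distortion_shift(10, 5, distortion_coefficients(p3 = 1e-3))
  expect_equal(tang$du, 2 * 1e-3 * 10 * 5)
  expect_equal(tang$dv, 1e-3 * (125 + 2 * 25))

  # barrel parameters pull pixels inward leaving background at the border
  bar <- apply_distortion(img, distortion_coefficients(p1 = -1e-4),
                          background = -1)
  expect_gt(sum(bar[c(1, 64), ] == -1) + sum(bar[, c(1, 64)] == -1), 0)
  # the center pixel never moves
  ctr <- apply_distortion(img, distortion_coefficients(p1 = 5e-4),
                          background = -1)
  expect_equal(ctr[32, 32] != -1, TRUE)
})
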