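# Thin-lens camera: pixel-ray generation, radiometric camera pass,
# annotation / depth / thermal maps.
#
# Three parallel planes define the geometry: the image plane (physical
# size = sensor size, at distance d behind the lens, with d set by the
# sensor width and the HFOV), the lens principal plane, and the focal
# plane at the focal distance in front of the lens. A pixel ray originates
# at a jitter-sampled point on the lens disk and passes through the focal
# plane point conjugate to a jitter-sampled point of the pixel (the line
# through the pixel point and the lens center). With a zero-diameter lens
# the model degenerates to a pinhole camera and everything is in focus.
#
# Radiometric contract: a pixel records the sample-averaged camera-weighted
# scattered exitance (W m-2) of the surface side it sees, accumulated over
# all scattering iterations; a flat Lambertian plate under a collimated
# source S at incidence theta therefore images to rho_o * S * cos(theta).

#' Camera intrinsics
#'
#' @param hfov Horizontal field of view, radians, in (0, pi).
#' @param resolution Length-2 integer `(width_px, height_px)`.
#' @param lens_diameter Lens diameter, m; 0 gives a pinhole camera.
#' @param focal_plane_distance Distance from the lens to the focal plane, m.
#' @param sensor_size Length-2 `(width_m, height_m)`; height defaults to
#'   width * height_px / width_px.
#' @param samples_per_pixel Rays per pixel in the radiometric pass.
#' @param response Named list of per-band `crt_spectrum` camera responses
#'   `C_lambda` (values in `[0,1]`); bands without an entry sense the full
#'   band (C = 1).
#' @return An object of class `crt_intrinsics`.
#' @export
camera_intrinsics <- function(hfov = 54 * pi / 180, resolution = c(64L, 64L),
                              lens_diameter = 0, focal_plane_distance = 3,
                              sensor_size = NULL, samples_per_pixel = 8L,
                              response = list()) {
  if (hfov <= 0 || hfov >= pi) stop("hfov must be in (0, pi)")
  if (lens_diameter < 0) stop("lens_diameter must be >= 0")
  if (focal_plane_distance <= 0) stop("focal_plane_distance must be > 0")
  if (samples_per_pixel < 1) stop("samples_per_pixel must be >= 1")
  resolution <- as.integer(resolution)
  if (is.null(sensor_size)) {
    sensor_size <- c(0.036, 0.036 * resolution[2] / resolution[1])
  }
  structure(list(hfov = hfov, resolution = resolution,
                 lens_diameter = lens_diameter,
                 focal_plane_distance = focal_plane_distance,
                 sensor_size = as.numeric(sensor_size),
                 samples_per_pixel = as.integer(samples_per_pixel),
                 response = response),
            class = "crt_intrinsics")
}

#' Camera pose
#'
#' @param position Camera (lens center) position, m.
#' @param lookat Point the camera looks at, m (used when `view_direction`
#'   is `NULL`).
#' @param view_direction Unit view direction (overrides `lookat`).
#' @param up Up hint, not parallel to the view direction.
#' @return An object of class `crt_pose` with an orthonormal basis
#'   `(right, up, forward)`.
#' @export
camera_pose <- function(position, lookat = NULL, view_direction = NULL,
                        up = c(0, 0, 1)) {
  position <- as.numeric(position)
  fwd <- if (!is.null(view_direction)) normalize3(view_direction)
         else if (!is.null(lookat)) normalize3(as.numeric(lookat) - position)
         else stop("provide lookat or view_direction")
  if (abs(sum(fwd * normalize3(up))) > 1 - 1e-9) {
    up <- if (abs(fwd[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  }
  right <- normalize3(cross3(fwd, up))
  upv <- cross3(right, fwd)
  structure(list(position = position, forward = fwd, right = right, up = upv),
            class = "crt_pose")
}

#' Assemble a camera rig
#'
#' @param intrinsics A [camera_intrinsics()].
#' @param pose A [camera_pose()].
#' @param label Camera name (keys rendered products).
#' @return An object of class `crt_camera`.
#' @export
camera_rig <- function(intrinsics, pose, label = "camera") {
  stopifnot(inherits(intrinsics, "crt_intrinsics"), inherits(pose, "crt_pose"))
  structure(list(intrinsics = intrinsics, pose = pose, label = label),
            class = "crt_camera")
}

camera_band_response <- function(camera, label) {
  camera$intrinsics$response[[label]]
}

#' Image-plane distance from the lens principal plane
#'
#' `d = (sensor_width / 2) / tan(hfov / 2)`.
#'
#' @param intr A [camera_intrinsics()].
#' @return Distance in m.
#' @export
image_plane_distance <- function(intr) {
  stopifnot(inherits(intr, "crt_intrinsics"))
  (intr$sensor_size[1] / 2) / tan(intr$hfov / 2)
}

# Focal-plane point conjugate to normalized sensor coordinates
# (xc right, yc down, each in [-0.5, 0.5]), n x 3.
focal_points <- function(intr, pose, xc, yc) {
  d <- image_plane_distance(intr)
  F <- intr$focal_plane_distance
  sx <- xc * intr$sensor_size[1] * F / d
  sy <- yc * intr$sensor_size[2] * F / d
  matrix(pose$position, length(xc), 3, byrow = TRUE) +
    F * matrix(pose$forward, length(xc), 3, byrow = TRUE) +
    outer(sx, pose$right) - outer(sy, pose$up)
}

# Jittered origins on the lens disk, n x 3. Zero diameter -> lens center.
lens_origins <- function(intr, pose, n) {
  if (intr$lens_diameter <= 0) {
    return(matrix(pose$position, n, 3, byrow = TRUE))
  }
  r <- (intr$lens_diameter / 2) * sqrt(stats::runif(n))
  phi <- 2 * pi * stats::runif(n)
  matrix(pose$position, n, 3, byrow = TRUE) +
    outer(r * cos(phi), pose$right) + outer(r * sin(phi), pose$up)
}

#' Sample thin-lens rays for one pixel
#'
#' `n` rays for pixel `(row, col)`: origins jitter-sampled on the lens
#' disk, each directed at the focal-plane point conjugate to a
#' jitter-sampled point inside the pixel (found by projecting the pixel
#' point through the lens center onto the focal plane). Deterministic
#' under `seed`.
#'
#' @param intr A [camera_intrinsics()].
#' @param pose A [camera_pose()].
#' @param pixel Length-2 integer `(row, col)`, 1-based, row 1 at the top.
#' @param n Number of rays.
#' @param seed Integer seed.
#' @return `list(origins=, directions=, focal_points=)` (`n x 3` each).
#' @export
sample_pixel_rays <- function(intr, pose, pixel, n = intr$samples_per_pixel,
                              seed = 1L) {
  W <- intr$resolution[1]; H <- intr$resolution[2]
  if (pixel[1] < 1 || pixel[1] > H || pixel[2] < 1 || pixel[2] > W) {
    stop("pixel outside resolution")
  }
  with_seed(seed, {
    xc <- (pixel[2] - 1 + stats::runif(n)) / W - 0.5
    yc <- (pixel[1] - 1 + stats::runif(n)) / H - 0.5
    q <- focal_points(intr, pose, xc, yc)
    o <- lens_origins(intr, pose, n)
    d <- q - o
    d <- d / sqrt(rowSums(d^2))
    list(origins = o, directions = d, focal_points = q)
  })
}

# Deterministic center rays (one per pixel, through pixel centers from the
# lens center), in row-major pixel order. Returns origins, dirs, row, col.
camera_center_rays <- function(intr, pose) {
  W <- intr$resolution[1]; H <- intr$resolution[2]
  px <- expand.grid(col = seq_len(W), row = seq_len(H))
  xc <- (px$col - 0.5) / W - 0.5
  yc <- (px$row - 0.5) / H - 0.5
  q <- focal_points(intr, pose, xc, yc)
  o <- matrix(pose$position, nrow(q), 3, byrow = TRUE)
  d <- q - o
  d <- d / sqrt(rowSums(d^2))
  list(origins = o, directions = d, row = px$row, col = px$col)
}

#' Radiometric camera pass
#'
#' Accumulates the camera-weighted to-be-scattered buffers of a transport
#' field into per-band images. Pixel rays are traced once; each pixel
#' averages, over its samples, the buffered camera-weighted exitance of
#' the side it hits (the reflected buffer for front-facing hits, the
#' transmitted buffer otherwise), summed over every retained scattering
#' iteration. Longwave emission reaches the camera through the same
#' buffers (it is injected into them by the emission pass). Misses
#' contribute the per-band sky radiance.
#'
#' @param sc A [scene()].
#' @param field A `crt_field` from [run_transport()] that was given this
#'   camera.
#' @param camera A [camera_rig()].
#' @param camera_index Position of `camera` in the `cameras` list passed
#'   to [run_transport()].
#' @param sky_radiance Named per-band sky values for miss pixels (default
#'   0).
#' @param seed Seed for the pixel/lens jitter.
#' @return Named list of `H x W` image matrices (W m-2), one per band.
#' @export
camera_pass <- function(sc, field, camera, camera_index = 1L,
                        sky_radiance = NULL, seed = 1L) {
  stopifnot(inherits(camera, "crt_camera"))
  intr <- camera$intrinsics; pose <- camera$pose
  W <- intr$resolution[1]; H <- intr$resolution[2]
  spp <- intr$samples_per_pixel
  npx <- W * H
  with_seed(seed, {
    col <- rep(rep(seq_len(W), times = H), times = spp)
    row <- rep(rep(seq_len(H), each = W), times = spp)
    xc <- (col - 1 + stats::runif(npx * spp)) / W - 0.5
    yc <- (row - 1 + stats::runif(npx * spp)) / H - 0.5
    q <- focal_points(intr, pose, xc, yc)
    o <- lens_origins(intr, pose, npx * spp)
    d <- q - o
    d <- d / sqrt(rowSums(d^2))
    h <- intersect_rays(sc, o, d)
    # total camera-weighted exitance over all scattering orders
    total <- Reduce(`+`, lapply(field$cam_history,
                                function(tc) tc[[camera_index]]))
    nb <- length(field$bands)
    images <- vector("list", nb)
    names(images) <- vapply(field$bands, function(b) b$label, character(1))
    pix <- (row - 1L) * W + col
    for (b in seq_len(nb)) {
      sky <- 0
      if (!is.null(sky_radiance)) {
        sv <- sky_radiance[[names(images)[b]]]
        if (!is.null(sv) && !is.na(sv)) sky <- sv
      }
      val <- rep(sky, npx * spp)
      if (any(h$hit)) {
        idx <- cbind(h$prim[h$hit], b, h$side[h$hit])
        val[h$hit] <- total[idx]
      }
      acc <- rowsum(val, pix, reorder = TRUE)[, 1] / spp
      img <- matrix(0, H, W)
      img[cbind(rep(seq_len(H), each = W), rep(seq_len(W), times = H))] <- acc
      images[[b]] <- img
    }
    images
  })
}

#' Render a scene through a camera
#'
#' Convenience wrapper: runs the transport model with the camera's
#' response, executes the camera pass, and returns a rendered product with
#' the images and the transport field.
#'
#' @inheritParams run_transport
#' @param camera A [camera_rig()].
#' @param sky_radiance,seed Passed to [camera_pass()] (the transport seed
#'   comes from `cfg`).
#' @return An object of class `crt_render`: `images` (per band), `camera`,
#'   `bands`, `field`, `seed`.
#' @export
render <- function(sc, camera, bands, cfg = transport_config(),
                   sky_radiance = NULL, default_temperature = NULL,
                   seed = cfg$seed) {
  if (inherits(bands, "crt_waveband")) bands <- list(bands)
  field <- run_transport(sc, bands, cameras = list(camera), cfg = cfg,
                         default_temperature = default_temperature)
  images <- camera_pass(sc, field, camera, camera_index = 1L,
                        sky_radiance = sky_radiance, seed = seed)
  structure(list(images = images, camera = camera, bands = bands,
                 field = field, seed = seed),
            class = "crt_render")
}

#' @export
print.crt_render <- function(x, ...) {
  r <- x$camera$intrinsics$resolution
  cat(sprintf("<crt_render> %dx%d px, bands: %s\n", r[1], r[2],
              paste(names(x$images), collapse = ", ")))
  invisible(x)
}

#' Per-pixel annotation (label map)
#'
#' One deterministic ray per pixel from the lens center through the pixel
#' center; the returned map holds the `data_key` datum of the nearest
#' primitive hit (no blending between primitives: a pixel is labelled by
#' exactly one primitive or by the background value).
#'
#' @param sc A [scene()].
#' @param camera A [camera_rig()].
#' @param data_key Name of the primitive datum to map (`"uid"` maps the
#'   unique identifier itself).
#' @param background Value for sky pixels (and, with a warning, for hit
#'   primitives lacking the datum).
#' @return `H x W` matrix.
#' @export
annotate <- function(sc, camera, data_key = "uid", background = NA) {
  intr <- camera$intrinsics
  cr <- camera_center_rays(intr, camera$pose)
  h <- intersect_rays(sc, cr$origins, cr$directions)
  out <- matrix(background, intr$resolution[2], intr$resolution[1])
  if (any(h$hit)) {
    vals <- vapply(sc$primitives, function(p) {
      if (identical(data_key, "uid")) as.numeric(p$uid)
      else {
        v <- p$data[[data_key]]
        if (is.null(v)) NA_real_ else as.numeric(v)
      }
    }, numeric(1))
    hv <- vals[h$prim[h$hit]]
    if (anyNA(hv)) {
      warning(sprintf("%d hit pixel(s) lack datum '%s'; background used",
                      sum(is.na(hv)), data_key))
      hv[is.na(hv)] <- background
    }
    out[cbind(cr$row[h$hit], cr$col[h$hit])] <- hv
  }
  out
}

#' Depth map
#'
#' Center-ray distance from the lens center to the nearest hit, m;
#' `Inf` for sky pixels.
#'
#' @inheritParams annotate
#' @export
depth_image <- function(sc, camera) {
  intr <- camera$intrinsics
  cr <- camera_center_rays(intr, camera$pose)
  h <- intersect_rays(sc, cr$origins, cr$directions)
  out <- matrix(Inf, intr$resolution[2], intr$resolution[1])
  out[cbind(cr$row[h$hit], cr$col[h$hit])] <- h$dist[h$hit]
  out
}

#' Thermal map
#'
#' Center-ray map of either the hit primitive's temperature (K) or its
#' emitted flux `emissivity * sigma * T^4` (W m-2).
#'
#' @inheritParams annotate
#' @param mode `"temperature"` or `"emitted_flux"`.
#' @param default_temperature Used for primitives without a `temperature`
#'   datum.
#' @param background Sky value.
#' @export
thermal_image <- function(sc, camera, mode = c("temperature", "emitted_flux"),
                          default_temperature = NULL, background = 0) {
  mode <- match.arg(mode)
  intr <- camera$intrinsics
  cr <- camera_center_rays(intr, camera$pose)
  h <- intersect_rays(sc, cr$origins, cr$directions)
  out <- matrix(background, intr$resolution[2], intr$resolution[1])
  if (any(h$hit)) {
    vals <- vapply(sc$primitives, function(p) {
      temp <- p$data$temperature %||% default_temperature
      if (is.null(temp)) {
        stop("primitive ", p$uid, " has no temperature and no default was given")
      }
      if (mode == "temperature") temp
      else stefan_boltzmann_flux(temp, p$emissivity)
    }, numeric(1))
    out[cbind(cr$row[h$hit], cr$col[h$hit])] <- vals[h$prim[h$hit]]
  }
  out
}
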