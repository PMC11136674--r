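# Reverse Monte Carlo ray-tracing radiation transport.
#
# Rays are launched FROM primitive surfaces toward sources (external pass)
# or over the hemisphere (diffuse sky, and redistribution of scattered
# energy), which guarantees every element is sampled regardless of its
# size. Per primitive, per band and per side the model tracks incident and
# absorbed flux and two families of "to-be-scattered" buffers: one weighted
# by the band properties (rho, tau) that drives the transport iteration,
# and one weighted by the camera properties (rho_o, tau_o) that the camera
# pass queries. Scattering and transmission are Lambertian; specular
# reflection is not modelled. At the end of each scattering iteration the
# buffers are zeroed and refilled from the redistributed energy; iteration
# continues until the residual buffered energy is an arbitrarily small
# fraction of the injected energy.
#
# All passes assemble every ray of the pass into one batch (with a
# deterministic RNG stream per primitive) and make a single vectorized
# sweep through the scene, so results are independent of traversal order.

#' Transport configuration
#'
#' @param rays_per_primitive_direct Rays per primitive per external source.
#' @param rays_per_primitive_diffuse Rays per primitive side for the sky
#'   pass and for each scattering redistribution.
#' @param max_scattering_iterations Iteration cap.
#' @param residual_fraction_tol Convergence threshold: iteration stops when
#'   buffered energy <= tol x injected energy.
#' @param seed Base seed; every (primitive, pass, iteration) combination
#'   derives its own stream from it.
#' @return An object of class `crt_transport_config`.
#' @export
transport_config <- function(rays_per_primitive_direct = 100L,
                             rays_per_primitive_diffuse = 50L,
                             max_scattering_iterations = 20L,
                             residual_fraction_tol = 0.005,
                             seed = 1L) {
  if (rays_per_primitive_direct < 1 || rays_per_primitive_diffuse < 1) {
    stop("ray counts must be >= 1")
  }
  if (max_scattering_iterations < 1) stop("max_scattering_iterations must be >= 1")
  if (residual_fraction_tol <= 0 || residual_fraction_tol >= 1) {
    stop("residual_fraction_tol must be in (0,1)")
  }
  structure(list(rays_per_primitive_direct = as.integer(rays_per_primitive_direct),
                 rays_per_primitive_diffuse = as.integer(rays_per_primitive_diffuse),
                 max_scattering_iterations = as.integer(max_scattering_iterations),
                 residual_fraction_tol = residual_fraction_tol,
                 seed = as.integer(seed)),
            class = "crt_transport_config")
}

# Deterministic per-(primitive, pass, iteration) stream seed.
stream_seed <- function(base, uid, pass_id, iter = 0L) {
  s <- (abs(as.numeric(base)) %% 65536) * 2654435 +
    as.numeric(uid) * 9973 + pass_id * 7919 + iter * 104729
  as.integer(s %% 2147483629) + 1L
}

# n cosine-weighted unit directions about `normal`.
cosine_dirs <- function(n, normal) {
  u1 <- stats::runif(n); u2 <- stats::runif(n)
  r <- sqrt(u1); phi <- 2 * pi * u2
  x <- r * cos(phi); y <- r * sin(phi); z <- sqrt(pmax(0, 1 - u1))
  a <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- normalize3(cross3(normal, a))
  t2 <- cross3(normal, t1)
  cbind(x * t1[1] + y * t2[1] + z * normal[1],
        x * t1[2] + y * t2[2] + z * normal[2],
        x * t1[3] + y * t2[3] + z * normal[3])
}

# n uniformly distributed points on the (masked) surface of a primitive.
sample_surface_points <- function(p, n) {
  pick <- function(m) {
    u <- stats::runif(m); v <- stats::runif(m)
    if (p$kind == "triangle") {
      flip <- u + v > 1
      u[flip] <- 1 - u[flip]; v[flip] <- 1 - v[flip]
    } else if (!is.null(p$mask)) {
      msk <- p$mask
      ui <- pmin(pmax(ceiling(u * ncol(msk)), 1L), ncol(msk))
      vi <- pmin(pmax(nrow(msk) - floor(v * nrow(msk)), 1L), nrow(msk))
      keep <- msk[cbind(vi, ui)]
      u <- u[keep]; v <- v[keep]
    }
    cbind(u, v)
  }
  uv <- pick(n)
  guard <- 0L
  while (nrow(uv) < n && guard < 50L) {
    uv <- rbind(uv, pick(n))
    guard <- guard + 1L
  }
  if (nrow(uv) < n) stop("failed to sample points on masked primitive")
  uv <- uv[seq_len(n), , drop = FALSE]
  v1 <- p$vertices[1, ]
  cbind(v1[1] + uv[, 1] * p$e1[1] + uv[, 2] * p$e2[1],
        v1[2] + uv[, 1] * p$e1[2] + uv[, 2] * p$e2[2],
        v1[3] + uv[, 1] * p$e1[3] + uv[, 2] * p$e2[3])
}

# Uniform directions within a cone of half-angle `half_deg` about `axis`.
cone_dirs <- function(n, axis, half_deg) {
  ca <- cos(half_deg * pi / 180)
  cz <- stats::runif(n, ca, 1)
  sz <- sqrt(pmax(0, 1 - cz^2))
  phi <- 2 * pi * stats::runif(n)
  a <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- normalize3(cross3(axis, a))
  t2 <- cross3(axis, t1)
  x <- sz * cos(phi); y <- sz * sin(phi)
  cbind(x * t1[1] + y * t2[1] + cz * axis[1],
        x * t1[2] + y * t2[2] + cz * axis[2],
        x * t1[3] + y * t2[3] + cz * axis[3])
}

# Reference source spectrum per band: the first external source with
# positive flux in that band (flat if none).
band_source_spectrum <- function(sc, band) {
  for (s in sc$sources) {
    if (is_external_source(s) && source_band_flux(s, band$label) > 0 &&
        !is.null(s$spectrum)) {
      return(s$spectrum)
    }
  }
  constant_spectrum(1)
}

# Per-primitive, per-band, per-side band properties (rho, tau) and
# camera-weighted properties (rho_o, tau_o) per camera. Spectral optics
# are band-integrated against the reference source spectrum (and camera
# response); scalar optics apply to every band directly, times the
# band-average camera response for the camera-weighted family. Bands
# outside the support of spectral optics (longwave) fall back to gray-body
# values rho = 1 - emissivity, tau = 0.
precompute_band_props <- function(sc, bands, cameras = list()) {
  np <- length(sc$primitives); nb <- length(bands); nc <- length(cameras)
  ncc <- max(nc, 1L)
  rho <- array(0, c(np, nb, 2)); tau <- array(0, c(np, nb, 2))
  rho_o <- lapply(seq_len(ncc), function(i) array(0, c(np, nb, 2)))
  tau_o <- lapply(seq_len(ncc), function(i) array(0, c(np, nb, 2)))
  for (ib in seq_len(nb)) {
    band <- bands[[ib]]
    S <- band_source_spectrum(sc, band)
    resp <- lapply(seq_len(ncc), function(ic) {
      if (nc >= ic) camera_band_response(cameras[[ic]], band$label) else NULL
    })
    # band-average response factor for scalar optics
    cfac <- vapply(resp, function(C) {
      if (is.null(C)) 1
      else band_camera_props(constant_spectrum(1), constant_spectrum(0),
                             C, S, band)$rho_o
    }, numeric(1))
    for (ip in seq_len(np)) {
      p <- sc$primitives[[ip]]
      for (side in 1:2) {
        op <- if (side == 1) p$optics_front else p$optics_back
        spectral <- is_spectrum(op$rho) || is_spectrum(op$tau)
        if (spectral) {
          rs <- if (is_spectrum(op$rho)) op$rho else constant_spectrum(op$rho)
          ts <- if (is_spectrum(op$tau)) op$tau else constant_spectrum(op$tau)
          covered <- band$lambda_min_nm >= min(rs$wavelengths_nm) &&
            band$lambda_max_nm <= max(rs$wavelengths_nm)
          if (covered) {
            bp <- band_surface_props(rs, ts, S, band)
            rho[ip, ib, side] <- bp$rho; tau[ip, ib, side] <- bp$tau
            for (ic in seq_len(ncc)) {
              cp <- band_camera_props(rs, ts, resp[[ic]], S, band)
              rho_o[[ic]][ip, ib, side] <- cp$rho_o
              tau_o[[ic]][ip, ib, side] <- cp$tau_o
            }
          } else {
            rho[ip, ib, side] <- 1 - p$emissivity
            for (ic in seq_len(ncc)) {
              rho_o[[ic]][ip, ib, side] <- (1 - p$emissivity) * cfac[ic]
            }
          }
        } else {
          rho[ip, ib, side] <- op$rho; tau[ip, ib, side] <- op$tau
          for (ic in seq_len(ncc)) {
            rho_o[[ic]][ip, ib, side] <- op$rho * cfac[ic]
            tau_o[[ic]][ip, ib, side] <- op$tau * cfac[ic]
          }
        }
      }
    }
  }
  list(rho = rho, tau = tau, rho_o = rho_o, tau_o = tau_o, n_cam = ncc)
}

new_field <- function(sc, bands, n_cam) {
  np <- length(sc$primitives); nb <- length(bands)
  list(incident = array(0, c(np, nb, 2)),
       absorbed = array(0, c(np, nb, 2)),
       tbs = array(0, c(np, nb, 2)),
       tbs_cam = lapply(seq_len(n_cam), function(i) array(0, c(np, nb, 2))),
       injected = numeric(nb), escaped = numeric(nb),
       areas = vapply(sc$primitives, function(p) p$area, numeric(1)))
}

# Vectorized deposit: incident flux matrix I (n_cells x nb) on cells
# (prim index jp, side js). `count_injected` distinguishes primary source
# energy from redistributed energy.
deposit_cells <- function(field, props, jp, js, I, count_injected = TRUE) {
  nb <- ncol(I)
  jo <- 3L - js
  for (b in seq_len(nb)) {
    idx <- cbind(jp, b, js)
    idxo <- cbind(jp, b, jo)
    r <- props$rho[idx]; t <- props$tau[idx]
    Ib <- I[, b]
    field$incident[idx] <- field$incident[idx] + Ib
    field$absorbed[idx] <- field$absorbed[idx] + (1 - r - t) * Ib
    field$tbs[idx] <- field$tbs[idx] + r * Ib
    field$tbs[idxo] <- field$tbs[idxo] + t * Ib
    for (ic in seq_along(field$tbs_cam)) {
      ro <- props$rho_o[[ic]][idx]; to <- props$tau_o[[ic]][idx]
      field$tbs_cam[[ic]][idx] <- field$tbs_cam[[ic]][idx] + ro * Ib
      field$tbs_cam[[ic]][idxo] <- field$tbs_cam[[ic]][idxo] + to * Ib
    }
    if (count_injected) {
      field$injected[b] <- field$injected[b] + sum(Ib * field$areas[jp])
    }
  }
  field
}

#' Direct (external-source) pass
#'
#' For every primitive and every external source, the incident flux is
#' estimated by source-visibility ray sampling: collimated sources use the
#' single beam direction with occlusion testing; the sun sphere samples
#' directions within its angular disk; terrestrial sphere / disk /
#' rectangle sources are area-sampled with solid-angle and cosine
#' weighting (isotropic Lambertian emission for spheres, one-sided cosine
#' emission for planar sources). Absorbed flux and both to-be-scattered
#' buffer families are filled from the incident estimate.
#'
#' @param sc A [scene()] whose sources include external sources.
#' @param bands List of [waveband()].
#' @param cfg A [transport_config()].
#' @param props,field Internal state from [run_transport()]; exposed for
#'   testing (recomputed when `NULL`).
#' @return The updated field.
#' @export
direct_pass <- function(sc, bands, cfg, props = NULL, field = NULL) {
  if (is.null(props)) props <- precompute_band_props(sc, bands)
  if (is.null(field)) field <- new_field(sc, bands, props$n_cam)
  labels <- vapply(bands, function(b) b$label, character(1))
  shortwave <- !vapply(bands, function(b) b$longwave, logical(1))
  ext <- Filter(is_external_source, sc$sources)
  n <- cfg$rays_per_primitive_direct
  np <- length(sc$primitives)
  for (isrc in seq_along(ext)) {
    s <- ext[[isrc]]
    flux <- vapply(labels, function(l) source_band_flux(s, l), numeric(1))
    flux[!shortwave] <- 0
    if (all(flux == 0)) next
    origins <- vector("list", np); dirs <- vector("list", np)
    wgt <- vector("list", np); sdist <- vector("list", np)
    for (ip in seq_len(np)) {
      p <- sc$primitives[[ip]]
      seed <- stream_seed(cfg$seed, p$uid, pass_id = 100L + isrc)
      smp <- with_seed(seed, sample_direct_rays(p, s, n))
      origins[[ip]] <- smp$pts; dirs[[ip]] <- smp$dirs
      wgt[[ip]] <- smp$w            # signed: + front, - back
      sdist[[ip]] <- smp$dist       # distance to source point (Inf = beam)
    }
    O <- do.call(rbind, origins); D <- do.call(rbind, dirs)
    w <- unlist(wgt); dist_src <- unlist(sdist)
    src_prim <- rep(seq_len(np), each = n)
    h <- intersect_rays(sc, O, D)
    open <- !h$hit | (h$hit & h$dist > dist_src - 1e-6)
    w <- w * open
    est_front <- rowsum(pmax(w, 0), src_prim, reorder = TRUE) / n
    est_back <- rowsum(pmax(-w, 0), src_prim, reorder = TRUE) / n
    for (side in 1:2) {
      est <- if (side == 1) est_front else est_back
      jp <- which(est[, 1] > 0)
      if (length(jp)) {
        I <- outer(est[jp, 1], flux)
        field <- deposit_cells(field, props, jp, rep(side, length(jp)), I)
      }
    }
  }
  field
}

# Rays + per-ray weights for one primitive under one external source.
# Weight is the per-unit-band-flux (or per-unit-power) irradiance
# contribution, signed by incident side.
sample_direct_rays <- function(p, s, n) {
  pts <- sample_surface_points(p, n)
  if (s$kind %in% c("collimated", "sun_sphere")) {
    dirs <- if (s$kind == "collimated") {
      matrix(s$direction, n, 3, byrow = TRUE)
    } else {
      cone_dirs(n, s$direction, s$angular_radius_deg)
    }
    ct <- dirs[, 1] * p$normal[1] + dirs[, 2] * p$normal[2] +
      dirs[, 3] * p$normal[3]
    list(pts = pts, dirs = dirs, w = ct, dist = rep(Inf, n))
  } else {
    if (s$kind == "sphere") {
      q <- matrix(stats::rnorm(3 * n), n, 3)
      q <- q / sqrt(rowSums(q^2))
      src_n <- q
      q <- q * s$radius + matrix(s$position, n, 3, byrow = TRUE)
    } else if (s$kind == "disk") {
      r <- s$radius * sqrt(stats::runif(n)); phi <- 2 * pi * stats::runif(n)
      a <- if (abs(s$normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      t1 <- normalize3(cross3(s$normal, a)); t2 <- cross3(s$normal, t1)
      q <- matrix(s$position, n, 3, byrow = TRUE) +
        outer(r * cos(phi), t1) + outer(r * sin(phi), t2)
      src_n <- matrix(s$normal, n, 3, byrow = TRUE)
    } else {
      u <- stats::runif(n, -0.5, 0.5) * s$size[1]
      v <- stats::runif(n, -0.5, 0.5) * s$size[2]
      a <- if (abs(s$normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      t1 <- normalize3(cross3(s$normal, a)); t2 <- cross3(s$normal, t1)
      q <- matrix(s$position, n, 3, byrow = TRUE) + outer(u, t1) + outer(v, t2)
      src_n <- matrix(s$normal, n, 3, byrow = TRUE)
    }
    d <- q - pts
    dist <- sqrt(rowSums(d^2))
    dirs <- d / dist
    ct_recv <- dirs[, 1] * p$normal[1] + dirs[, 2] * p$normal[2] +
      dirs[, 3] * p$normal[3]
    ct_src <- pmax(0, -rowSums(dirs * src_n))
    # E = P/n * sum( cos_src * cos_recv / (pi d^2) )  [M A = P]
    w <- ct_src * ct_recv / (pi * dist^2)
    list(pts = pts, dirs = dirs, w = w, dist = dist)
  }
}

#' Diffuse (sky) pass
#'
#' Cosine-weighted hemispherical ray sampling from each primitive side;
#' rays that escape to the sky collect the sky flux (shortwave diffuse
#' flux, or `sigma T_sky^4` in longwave bands). Rays that hit primitives
#' collect nothing in this pass -- inter-primitive exchange is handled by
#' the scattering iterations.
#'
#' @inheritParams direct_pass
#' @export
diffuse_pass <- function(sc, bands, cfg, props = NULL, field = NULL) {
  if (is.null(props)) props <- precompute_band_props(sc, bands)
  if (is.null(field)) field <- new_field(sc, bands, props$n_cam)
  labels <- vapply(bands, function(b) b$label, character(1))
  longwave <- vapply(bands, function(b) b$longwave, logical(1))
  nb <- length(bands)
  sky <- numeric(nb)
  for (s in sc$sources) {
    if (s$kind == "diffuse_sky") {
      f <- vapply(labels, function(l) source_band_flux(s, l), numeric(1))
      f[longwave] <- 0
      sky <- sky + f
    } else if (s$kind == "longwave_sky") {
      sky[longwave] <- sky[longwave] + stefan_boltzmann_flux(s$temperature_k)
    }
  }
  if (all(sky == 0)) return(field)
  n <- cfg$rays_per_primitive_diffuse
  np <- length(sc$primitives)
  origins <- vector("list", 2L * np); dirs <- vector("list", 2L * np)
  for (ip in seq_len(np)) {
    p <- sc$primitives[[ip]]
    for (side in 1:2) {
      nrm <- if (side == 1) p$normal else -p$normal
      seed <- stream_seed(cfg$seed, p$uid, pass_id = 200L + side)
      smp <- with_seed(seed, {
        list(pts = sample_surface_points(p, n), d = cosine_dirs(n, nrm))
      })
      k <- (ip - 1L) * 2L + side
      origins[[k]] <- smp$pts; dirs[[k]] <- smp$d
    }
  }
  O <- do.call(rbind, origins); D <- do.call(rbind, dirs)
  cell <- rep(seq_len(2L * np), each = n)
  h <- intersect_rays(sc, O, D)
  frac <- rowsum(as.numeric(!h$hit), cell, reorder = TRUE)[, 1] / n
  live <- which(frac > 0)
  if (length(live)) {
    jp <- (live - 1L) %/% 2L + 1L
    js <- (live - 1L) %% 2L + 1L
    I <- outer(frac[live], sky)
    field <- deposit_cells(field, props, jp, js, I)
  }
  field
}

#' Longwave emission pass
#'
#' Each primitive side emits `emissivity * sigma * T^4` W m-2 into every
#' longwave band, where `T` is the primitive's `temperature` annotation
#' datum (or `default_temperature`). Emitted energy enters the same
#' to-be-scattered machinery as reflected energy, so radiative exchange
#' between primitives becomes self-consistent over the scattering
#' iterations.
#'
#' @inheritParams direct_pass
#' @param default_temperature Fallback temperature, K, when a primitive has
#'   no `temperature` datum; if `NULL`, a missing temperature is an error.
#' @export
emission_pass <- function(sc, bands, cfg, props = NULL, field = NULL,
                          default_temperature = NULL) {
  if (is.null(props)) props <- precompute_band_props(sc, bands)
  if (is.null(field)) field <- new_field(sc, bands, props$n_cam)
  longwave <- which(vapply(bands, function(b) b$longwave, logical(1)))
  if (!length(longwave)) return(field)
  for (ip in seq_along(sc$primitives)) {
    p <- sc$primitives[[ip]]
    temp <- p$data$temperature %||% default_temperature
    if (is.null(temp)) {
      stop("primitive ", p$uid, " has no temperature and no default was given")
    }
    F <- stefan_boltzmann_flux(temp, p$emissivity)
    if (F == 0) next
    for (side in 1:2) {
      for (b in longwave) {
        field$tbs[ip, b, side] <- field$tbs[ip, b, side] + F
        for (ic in seq_along(field$tbs_cam)) {
          field$tbs_cam[[ic]][ip, b, side] <- field$tbs_cam[[ic]][ip, b, side] + F
        }
        field$injected[b] <- field$injected[b] + F * field$areas[ip]
      }
    }
  }
  field
}

#' One scattering iteration
#'
#' Every primitive side holding buffered to-be-scattered energy re-emits it
#' through cosine-weighted (Lambertian) hemispherical rays, all bands in
#' one sweep. Receiving primitives accumulate incident/absorbed flux and
#' refill fresh buffers (both families); rays that miss the scene escape.
#' The old buffers are zeroed after redistribution.
#'
#' @inheritParams direct_pass
#' @param iter Iteration index (seeds the per-primitive streams).
#' @return `list(field=, residual=)` where `residual` is the total energy
#'   (W) left in the band-weighted buffers after the iteration.
#' @export
scattering_iteration <- function(sc, bands, cfg, props, field, iter = 1L) {
  np <- length(sc$primitives); nb <- length(bands)
  old_tbs <- field$tbs
  field$tbs <- array(0, c(np, nb, 2))
  for (ic in seq_along(field$tbs_cam)) {
    field$tbs_cam[[ic]] <- array(0, c(np, nb, 2))
  }
  n <- cfg$rays_per_primitive_diffuse
  emit <- which(apply(old_tbs, c(1, 3), sum) > 0, arr.ind = TRUE)
  if (nrow(emit) == 0L) return(list(field = field, residual = 0))
  origins <- vector("list", nrow(emit)); dirs <- vector("list", nrow(emit))
  eray <- matrix(0, nrow(emit), nb)   # W per ray per band
  for (k in seq_len(nrow(emit))) {
    ip <- emit[k, 1]; side <- emit[k, 2]
    p <- sc$primitives[[ip]]
    nrm <- if (side == 1) p$normal else -p$normal
    seed <- stream_seed(cfg$seed, p$uid, pass_id = 300L + side, iter = iter)
    smp <- with_seed(seed, {
      list(pts = sample_surface_points(p, n), d = cosine_dirs(n, nrm))
    })
    origins[[k]] <- smp$pts; dirs[[k]] <- smp$d
    eray[k, ] <- old_tbs[ip, , side] * field$areas[ip] / n
  }
  O <- do.call(rbind, origins); D <- do.call(rbind, dirs)
  src <- rep(seq_len(nrow(emit)), each = n)
  h <- intersect_rays(sc, O, D)
  E <- eray[src, , drop = FALSE]      # per-ray band energies
  miss <- !h$hit
  if (any(miss)) {
    field$escaped <- field$escaped + colSums(E[miss, , drop = FALSE])
  }
  if (any(h$hit)) {
    hits <- which(h$hit)
    grp <- (h$prim[hits] - 1L) * 2L + h$side[hits]
    dep <- rowsum(E[hits, , drop = FALSE], grp, reorder = TRUE)  # W per cell
    gi <- as.integer(rownames(dep))
    jp <- (gi - 1L) %/% 2L + 1L
    js <- (gi - 1L) %% 2L + 1L
    I <- dep / field$areas[jp]
    field <- deposit_cells(field, props, jp, js, I, count_injected = FALSE)
  }
  aw <- array(field$areas, c(np, nb, 2))
  list(field = field, residual = sum(field$tbs * aw))
}

#' Run the full transport calculation
#'
#' Executes the direct, diffuse-sky and longwave-emission passes, then
#' iterates scattering until the residual buffered energy falls below
#' `residual_fraction_tol` of the injected energy or the iteration cap is
#' reached (with a warning). Per-iteration camera-weighted buffers are
#' retained so a camera pass can accumulate every scattering order.
#' Deterministic under a fixed seed and invariant to primitive ordering.
#'
#' @param sc A [scene()].
#' @param bands List of [waveband()] (a single band is accepted).
#' @param cameras List of [camera_rig()] whose responses weight the
#'   `rho_o`/`tau_o` buffers; may be empty.
#' @param cfg A [transport_config()].
#' @param default_temperature Passed to [emission_pass()].
#' @return An object of class `crt_field`: arrays `incident`, `absorbed`,
#'   `tbs` (`n_prim x n_band x 2`, W m-2; side 1 = front), `cam_history`
#'   (list over iterations of per-camera buffer arrays), the per-iteration
#'   energy `ledger` (W), and per-band injected/escaped totals.
#' @export
run_transport <- function(sc, bands, cameras = list(),
                          cfg = transport_config(),
                          default_temperature = NULL) {
  stopifnot(inherits(sc, "crt_scene"))
  if (inherits(bands, "crt_waveband")) bands <- list(bands)
  if (inherits(cameras, "crt_camera")) cameras <- list(cameras)
  props <- precompute_band_props(sc, bands, cameras)
  field <- new_field(sc, bands, props$n_cam)
  field <- direct_pass(sc, bands, cfg, props, field)
  field <- diffuse_pass(sc, bands, cfg, props, field)
  if (any(vapply(bands, function(b) b$longwave, logical(1)))) {
    field <- emission_pass(sc, bands, cfg, props, field, default_temperature)
  }
  np <- length(sc$primitives); nb <- length(bands)
  aw <- array(field$areas, c(np, nb, 2))
  cam_history <- list(field$tbs_cam)
  residual <- sum(field$tbs * aw)
  injected <- sum(field$injected)
  ledger <- data.frame(iteration = 0L, injected = injected,
                       absorbed = sum(field$absorbed * aw),
                       escaped = sum(field$escaped), residual = residual)
  iter <- 0L
  while (residual > cfg$residual_fraction_tol * max(injected, 1e-300) &&
         iter < cfg$max_scattering_iterations) {
    iter <- iter + 1L
    out <- scattering_iteration(sc, bands, cfg, props, field, iter)
    field <- out$field
    residual <- out$residual
    cam_history[[iter + 1L]] <- field$tbs_cam
    ledger <- rbind(ledger, data.frame(
      iteration = iter, injected = sum(field$injected),
      absorbed = sum(field$absorbed * aw),
      escaped = sum(field$escaped), residual = residual))
  }
  injected <- sum(field$injected)
  if (residual > cfg$residual_fraction_tol * max(injected, 1e-300)) {
    warning(sprintf("transport did not converge in %d iterations (residual %.3g W)",
                    iter, residual))
  }
  structure(list(incident = field$incident, absorbed = field$absorbed,
                 tbs = field$tbs, cam_history = cam_history,
                 injected_per_band = field$injected,
                 escaped_per_band = field$escaped,
                 ledger = ledger, props = props, bands = bands,
                 areas = field$areas, cfg = cfg, n_iterations = iter),
            class = "crt_field")
}

#' @export
print.crt_field <- function(x, ...) {
  cat(sprintf("<crt_field> %d primitives, %d bands, %d scattering iterations\n",
              dim(x$absorbed)[1], dim(x$absorbed)[2], x$n_iterations))
  print(utils::tail(x$ledger, 3))
  invisible(x)
}

#' Total absorbed flux per primitive for one band
#'
#' Sum of the per-side absorbed fluxes, W m-2 (relative to the primitive
#' area).
#'
#' @param field A `crt_field` from [run_transport()].
#' @param band_index Band position in the field's band list.
#' @export
absorbed_flux <- function(field, band_index = 1L) {
  field$absorbed[, band_index, 1] + field$absorbed[, band_index, 2]
}
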