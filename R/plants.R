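# Procedural plant generation.
#
# Deliberately simplified parametric plants (stem / petiole / leaf / fruit
# placement with seeded random variation within prescribed ranges). The
# contract is statistical -- element counts, size ranges, determinism under
# a fixed seed -- not geometric identity with any particular crop model.

#' Parameters for a procedural plant
#'
#' Species presets set typical ranges; every range can be overridden. The
#' strawberry-like preset uses plant height 0.2--0.4 m, fruit radius
#' 0.04--0.08 m, leaf length 0.05--0.1 m, 15 stems per plant and 1--3
#' fruit per stem.
#'
#' @param species One of `"bean_like"`, `"strawberry_like"`,
#'   `"sorghum_like"`.
#' @param plant_height_range,leaf_length_range,fruit_radius_range Ordered
#'   two-element ranges, m.
#' @param leaves_per_petiole,stems_per_plant Integer counts.
#' @param fruit_count_range Ordered integer range of fruit per stem.
#' @param rotation_jitter Length-3 maximum rotation jitter about the three
#'   axes, radians.
#' @param seed Integer seed controlling all random variation.
#' @return An object of class `crt_plant_params`.
#' @export
procedural_plant_params <- function(species = c("bean_like",
                                                "strawberry_like",
                                                "sorghum_like"),
                                    plant_height_range = NULL,
                                    leaf_length_range = NULL,
                                    leaves_per_petiole = NULL,
                                    stems_per_plant = NULL,
                                    fruit_radius_range = NULL,
                                    fruit_count_range = NULL,
                                    rotation_jitter = c(0.2, 0.2, pi),
                                    seed = 1L) {
  species <- match.arg(species)
  preset <- switch(species,
    bean_like = list(h = c(0.10, 0.20), l = c(0.04, 0.08), lpp = 3L,
                     spp = 3L, fr = c(0, 0), fc = c(0L, 0L)),
    strawberry_like = list(h = c(0.2, 0.4), l = c(0.05, 0.1), lpp = 3L,
                           spp = 15L, fr = c(0.04, 0.08), fc = c(1L, 3L)),
    sorghum_like = list(h = c(0.8, 1.4), l = c(0.3, 0.6), lpp = 1L,
                        spp = 1L, fr = c(0, 0), fc = c(0L, 0L)))
  p <- list(species = species,
            plant_height_range = plant_height_range %||% preset$h,
            leaf_length_range = leaf_length_range %||% preset$l,
            leaves_per_petiole = leaves_per_petiole %||% preset$lpp,
            stems_per_plant = stems_per_plant %||% preset$spp,
            fruit_radius_range = fruit_radius_range %||% preset$fr,
            fruit_count_range = fruit_count_range %||% preset$fc,
            rotation_jitter = rotation_jitter, seed = as.integer(seed))
  for (nm in c("plant_height_range", "leaf_length_range",
               "fruit_radius_range", "fruit_count_range")) {
    r <- p[[nm]]
    if (length(r) != 2L || any(r < 0) || r[1] > r[2]) {
      stop("invalid range for ", nm)
    }
  }
  structure(p, class = "crt_plant_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run expr with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

runif_range <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n) else stats::runif(n, range[1], range[2])
}

#' Elliptical leaf cutout mask
#'
#' @param n Mask resolution (n x n texels).
#' @return Logical matrix with an inscribed ellipse opaque.
#' @export
ellipse_mask <- function(n = 32) {
  u <- (seq_len(n) - 0.5) / n
  outer(u, u, function(r, c) ((r - 0.5) / 0.5)^2 + ((c - 0.5) / 0.5)^2 <= 1)
}

# Octahedron triangles approximating a fruit of given radius.
fruit_octahedron <- function(center, radius, optics_fruit, data) {
  px <- center + c(radius, 0, 0); mx <- center - c(radius, 0, 0)
  py <- center + c(0, radius, 0); my <- center - c(0, radius, 0)
  pz <- center + c(0, 0, radius); mz <- center - c(0, 0, radius)
  faces <- list(list(px, py, pz), list(py, mx, pz), list(mx, my, pz),
                list(my, px, pz), list(py, px, mz), list(mx, py, mz),
                list(my, mx, mz), list(px, my, mz))
  lapply(faces, function(f) {
    make_triangle(f[[1]], f[[2]], f[[3]], optics_front = optics_fruit,
                  data = data)
  })
}

#' Build a procedural plant
#'
#' Stems are thin vertical rectangles jittered within the configured
#' rotation ranges; each stem carries one petiole whorl of elliptical
#' masked-patch leaves and (species permitting) a set of octahedral fruit.
#' Every leaf primitive carries `plant_id` and `leaf_id`; fruit carry
#' `plant_id` and `fruit_id`. Deterministic for a fixed seed.
#'
#' @param params A [procedural_plant_params()].
#' @param base Plant base position, m.
#' @param plant_id Integer identifier stored on every primitive.
#' @param leaf_optics,stem_optics,fruit_optics [optics()] for the organ
#'   classes.
#' @return List of `crt_primitive`.
#' @export
build_plant <- function(params, base = c(0, 0, 0), plant_id = 1L,
                        leaf_optics = optics(rho = 0.1, tau = 0.05),
                        stem_optics = optics(rho = 0.15),
                        fruit_optics = optics(rho = 0.3)) {
  stopifnot(inherits(params, "crt_plant_params"))
  with_seed(params$seed, {
    prims <- list()
    leaf_id <- 0L
    fruit_id <- 0L
    mask <- ellipse_mask(24)
    jit <- function(mx) if (mx == 0) 0 else stats::runif(1, -mx, mx)
    for (is in seq_len(params$stems_per_plant)) {
      h <- runif_range(1, params$plant_height_range)
      ang <- 2 * pi * (is - 1) / max(1, params$stems_per_plant)
      lean <- jit(params$rotation_jitter[1])
      top <- base + c(0.15 * h * sin(lean) * cos(ang),
                      0.15 * h * sin(lean) * sin(ang), h)
      mid <- (base + top) / 2
      stem_dir <- normalize3(top - base)
      prims[[length(prims) + 1L]] <- make_patch(
        center = mid, size = c(0.01 * max(1, h / 0.2), sqrt(sum((top - base)^2))),
        rotation = c(acos(stem_dir[3]), 0, atan2(stem_dir[2], stem_dir[1])),
        optics_front = stem_optics,
        data = list(plant_id = plant_id, class = 2L))
      for (il in seq_len(params$leaves_per_petiole)) {
        leaf_id <- leaf_id + 1L
        ll <- runif_range(1, params$leaf_length_range)
        lw <- 0.7 * ll
        phi <- ang + 2 * pi * (il - 1) / max(1, params$leaves_per_petiole) +
          jit(params$rotation_jitter[3])
        tilt <- pi / 5 + jit(params$rotation_jitter[1])
        roll <- jit(params$rotation_jitter[2])
        ctr <- top + c(cos(phi) * 0.6 * ll, sin(phi) * 0.6 * ll, -0.1 * ll)
        prims[[length(prims) + 1L]] <- make_patch(
          center = ctr, size = c(lw, ll), rotation = c(tilt, roll, phi),
          mask = mask, optics_front = leaf_optics,
          data = list(plant_id = plant_id, leaf_id = leaf_id, class = 1L,
                      leaf_length = ll))
      }
      nf <- if (params$fruit_count_range[2] > 0) {
        sample(params$fruit_count_range[1]:params$fruit_count_range[2], 1)
      } else 0L
      for (ifr in seq_len(nf)) {
        fruit_id <- fruit_id + 1L
        fr <- runif_range(1, params$fruit_radius_range)
        phi <- stats::runif(1, 0, 2 * pi)
        ctr <- base + c(cos(phi) * 0.3 * h, sin(phi) * 0.3 * h,
                        max(fr, 0.15 * h))
        prims <- c(prims, fruit_octahedron(
          ctr, fr, fruit_optics,
          data = list(plant_id = plant_id, fruit_id = fruit_id, class = 3L,
                      fruit_radius = fr)))
      }
    }
    prims
  })
}
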