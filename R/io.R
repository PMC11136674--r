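# Serialization of rendered products, run configuration, and the batch
# dataset generator.

#' Write a band image
#'
#' `png8` applies an exposure scale to the configured white-point flux and
#' a gamma curve, quantizes to 8 bits and writes a PNG (grayscale for a
#' matrix, RGB for an `H x W x 3` array). `float_raster` writes a lossless
#' band-stacked binary raster of doubles with a plain-text sidecar header
#' (`<path>.hdr`) carrying dimensions, band labels and units -- suitable
#' for hyperspectral cubes and bit-exact round trips via
#' [read_float_raster()].
#'
#' @param raster `H x W` matrix or `H x W x B` array (W m-2).
#' @param path Output file.
#' @param mode `"png8"` or `"float_raster"`.
#' @param white_point Flux mapped to full scale in `png8` mode.
#' @param gamma Display gamma for `png8`.
#' @param band_labels,units Header metadata for `float_raster`.
#' @return `path`, invisibly.
#' @export
write_band_image <- function(raster, path, mode = c("png8", "float_raster"),
                             white_point = NULL, gamma = 2.2,
                             band_labels = NULL, units = "W m-2") {
  mode <- match.arg(mode)
  if (any(!is.finite(raster))) stop("raster contains non-finite values")
  if (mode == "png8") {
    if (is.null(white_point)) white_point <- max(raster, 1e-12)
    v <- pmin(pmax(raster / white_point, 0), 1)^(1 / gamma)
    v <- round(v * 255) / 255
    png::writePNG(v, target = path)
  } else {
    write_float_raster(raster, path, band_labels = band_labels, units = units)
  }
  invisible(path)
}

#' Lossless float raster with text header
#'
#' Doubles in column-major order of the `H x W x B` array, little-endian;
#' the header (`<path>.hdr`) lists `height`, `width`, `bands`, labels and
#' units.
#'
#' @param raster Matrix or 3-d array.
#' @param path Data file path.
#' @param band_labels Character vector (defaults to `band_1` ...).
#' @param units Unit string stored in the header.
#' @export
write_float_raster <- function(raster, path, band_labels = NULL,
                               units = "W m-2") {
  a <- if (length(dim(raster)) == 2L) array(raster, c(dim(raster), 1L)) else raster
  if (is.null(band_labels)) band_labels <- paste0("band_", seq_len(dim(a)[3]))
  hdr <- c(sprintf("height %d", dim(a)[1]), sprintf("width %d", dim(a)[2]),
           sprintf("bands %d", dim(a)[3]),
           sprintf("labels %s", paste(band_labels, collapse = ",")),
           sprintf("units %s", units), "dtype float64le")
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(a), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_float_raster
#' @export
read_float_raster <- function(path) {
  hdr <- readLines(paste0(path, ".hdr"))
  get <- function(key) sub(paste0("^", key, " "), "",
                           grep(paste0("^", key, " "), hdr, value = TRUE)[1])
  H <- as.integer(get("height")); W <- as.integer(get("width"))
  B <- as.integer(get("bands"))
  labels <- strsplit(get("labels"), ",")[[1]]
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = H * W * B, size = 8, endian = "little")
  a <- array(v, c(H, W, B))
  dimnames(a) <- list(NULL, NULL, labels)
  a
}

#' Bounding boxes from a label map (YOLO format)
#'
#' One box per distinct label value covering all its pixels, normalized to
#' `[0,1]`: `(class, x_center, y_center, width, height)`. Labels with
#' fewer than `min_pixels` pixels are dropped.
#'
#' @param label_map Matrix of labels.
#' @param min_pixels Minimum pixel count per label.
#' @param background Background value to ignore (`NA` always ignored).
#' @return data.frame with columns `class`, `x_center`, `y_center`,
#'   `width`, `height`.
#' @export
boxes_from_labels <- function(label_map, min_pixels = 1L, background = NA) {
  H <- nrow(label_map); W <- ncol(label_map)
  vals <- unique(as.vector(label_map))
  vals <- vals[!is.na(vals)]
  if (!is.na(background)) vals <- vals[vals != background]
  out <- list()
  for (v in sort(vals)) {
    idx <- which(label_map == v, arr.ind = TRUE)
    if (nrow(idx) < min_pixels) next
    rmin <- min(idx[, 1]); rmax <- max(idx[, 1])
    cmin <- min(idx[, 2]); cmax <- max(idx[, 2])
    out[[length(out) + 1L]] <- data.frame(
      class = v,
      x_center = ((cmin + cmax) / 2 - 0.5) / W,
      y_center = ((rmin + rmax) / 2 - 0.5) / H,
      width = (cmax - cmin + 1) / W,
      height = (rmax - rmin + 1) / H)
  }
  if (!length(out)) {
    return(data.frame(class = numeric(0), x_center = numeric(0),
                      y_center = numeric(0), width = numeric(0),
                      height = numeric(0)))
  }
  do.call(rbind, out)
}

#' Write YOLO box files
#'
#' @param boxes data.frame from [boxes_from_labels()].
#' @param path Output text file (space-separated, one box per line).
#' @export
write_yolo_boxes <- function(boxes, path) {
  lines <- sprintf("%g %.6f %.6f %.6f %.6f", boxes$class, boxes$x_center,
                   boxes$y_center, boxes$width, boxes$height)
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Run configuration

config_schema <- list(
  top = c("seed", "output_dir", "images", "bands", "camera", "scene",
          "sources", "transport", "annotate", "distortion", "export"),
  band = c("label", "min", "max", "longwave"),
  camera = c("hfov_deg", "resolution", "lens_diameter", "focal_distance",
             "sensor_size", "samples_per_pixel", "position", "lookat",
             "response_files"),
  scene = c("fixture", "fixture_seed", "ground", "plants"),
  ground = c("extent", "tiles", "rho", "tau"),
  plants = c("species", "count", "spacing", "seed", "stems_per_plant",
             "leaves_per_petiole", "plant_height_range", "leaf_length_range",
             "fruit_radius_range", "fruit_count_range", "rotation_jitter"),
  source = c("kind", "zenith_deg", "azimuth_deg", "zenith_range_deg",
             "azimuth_range_deg", "fluxes", "temperature", "position",
             "radius", "power", "normal", "size", "spectrum_file"),
  transport = c("rays_direct", "rays_diffuse", "max_iterations",
                "residual_tol"),
  distortion = c("p1", "p2", "p3", "p4"),
  export = c("mode", "white_point", "gamma"))

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop(sprintf("unknown config key(s) in %s: %s", where,
                 paste(bad, collapse = ", ")))
  }
  invisible(x)
}

#' Load and validate a run configuration
#'
#' YAML configuration for [run_batch()]; unknown keys are rejected before
#' any computation.
#'
#' @param path YAML file.
#' @return Validated config list of class `crt_config`.
#' @export
load_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' @param config A config list (e.g. from [yaml::read_yaml()]).
#' @rdname load_run_config
#' @export
validate_run_config <- function(config) {
  check_keys(config, config_schema$top, "top level")
  if (is.null(config$bands) || !length(config$bands)) stop("config needs bands")
  for (b in config$bands) check_keys(b, config_schema$band, "bands[]")
  if (is.null(config$camera)) stop("config needs a camera")
  check_keys(config$camera, config_schema$camera, "camera")
  if (is.null(config$scene)) stop("config needs a scene")
  check_keys(config$scene, config_schema$scene, "scene")
  if (!is.null(config$scene$ground)) {
    check_keys(config$scene$ground, config_schema$ground, "scene.ground")
  }
  if (!is.null(config$scene$plants)) {
    check_keys(config$scene$plants, config_schema$plants, "scene.plants")
  }
  if (is.null(config$sources)) stop("config needs sources")
  for (s in config$sources) check_keys(s, config_schema$source, "sources[]")
  if (!is.null(config$transport)) {
    check_keys(config$transport, config_schema$transport, "transport")
  }
  if (!is.null(config$distortion)) {
    check_keys(config$distortion, config_schema$distortion, "distortion")
  }
  if (!is.null(config$export)) {
    check_keys(config$export, config_schema$export, "export")
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$images <- as.integer(config$images %||% 1L)
  structure(config, class = c("crt_config", "list"))
}

config_bands <- function(config) {
  lapply(config$bands, function(b) {
    waveband(b$label, b$min, b$max, longwave = isTRUE(b$longwave))
  })
}

config_camera <- function(config) {
  cc <- config$camera
  response <- list()
  if (!is.null(cc$response_files)) {
    response <- lapply(cc$response_files, read_spectrum)
  }
  intr <- camera_intrinsics(
    hfov = (cc$hfov_deg %||% 54) * pi / 180,
    resolution = as.integer(cc$resolution %||% c(64L, 64L)),
    lens_diameter = cc$lens_diameter %||% 0,
    focal_plane_distance = cc$focal_distance %||% 3,
    sensor_size = cc$sensor_size,
    samples_per_pixel = cc$samples_per_pixel %||% 4L,
    response = response)
  pose <- camera_pose(position = as.numeric(cc$position %||% c(0, 0, 3)),
                      lookat = as.numeric(cc$lookat %||% c(0, 0, 0)))
  camera_rig(intr, pose)
}

config_transport <- function(config, seed) {
  tc <- config$transport %||% list()
  transport_config(
    rays_per_primitive_direct = tc$rays_direct %||% 100L,
    rays_per_primitive_diffuse = tc$rays_diffuse %||% 50L,
    max_scattering_iterations = tc$max_iterations %||% 20L,
    residual_fraction_tol = tc$residual_tol %||% 0.005,
    seed = seed)
}

# Direction toward the sun from zenith/azimuth angles (degrees).
sun_direction <- function(zenith_deg, azimuth_deg) {
  z <- zenith_deg * pi / 180; a <- azimuth_deg * pi / 180
  c(sin(z) * cos(a), sin(z) * sin(a), cos(z))
}

# Build per-image scene + sources (angles and plant variation may be
# randomized per image under the image seed).
config_scene <- function(config, image_seed) {
  scn <- config$scene
  sources <- list()
  meta <- list()
  for (s in config$sources) {
    kind <- s$kind %||% "collimated"
    fluxes <- unlist(s$fluxes)
    zen <- s$zenith_deg %||% 0
    azi <- s$azimuth_deg %||% 0
    if (!is.null(s$zenith_range_deg)) {
      zen <- with_seed(image_seed + 11L,
                       stats::runif(1, s$zenith_range_deg[[1]],
                                    s$zenith_range_deg[[2]]))
    }
    if (!is.null(s$azimuth_range_deg)) {
      azi <- with_seed(image_seed + 13L,
                       stats::runif(1, s$azimuth_range_deg[[1]],
                                    s$azimuth_range_deg[[2]]))
    }
    src <- switch(kind,
      collimated = source_collimated(sun_direction(zen, azi), fluxes),
      sun_sphere = source_sun_sphere(sun_direction(zen, azi), fluxes),
      diffuse_sky = source_diffuse_sky(fluxes),
      longwave_sky = source_longwave_sky(s$temperature),
      sphere = source_sphere(as.numeric(s$position), s$radius,
                             unlist(s$power)),
      disk = source_disk(as.numeric(s$position), as.numeric(s$normal),
                         s$radius, unlist(s$power)),
      rectangle = source_rectangle(as.numeric(s$position),
                                   as.numeric(s$normal),
                                   as.numeric(s$size), unlist(s$power)),
      stop("unknown source kind: ", kind))
    sources[[length(sources) + 1L]] <- src
    meta[[length(meta) + 1L]] <- list(kind = kind, zenith_deg = zen,
                                      azimuth_deg = azi)
  }
  prims <- list()
  if (!is.null(scn$fixture)) {
    fx <- generate_fixture(scn$fixture, seed = scn$fixture_seed %||% image_seed)
    prims <- c(prims, fx$scene$primitives)
  }
  if (!is.null(scn$ground)) {
    g <- scn$ground
    prims <- c(prims, build_ground(
      extent = as.numeric(g$extent %||% c(4, 4)),
      tiles = as.integer(g$tiles %||% c(2L, 2L)),
      optics_front = optics(rho = g$rho %||% 0.2, tau = g$tau %||% 0)))
  }
  if (!is.null(scn$plants)) {
    p <- scn$plants
    count <- p$count %||% 1L
    spacing <- p$spacing %||% 0.5
    for (k in seq_len(count)) {
      pp <- procedural_plant_params(
        species = p$species %||% "bean_like",
        stems_per_plant = p$stems_per_plant,
        leaves_per_petiole = p$leaves_per_petiole,
        plant_height_range = if (!is.null(p$plant_height_range))
          as.numeric(p$plant_height_range) else NULL,
        leaf_length_range = if (!is.null(p$leaf_length_range))
          as.numeric(p$leaf_length_range) else NULL,
        fruit_radius_range = if (!is.null(p$fruit_radius_range))
          as.numeric(p$fruit_radius_range) else NULL,
        fruit_count_range = if (!is.null(p$fruit_count_range))
          as.numeric(p$fruit_count_range) else NULL,
        seed = (p$seed %||% image_seed) + k)
      base <- c(((k - 1) %% 3 - 1) * spacing, ((k - 1) %/% 3 - 1) * spacing, 0)
      prims <- c(prims, build_plant(pp, base = base, plant_id = k))
    }
  }
  list(scene = scene(prims, sources = sources), meta = meta)
}

#' Render a batch dataset from a configuration
#'
#' Renders `config$images` images; image `i` uses the derived seed
#' `config$seed + i` for scene variation, source-angle sampling and
#' transport, so each image is independent of the others and the output is
#' identical however the images are scheduled (`indices` renders any
#' subset, in any order, to the same bytes). Band images, annotation maps,
#' YOLO boxes and JSON metadata are written under `config$output_dir`
#' along with a manifest.
#'
#' @param config A validated config (see [load_run_config()]).
#' @param indices Image indices to render (default all).
#' @return File manifest data.frame, invisibly.
#' @export
run_batch <- function(config, indices = NULL) {
  config <- validate_run_config(unclass(config))
  out_dir <- config$output_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bands <- config_bands(config)
  camera <- config_camera(config)
  if (is.null(indices)) indices <- seq_len(config$images)
  export <- config$export %||% list()
  mode <- export$mode %||% "png8"
  errors <- list()
  manifest <- list()
  for (i in indices) {
    image_seed <- config$seed + i
    res <- try({
      built <- config_scene(config, image_seed)
      cfg <- config_transport(config, seed = image_seed)
      rnd <- render(built$scene, camera, bands, cfg = cfg, seed = image_seed)
      files <- character(0)
      for (bl in names(rnd$images)) {
        img <- rnd$images[[bl]]
        if (!is.null(config$distortion)) {
          dc <- config$distortion
          img <- apply_distortion(img, distortion_coefficients(
            dc$p1 %||% 0, dc$p2 %||% 0, dc$p3 %||% 0, dc$p4 %||% 0))
        }
        fn <- file.path(out_dir, sprintf("img_%04d_%s.%s", i, bl,
                                         if (mode == "png8") "png" else "bin"))
        write_band_image(img, fn, mode = mode,
                         white_point = export$white_point,
                         gamma = export$gamma %||% 2.2)
        files <- c(files, fn)
      }
      for (key in config$annotate %||% list()) {
        lm <- annotate(built$scene, camera, data_key = key, background = NA)
        fn <- file.path(out_dir, sprintf("img_%04d_label_%s.bin", i, key))
        lm[is.na(lm)] <- -1
        write_float_raster(lm, fn, band_labels = key, units = key)
        files <- c(files, fn)
        bx <- boxes_from_labels(lm, background = -1)
        fb <- file.path(out_dir, sprintf("img_%04d_boxes_%s.txt", i, key))
        write_yolo_boxes(bx, fb)
        files <- c(files, fb)
      }
      meta <- list(index = i, seed = image_seed, sources = built$meta,
                   n_primitives = length(built$scene$primitives),
                   bands = vapply(bands, function(b) b$label, character(1)),
                   files = basename(files))
      fm <- file.path(out_dir, sprintf("img_%04d_meta.json", i))
      jsonlite::write_json(meta, fm, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
      files <- c(files, fm)
      data.frame(index = i, file = basename(files))
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      errors[[length(errors) + 1L]] <- list(index = i,
                                            error = as.character(res))
    } else {
      manifest[[length(manifest) + 1L]] <- res
    }
  }
  man <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(index = integer(0), file = character(0))
  utils::write.csv(man, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  if (length(errors)) {
    for (e in errors) {
      message(sprintf("image %d failed: %s", e$index, e$error))
    }
    stop(sprintf("%d of %d image(s) failed", length(errors), length(indices)))
  }
  invisible(man)
}
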