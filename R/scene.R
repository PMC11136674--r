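# Scene construction: planar primitives (triangles and rectangular patches,
# optionally cut out by a PNG alpha mask), per-primitive two-sided optical
# properties and an open-ended annotation data map. World frame is
# right-handed with z up; lengths in meters.

#' Surface optical properties
#'
#' Either flat per-band scalars or full spectra. Scalars apply unchanged to
#' every band (including longwave); spectra are band-integrated with the
#' source spectrum and camera response before transport.
#'
#' @param rho,tau Reflectivity and transmissivity: single numerics in
#'   `[0,1]` or `crt_spectrum` objects.
#' @return An object of class `crt_optics`.
#' @export
optics <- function(rho = 0, tau = 0) {
  chk <- function(x, nm) {
    if (is_spectrum(x)) {
      if (any(x$values > 1)) stop(nm, " spectrum must be <= 1")
      return(x)
    }
    stopifnot(is.numeric(x), length(x) == 1L)
    if (x < 0 || x > 1) stop(nm, " must be in [0,1]")
    x
  }
  rho <- chk(rho, "rho"); tau <- chk(tau, "tau")
  if (!is_spectrum(rho) && !is_spectrum(tau) && rho + tau > 1) {
    stop("rho + tau must be <= 1")
  }
  structure(list(rho = rho, tau = tau), class = "crt_optics")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length vector")
  v / n
}

#' Rotation matrix from Euler angles
#'
#' Intrinsic rotations applied in x, then y, then z order:
#' `R = Rz %*% Ry %*% Rx`.
#'
#' @param rx,ry,rz Rotation angles about the world axes, radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(rx = 0, ry = 0, rz = 0) {
  Rx <- matrix(c(1, 0, 0, 0, cos(rx), sin(rx), 0, -sin(rx), cos(rx)), 3, 3)
  Ry <- matrix(c(cos(ry), 0, -sin(ry), 0, 1, 0, sin(ry), 0, cos(ry)), 3, 3)
  Rz <- matrix(c(cos(rz), sin(rz), 0, -sin(rz), cos(rz), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

new_primitive <- function(kind, vertices, optics_front, optics_back,
                          emissivity, data, mask = NULL, uid = NA_integer_) {
  e1 <- vertices[2, ] - vertices[1, ]
  e2 <- vertices[nrow(vertices), ] - vertices[1, ]
  nrm <- cross3(e1, e2)
  a2 <- sqrt(sum(nrm^2))
  if (a2 < 1e-14) stop("degenerate primitive (zero area)")
  normal <- nrm / a2
  area <- if (kind == "patch") a2 else a2 / 2
  fill <- 1
  if (!is.null(mask)) {
    fill <- mean(mask)
    if (fill <= 0) stop("mask has no opaque texels")
  }
  structure(list(uid = uid, kind = kind, vertices = vertices,
                 normal = normal, e1 = e1, e2 = e2,
                 area = area * fill, full_area = area, fill = fill,
                 optics_front = optics_front, optics_back = optics_back,
                 emissivity = emissivity, data = data, mask = mask),
            class = "crt_primitive")
}

#' Create a rectangular patch primitive
#'
#' A `size[1] x size[2]` rectangle centered at `center`, initially in the
#' xy-plane with front normal +z, then rotated by [rotation_matrix()]
#' angles. An optional boolean mask (rows = texture v, cols = texture u,
#' e.g. from [read_png_mask()]) cuts the patch to an arbitrary outline:
#' masked-out texels are fully transparent and do not count toward the
#' area.
#'
#' @param center Length-3 numeric, m.
#' @param size Length-2 numeric `(width, height)`, m.
#' @param rotation Length-3 Euler angles `(rx, ry, rz)`, radians.
#' @param mask Logical matrix or `NULL`.
#' @param optics_front,optics_back [optics()] for the two sides (back
#'   defaults to front).
#' @param emissivity Longwave emissivity in `[0,1]`.
#' @param data Named list of annotation data (e.g. `plant_id`,
#'   `temperature`).
#' @return A `crt_primitive`.
#' @export
make_patch <- function(center = c(0, 0, 0), size = c(1, 1),
                       rotation = c(0, 0, 0), mask = NULL,
                       optics_front = optics(), optics_back = NULL,
                       emissivity = 0.95, data = list()) {
  if (any(size <= 0)) stop("patch size must be > 0")
  R <- rotation_matrix(rotation[1], rotation[2], rotation[3])
  base <- rbind(c(-size[1] / 2, -size[2] / 2, 0),
                c( size[1] / 2, -size[2] / 2, 0),
                c( size[1] / 2,  size[2] / 2, 0),
                c(-size[1] / 2,  size[2] / 2, 0))
  verts <- t(R %*% t(base)) + matrix(center, 4, 3, byrow = TRUE)
  if (is.null(optics_back)) optics_back <- optics_front
  new_primitive("patch", verts, optics_front, optics_back, emissivity, data,
                mask = mask)
}

#' Create a triangle primitive
#'
#' @param v1,v2,v3 Length-3 vertices, m; front normal follows the
#'   right-hand rule on (v2-v1, v3-v1).
#' @inheritParams make_patch
#' @return A `crt_primitive`.
#' @export
make_triangle <- function(v1, v2, v3, optics_front = optics(),
                          optics_back = NULL, emissivity = 0.95,
                          data = list()) {
  if (is.null(optics_back)) optics_back <- optics_front
  new_primitive("triangle", rbind(v1, v2, v3), optics_front, optics_back,
                emissivity, data)
}

#' Load a PNG alpha channel as a boolean texture mask
#'
#' Texels with alpha > 0.5 are opaque; masking is binary (no partial
#' transparency). Grayscale/RGB images without an alpha channel are fully
#' opaque.
#'
#' @param path PNG file path.
#' @return Logical matrix (rows top-to-bottom as in the image).
#' @export
read_png_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3 && dim(img)[3] %in% c(2, 4)) {
    alpha <- img[, , dim(img)[3]]
  } else {
    alpha <- matrix(1, nrow = dim(img)[1], ncol = dim(img)[2])
  }
  alpha > 0.5
}

#' Assemble a scene
#'
#' @param primitives List of `crt_primitive` (nested lists are flattened).
#' @param sources List of radiation sources (see [source_collimated()] and
#'   friends).
#' @return An object of class `crt_scene` with unique sequential uids.
#' @export
scene <- function(primitives, sources = list()) {
  prims <- flatten_primitives(primitives)
  if (length(prims) == 0L) stop("scene has no primitives")
  uids <- vapply(prims, function(p) p$uid, integer(1))
  if (all(is.na(uids))) {
    for (i in seq_along(prims)) prims[[i]]$uid <- i
  } else if (anyNA(uids)) {
    mx <- max(uids, na.rm = TRUE)
    for (i in seq_along(prims)) {
      if (is.na(prims[[i]]$uid)) prims[[i]]$uid <- (mx <- mx + 1L)
    }
  }
  uids <- vapply(prims, function(p) p$uid, integer(1))
  if (anyDuplicated(uids)) stop("primitive uids must be unique")
  verts <- do.call(rbind, lapply(prims, function(p) p$vertices))
  structure(list(primitives = prims, sources = sources,
                 bbox = rbind(apply(verts, 2, min), apply(verts, 2, max))),
            class = "crt_scene")
}

flatten_primitives <- function(x) {
  if (inherits(x, "crt_primitive")) return(list(x))
  if (!is.list(x)) stop("expected primitives")
  do.call(c, lapply(x, flatten_primitives))
}

#' @export
print.crt_scene <- function(x, ...) {
  cat(sprintf("<crt_scene> %d primitives, %d sources, total area %.3f m2\n",
              length(x$primitives), length(x$sources),
              sum(vapply(x$primitives, function(p) p$area, numeric(1)))))
  invisible(x)
}

#' Set annotation data on primitives
#'
#' @param primitives List of `crt_primitive`.
#' @param ... Named scalar values to set on every primitive.
#' @return The modified list.
#' @export
set_primitive_data <- function(primitives, ...) {
  vals <- list(...)
  lapply(flatten_primitives(primitives), function(p) {
    p$data[names(vals)] <- vals
    p
  })
}

#' Build a tiled ground surface
#'
#' `tiles[1] x tiles[2]` rectangular patches covering
#' `extent[1] x extent[2]` m centered on the origin at z = 0, front normals
#' +z.
#'
#' @param extent Length-2 `(x_extent, y_extent)`, m.
#' @param tiles Length-2 integer `(nx, ny)`.
#' @param texture Optional logical mask applied to every tile.
#' @param optics_front Tile optics.
#' @param data Annotation data applied to every tile.
#' @inheritParams make_patch
#' @return List of patch primitives.
#' @export
build_ground <- function(extent = c(8, 8), tiles = c(4, 4), texture = NULL,
                         optics_front = optics(rho = 0.2), emissivity = 0.95,
                         data = list(class = 0)) {
  if (any(extent <= 0) || any(tiles < 1)) stop("invalid ground specification")
  dx <- extent[1] / tiles[1]
  dy <- extent[2] / tiles[2]
  out <- list()
  for (iy in seq_len(tiles[2])) {
    for (ix in seq_len(tiles[1])) {
      cx <- -extent[1] / 2 + (ix - 0.5) * dx
      cy <- -extent[2] / 2 + (iy - 0.5) * dy
      out[[length(out) + 1L]] <- make_patch(
        center = c(cx, cy, 0), size = c(dx, dy), mask = texture,
        optics_front = optics_front, emissivity = emissivity, data = data)
    }
  }
  out
}

#' Import a triangle mesh from OBJ or ASCII PLY
#'
#' Minimal importers for the two standard polygon formats: vertices and
#' faces only (normals/uvs ignored); polygonal faces are fan-triangulated;
#' degenerate faces are skipped with a message.
#'
#' @param path Mesh file (`.obj` or `.ply`).
#' @param optics_front,optics_back,emissivity,data Applied to every
#'   triangle.
#' @return List of triangle primitives.
#' @export
import_mesh <- function(path, optics_front = optics(rho = 0.2),
                        optics_back = NULL, emissivity = 0.95, data = list()) {
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
                 obj = parse_obj(path),
                 ply = parse_ply(path),
                 stop("unsupported mesh format: ", ext))
  if (nrow(mesh$faces) == 0L) stop("mesh contains no faces")
  prims <- list()
  skipped <- 0L
  for (i in seq_len(nrow(mesh$faces))) {
    f <- mesh$faces[i, ]
    tri <- try(make_triangle(mesh$vertices[f[1], ], mesh$vertices[f[2], ],
                             mesh$vertices[f[3], ],
                             optics_front = optics_front,
                             optics_back = optics_back,
                             emissivity = emissivity, data = data),
               silent = TRUE)
    if (inherits(tri, "try-error")) skipped <- skipped + 1L
    else prims[[length(prims) + 1L]] <- tri
  }
  if (skipped > 0L) message(skipped, " degenerate face(s) skipped")
  if (length(prims) == 0L) stop("mesh contains no valid faces")
  prims
}

parse_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(vl) == 0L) stop("OBJ file has no vertices")
  verts <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                                 function(x) as.numeric(x[1:3])))
  faces <- list()
  for (f in fl) {
    idx <- vapply(strsplit(trimws(sub("^f", "", f)), "\\s+")[[1]],
                  function(tok) as.integer(strsplit(tok, "/")[[1]][1]),
                  integer(1))
    for (j in seq_len(length(idx) - 2L)) {   # fan triangulation
      faces[[length(faces) + 1L]] <- c(idx[1], idx[j + 1], idx[j + 2])
    }
  }
  list(vertices = verts,
       faces = if (length(faces)) do.call(rbind, faces) else matrix(0L, 0, 3))
}

parse_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || trimws(lines[1]) != "ply") stop("not a PLY file")
  if (!any(grepl("format\\s+ascii", lines))) stop("only ASCII PLY supported")
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop("PLY header not terminated")
  nv <- as.integer(sub(".*element\\s+vertex\\s+(\\d+).*", "\\1",
                       grep("element\\s+vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub(".*element\\s+face\\s+(\\d+).*", "\\1",
                       grep("element\\s+face", lines, value = TRUE)[1]))
  body <- lines[(endh + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  verts <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                                 function(x) as.numeric(x[1:3])))
  faces <- list()
  if (!is.na(nf) && nf > 0) {
    for (i in seq_len(nf)) {
      tok <- as.integer(strsplit(trimws(body[nv + i]), "\\s+")[[1]])
      cnt <- tok[1]
      idx <- tok[2:(1 + cnt)] + 1L   # PLY is 0-based
      for (j in seq_len(cnt - 2L)) {
        faces[[length(faces) + 1L]] <- c(idx[1], idx[j + 1], idx[j + 2])
      }
    }
  }
  list(vertices = verts,
       faces = if (length(faces)) do.call(rbind, faces) else matrix(0L, 0, 3))
}
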