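test_that("patches carry the right area, normal and mask fill fraction", {
  p <- make_patch(center = c(0, 0, 0), size = c(1, 1))
  expect_equal(p$area, 1)
  expect_equal(p$normal, c(0, 0, 1))

  half <- matrix(FALSE, 8, 8)
  half[, 1:4] <- TRUE
  pm <- make_patch(size = c(2, 1), mask = half)
  expect_equal(pm$fill, 0.5)
  expect_equal(pm$area, 1)
  expect_equal(pm$area + (pm$full_area - pm$area), 2)  # masked + cut = full

  rot <- make_patch(rotation = c(pi / 2, 0, 0))
  expect_equal(rot$normal, as.numeric(rotation_matrix(pi / 2, 0, 0) %*% c(0, 0, 1)),
               tolerance = 1e-12)
  expect_error(make_patch(size = c(0, 1)), "size")
})

test_that("ground tiling covers the extent on a regular lattice", {
  g <- build_ground(extent = c(8, 8), tiles = c(4, 4))
  expect_length(g, 16)
  areas <- vapply(g, function(p) p$area, numeric(1))
  expect_equal(areas, rep(4, 16))
  expect_equal(sum(areas), 64)
  centers <- t(vapply(g, function(p) colMeans(p$vertices), numeric(3)))
  expect_equal(sort(unique(centers[, 1])), c(-3, -1, 1, 3))
  expect_equal(sort(unique(centers[, 2])), c(-3, -1, 1, 3))
})

test_that("OBJ and PLY import triangulate faces with correct areas", {
  obj <- tempfile(fileext = ".obj")
  # unit cube, 8 vertices, 6 quad faces -> 12 triangles, area 6
  v <- expand.grid(x = 0:1, y = 0:1, z = 0:1)
  writeLines(c(
    sprintf("v %d %d %d", v$x, v$y, v$z),
    "f 1 2 4 3", "f 5 7 8 6", "f 1 5 6 2", "f 3 4 8 7",
    "f 1 3 7 5", "f 2 6 8 4"), obj)
  tris <- import_mesh(obj)
  expect_length(tris, 12)
  expect_equal(sum(vapply(tris, function(p) p$area, numeric(1))), 6)

  heron <- function(a, b, c) {
    la <- sqrt(sum((b - c)^2)); lb <- sqrt(sum((a - c)^2))
    lc <- sqrt(sum((a - b)^2))
    s <- (la + lb + lc) / 2
    sqrt(s * (s - la) * (s - lb) * (s - lc))
  }
  verts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.3, 1.2, 0), c(0.5, 0.4, 0.9))
  ply <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0",
               "element vertex 4",
               "property float x", "property float y", "property float z",
               "element face 4", "property list uchar int vertex_indices",
               "end_header",
               apply(verts, 1, paste, collapse = " "),
               "3 0 1 2", "3 0 1 3", "3 0 2 3", "3 1 2 3"), ply)
  tet <- import_mesh(ply)
  expect_length(tet, 4)
  faces <- list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  for (i in 1:4) {
    f <- faces[[i]]
    expect_equal(tet[[i]]$area,
                 heron(verts[f[1], ], verts[f[2], ], verts[f[3], ]),
                 tolerance = 1e-12)
  }

  empty <- tempfile(fileext = ".obj")
  writeLines("v 0 0 0", empty)
  expect_error(import_mesh(empty), "no faces")
})

test_that("procedural plants are reproducible and respect their ranges", {
  pp <- procedural_plant_params("strawberry_like", seed = 11L)
  a <- build_plant(pp)
  b <- build_plant(pp)
  expect_identical(lapply(a, function(p) p$vertices),
                   lapply(b, function(p) p$vertices))

  # every leaf primitive carries plant and leaf identifiers
  leaves <- Filter(function(p) identical(p$data$class, 1L), a)
  expect_gt(length(leaves), 0)
  expect_true(all(vapply(leaves, function(p) !is.null(p$data$leaf_id) &&
                           !is.null(p$data$plant_id), logical(1))))
  expect_equal(length(leaves), pp$stems_per_plant * pp$leaves_per_petiole)
  fruit <- Filter(function(p) identical(p$data$class, 3L), a)
  n_fruit <- length(unique(vapply(fruit, function(p) p$data$fruit_id, 1)))
  expect_gte(n_fruit, pp$stems_per_plant * pp$fruit_count_range[1])
  expect_lte(n_fruit, pp$stems_per_plant * pp$fruit_count_range[2])

  # degenerate ranges + zero jitter -> identical prototype across seeds
  fixed <- procedural_plant_params("bean_like",
                                   plant_height_range = c(0.15, 0.15),
                                   leaf_length_range = c(0.06, 0.06),
                                   rotation_jitter = c(0, 0, 0), seed = 1L)
  fixed2 <- fixed; fixed2$seed <- 99L
  expect_equal(lapply(build_plant(fixed), function(p) p$vertices),
               lapply(build_plant(fixed2), function(p) p$vertices),
               tolerance = 1e-12)

  # sampled leaf lengths stay inside the configured range
  lens <- unlist(lapply(1:30, function(s) {
    pl <- build_plant(procedural_plant_params("bean_like", seed = s))
    vapply(Filter(function(p) identical(p$data$class, 1L), pl),
           function(p) p$data$leaf_length, numeric(1))
  }))
  expect_gte(min(lens), 0.04)
  expect_lte(max(lens), 0.08)
  expect_gt(diff(range(lens)), 0.02)   # variation actually happens
})

test_that("scene assembly enforces unique uids and flattens nesting", {
  g <- build_ground(tiles = c(2, 2))
  sc <- scene(list(g, make_patch(center = c(0, 0, 1))))
  expect_length(sc$primitives, 5)
  uids <- vapply(sc$primitives, function(p) p$uid, integer(1))
  expect_false(anyDuplicated(uids) > 0)
  p1 <- make_patch(); p1$uid <- 7L
  p2 <- make_patch(center = c(1, 0, 0)); p2$uid <- 7L
  expect_error(scene(list(p1, p2)), "unique")
  expect_error(scene(list()), "no primitives")
})

test_that("ray intersection matches the brute-force oracle", {
  sc <- generate_fixture("mini_canopy", seed = 2)$scene
  d <- intersect_ray(sc, c(0.2, -0.3, 5), c(0, 0, -1))
  expect_false(is.null(d))

  simple <- scene(list(make_patch(size = c(10, 10))))
  hit <- intersect_ray(simple, c(0, 0, 5), c(0, 0, -1))
  expect_equal(hit$dist, 5)
  expect_equal(hit$side, 1L)  # descending ray sees the front (up) face

  stacked <- scene(list(make_patch(center = c(0, 0, 1)), make_patch()))
  nearer <- intersect_ray(stacked, c(0, 0, 5), c(0, 0, -1))
  expect_equal(nearer$uid, stacked$primitives[[1]]$uid)

  set.seed(31)
  n <- 300
  o <- cbind(runif(n, -1, 1), runif(n, -1, 1), runif(n, 1.2, 4))
  dr <- matrix(rnorm(3 * n), n, 3)
  dr <- dr / sqrt(rowSums(dr^2))
  h <- intersect_rays(sc, o, dr)
  for (i in seq_len(n)) {
    ref <- brute_intersect(sc, o[i, ], dr[i, ])
    if (is.null(ref)) {
      expect_false(h$hit[i])
    } else {
      expect_equal(h$uid[i], ref$uid)
      expect_equal(h$dist[i], ref$dist, tolerance = 1e-12)
      expect_equal(h$side[i], ref$side)
    }
  }
})

test_that("masked-out texels are transparent to rays", {
  ring <- !ellipse_mask(16)          # opaque outside the ellipse
  sc <- scene(list(make_patch(size = c(2, 2), mask = ring),
                   make_patch(center = c(0, 0, -1), size = c(4, 4))))
  through <- intersect_ray(sc, c(0, 0, 5), c(0, 0, -1))   # center: hole
  expect_equal(through$uid, sc$primitives[[2]]$uid)
  edge <- intersect_ray(sc, c(0.95, 0.95, 5), c(0, 0, -1)) # corner: opaque
  expect_equal(edge$uid, sc$primitives[[1]]$uid)
})

test_that("PNG alpha masks binarize at 0.5", {
  img <- array(1, c(4, 4, 4))
  img[, , 4] <- matrix(c(rep(0.9, 8), rep(0.1, 8)), 4, 4)
  path <- tempfile(fileext = ".png")
  png::writePNG(img, path)
  m <- read_png_mask(path)
  expect_equal(mean(m), 0.5)
})
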