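# Ray-scene intersection.
#
# The intersection kernel sweeps every primitive with fully vectorized
# ray-plane / ray-triangle math over all rays at once. At desk-scale scene
# sizes this exhaustive sweep is the fast path in R (and its semantics are
# pinned by a scalar brute-force oracle in the tests); an acceleration
# structure would be an optimization, never a semantics change.

#' Intersect a batch of rays with a scene
#'
#' Nearest intersection per ray with distance > `eps` (the self-intersection
#' guard after scattering). Masked-out patch texels are fully transparent:
#' the ray passes through. The hit side is the front face when the ray
#' direction opposes the primitive normal.
#'
#' @param sc A [scene()].
#' @param origins,dirs `n x 3` matrices of ray origins and unit directions.
#' @param eps Minimum hit distance, m.
#' @return List with per-ray vectors: `hit` (logical), `prim` (index into
#'   `sc$primitives`), `uid`, `dist` (m), `side` (1 = front, 2 = back) and
#'   an `n x 3` matrix `point`. Misses carry `NA`.
#' @export
intersect_rays <- function(sc, origins, dirs, eps = 1e-6) {
  stopifnot(inherits(sc, "crt_scene"))
  if (is.null(dim(origins))) origins <- matrix(origins, ncol = 3)
  if (is.null(dim(dirs))) dirs <- matrix(dirs, ncol = 3)
  n <- nrow(origins)
  best_t <- rep(Inf, n)
  best_p <- rep(NA_integer_, n)
  best_side <- rep(NA_integer_, n)
  ox <- origins[, 1]; oy <- origins[, 2]; oz <- origins[, 3]
  dx <- dirs[, 1]; dy <- dirs[, 2]; dz <- dirs[, 3]

  for (ip in seq_along(sc$primitives)) {
    p <- sc$primitives[[ip]]
    nr <- p$normal
    dp <- dx * nr[1] + dy * nr[2] + dz * nr[3]
    p0 <- p$vertices[1, ]
    tt <- ((p0[1] - ox) * nr[1] + (p0[2] - oy) * nr[2] + (p0[3] - oz) * nr[3]) / dp
    cand <- is.finite(tt) & tt > eps & tt < best_t
    if (!any(cand)) next
    hx <- ox[cand] + tt[cand] * dx[cand] - p0[1]
    hy <- oy[cand] + tt[cand] * dy[cand] - p0[2]
    hz <- oz[cand] + tt[cand] * dz[cand] - p0[3]
    if (p$kind == "patch") {
      e1 <- p$e1; e2 <- p$e2
      u <- (hx * e1[1] + hy * e1[2] + hz * e1[3]) / sum(e1^2)
      v <- (hx * e2[1] + hy * e2[2] + hz * e2[3]) / sum(e2^2)
      inside <- u >= 0 & u <= 1 & v >= 0 & v <= 1
      if (!is.null(p$mask) && any(inside)) {
        m <- p$mask
        ui <- pmin(pmax(ceiling(u[inside] * ncol(m)), 1L), ncol(m))
        vi <- pmin(pmax(nrow(m) - floor(v[inside] * nrow(m)), 1L), nrow(m))
        inside[inside] <- m[cbind(vi, ui)]
      }
    } else {
      # barycentric coordinates in the (e1, e2) basis
      e1 <- p$e1; e2 <- p$e2
      d00 <- sum(e1^2); d01 <- sum(e1 * e2); d11 <- sum(e2^2)
      den <- d00 * d11 - d01^2
      d20 <- hx * e1[1] + hy * e1[2] + hz * e1[3]
      d21 <- hx * e2[1] + hy * e2[2] + hz * e2[3]
      v <- (d11 * d20 - d01 * d21) / den
      w <- (d00 * d21 - d01 * d20) / den
      inside <- v >= 0 & w >= 0 & (v + w) <= 1
    }
    if (!any(inside)) next
    idx <- which(cand)[inside]
    best_t[idx] <- tt[idx]
    best_p[idx] <- ip
    best_side[idx] <- ifelse(dp[idx] < 0, 1L, 2L)
  }

  hit <- is.finite(best_t)
  uid <- rep(NA_integer_, n)
  if (any(hit)) {
    uid[hit] <- vapply(sc$primitives[best_p[hit]], function(p) p$uid,
                       integer(1))
  }
  point <- cbind(ox + best_t * dx, oy + best_t * dy, oz + best_t * dz)
  point[!hit, ] <- NA_real_
  list(hit = hit, prim = best_p, uid = uid,
       dist = ifelse(hit, best_t, NA_real_), side = best_side, point = point)
}

#' Intersect a single ray with a scene
#'
#' @param origin,direction Length-3 numeric; `direction` is normalized
#'   internally.
#' @inheritParams intersect_rays
#' @return A list `(uid, prim, dist, side, point)` or `NULL` on miss.
#' @export
intersect_ray <- function(sc, origin, direction, eps = 1e-6) {
  d <- normalize3(direction)
  h <- intersect_rays(sc, matrix(origin, 1), matrix(d, 1), eps = eps)
  if (!h$hit[1]) return(NULL)
  list(uid = h$uid[1], prim = h$prim[1], dist = h$dist[1], side = h$side[1],
       point = h$point[1, ])
}
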