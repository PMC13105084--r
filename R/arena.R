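#' Arena specification
#'
#' Geometry of the hexagonal open-field arena: a regular hexagonal prism with
#' its floor at z = 0 and the z axis aligned with gravity. The default
#' dimensions are a 2.4 m tall arena with 1.5 m sides, mid-level benches at
#' about 1.5 m, and a grated ceiling at the top that the animal can hang from.
#'
#' @param side_m hexagon side length (m)
#' @param height_m arena height (m)
#' @param bench_z_m height of the mid-level benches (m)
#' @param ceiling_z_m height of the ceiling surface (m); defaults to `height_m`
#' @param center arena center (x, y, z = 0), m
#' @param floor_normal unit normal of the floor plane (gravity-aligned)
#' @return an `arena_spec` object
#' @export
arena_spec <- function(side_m = 1.5, height_m = 2.4, bench_z_m = 1.5,
                       ceiling_z_m = height_m, center = c(0, 0, 0),
                       floor_normal = c(0, 0, 1)) {
  stopifnot(side_m > 0, height_m > 0,
            bench_z_m > 0, bench_z_m < ceiling_z_m,
            ceiling_z_m <= height_m + 1e-9,
            length(center) == 3, length(floor_normal) == 3)
  nrm <- sqrt(sum(floor_normal^2))
  if (abs(nrm - 1) > 1e-6) stop("floor_normal must have unit norm")
  structure(list(side_m = side_m, height_m = height_m,
                 bench_z_m = bench_z_m, ceiling_z_m = ceiling_z_m,
                 center = as.numeric(center),
                 floor_normal = as.numeric(floor_normal) / nrm),
            class = "arena_spec")
}

## vertices of the hexagon cross-section (flat-topped; first vertex on +x)
hex_vertices <- function(arena) {
  ang <- (0:5) * pi / 3
  cbind(arena$center[1] + arena$side_m * cos(ang),
        arena$center[2] + arena$side_m * sin(ang))
}

#' Test whether horizontal points lie inside the hexagonal cross-section
#' @param arena an `arena_spec`
#' @param xy n x 2 matrix of horizontal coordinates (m)
#' @param margin shrink the hexagon by this margin (m) before testing
#' @return logical vector
#' @export
in_hexagon <- function(arena, xy, margin = 0) {
  xy <- matrix(xy, ncol = 2)
  dx <- xy[, 1] - arena$center[1]
  dy <- xy[, 2] - arena$center[2]
  apo <- arena$side_m * sqrt(3) / 2 - margin
  ## regular hexagon = intersection of 3 slabs through opposite edge pairs
  e1 <- abs(dx * cos(pi / 6) + dy * sin(pi / 6))
  e2 <- abs(dx * cos(pi / 2) + dy * sin(pi / 2))
  e3 <- abs(dx * cos(5 * pi / 6) + dy * sin(5 * pi / 6))
  e1 <= apo & e2 <= apo & e3 <= apo
}

#' Distance from interior points to the hexagon wall along a horizontal ray
#'
#' The first intersection of the ray `origin + t * direction` (horizontal
#' components only) with the six wall planes, restricted to the wall segments.
#' Used as the distance-to-wall-along-gaze visual proxy.
#'
#' @param arena an `arena_spec`
#' @param origin n x 2 (or length-2) horizontal ray origins (m)
#' @param direction n x 2 (or length-2) horizontal ray directions (not
#'   necessarily unit length; zero-length directions give `NA`)
#' @return numeric vector of distances (m); 0 with attribute
#'   `out_of_arena = TRUE` entries for origins outside the hexagon
#' @export
ray_wall_distance <- function(arena, origin, direction) {
  origin <- matrix(origin, ncol = 2)
  direction <- matrix(direction, ncol = 2)
  n <- nrow(origin)
  stopifnot(nrow(direction) == n)
  verts <- hex_vertices(arena)
  out <- rep(NA_real_, n)
  oob <- !in_hexagon(arena, origin, margin = -1e-9)
  dn <- sqrt(rowSums(direction^2))
  for (i in seq_len(n)) {
    if (oob[i]) { out[i] <- 0; next }
    if (!is.finite(dn[i]) || dn[i] < 1e-12) next
    d <- direction[i, ] / dn[i]
    o <- origin[i, ]
    best <- Inf
    for (e in 1:6) {
      a <- verts[e, ]
      b <- verts[(e %% 6) + 1, ]
      ab <- b - a
      denom <- d[1] * ab[2] - d[2] * ab[1]
      if (abs(denom) < 1e-12) next
      t <- ((a[1] - o[1]) * ab[2] - (a[2] - o[2]) * ab[1]) / denom
      u <- if (abs(ab[1]) > abs(ab[2])) (o[1] + t * d[1] - a[1]) / ab[1]
           else (o[2] + t * d[2] - a[2]) / ab[2]
      if (t >= 0 && u >= -1e-9 && u <= 1 + 1e-9 && t < best) best <- t
    }
    out[i] <- if (is.finite(best)) best else NA_real_
  }
  attr(out, "out_of_arena") <- oob
  out
}

#' Dense ray-marching oracle for the wall distance
#'
#' Steps along the ray in small increments until it exits the hexagon, then
#' bisects the final step. Independent of the analytic edge-intersection
#' computation; used to validate it.
#'
#' @inheritParams ray_wall_distance
#' @param step march step (m)
#' @return numeric vector of distances (m)
#' @export
ray_wall_distance_march <- function(arena, origin, direction, step = 1e-3) {
  origin <- matrix(origin, ncol = 2)
  direction <- matrix(direction, ncol = 2)
  n <- nrow(origin)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    d <- direction[i, ]
    dn <- sqrt(sum(d^2))
    if (dn < 1e-12) next
    d <- d / dn
    if (!in_hexagon(arena, origin[i, , drop = FALSE])) { out[i] <- 0; next }
    t <- 0
    tmax <- 4 * arena$side_m
    while (t < tmax &&
           in_hexagon(arena, rbind(origin[i, ] + (t + step) * d))) {
      t <- t + step
    }
    lo <- t; hi <- t + step
    for (k in 1:30) {
      mid <- (lo + hi) / 2
      if (in_hexagon(arena, rbind(origin[i, ] + mid * d))) lo <- mid else hi <- mid
    }
    out[i] <- (lo + hi) / 2
  }
  out
}
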