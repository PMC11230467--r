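# Planar polygon engine.
#
# All area mathematics in the package happens here, in projected planar
# coordinates. A geometry ("pgeom") is a set of simple rings, each carrying a
# sign: +1 for outer boundaries, -1 for holes. Its area is the signed sum of
# ring areas, and the intersection area of two geometries is computed exactly
# by decomposing every ring into a signed triangle fan and clipping triangle
# pairs (a convex clip, so Sutherland-Hodgman is exact). This is valid for
# arbitrary simple rings because the signed fan of a simple polygon
# reproduces its indicator function.

#' Signed area of a ring (shoelace formula)
#'
#' @param xy two-column numeric matrix of vertices, ring open (first vertex
#'   not repeated at the end). Positive for counter-clockwise rings.
#' @return signed area in squared coordinate units.
#' @keywords internal
ring_signed_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

ring_bbox <- function(xy) {
  c(min(xy[, 1]), min(xy[, 2]), max(xy[, 1]), max(xy[, 2]))
}

bbox_disjoint <- function(b1, b2) {
  b1[3] < b2[1] || b2[3] < b1[1] || b1[4] < b2[2] || b2[4] < b1[2]
}

# Drop consecutive duplicate vertices and a repeated closing vertex.
dedupe_ring <- function(xy, tol = 1e-12) {
  n <- nrow(xy)
  if (n < 2) return(xy)
  scale <- max(1, max(abs(xy)))
  keep <- c(TRUE, rowSums(abs(xy[-1, , drop = FALSE] -
                              xy[-n, , drop = FALSE])) > tol * scale)
  xy <- xy[keep, , drop = FALSE]
  n <- nrow(xy)
  if (n > 1 && sum(abs(xy[n, ] - xy[1, ])) <= tol * scale)
    xy <- xy[-n, , drop = FALSE]
  xy
}

# Proper intersection of segments p1-p2 and p3-p4 (interior crossing).
# Returns c(t, u, x, y) with t, u in (0,1), or NULL.
seg_cross <- function(p1, p2, p3, p4, eps = 1e-12) {
  r <- p2 - p1; s <- p4 - p3
  denom <- r[1] * s[2] - r[2] * s[1]
  if (abs(denom) < eps) return(NULL)
  qp <- p3 - p1
  t <- (qp[1] * s[2] - qp[2] * s[1]) / denom
  u <- (qp[1] * r[2] - qp[2] * r[1]) / denom
  if (t <= eps || t >= 1 - eps || u <= eps || u >= 1 - eps) return(NULL)
  c(t, u, p1[1] + t * r[1], p1[2] + t * r[2])
}

#' Repair a self-intersecting ring
#'
#' Splits a ring at its proper self-intersections into simple loops (the
#' planar analogue of a zero-width buffer): a bow-tie becomes two triangles.
#' Degenerate loops (fewer than 3 vertices or negligible area) are dropped.
#'
#' @param xy two-column vertex matrix, ring open.
#' @param tol relative tolerance for coincident points.
#' @return list of simple ring matrices; a single-element list when the ring
#'   was already simple.
#' @keywords internal
repair_ring <- function(xy, tol = 1e-9) {
  xy <- dedupe_ring(xy)
  n <- nrow(xy)
  if (n < 3) return(list())
  scale <- max(1, max(abs(xy)))
  # collect proper crossings per edge
  hits <- vector("list", n)
  any_hit <- FALSE
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1) next
      if (i == 1 && j == n) next       # adjacent around the wrap
      p1 <- xy[i, ]; p2 <- xy[if (i == n) 1 else i + 1, ]
      p3 <- xy[j, ]; p4 <- xy[if (j == n) 1 else j + 1, ]
      cr <- seg_cross(p1, p2, p3, p4)
      if (!is.null(cr)) {
        any_hit <- TRUE
        hits[[i]] <- rbind(hits[[i]], c(cr[1], cr[3], cr[4]))
        hits[[j]] <- rbind(hits[[j]], c(cr[2], cr[3], cr[4]))
      }
    }
  }
  if (!any_hit) return(list(xy))
  # augmented vertex walk with crossings inserted in order along each edge
  pts <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    pts <- rbind(pts, xy[i, ])
    h <- hits[[i]]
    if (!is.null(h)) {
      h <- h[order(h[, 1]), , drop = FALSE]
      pts <- rbind(pts, h[, 2:3, drop = FALSE])
    }
  }
  # extract simple loops by splitting whenever a point reappears
  key <- function(p) paste(round(p / (tol * scale)), collapse = "_")
  loops <- list()
  path <- matrix(numeric(0), 0, 2)
  seen <- character(0)
  for (i in seq_len(nrow(pts))) {
    k <- key(pts[i, ])
    pos <- match(k, seen)
    if (!is.na(pos)) {
      loop <- path[seq(pos, nrow(path)), , drop = FALSE]
      if (nrow(loop) >= 3) loops[[length(loops) + 1]] <- loop
      keep <- seq_len(pos - 1)
      path <- path[keep, , drop = FALSE]
      seen <- seen[keep]
    }
    path <- rbind(path, pts[i, ])
    seen <- c(seen, k)
  }
  if (nrow(path) >= 3) loops[[length(loops) + 1]] <- path
  loops <- lapply(loops, dedupe_ring)
  area_floor <- (tol * scale)^2
  Filter(function(l) nrow(l) >= 3 && abs(ring_signed_area(l)) > area_floor,
         loops)
}

# Triangle fan of a simple ring, normalised so that the signed sum of
# triangle indicators equals the ring's indicator. Each element:
# list(xy = 3x2 CCW matrix, sign = +-1, bbox).
fan_triangles <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(list())
  ccw <- ring_signed_area(xy) >= 0
  v0 <- xy[1, ]
  tris <- list()
  for (k in 2:(n - 1)) {
    tri <- rbind(v0, xy[k, ], xy[k + 1, ])
    a <- ring_signed_area(tri)
    if (a == 0) next
    s <- if (a > 0) 1L else -1L
    if (a < 0) tri <- tri[3:1, , drop = FALSE]   # store CCW
    if (!ccw) s <- -s                            # relative to ring interior
    tris[[length(tris) + 1]] <- list(xy = tri, sign = s, bbox = ring_bbox(tri))
  }
  tris
}

# Sutherland-Hodgman clip of a subject polygon against one half-plane,
# the left side of the directed edge p -> q.
clip_halfplane <- function(pts, p, q, eps = 1e-13) {
  n <- nrow(pts)
  if (n == 0) return(pts)
  dx <- q[1] - p[1]; dy <- q[2] - p[2]
  d <- dx * (pts[, 2] - p[2]) - dy * (pts[, 1] - p[1])
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    di <- d[i]; dj <- d[j]
    if (dj >= -eps) {
      if (di < -eps) {
        t <- di / (di - dj)
        out <- rbind(out, pts[i, ] + t * (pts[j, ] - pts[i, ]))
      }
      out <- rbind(out, pts[j, ])
    } else if (di > eps) {
      t <- di / (di - dj)
      out <- rbind(out, pts[i, ] + t * (pts[j, ] - pts[i, ]))
    }
  }
  out
}

# Unsigned area of the intersection of two CCW triangles.
tri_tri_area <- function(a, b) {
  pts <- a
  for (i in 1:3) {
    j <- if (i == 3) 1 else i + 1
    pts <- clip_halfplane(pts, b[i, ], b[j, ])
    if (nrow(pts) < 3) return(0)
  }
  abs(ring_signed_area(pts))
}

#' Construct a planar geometry
#'
#' @param rings list of two-column vertex matrices.
#' @param signs integer vector, +1 for outer rings, -1 for holes (recycled).
#' @return object of class `pgeom` with precomputed triangle fans.
#' @export
planar_geom <- function(rings, signs = 1L) {
  if (is.matrix(rings)) rings <- list(rings)
  signs <- rep_len(as.integer(signs), length(rings))
  rr <- list()
  for (i in seq_along(rings)) {
    xy <- dedupe_ring(as.matrix(rings[[i]]))
    if (nrow(xy) < 3) next
    rr[[length(rr) + 1]] <- list(
      xy = xy, sign = signs[i],
      bbox = ring_bbox(xy), tris = fan_triangles(xy)
    )
  }
  if (!length(rr)) stop("geometry has no non-degenerate ring")
  bb <- sapply(rr, `[[`, "bbox")
  structure(list(rings = rr,
                 bbox = c(min(bb[1, ]), min(bb[2, ]), max(bb[3, ]), max(bb[4, ]))),
            class = "pgeom")
}

#' Axis-aligned rectangle geometry
#' @param xmin,ymin,xmax,ymax rectangle bounds.
#' @export
planar_rect <- function(xmin, ymin, xmax, ymax) {
  planar_geom(cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax)))
}

#' Area of a planar geometry
#' @param g a [planar_geom()] object.
#' @return area in squared coordinate units (holes subtracted).
#' @export
planar_area <- function(g) {
  sum(vapply(g$rings, function(r) r$sign * abs(ring_signed_area(r$xy)), 0))
}

#' Exact intersection area of two planar geometries
#'
#' Decomposes each ring into a signed triangle fan and sums pairwise
#' triangle-triangle intersection areas, so the result is exact (up to
#' floating point) for arbitrary simple rings including holes and
#' multi-part geometries.
#'
#' @param g1,g2 [planar_geom()] objects in the same planar coordinate system.
#' @return non-negative intersection area.
#' @export
intersection_area <- function(g1, g2) {
  if (bbox_disjoint(g1$bbox, g2$bbox)) return(0)
  tot <- 0
  for (r1 in g1$rings) {
    for (r2 in g2$rings) {
      if (bbox_disjoint(r1$bbox, r2$bbox)) next
      s <- r1$sign * r2$sign
      for (t1 in r1$tris) {
        for (t2 in r2$tris) {
          if (bbox_disjoint(t1$bbox, t2$bbox)) next
          a <- tri_tri_area(t1$xy, t2$xy)
          if (a > 0) tot <- tot + s * t1$sign * t2$sign * a
        }
      }
    }
  }
  max(tot, 0)
}

# Even-odd point-in-ring test, vectorised over points.
points_in_ring <- function(px, py, xy) {
  n <- nrow(xy)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]; xj <- xy[j, 1]; yj <- xy[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Test points for containment in a geometry
#' @param pts two-column matrix of points.
#' @param g a [planar_geom()] object.
#' @return logical vector (holes excluded).
#' @export
points_in_geom <- function(pts, g) {
  val <- rep(0L, nrow(pts))
  for (r in g$rings) {
    val <- val + r$sign * points_in_ring(pts[, 1], pts[, 2], r$xy)
  }
  val > 0L
}

#' Monte-Carlo oracle for intersection areas
#'
#' Estimates `area(g1 ∩ g2)` by rejection sampling over the bounding box of
#' `g1`. Used as an independent check on [intersection_area()].
#'
#' @param g1,g2 [planar_geom()] objects (or ring matrices, coerced).
#' @param n_points number of uniform sample points (at least 1000).
#' @param seed integer seed for the sampler.
#' @return list with `estimate`, `se` (binomial standard error) and
#'   `n_points`.
#' @export
mc_area_oracle <- function(g1, g2, n_points = 10000L, seed = 1L) {
  if (!inherits(g1, "pgeom")) g1 <- planar_geom(g1)
  if (!inherits(g2, "pgeom")) g2 <- planar_geom(g2)
  if (n_points < 1000) stop("n_points must be at least 1000")
  bb <- g1$bbox
  w <- bb[3] - bb[1]; h <- bb[4] - bb[2]
  if (w <= 0 || h <= 0) stop("degenerate bounding box")
  box_area <- w * h
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  pts <- cbind(runif(n_points, bb[1], bb[3]), runif(n_points, bb[2], bb[4]))
  hit <- points_in_geom(pts, g1) & points_in_geom(pts, g2)
  p <- mean(hit)
  list(estimate = box_area * p,
       se = box_area * sqrt(p * (1 - p) / n_points),
       n_points = n_points)
}

# Seed handling: set a temporary seed without clobbering the caller's RNG.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
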