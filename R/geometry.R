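# Internal planar-geometry helpers shared by the morphospace and vision code.
# Polygons are n x 2 matrices of vertices, stored open (no repeated endpoint);
# counterclockwise orientation has positive signed area (y increases upward).

#' @noRd
signed_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' @noRd
polygon_perimeter <- function(pts) {
  nxt <- pts[c(seq_len(nrow(pts))[-1], 1), , drop = FALSE]
  sum(sqrt(rowSums((nxt - pts)^2)))
}

# Convex hull vertices in counterclockwise order (chull returns clockwise).
#' @noRd
convex_hull_ccw <- function(pts) {
  idx <- grDevices::chull(pts)
  pts[rev(idx), , drop = FALSE]
}

# Sutherland-Hodgman clipping of `subject` by a convex ccw `clip` polygon.
# Returns a (possibly empty) vertex matrix.
#' @noRd
clip_polygon_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0) return(out)
    a <- clip[i, ]
    b <- clip[if (i == nc) 1L else i + 1L, ]
    inp <- out
    n <- nrow(inp)
    # >= 0 is the interior side of edge a->b for a ccw clip polygon
    side <- (b[1] - a[1]) * (inp[, 2] - a[2]) - (b[2] - a[2]) * (inp[, 1] - a[1])
    keep <- vector("list", 2L * n)
    m <- 0L
    for (j in seq_len(n)) {
      k <- if (j == n) 1L else j + 1L
      inj <- side[j] >= -1e-12
      ink <- side[k] >= -1e-12
      if (inj) {
        m <- m + 1L
        keep[[m]] <- inp[j, ]
      }
      if (xor(inj, ink)) {
        t <- side[j] / (side[j] - side[k])
        m <- m + 1L
        keep[[m]] <- inp[j, ] + t * (inp[k, ] - inp[j, ])
      }
    }
    out <- if (m == 0L) matrix(numeric(0), 0, 2) else do.call(rbind, keep[seq_len(m)])
  }
  dedupe_vertices(out)
}

# Drop consecutive (near-)duplicate vertices produced by clipping.
#' @noRd
dedupe_vertices <- function(pts, tol = 1e-12) {
  n <- nrow(pts)
  if (n < 2) return(pts)
  nxt <- pts[c(2:n, 1), , drop = FALSE]
  d <- sqrt(rowSums((nxt - pts)^2))
  scale <- max(1, max(abs(pts)))
  pts[d > tol * scale, , drop = FALSE]
}

# Area of the intersection of two convex ccw polygons.
#' @noRd
convex_intersection_area <- function(a, b) {
  inter <- clip_polygon_convex(a, b)
  if (nrow(inter) < 3) return(0)
  abs(signed_area(inter))
}

# Point-in-convex-polygon test (ccw vertices); boundary counts as inside.
#' @noRd
point_in_convex <- function(p, poly, tol = 1e-9) {
  n <- nrow(poly)
  if (n == 0) return(FALSE)
  scale <- max(1, max(abs(poly)))
  if (n < 3) return(point_near_chain(p, poly, tol * scale))
  nxt <- poly[c(2:n, 1), , drop = FALSE]
  cr <- (nxt[, 1] - poly[, 1]) * (p[2] - poly[, 2]) -
    (nxt[, 2] - poly[, 2]) * (p[1] - poly[, 1])
  all(cr >= -tol * scale)
}

# Distance-based membership for degenerate (point/segment) "hulls".
#' @noRd
point_near_chain <- function(p, chain, tol) {
  n <- nrow(chain)
  if (n == 1) return(sqrt(sum((p - chain[1, ])^2)) <= tol)
  for (i in seq_len(n - 1)) {
    if (point_segment_distance(p, chain[i, ], chain[i + 1, ]) <= tol) return(TRUE)
  }
  FALSE
}

#' @noRd
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((p - a - t * ab)^2))
}

# General even-odd point-in-polygon with boundary tolerance (polygon need not
# be convex); used for head-capsule containment tests.
#' @noRd
point_in_polygon <- function(p, poly, tol = 1e-9) {
  n <- nrow(poly)
  scale <- max(1, max(abs(poly)))
  closed <- rbind(poly, poly[1, ])
  for (i in seq_len(n)) {
    if (point_segment_distance(p, closed[i, ], closed[i + 1, ]) <= tol * scale) {
      return(TRUE)
    }
  }
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((poly[i, 2] > p[2]) != (poly[j, 2] > p[2])) {
      xint <- poly[i, 1] + (p[2] - poly[i, 2]) / (poly[j, 2] - poly[i, 2]) *
        (poly[j, 1] - poly[i, 1])
      if (p[1] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' @noRd
rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' @noRd
unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length direction vector", call. = FALSE)
  v / n
}

# Signed angle of direction v relative to reference direction ref
# (positive = counterclockwise from ref).
#' @noRd
signed_angle_from <- function(ref, v) {
  atan2(ref[1] * v[2] - ref[2] * v[1], ref[1] * v[1] + ref[2] * v[2])
}

# First intersection parameter t >= 0 of the ray origin + t*dir with a convex
# ccw polygon, or NA if the ray misses it (slab/half-plane method).
#' @noRd
ray_convex_entry <- function(origin, dir, poly) {
  n <- nrow(poly)
  if (n < 3) return(NA_real_)
  t_lo <- 0
  t_hi <- Inf
  for (i in seq_len(n)) {
    a <- poly[i, ]
    b <- poly[if (i == n) 1L else i + 1L, ]
    # inward normal of edge a->b for ccw polygon
    nrm <- c(-(b[2] - a[2]), b[1] - a[1])
    denom <- sum(nrm * dir)
    num <- sum(nrm * (a - origin))
    if (abs(denom) < 1e-300) {
      if (num > 1e-12) return(NA_real_)  # parallel and outside
    } else {
      t <- num / denom
      if (denom > 0) t_lo <- max(t_lo, t) else t_hi <- min(t_hi, t)
      if (t_lo > t_hi) return(NA_real_)
    }
  }
  if (t_lo > t_hi) NA_real_ else t_lo
}

#' @noRd
rect_polygon <- function(xlim, ylim) {
  cbind(c(xlim[1], xlim[2], xlim[2], xlim[1]),
        c(ylim[1], ylim[1], ylim[2], ylim[2]))
}
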