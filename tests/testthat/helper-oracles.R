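# Test fixtures and independent oracles.  Every oracle here deliberately
# takes a different computational route from the package implementation:
# trapezoidal quadrature instead of segment closed forms, eigen(cov())
# instead of prcomp, dense ray sampling instead of closed-form angles,
# rasterized cone membership instead of polygon clipping.

circle_outline <- function(r = 1, n = 720, center = c(0, 0), phase = 0) {
  th <- phase + 2 * pi * (0:(n - 1)) / n
  outline(cbind(center[1] + r * cos(th), center[2] + r * sin(th)), "circle")
}

ellipse_outline <- function(a = 3, b = 1, n = 720) {
  th <- 2 * pi * (0:(n - 1)) / n
  outline(cbind(a * cos(th), b * sin(th)), "ellipse")
}

square_outline <- function(side = 1) {
  outline(side * cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), "square")
}

# random smooth radial blob, deterministic under seed
blob_outline <- function(seed, n = 600, n_modes = 6) {
  withr::with_seed(seed, {
    amp <- stats::rnorm(n_modes, 0, 0.06 / seq_len(n_modes))
    pha <- stats::runif(n_modes, 0, 2 * pi)
  })
  th <- 2 * pi * (0:(n - 1)) / n
  r <- 1 + Reduce(`+`, lapply(seq_len(n_modes), function(k) {
    amp[k] * cos(k * th + pha[k])
  }))
  outline(cbind(r * cos(th), r * sin(th)), paste0("blob", seed))
}

# Trapezoidal quadrature of the defining Fourier integrals on the
# piecewise-linear contour, on a dense arc-length grid.
efa_oracle <- function(out, N, K = 20000) {
  pts <- out$points
  m <- nrow(pts)
  closed <- rbind(pts, pts[1, ])
  dt <- sqrt(rowSums(diff(closed)^2))
  tk <- c(0, cumsum(dt))
  Tt <- tk[m + 1]
  s <- seq(0, Tt, length.out = K + 1)
  x <- stats::approx(tk, closed[, 1], xout = s)$y
  y <- stats::approx(tk, closed[, 2], xout = s)$y
  h <- Tt / K
  trap <- function(f) h * (sum(f) - (f[1] + f[K + 1]) / 2)
  a <- b <- cc <- d <- numeric(N)
  for (n in seq_len(N)) {
    cn <- cos(2 * pi * n * s / Tt)
    sn <- sin(2 * pi * n * s / Tt)
    a[n] <- 2 / Tt * trap(x * cn)
    b[n] <- 2 / Tt * trap(x * sn)
    cc[n] <- 2 / Tt * trap(y * cn)
    d[n] <- 2 / Tt * trap(y * sn)
  }
  list(a0 = trap(x) / Tt, c0 = trap(y) / Tt, a = a, b = b, c = cc, d = d)
}

# mean distance from each point to the nearest segment of a closed polygon
mean_dist_to_polygon <- function(pts, poly) {
  m <- nrow(poly)
  closed <- rbind(poly, poly[1, ])
  mean(vapply(seq_len(nrow(pts)), function(i) {
    min(vapply(seq_len(m), function(j) {
      a <- closed[j, ]
      ab <- closed[j + 1, ] - a
      t <- max(0, min(1, sum((pts[i, ] - a) * ab) / sum(ab^2)))
      sqrt(sum((pts[i, ] - a - t * ab)^2))
    }, numeric(1)))
  }, numeric(1)))
}

# point membership in an infinite cone given apex/central direction/half-angle
in_cone <- function(p, apex, central, half_angle, tol = 0) {
  v <- p - apex
  if (sum(v^2) == 0) return(TRUE)
  ang <- acos(max(-1, min(1, sum(v * central) / sqrt(sum(v^2)))))
  ang <= half_angle + tol
}

# rasterized overlap onset along the +y midline from `origin`
raster_onset <- function(left, right, origin = c(0, 0), y_max = 6,
                         step = 1e-3) {
  ys <- seq(0, y_max, by = step)
  for (y in ys) {
    p <- origin + c(0, y)
    if (in_cone(p, left$apex, left$central_dir, left$half_angle) &&
        in_cone(p, right$apex, right$central_dir, right$half_angle)) {
      return(y)
    }
  }
  NA_real_
}

# fixed suite of shapes for round-trip error measurements
roundtrip_suite <- function() {
  c(list(circle_outline(1, 400), ellipse_outline(3, 1, 400),
         ellipse_outline(1, 2, 400),
         resample_equal_arclength(square_outline(1), 400),
         resample_equal_arclength(square_outline(2.5), 400)),
    lapply(1:5, blob_outline))
}

expect_outline_valid <- function(o) {
  expect_s3_class(o, "outline")
  expect_gte(nrow(o$points), 3)
  expect_gt(outline_area(o), 0)
}
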