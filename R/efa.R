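#' Elliptical Fourier decomposition of a closed outline
#'
#' Computes the elliptical Fourier coefficients of an outline by the exact
#' closed forms for a piecewise-linear contour (Kuhl-Giardina formulation):
#' with segment increments \eqn{\Delta x_p, \Delta y_p}, segment lengths
#' \eqn{\Delta t_p}, cumulative arc length \eqn{t_p} and perimeter \eqn{T},
#' \deqn{a_n = \frac{T}{2 n^2 \pi^2} \sum_p \frac{\Delta x_p}{\Delta t_p}
#'   \left[\cos\frac{2\pi n t_p}{T} - \cos\frac{2\pi n t_{p-1}}{T}\right]}
#' and analogously \eqn{b_n} (sines), \eqn{c_n, d_n} (with \eqn{\Delta y_p}).
#' The DC terms \eqn{a_0, c_0} are the centroid of the arc-length
#' parameterization, computed exactly per segment.
#'
#' @param x an [outline], counterclockwise.
#' @param n_harmonics number of harmonics N; must not exceed the Nyquist
#'   bound `floor(n_points / 2)`.
#' @return An object of class `efa_coeffs`: list with `a0`, `c0`, numeric
#'   vectors `a`, `b`, `c`, `d` of length N, `n_harmonics`, and a
#'   `normalized` flag list (`centered`, `scaled`, `rotation_aligned`).
#' @seealso [efa_reconstruct()], [efa_normalize()], [harmonic_power()]
#' @examples
#' th <- 2 * pi * (0:239) / 240
#' circ <- outline(cbind(2 * cos(th), 2 * sin(th)), "circle")
#' cf <- efa_decompose(circ, 4)
#' round(c(cf$a[1], cf$d[1]), 4)  # ~ (2, 2)
#' @export
efa_decompose <- function(x, n_harmonics) {
  stopifnot(inherits(x, "outline"))
  n_harmonics <- as.integer(n_harmonics)
  if (is.na(n_harmonics) || n_harmonics < 1) {
    stop("n_harmonics must be a positive integer", call. = FALSE)
  }
  pts <- x$points
  m <- nrow(pts)
  if (n_harmonics > floor(m / 2)) {
    stop(sprintf("n_harmonics (%d) exceeds the Nyquist bound floor(%d/2) = %d",
                 n_harmonics, m, floor(m / 2)), call. = FALSE)
  }
  closed <- rbind(pts, pts[1, ])
  dxy <- diff(closed)
  dt <- sqrt(rowSums(dxy^2))
  t <- cumsum(dt)
  T <- t[m]
  t0 <- c(0, t[-m])
  n <- seq_len(n_harmonics)
  # phase matrices: m x N
  ph1 <- outer(t, n) * (2 * pi / T)
  ph0 <- outer(t0, n) * (2 * pi / T)
  dcos <- cos(ph1) - cos(ph0)
  dsin <- sin(ph1) - sin(ph0)
  vx <- dxy[, 1] / dt
  vy <- dxy[, 2] / dt
  const <- T / (2 * pi^2 * n^2)
  a <- const * colSums(vx * dcos)
  b <- const * colSums(vx * dsin)
  cc <- const * colSums(vy * dcos)
  d <- const * colSums(vy * dsin)
  # exact arc-length centroid of the piecewise-linear contour
  a0 <- sum(dt * (closed[1:m, 1] + closed[2:(m + 1), 1]) / 2) / T
  c0 <- sum(dt * (closed[1:m, 2] + closed[2:(m + 1), 2]) / 2) / T
  structure(
    list(a0 = a0, c0 = c0, a = a, b = b, c = cc, d = d,
         n_harmonics = n_harmonics,
         normalized = list(centered = FALSE, scaled = FALSE,
                           rotation_aligned = FALSE),
         specimen_id = x$specimen_id),
    class = "efa_coeffs"
  )
}

#' @export
print.efa_coeffs <- function(x, ...) {
  flags <- paste(names(x$normalized)[unlist(x$normalized)], collapse = ",")
  cat(sprintf("<efa_coeffs> %s: %d harmonics%s\n",
              x$specimen_id %||% "?", x$n_harmonics,
              if (nzchar(flags)) paste0(" [", flags, "]") else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build an `efa_coeffs` object from raw coefficient values
#'
#' Mostly useful for tests and for reinterpreting principal-component
#' positions as shapes.
#'
#' @param a,b,c,d numeric vectors of equal length (one entry per harmonic).
#' @param a0,c0 DC offsets.
#' @param normalized named list of flags.
#' @param specimen_id optional id.
#' @return An `efa_coeffs` object.
#' @export
efa_coeffs <- function(a, b, c, d, a0 = 0, c0 = 0,
                       normalized = list(centered = FALSE, scaled = FALSE,
                                         rotation_aligned = FALSE),
                       specimen_id = NA_character_) {
  N <- length(a)
  if (N < 1 || length(b) != N || length(c) != N || length(d) != N) {
    stop("a, b, c, d must be equal-length vectors with at least one harmonic",
         call. = FALSE)
  }
  structure(list(a0 = a0, c0 = c0, a = a, b = b, c = c, d = d,
                 n_harmonics = N, normalized = normalized,
                 specimen_id = specimen_id),
            class = "efa_coeffs")
}

#' Reconstruct an outline from elliptical Fourier coefficients
#'
#' Samples the truncated Fourier series at `n_points` equally spaced values
#' of the contour parameter.
#'
#' @param cf an `efa_coeffs` object.
#' @param n_points number of points to sample (>= 3).
#' @return An [outline].
#' @export
efa_reconstruct <- function(cf, n_points = 256) {
  stopifnot(inherits(cf, "efa_coeffs"))
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 3) {
    stop("n_points must be an integer >= 3", call. = FALSE)
  }
  tt <- 2 * pi * (seq_len(n_points) - 1) / n_points
  n <- seq_len(cf$n_harmonics)
  C <- cos(outer(tt, n))
  S <- sin(outer(tt, n))
  xs <- cf$a0 + C %*% cf$a + S %*% cf$b
  ys <- cf$c0 + C %*% cf$c + S %*% cf$d
  outline(cbind(as.numeric(xs), as.numeric(ys)),
          specimen_id = cf$specimen_id %||% "reconstruction",
          group = "extant")
}

# Largest singular value of the first-harmonic 2x2 matrix = length of the
# semi-major axis of the first-harmonic ellipse (the scale functional).
#' @noRd
first_harmonic_scale <- function(cf) {
  M <- matrix(c(cf$a[1], cf$c[1], cf$b[1], cf$d[1]), 2, 2)
  svd(M, nu = 0, nv = 0)$d[1]
}

#' Normalize elliptical Fourier coefficients
#'
#' * `center`: zero the DC terms, removing position.
#' * `scale`: divide all harmonic coefficients by the length of the
#'   first-harmonic ellipse's semi-major axis, removing size.
#' * `align`: standardize start point and rotation via the first-harmonic
#'   ellipse (phase then rotation normalization), removing in-plane rotation
#'   and start-point choice. Off by default: consistently oriented digitized
#'   shapes do not need it.
#'
#' @param cf an `efa_coeffs` object.
#' @param center,scale,align logical flags.
#' @return A normalized `efa_coeffs` object with updated flags.
#' @export
efa_normalize <- function(cf, center = TRUE, scale = TRUE, align = FALSE) {
  stopifnot(inherits(cf, "efa_coeffs"))
  if (center) {
    cf$a0 <- 0
    cf$c0 <- 0
    cf$normalized$centered <- TRUE
  }
  if (scale || align) {
    mag1 <- sqrt(cf$a[1]^2 + cf$b[1]^2 + cf$c[1]^2 + cf$d[1]^2)
    if (mag1 < 1e-12) {
      stop("degenerate coefficients: first harmonic has zero magnitude",
           call. = FALSE)
    }
  }
  if (align) {
    cf <- align_first_harmonic(cf)
    cf$normalized$rotation_aligned <- TRUE
  }
  if (scale) {
    s <- first_harmonic_scale(cf)
    for (f in c("a", "b", "c", "d")) cf[[f]] <- cf[[f]] / s
    cf$normalized$scaled <- TRUE
  }
  cf
}

# Kuhl-Giardina phase + rotation alignment.  The phase angle theta and the
# rotation psi are determined from harmonic 1; the residual pi/2-family
# ambiguity (semi-axis choice, half-period start shift) is resolved
# deterministically: prefer the semi-major axis (largest |a1|), then make the
# first above-tolerance higher-harmonic coefficient positive.
#' @noRd
align_first_harmonic <- function(cf) {
  theta0 <- 0.5 * atan2(2 * (cf$a[1] * cf$b[1] + cf$c[1] * cf$d[1]),
                        cf$a[1]^2 + cf$c[1]^2 - cf$b[1]^2 - cf$d[1]^2)
  apply_phase_rotation <- function(cf, theta) {
    n <- seq_len(cf$n_harmonics)
    cn <- cos(n * theta)
    sn <- sin(n * theta)
    a <- cf$a * cn + cf$b * sn
    b <- -cf$a * sn + cf$b * cn
    cc <- cf$c * cn + cf$d * sn
    d <- -cf$c * sn + cf$d * cn
    psi <- atan2(cc[1], a[1])
    cp <- cos(psi)
    sp <- sin(psi)
    out <- cf
    out$a <- cp * a + sp * cc
    out$c <- -sp * a + cp * cc
    out$b <- cp * b + sp * d
    out$d <- -sp * b + cp * d
    out
  }
  candidates <- lapply(theta0 + (0:3) * (pi / 2), function(th) {
    apply_phase_rotation(cf, th)
  })
  a1 <- vapply(candidates, function(cc) cc$a[1], numeric(1))
  keep <- which(a1 >= max(a1) - 1e-9 * max(abs(a1), 1))
  if (length(keep) > 1) {
    # tie-break on the sign of the first non-negligible trailing coefficient
    score <- vapply(candidates[keep], function(cc) {
      v <- c(cc$d[1], if (cc$n_harmonics > 1)
        as.numeric(rbind(cc$a, cc$b, cc$c, cc$d)[, -1]) else numeric(0))
      i <- which(abs(v) > 1e-9)
      if (length(i) == 0) 1 else sign(v[i[1]])
    }, numeric(1))
    keep <- keep[order(-score)][1]
  } else {
    keep <- keep[1]
  }
  candidates[[keep]]
}

#' Harmonic power profile of a coefficient set
#'
#' The power of harmonic n is \eqn{P_n = (a_n^2+b_n^2+c_n^2+d_n^2)/2}; the DC
#' terms (position) are excluded. The cumulative fraction is used to decide
#' how many harmonics suffice to describe a shape.
#'
#' @param cf an `efa_coeffs` object.
#' @return An object of class `harmonic_power_profile`: list with
#'   `per_harmonic_power` and `cumulative_fraction`.
#' @export
harmonic_power <- function(cf) {
  stopifnot(inherits(cf, "efa_coeffs"))
  P <- (cf$a^2 + cf$b^2 + cf$c^2 + cf$d^2) / 2
  structure(list(per_harmonic_power = P,
                 cumulative_fraction = cumsum(P) / sum(P)),
            class = "harmonic_power_profile")
}

#' Calibrate the number of harmonics for a dataset
#'
#' Decomposes every outline to a high-order reference (the smaller of the
#' set's Nyquist bound and `max(4 * max_harmonics, 32)` harmonics), averages
#' the cumulative power fractions across specimens, and returns the smallest
#' N such that the mean cumulative fraction at N reaches `threshold`. With
#' `mode = "per_specimen"` every specimen individually must reach the
#' threshold.
#'
#' @param set an [outline_set].
#' @param threshold power fraction in (0, 1], e.g. 0.99.
#' @param max_harmonics largest N considered.
#' @param mode `"mean"` (dataset-level, default) or `"per_specimen"`.
#' @return Integer N, with the achieved mean cumulative fractions for
#'   1..max_harmonics attached as attribute `"cumulative"`.
#' @export
calibrate_harmonics <- function(set, threshold = 0.99, max_harmonics = 32,
                                mode = c("mean", "per_specimen")) {
  stopifnot(inherits(set, "outline_set"))
  mode <- match.arg(mode)
  if (!(threshold > 0 && threshold <= 1)) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  max_harmonics <- as.integer(max_harmonics)
  min_pts <- min(vapply(set$outlines, function(o) nrow(o$points), integer(1)))
  n_ref <- min(floor(min_pts / 2), max(4L * max_harmonics, 32L))
  if (n_ref < max_harmonics) {
    stop("outlines have too few points to decompose to max_harmonics",
         call. = FALSE)
  }
  cum <- vapply(set$outlines, function(o) {
    harmonic_power(efa_decompose(o, n_ref))$cumulative_fraction[seq_len(max_harmonics)]
  }, numeric(max_harmonics))
  cum <- matrix(cum, nrow = max_harmonics)
  achieved <- if (mode == "mean") rowMeans(cum) else apply(cum, 1, min)
  hit <- which(achieved >= threshold)
  if (length(hit) == 0) {
    stop(sprintf(
      "calibration failed: cumulative power fraction at max_harmonics = %d is %.6f < threshold %.6f",
      max_harmonics, achieved[max_harmonics], threshold), call. = FALSE)
  }
  structure(hit[1], cumulative = rowMeans(cum))
}

#' Export / import EFA coefficients as CSV
#'
#' Long format with columns `specimen_id, n, a, b, c, d`; normalization flags
#' are recorded in a `# normalized:` comment line and restored on read.
#'
#' @param cfs list of `efa_coeffs` objects (or a single one).
#' @param path CSV path.
#' @return `path` invisibly for write; a list of `efa_coeffs` for read.
#' @export
write_efa_csv <- function(cfs, path) {
  if (inherits(cfs, "efa_coeffs")) cfs <- list(cfs)
  flags <- cfs[[1]]$normalized
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# normalized: centered=%s scaled=%s rotation_aligned=%s",
                     flags$centered, flags$scaled, flags$rotation_aligned), con)
  writeLines("specimen_id,n,a,b,c,d", con)
  for (cf in cfs) {
    writeLines(sprintf("%s,%d,%.17g,%.17g,%.17g,%.17g",
                       cf$specimen_id %||% "?", seq_len(cf$n_harmonics),
                       cf$a, cf$b, cf$c, cf$d), con)
  }
  invisible(path)
}

#' @rdname write_efa_csv
#' @export
read_efa_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  flags <- list(centered = FALSE, scaled = FALSE, rotation_aligned = FALSE)
  if (grepl("^# normalized:", lines[1])) {
    for (f in names(flags)) {
      flags[[f]] <- grepl(paste0(f, "=TRUE"), lines[1])
    }
    lines <- lines[-1]
  }
  d <- utils::read.csv(text = paste(lines, collapse = "\n"),
                       stringsAsFactors = FALSE)
  lapply(split(d, factor(d$specimen_id, levels = unique(d$specimen_id))),
         function(s) {
           s <- s[order(s$n), ]
           efa_coeffs(s$a, s$b, s$c, s$d, normalized = flags,
                      specimen_id = s$specimen_id[1])
         })
}
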