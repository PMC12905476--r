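#' Build the specimen-by-coefficient matrix for a morphospace
#'
#' Decomposes every outline of the set to `n_harmonics`, applies the
#' requested normalizations, and flattens each specimen's coefficients into
#' one row in the fixed column order a1, b1, c1, d1, ..., aN, bN, cN, dN.
#' Row order follows the set (manifest) order.
#'
#' @param set an [outline_set].
#' @param n_harmonics harmonics per specimen.
#' @param center,scale,align normalization flags passed to [efa_normalize()].
#' @return An object of class `coefficient_matrix`: list with `x` (numeric
#'   matrix, specimens x 4N), `ids`, `groups`, `n_harmonics`, `flags`.
#' @export
build_matrix <- function(set, n_harmonics, center = TRUE, scale = TRUE,
                         align = FALSE) {
  stopifnot(inherits(set, "outline_set"))
  rows <- lapply(set$outlines, function(o) {
    cf <- tryCatch(
      efa_normalize(efa_decompose(o, n_harmonics), center = center,
                    scale = scale, align = align),
      error = function(e) {
        stop(sprintf("specimen %s: %s", o$specimen_id, conditionMessage(e)),
             call. = FALSE)
      })
    as.numeric(rbind(cf$a, cf$b, cf$c, cf$d))
  })
  x <- do.call(rbind, rows)
  colnames(x) <- as.vector(t(outer(seq_len(n_harmonics), c("a", "b", "c", "d"),
                                   function(n, l) paste0(l, n))))
  rownames(x) <- unname(outline_ids(set))
  structure(list(x = x, ids = unname(outline_ids(set)),
                 groups = unname(outline_groups(set)),
                 n_harmonics = n_harmonics,
                 flags = list(centered = center, scaled = scale,
                              rotation_aligned = align)),
            class = "coefficient_matrix")
}

#' Principal component analysis of a coefficient matrix
#'
#' Covariance PCA: columns are centered but not rescaled to unit variance
#' (all coefficient columns share units after shape scaling; rescaling would
#' distort the harmonic weighting). The sign of each component is fixed so
#' that its largest-magnitude loading is positive, making results
#' deterministic.
#'
#' @param cm a `coefficient_matrix` (or plain numeric matrix with >= 2 rows).
#' @return An object of class `shape_pca`: list with `eigenvalues`
#'   (nonincreasing), `variance_fraction`, `loadings` (orthonormal columns),
#'   `scores`, `column_means`, `ids`, `groups`.
#' @export
run_pca <- function(cm) {
  if (inherits(cm, "coefficient_matrix")) {
    x <- cm$x
    ids <- cm$ids
    groups <- cm$groups
  } else {
    x <- as.matrix(cm)
    ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
    groups <- rep(NA_character_, nrow(x))
  }
  if (nrow(x) < 2) stop("PCA needs at least 2 specimens", call. = FALSE)
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  loadings <- p$rotation
  scores <- p$x
  for (k in seq_len(ncol(loadings))) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  tot <- sum(ev)
  vf <- if (tot > 0) ev / tot else rep(0, length(ev))
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(ncol(scores)))
  rownames(scores) <- ids
  structure(list(eigenvalues = ev, variance_fraction = vf,
                 loadings = loadings, scores = scores,
                 column_means = p$center, ids = ids, groups = groups),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  k <- min(4, length(x$variance_fraction))
  cat(sprintf("<shape_pca> %d specimens, %d components; variance: %s\n",
              nrow(x$scores), length(x$eigenvalues),
              paste(sprintf("PC%d %.1f%%", seq_len(k),
                            100 * x$variance_fraction[seq_len(k)]),
                    collapse = ", ")))
  invisible(x)
}

#' Number of components needed to exceed a variance threshold
#'
#' @param pca a `shape_pca`.
#' @param threshold variance fraction in (0, 1), e.g. 0.99.
#' @return Smallest k whose cumulative variance fraction strictly exceeds
#'   `threshold`.
#' @export
count_components_for_threshold <- function(pca, threshold = 0.99) {
  stopifnot(inherits(pca, "shape_pca"))
  cum <- cumsum(pca$variance_fraction)
  hit <- which(cum > threshold)
  if (length(hit) == 0) stop("no component set exceeds the threshold (zero variance?)",
                             call. = FALSE)
  hit[1]
}

#' Reconstruct the shape at a morphospace position
#'
#' Interprets `column_means + score * loading` as flattened elliptical
#' Fourier coefficients and inverse-transforms them, e.g. to render the
#' shapes at the extremes of a principal component.
#'
#' @param pca a `shape_pca` built from EFA coefficients.
#' @param component_index which component to move along.
#' @param score position along that component (in score units).
#' @param n_points points in the reconstructed outline.
#' @return An [outline].
#' @export
shape_at_position <- function(pca, component_index = 1, score = 0,
                              n_points = 256) {
  stopifnot(inherits(pca, "shape_pca"))
  if (component_index < 1 || component_index > ncol(pca$loadings)) {
    stop("component_index out of range", call. = FALSE)
  }
  v <- pca$column_means + score * pca$loadings[, component_index]
  if (length(v) %% 4 != 0) {
    stop("coefficient vector length is not a multiple of 4", call. = FALSE)
  }
  m <- matrix(v, nrow = 4)
  cf <- efa_coeffs(m[1, ], m[2, ], m[3, ], m[4, ],
                   specimen_id = sprintf("PC%d@%.3g", component_index, score))
  efa_reconstruct(cf, n_points)
}

#' Convex-hull occupancy of groups in a morphospace plane
#'
#' Computes per-group convex hulls in the plane of two chosen components,
#' their areas, all pairwise hull overlap areas, and per-specimen flags for
#' lying inside each group hull (hull boundary counts as inside) and outside
#' all of them. Groups with fewer than 3 distinct non-collinear points give a
#' degenerate hull (area 0), flagged rather than raised.
#'
#' @param pca a `shape_pca`.
#' @param axes pair of component indices, default `c(1, 2)`.
#' @param groups per-specimen group labels; defaults to those stored in the
#'   PCA.
#' @return An object of class `occupancy_report`: list with `axes`, `hulls`
#'   (per group: `vertices`, `area`, `degenerate`), `overlap` (symmetric
#'   matrix of pairwise intersection areas; diagonal holds group areas),
#'   `inside` (specimen x group logical matrix), `outside_all` (logical:
#'   specimen falls outside every non-degenerate group hull; a degenerate
#'   hull encloses no area and does not count as occupied morphospace).
#' @export
morphospace_occupancy <- function(pca, axes = c(1, 2), groups = NULL) {
  stopifnot(inherits(pca, "shape_pca"))
  if (is.null(groups)) groups <- pca$groups
  pts <- pca$scores[, axes, drop = FALSE]
  glev <- unique(groups)
  hulls <- lapply(glev, function(g) {
    gp <- pts[groups == g, , drop = FALSE]
    gp <- unique(gp)
    if (nrow(gp) >= 3) {
      hull <- convex_hull_ccw(gp)
      area <- abs(signed_area(hull))
      if (area > 1e-12 * max(1, max(abs(gp))^2)) {
        return(list(vertices = hull, area = area, degenerate = FALSE))
      }
    }
    list(vertices = gp[grDevices::chull(gp), , drop = FALSE], area = 0,
         degenerate = TRUE)
  })
  names(hulls) <- glev
  overlap <- matrix(0, length(glev), length(glev), dimnames = list(glev, glev))
  if (length(glev) > 1) {
    for (i in seq_along(glev)[-length(glev)]) {
      for (j in (i + 1):length(glev)) {
        if (!hulls[[i]]$degenerate && !hulls[[j]]$degenerate) {
          ov <- convex_intersection_area(hulls[[i]]$vertices,
                                         hulls[[j]]$vertices)
          overlap[i, j] <- overlap[j, i] <- ov
        }
      }
    }
  }
  diag(overlap) <- vapply(hulls, function(h) h$area, numeric(1))
  inside <- matrix(FALSE, nrow(pts), length(glev),
                   dimnames = list(pca$ids, glev))
  for (g in seq_along(glev)) {
    h <- hulls[[g]]
    for (i in seq_len(nrow(pts))) {
      inside[i, g] <- if (h$degenerate) {
        point_near_chain(pts[i, ], h$vertices,
                         1e-9 * max(1, max(abs(pts))))
      } else {
        point_in_convex(pts[i, ], h$vertices)
      }
    }
  }
  # degenerate hulls enclose no area, so they do not count as occupied
  # regions when asking whether a specimen plots outside all groups
  occupied <- !vapply(hulls, function(h) h$degenerate, logical(1))
  outside_all <- if (any(occupied)) {
    !apply(inside[, occupied, drop = FALSE], 1, any)
  } else {
    rep(TRUE, nrow(pts))
  }
  structure(list(axes = axes, hulls = hulls, overlap = overlap,
                 inside = inside, outside_all = outside_all,
                 groups = groups),
            class = "occupancy_report")
}

#' @export
print.occupancy_report <- function(x, ...) {
  cat("<occupancy_report> axes", paste(x$axes, collapse = "/"), "\n")
  for (g in names(x$hulls)) {
    cat(sprintf("  %s: area %.4g%s\n", g, x$hulls[[g]]$area,
                if (x$hulls[[g]]$degenerate) " (degenerate)" else ""))
  }
  out <- sum(x$outside_all)
  cat(sprintf("  specimens outside all hulls: %d\n", out))
  invisible(x)
}

#' Export PCA scores as CSV
#'
#' Writes `specimen_id`, the first `k` component scores, and `group`.
#'
#' @param pca a `shape_pca`.
#' @param path output CSV path.
#' @param k number of components to write (default all).
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(pca, path, k = ncol(pca$scores)) {
  d <- data.frame(specimen_id = pca$ids,
                  pca$scores[, seq_len(k), drop = FALSE],
                  group = pca$groups, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
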