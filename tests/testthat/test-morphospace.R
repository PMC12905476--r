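make_test_set <- function(n = 6, seed = 1) {
  outline_set(lapply(seq_len(n), function(i) {
    o <- blob_outline(seed * 100 + i, n = 300)
    o$specimen_id <- sprintf("b%02d", i)
    o$group <- if (i <= n / 2) "extant" else "fossil"
    o
  }))
}

test_that("coefficient matrix has the documented layout", {
  set <- outline_set(lapply(1:3, function(i) {
    o <- ellipse_outline(1 + i, 1, 300)
    o$specimen_id <- paste0("e", i)
    o
  }))
  cm <- build_matrix(set, 2)
  expect_equal(dim(cm$x), c(3, 8))
  expect_equal(colnames(cm$x), c("a1", "b1", "c1", "d1", "a2", "b2", "c2", "d2"))
  expect_equal(rownames(cm$x), c("e1", "e2", "e3"))

  identical_set <- outline_set(lapply(1:3, function(i) {
    o <- blob_outline(5)
    o$specimen_id <- paste0("s", i)
    o
  }))
  m2 <- build_matrix(identical_set, 4)$x
  expect_equal(m2[1, ], m2[2, ])
  expect_equal(m2[2, ], m2[3, ])
})

test_that("matrix construction is deterministic and names degenerate specimens", {
  spec <- population_spec(n_extant = 3, n_fossil = 3, outliers = list(),
                          seed = 11)
  m1 <- build_matrix(gen_population(spec, 200), 8)$x
  m2 <- build_matrix(gen_population(spec, 200), 8)$x
  expect_identical(m1, m2)
})

test_that("PCA matches an independent covariance eigendecomposition", {
  for (seed in c(2, 3)) {
    x <- withr::with_seed(seed, matrix(stats::rnorm(160), 20, 8))
    p <- run_pca(x)
    e <- eigen(stats::cov(x), symmetric = TRUE)
    expect_equal(p$eigenvalues[1:8], e$values, tolerance = 1e-9)
    expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-12)
    # trace conservation
    expect_equal(sum(p$eigenvalues), sum(diag(stats::cov(x))),
                 tolerance = 1e-10)
    # scores reproduce the centered data projection
    cx <- sweep(x, 2, colMeans(x))
    expect_equal(unname(p$scores), unname(cx %*% p$loadings),
                 tolerance = 1e-9)
    # orthonormal loadings, diagonal score covariance
    expect_equal(crossprod(p$loadings), diag(8), tolerance = 1e-8,
                 ignore_attr = TRUE)
    sc <- stats::cov(p$scores)
    expect_lt(max(abs(sc - diag(diag(sc)))), 1e-8)
    # deterministic sign: largest loading entry positive
    for (k in 1:8) expect_gt(max(p$loadings[, k]), 0)
  }
})

test_that("degenerate PCA inputs behave as documented", {
  same <- matrix(1, 5, 4)
  p <- run_pca(same)
  expect_true(all(p$eigenvalues < 1e-28))
  expect_error(run_pca(matrix(1, 1, 4)), "at least 2")

  sym <- rbind(c(1, 2), c(-1, -2))
  p2 <- run_pca(sym)
  expect_equal(p2$variance_fraction, c(1, 0), tolerance = 1e-12)
})

test_that("component counting scans the cumulative variance", {
  fake <- structure(list(variance_fraction = c(0.6, 0.3, 0.1)),
                    class = "shape_pca")
  expect_equal(count_components_for_threshold(fake, 0.85), 2)
  expect_equal(count_components_for_threshold(
    structure(list(variance_fraction = 1), class = "shape_pca"), 0.99), 1)

  set <- make_test_set(8)
  p <- run_pca(build_matrix(set, 6))
  k <- count_components_for_threshold(p, 0.9)
  expect_equal(k, which(cumsum(p$variance_fraction) > 0.9)[1])
})

test_that("shapes rendered at morphospace positions vary as the scores do", {
  # population varying (almost) only in head width
  outs <- lapply(1:8, function(i) {
    gen_head_outline(head_shape_params(head_width_ratio = 0.8 + 0.15 * i),
                     250, specimen_id = paste0("w", i))
  })
  p <- run_pca(build_matrix(outline_set(outs), 10))
  mean_shape <- shape_at_position(p, 1, 0)
  v <- p$column_means
  m <- matrix(v, nrow = 4)
  direct <- efa_reconstruct(efa_coeffs(m[1, ], m[2, ], m[3, ], m[4, ]), 256)
  expect_equal(mean_shape$points, direct$points, tolerance = 1e-12)

  sd1 <- stats::sd(p$scores[, 1])
  widths <- vapply(c(-2, 0, 2) * sd1, function(s) {
    pts <- shape_at_position(p, 1, s, 256)$points
    diff(range(pts[, 1])) / diff(range(pts[, 2]))
  }, numeric(1))
  expect_true(all(diff(widths) > 0) || all(diff(widths) < 0))

  expect_identical(shape_at_position(p, 1, 1.5)$points,
                   shape_at_position(p, 1, 1.5)$points)
  expect_error(shape_at_position(p, 99, 0), "out of range")
})

test_that("hull occupancy handles overlap, degeneracy and outliers", {
  # two unit squares offset by 0.5: overlap area 0.5 exactly
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  scores <- rbind(sq, sweep(sq, 2, c(0.5, 0), "+"), c(5, 0.5))
  fake <- structure(list(
    scores = cbind(PC1 = scores[, 1], PC2 = scores[, 2]),
    ids = sprintf("s%d", 1:9),
    groups = c(rep("extant", 4), rep("fossil", 4), "new")),
    class = "shape_pca")
  occ <- morphospace_occupancy(fake)
  expect_equal(occ$hulls$extant$area, 1)
  expect_equal(occ$overlap["extant", "fossil"], 0.5, tolerance = 1e-12)
  expect_equal(occ$overlap["fossil", "extant"], occ$overlap["extant", "fossil"])
  expect_lte(occ$overlap["extant", "fossil"],
             min(occ$hulls$extant$area, occ$hulls$fossil$area))
  # outlier at (5, 0.5) outside both; oracle: explicit half-plane test
  in_square <- function(p, lo) all(p >= lo) && all(p <= lo + 1)
  expect_false(in_square(c(5, 0.5), c(0, 0)))
  expect_true(occ$outside_all[["s9"]])
  expect_false(any(occ$outside_all[1:8]))
  # boundary counts as inside: shared corner point of both squares
  expect_true(occ$inside["s2", "fossil"])  # (1,0) on fossil hull boundary

  collinear <- structure(list(
    scores = cbind(PC1 = c(0, 1, 2), PC2 = c(0, 1, 2)),
    ids = c("a", "b", "c"), groups = rep("fossil", 3)),
    class = "shape_pca")
  occ2 <- morphospace_occupancy(collinear)
  expect_true(occ2$hulls$fossil$degenerate)
  expect_equal(occ2$hulls$fossil$area, 0)
})

test_that("well-separated latent clusters split cleanly along PC1", {
  outs <- list()
  for (i in 1:6) {
    outs[[i]] <- gen_head_outline(
      head_shape_params(stylet_length_ratio = 1.0 + 0.01 * i), 250,
      specimen_id = paste0("a", i), group = "extant")
  }
  for (i in 1:6) {
    outs[[6 + i]] <- gen_head_outline(
      head_shape_params(stylet_length_ratio = 1.6 + 0.01 * i), 250,
      specimen_id = paste0("b", i), group = "fossil")
  }
  p <- run_pca(build_matrix(outline_set(outs), 10))
  s1 <- p$scores[1:6, 1]
  s2 <- p$scores[7:12, 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
})

test_that("scores CSV export carries ids, components and groups", {
  set <- make_test_set(6)
  p <- run_pca(build_matrix(set, 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_scores_csv(p, path, k = 3)
  d <- utils::read.csv(path)
  expect_equal(names(d), c("specimen_id", "PC1", "PC2", "PC3", "group"))
  expect_equal(nrow(d), 6)
  expect_equal(d$PC1, unname(p$scores[, 1]), tolerance = 1e-12)
})
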