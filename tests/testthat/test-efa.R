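test_that("dense circle decomposition matches the analytic first harmonic", {
  cf <- efa_decompose(circle_outline(2, 720), 8)
  expect_equal(cf$a[1], 2, tolerance = 1e-3)
  expect_equal(cf$d[1], 2, tolerance = 1e-3)
  expect_lt(abs(cf$b[1]) + abs(cf$c[1]), 1e-3)
  pw <- harmonic_power(cf)$per_harmonic_power
  expect_lt(sum(pw[-1]), 1e-6)
  expect_equal(cf$a0, 0, tolerance = 1e-9)
  expect_equal(cf$c0, 0, tolerance = 1e-9)
})

test_that("closed-form coefficients match trapezoidal integration oracles", {
  shapes <- list(circle_outline(2, 500), ellipse_outline(3, 1, 500),
                 resample_equal_arclength(square_outline(), 400),
                 blob_outline(11))
  for (sh in shapes) {
    got <- efa_decompose(sh, 10)
    want <- efa_oracle(sh, 10)
    ref <- max(abs(unlist(want[c("a", "b", "c", "d")])))
    for (f in c("a", "b", "c", "d")) {
      expect_lt(max(abs(got[[f]] - want[[f]])) / ref, 1e-4)
    }
    expect_lt(abs(got$a0 - want$a0) / max(1, abs(want$a0)), 1e-4)
  }
})

test_that("translation moves only the DC terms", {
  o <- blob_outline(7)
  cf0 <- efa_decompose(o, 8)
  o2 <- o
  o2$points <- sweep(o$points, 2, c(-10, 5), "+")
  cf1 <- efa_decompose(o2, 8)
  for (f in c("a", "b", "c", "d")) {
    expect_equal(cf1[[f]], cf0[[f]], tolerance = 1e-12)
  }
  expect_equal(cf1$a0 - cf0$a0, -10, tolerance = 1e-9)
  expect_equal(cf1$c0 - cf0$c0, 5, tolerance = 1e-9)
})

test_that("scaling coordinates scales every harmonic coefficient", {
  o <- blob_outline(8)
  cf0 <- efa_decompose(o, 8)
  o2 <- o
  o2$points <- 3.5 * o$points
  cf1 <- efa_decompose(o2, 8)
  for (f in c("a", "b", "c", "d")) {
    expect_equal(cf1[[f]], 3.5 * cf0[[f]], tolerance = 1e-10)
  }
})

test_that("the Nyquist bound and n_points floor are enforced", {
  sq <- square_outline()
  expect_error(efa_decompose(sq, 3), "Nyquist")
  expect_silent(efa_decompose(sq, 2))
  cf <- efa_decompose(circle_outline(1, 100), 4)
  expect_error(efa_reconstruct(cf, 2), ">= 3")
  expect_error(efa_coeffs(numeric(0), numeric(0), numeric(0), numeric(0)),
               "at least one harmonic")
})

test_that("a single-harmonic unit coefficient set reconstructs a circle", {
  cf <- efa_coeffs(1, 0, 0, 1)
  o <- efa_reconstruct(cf, 128)
  expect_true(all(abs(sqrt(rowSums(o$points^2)) - 1) < 1e-9))
})

test_that("square round trip at high harmonic count is tight", {
  sq <- resample_equal_arclength(square_outline(), 256)
  rec <- efa_reconstruct(efa_decompose(sq, 64), 256)
  expect_lt(mean_dist_to_polygon(rec$points, square_outline()$points), 0.01)
})

test_that("total coefficient power equals reconstructed signal power", {
  # Parseval: mean squared centered signal over the period = sum of P_n
  for (sh in list(blob_outline(9),
                  resample_equal_arclength(square_outline(), 200))) {
    cf <- efa_decompose(sh, 12)
    P <- sum(harmonic_power(cf)$per_harmonic_power)
    M <- 4 * cf$n_harmonics  # above Nyquist for the truncated series
    rec <- efa_reconstruct(cf, M)
    sig <- mean((rec$points[, 1] - cf$a0)^2 + (rec$points[, 2] - cf$c0)^2)
    expect_equal(sig, P, tolerance = 1e-6)
  }
})

test_that("centering and scaling normalize a circle to the unit harmonic", {
  cf <- efa_normalize(efa_decompose(circle_outline(5, 720, center = c(2, -1)), 6),
                      center = TRUE, scale = TRUE)
  expect_equal(cf$a0, 0)
  expect_equal(cf$c0, 0)
  expect_equal(cf$a[1], 1, tolerance = 1e-4)
  expect_equal(cf$d[1], 1, tolerance = 1e-4)
  expect_lt(abs(cf$b[1]) + abs(cf$c[1]), 1e-4)
  expect_true(cf$normalized$centered && cf$normalized$scaled)
})

test_that("normalization is idempotent", {
  cf <- efa_normalize(efa_decompose(blob_outline(12), 8), TRUE, TRUE, TRUE)
  again <- efa_normalize(cf, TRUE, TRUE, TRUE)
  for (f in c("a0", "c0", "a", "b", "c", "d")) {
    expect_equal(again[[f]], cf[[f]], tolerance = 1e-9)
  }
})

test_that("alignment removes in-plane rotation", {
  base <- ellipse_outline(3, 1, 720)
  # make the shape asymmetric so start/rotation are uniquely recoverable
  pts <- base$points
  pts[, 1] <- pts[, 1] + 0.4 * pts[, 2]^2
  o <- outline(pts, "bent")
  ref <- efa_normalize(efa_decompose(o, 8), TRUE, TRUE, TRUE)
  for (ang in c(37, 118, -64) * pi / 180) {
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    rot <- outline(o$points %*% t(R), "rot")
    cf <- efa_normalize(efa_decompose(rot, 8), TRUE, TRUE, TRUE)
    for (f in c("a", "b", "c", "d")) {
      expect_equal(cf[[f]], ref[[f]], tolerance = 1e-6)
    }
  }
})

test_that("degenerate first harmonic is rejected when scaling", {
  cf <- efa_coeffs(c(0, 1), c(0, 0), c(0, 0), c(0, 1))
  expect_error(efa_normalize(cf, scale = TRUE), "degenerate")
})

test_that("harmonic power profile arithmetic", {
  cf <- efa_coeffs(a = c(2, 0), b = c(0, 1), c = c(0, 1), d = c(2, 0))
  hp <- harmonic_power(cf)
  expect_equal(hp$per_harmonic_power, c(4, 1))
  expect_equal(hp$cumulative_fraction, c(0.8, 1.0))

  one <- harmonic_power(efa_coeffs(1, 0, 0, 1))
  expect_equal(one$per_harmonic_power, 1)
  expect_equal(one$cumulative_fraction, 1.0)

  ell <- harmonic_power(efa_decompose(ellipse_outline(3, 1, 720), 20))
  expect_gt(ell$cumulative_fraction[1], 0.98)
  expect_equal(ell$cumulative_fraction[20], 1, tolerance = 1e-12)
})

test_that("harmonic calibration matches a brute-force scan", {
  # near-circular ellipses: harmonic 1 alone carries > 99% of the power
  ellipses <- outline_set(lapply(1:4, function(i) {
    o <- ellipse_outline(1 + 0.1 * i, 1, 400)
    o$specimen_id <- paste0("e", i)
    o
  }))
  expect_equal(as.integer(calibrate_harmonics(ellipses, 0.99, 16)), 1L)

  sq <- outline_set(list(resample_equal_arclength(square_outline(), 400)))
  n_cal <- calibrate_harmonics(sq, 0.99, 32)
  # oracle: exhaustive scan of the square's own high-order power profile
  cum <- harmonic_power(efa_decompose(sq$outlines[[1]],
                                      max(4 * 32, 32)))$cumulative_fraction
  expect_equal(as.integer(n_cal), which(cum[1:32] >= 0.99)[1])

  noisy <- blob_outline(20, n = 800, n_modes = 6)
  noisy$points <- withr::with_seed(1, noisy$points +
                                     matrix(stats::rnorm(1600, 0, 0.004), ncol = 2))
  star <- outline_set(list(noisy))
  achieved <- harmonic_power(efa_decompose(noisy, 32))  # sanity: power beyond 5
  expect_error(calibrate_harmonics(star, 1.0, 5), "calibration failed")
})

test_that("coefficient CSV export round-trips values and flags", {
  cfs <- lapply(1:3, function(i) {
    cf <- efa_normalize(efa_decompose(blob_outline(i), 6), TRUE, TRUE, FALSE)
    cf$specimen_id <- paste0("s", i)
    cf
  })
  p <- withr::local_tempfile(fileext = ".csv")
  write_efa_csv(cfs, p)
  back <- read_efa_csv(p)
  expect_equal(length(back), 3)
  expect_equal(back$s2$a, cfs[[2]]$a, tolerance = 1e-15)
  expect_true(back$s1$normalized$centered)
  expect_true(back$s1$normalized$scaled)
  expect_false(back$s1$normalized$rotation_aligned)
})
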