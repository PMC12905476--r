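std_eye <- function(...) {
  eye_geometry(lens_center = c(0, 0), lens_normal = c(0, 1),
               lens_aperture = 0.2, retina_depth = 0.4, retina_extent = 0.2,
               ...)
}

test_that("Snell external angle: closed form, identities, saturation", {
  expect_equal(snell_external_angle(0, 1.4), 0)
  expect_equal(snell_external_angle(pi / 6, 1), pi / 6)
  expect_equal(snell_external_angle(pi / 6, 1.4), asin(0.7))
  expect_equal(snell_external_angle(pi / 6, 1.4) * 180 / pi, 44.427,
               tolerance = 1e-4)
  # saturates at grazing beyond the critical angle
  expect_equal(snell_external_angle(1.2, 1.4), pi / 2)
  expect_error(snell_external_angle(-0.1, 1.4), "nonnegative")
  expect_error(snell_external_angle(pi / 2, 1.4), "below pi/2")
})

test_that("external half-angle is nondecreasing in the refractive index", {
  th <- 25 * pi / 180
  ns <- seq(1, 2, by = 0.05)
  ext <- vapply(ns, function(n) snell_external_angle(th, n), numeric(1))
  expect_true(all(diff(ext) >= 0))
  expect_equal(ext[1], th)
})

test_that("geometric half-angle matches the closed form and ray sampling", {
  vf <- eye_field_of_view(std_eye(), "geometric")
  expect_equal(vf$half_angle, atan(0.2 / 0.4), tolerance = 1e-12)
  expect_equal(vf$apex, c(0, -0.2), tolerance = 1e-12)

  # oracle: densely sample (retina point, aperture point) ray directions and
  # take the extreme angle relative to the lens normal
  max_ang <- max(vapply(seq(-0.1, 0.1, length.out = 201), function(rx) {
    max(vapply(seq(-0.1, 0.1, length.out = 201), function(ax) {
      d <- c(ax, 0) - c(rx, -0.4)
      abs(atan2(d[1], d[2]))
    }, numeric(1)))
  }, numeric(1)))
  expect_lt(abs(vf$half_angle - max_ang) * 180 / pi, 0.1)
})

test_that("refractive mode widens the field per Snell and is identity at n=1", {
  geo <- eye_field_of_view(std_eye(), "geometric")
  ref <- eye_field_of_view(std_eye(), "refractive")
  expect_equal(ref$half_angle, asin(1.4 * sin(geo$half_angle)),
               tolerance = 1e-12)
  expect_equal(ref$half_angle * 180 / pi, 38.76, tolerance = 1e-3)
  expect_gt(ref$half_angle, geo$half_angle)

  n1 <- eye_field_of_view(std_eye(refractive_index = 1), "refractive")
  expect_equal(n1$half_angle, geo$half_angle, tolerance = 1e-12)
  expect_equal(n1$boundary_rays, geo$boundary_rays, tolerance = 1e-12)
})

test_that("boundary rays are symmetric at zero tilt and asymmetric otherwise", {
  vf <- eye_field_of_view(std_eye(), "geometric")
  expect_equal(vf$boundary_rays[1, 1], -vf$boundary_rays[2, 1],
               tolerance = 1e-12)
  expect_equal(vf$boundary_rays[1, 2], vf$boundary_rays[2, 2],
               tolerance = 1e-12)
  expect_equal(vf$central_dir, c(0, 1), tolerance = 1e-12)

  tilted <- eye_field_of_view(std_eye(tilt = 0.3), "geometric")
  expect_gt(abs(tilted$central_dir[1]), 1e-3)

  expect_error(eye_geometry(c(0, 0), c(0, 1), 0.2, 0, 0.2), "positive")
})

test_that("narrow limiting-ray convention gives a smaller field", {
  # same-side edge pairing: half-angle atan(((a - e)/2) / d)
  eye2 <- eye_geometry(c(0, 0), c(0, 1), 0.4, 0.4, 0.2)
  wide <- eye_field_of_view(eye2, "geometric", convention = "wide")
  narrow <- eye_field_of_view(eye2, "geometric", convention = "narrow")
  expect_lt(narrow$half_angle, wide$half_angle)
  expect_equal(narrow$half_angle, atan(((0.4 - 0.2) / 2) / 0.4),
               tolerance = 1e-9)
  expect_equal(wide$half_angle, atan(((0.4 + 0.2) / 2) / 0.4),
               tolerance = 1e-9)
})

test_that("binocular overlap onset matches the closed form and rasterized oracle", {
  ha <- atan(0.5)
  l <- view_field(c(-0.5, 0), c(0, 1), ha)
  r <- view_field(c(0.5, 0), c(0, 1), ha)
  win <- rect_window(c(-5, 5), c(-1, 9))
  bin <- binocular_overlap(l, r, win, origin = c(0, 0))
  expect_equal(bin$onset_distance, 1.0, tolerance = 1e-6)
  oracle <- raster_onset(l, r, c(0, 0))
  expect_lt(abs(bin$onset_distance - oracle), 0.01)

  # region is contained in each monocular field polygon
  for (vf in list(l, r)) {
    mono <- field_polygon(vf, win)
    inter <- convex_intersection_area <- abs(
      stemmorph:::convex_intersection_area(bin$region, mono))
    expect_lt(abs(inter - bin$area), 1e-9 * max(1, bin$area))
  }

  # mirror symmetry of the region about the midline
  mirrored <- cbind(-bin$region[, 1], bin$region[, 2])
  d <- max(vapply(seq_len(nrow(bin$region)), function(i) {
    min(sqrt(rowSums(sweep(mirrored, 2, bin$region[i, ])^2)))
  }, numeric(1)))
  expect_lt(d, 1e-6)
})

test_that("degenerate binocular configurations behave as documented", {
  f <- view_field(c(0, 0), c(0, 1), pi / 6)
  win <- rect_window(c(-4, 4), c(-4, 4))
  self <- binocular_overlap(f, f, win)
  mono <- field_polygon(f, win)
  expect_equal(self$area, abs(stemmorph:::signed_area(mono)),
               tolerance = 1e-9)

  away_l <- view_field(c(-0.5, 0), c(-1, 0), pi / 6)
  away_r <- view_field(c(0.5, 0), c(1, 0), pi / 6)
  none <- binocular_overlap(away_l, away_r, win)
  expect_equal(none$area, 0)
  expect_identical(none$relation_to_stylets, "none")
  expect_true(is.na(none$onset_distance))
})

test_that("stylet zone is the expected circular sector", {
  lay <- gen_layout("flat_short")
  lay$stylet_span_angle <- pi
  lay$stylet_length <- 1
  z <- stylet_zone(lay)
  expect_equal(abs(stemmorph:::signed_area(z)), pi / 2,
               tolerance = 0.005 * pi / 2)

  lay$stylet_span_angle <- pi / 3
  lay$stylet_length <- 3
  z2 <- stylet_zone(lay)
  expect_equal(abs(stemmorph:::signed_area(z2)), 9 * pi / 6,
               tolerance = 0.005 * 9 * pi / 6)
  expect_identical(stylet_zone(lay), z2)
})

test_that("overlap classification against the stylet zone", {
  lay <- gen_layout("flat_short")  # stylet reach 1.5 from (0, 0)
  zone <- stylet_zone(lay)
  win <- rect_window(c(-5, 5), c(-1.5, 8.5))
  mk_bin <- function(onset_y) {
    ha <- pi / 8
    l <- view_field(c(-onset_y * tan(ha), 0), c(0, 1), ha)
    r <- view_field(c(onset_y * tan(ha), 0), c(0, 1), ha)
    binocular_overlap(l, r, win, origin = c(0, 0))
  }
  near <- mk_bin(0.5)
  expect_equal(near$onset_distance, 0.5, tolerance = 1e-6)
  cls <- classify_overlap(near, zone)
  expect_identical(cls$relation, "between_stylets")
  expect_gt(cls$area, 0)

  far <- mk_bin(3.0)
  cls2 <- classify_overlap(far, zone)
  expect_identical(cls2$relation, "beyond_stylets")
  expect_equal(cls2$area, 0)

  empty <- binocular_overlap(view_field(c(-1, 0), c(-1, 0), pi / 8),
                             view_field(c(1, 0), c(1, 0), pi / 8), win)
  expect_identical(classify_overlap(empty, zone)$relation, "none")
})

test_that("scenario evaluation reproduces the qualitative orderings", {
  rep <- evaluate_scenarios(gen_layout("flat_short"))
  get <- function(sc, mode, col) rep[rep$scenario == sc & rep$mode == mode, col]

  expect_true(get("flat_short", "refractive", "feasible"))
  expect_identical(get("flat_short", "refractive", "relation"),
                   "between_stylets")
  expect_identical(get("tapering_long", "geometric", "relation"),
                   "beyond_stylets")
  expect_identical(get("tapering_long", "refractive", "relation"),
                   "between_stylets")
  expect_false(get("long_clipped", "geometric", "feasible"))
  expect_true(get("tilted", "geometric", "relation") %in%
                c("none", "beyond_stylets"))
  expect_true(get("tilted", "refractive", "relation") %in%
                c("none", "beyond_stylets"))
  expect_error(evaluate_scenarios(gen_layout("flat_short"), "bogus"),
               "unknown scenario")
})

test_that("refraction pulls the tapering-long overlap closer than geometric", {
  rep <- evaluate_scenarios(gen_layout("tapering_long"),
                            scenarios = "tapering_long")
  on_geo <- rep$onset_distance[rep$mode == "geometric"]
  on_ref <- rep$onset_distance[rep$mode == "refractive"]
  expect_lt(on_ref, on_geo)
  expect_gt(on_geo, 1.5)  # beyond the stylet reach
  expect_lt(on_ref, 1.5)  # within it
})

test_that("mirror-symmetric layouts give a mirror-symmetric binocular region", {
  lay <- gen_layout("flat_short")
  lf <- eye_field_of_view(lay$left_eye, "refractive")
  rf <- eye_field_of_view(lay$right_eye, "refractive")
  win <- rect_window(c(-5, 5), c(-6, 4))
  bin <- binocular_overlap(lf, rf, win, origin = lay$anterior_point)
  expect_gt(bin$area, 0)
  mirrored <- cbind(-bin$region[, 1], bin$region[, 2])
  d <- max(vapply(seq_len(nrow(bin$region)), function(i) {
    min(sqrt(rowSums(sweep(mirrored, 2, bin$region[i, ])^2)))
  }, numeric(1)))
  expect_lt(d, 1e-6 * diff(range(lay$head_polygon[, 1])))
})

test_that("widening the retina never shrinks the binocular region", {
  lay <- gen_layout("flat_short")
  win <- rect_window(c(-5, 5), c(-6, 4))
  extents <- withr::with_seed(42, sort(stats::runif(8, 0.1, 0.45)))
  areas <- vapply(extents, function(e) {
    mk <- function(eye) {
      eye_geometry(eye$lens_center, eye$lens_normal, eye$lens_aperture,
                   eye$retina_depth, e, eye$refractive_index)
    }
    bin <- binocular_overlap(eye_field_of_view(mk(lay$left_eye)),
                             eye_field_of_view(mk(lay$right_eye)), win)
    bin$area
  }, numeric(1))
  expect_true(all(diff(areas) >= -1e-9))
})

test_that("layout JSON round-trips", {
  lay <- gen_layout("tilted", head_scale = 2.5)
  p <- withr::local_tempfile(fileext = ".json")
  write_layout_json(lay, p)
  back <- read_layout_json(p)
  expect_equal(back$left_eye$tilt, lay$left_eye$tilt, tolerance = 1e-12)
  expect_equal(back$head_polygon, lay$head_polygon, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$stylet_length, lay$stylet_length)
  expect_equal(back$eyes_feasible, lay$eyes_feasible)
})
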