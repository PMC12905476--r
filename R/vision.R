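#' Geometry of one flat-lensed stemma in the dorsal plane
#'
#' The model is two-dimensional, drawn in the dorsal plane of the head. A
#' stemma is a flat lens segment of width `lens_aperture` centered at
#' `lens_center` and oriented perpendicular to the outward viewing direction
#' `lens_normal`, with a retina segment of width `retina_extent` lying
#' `retina_depth` behind the lens. `tilt` rotates the eye's inner axis (lens
#' center to retina center, with the retina kept perpendicular to that axis)
#' away from the lens normal; 0 means the retina sits squarely behind the
#' lens. A positive tilt swings the retina counterclockwise, so the field of
#' view swings clockwise. The refractive index applies at the single flat
#' air-lens interface; the lens is treated as optically continuous with the
#' eye interior (a flat lens has no further dioptric apparatus).
#'
#' @param lens_center numeric length-2 point.
#' @param lens_normal outward viewing direction (normalized internally).
#' @param lens_aperture flat-lens width (> 0).
#' @param retina_depth distance from lens plane to retina (> 0).
#' @param retina_extent retina width (> 0).
#' @param refractive_index n >= 1 (1 = no refraction).
#' @param tilt retina-axis angle relative to `-lens_normal`, radians.
#' @return An object of class `eye_geometry`.
#' @export
eye_geometry <- function(lens_center, lens_normal, lens_aperture,
                         retina_depth, retina_extent,
                         refractive_index = 1.4, tilt = 0) {
  lens_center <- as.numeric(lens_center)
  stopifnot(length(lens_center) == 2)
  lens_normal <- unit_vec(as.numeric(lens_normal))
  if (lens_aperture <= 0 || retina_depth <= 0 || retina_extent <= 0) {
    stop("lens_aperture, retina_depth and retina_extent must be positive",
         call. = FALSE)
  }
  if (refractive_index < 1) stop("refractive index must be >= 1", call. = FALSE)
  structure(list(lens_center = lens_center, lens_normal = lens_normal,
                 lens_aperture = lens_aperture, retina_depth = retina_depth,
                 retina_extent = retina_extent,
                 refractive_index = refractive_index, tilt = tilt),
            class = "eye_geometry")
}

# Key points of an eye: aperture edges A- (clockwise side) / A+ and retina
# edges R- / R+, with +t = counterclockwise tangent of the lens plane.
#' @noRd
eye_points <- function(eye) {
  n <- eye$lens_normal
  tang <- c(-n[2], n[1])  # ccw: rotate normal by +90 deg
  ap <- eye$lens_aperture / 2
  Rt <- rot2(eye$tilt)
  axis <- as.numeric(Rt %*% (-n))
  rdir <- as.numeric(Rt %*% tang)
  rc <- eye$lens_center + eye$retina_depth * axis
  list(A_minus = eye$lens_center - ap * tang,
       A_plus = eye$lens_center + ap * tang,
       R_minus = rc - (eye$retina_extent / 2) * rdir,
       R_plus = rc + (eye$retina_extent / 2) * rdir,
       tangent = tang, retina_center = rc)
}

#' External (air-side) angle at a flat interface by Snell's law
#'
#' For a ray traveling at `theta_internal` from the interface normal inside a
#' medium of refractive index `n`, returns the air-side angle
#' `asin(min(1, n * sin(theta_internal)))`; beyond the critical angle the
#' result saturates at pi/2 (grazing emergence).
#'
#' @param theta_internal internal angle(s) from the normal, radians, in
#'   `[0, pi/2)`.
#' @param n refractive index (>= 1).
#' @return External angle(s), radians.
#' @examples
#' snell_external_angle(pi / 6, 1.4) * 180 / pi  # ~ 44.43 degrees
#' @export
snell_external_angle <- function(theta_internal, n) {
  if (any(theta_internal < 0)) {
    stop("theta_internal must be nonnegative", call. = FALSE)
  }
  if (any(theta_internal >= pi / 2)) {
    stop("theta_internal must be below pi/2", call. = FALSE)
  }
  if (n < 1) stop("refractive index must be >= 1", call. = FALSE)
  asin(pmin(1, n * sin(theta_internal)))
}

#' Planar field of view of one stemma
#'
#' Limiting rays are drawn from each retina edge through the *opposite*
#' aperture edge (wide-acceptance convention, the default: any retina point
#' can receive light through any aperture point, appropriate for a short eye
#' with a large opening angle); `convention = "narrow"` uses same-side edges
#' instead. In `geometric` mode the rays leave the lens unchanged; in
#' `refractive` mode each internal boundary angle is mapped through
#' [snell_external_angle()] at the flat lens interface, widening the field.
#' A tilted retina gives asymmetric boundary rays.
#'
#' @param eye an [eye_geometry].
#' @param mode `"geometric"` or `"refractive"`.
#' @param convention `"wide"` (default) or `"narrow"` limiting-ray pairing.
#' @return An object of class `view_field`: list with `apex` (intersection
#'   of the boundary lines, the virtual cone apex), `boundary_rays` (2 x 2
#'   matrix, unit direction per row: clockwise then counterclockwise bound),
#'   `half_angle`, `central_dir`, `mode`.
#' @export
eye_field_of_view <- function(eye, mode = c("geometric", "refractive"),
                              convention = c("wide", "narrow")) {
  stopifnot(inherits(eye, "eye_geometry"))
  mode <- match.arg(mode)
  convention <- match.arg(convention)
  pp <- eye_points(eye)
  n <- eye$lens_normal
  if (convention == "wide") {
    u_minus <- unit_vec(pp$A_minus - pp$R_plus)   # clockwise-side bound
    u_plus <- unit_vec(pp$A_plus - pp$R_minus)    # counterclockwise-side bound
  } else {
    u_minus <- unit_vec(pp$A_minus - pp$R_minus)
    u_plus <- unit_vec(pp$A_plus - pp$R_plus)
  }
  th_minus <- signed_angle_from(n, u_minus)  # negative (clockwise of normal)
  th_plus <- signed_angle_from(n, u_plus)
  if (max(abs(c(th_minus, th_plus))) >= pi / 2) {
    stop("degenerate eye geometry: internal boundary ray at or beyond 90 degrees",
         call. = FALSE)
  }
  if (mode == "refractive") {
    th_minus <- sign(th_minus) * snell_external_angle(abs(th_minus),
                                                      eye$refractive_index)
    th_plus <- sign(th_plus) * snell_external_angle(abs(th_plus),
                                                    eye$refractive_index)
  }
  u_minus <- as.numeric(rot2(th_minus) %*% n)
  u_plus <- as.numeric(rot2(th_plus) %*% n)
  apex <- line_intersection(pp$A_minus, u_minus, pp$A_plus, u_plus)
  half_angle <- (th_plus - th_minus) / 2
  central <- as.numeric(rot2((th_plus + th_minus) / 2) %*% n)
  br <- rbind(u_minus, u_plus)
  dimnames(br) <- NULL
  view_field(apex = apex, central_dir = central, half_angle = half_angle,
             boundary_rays = br, mode = mode)
}

# Intersection of two lines given as (point, direction); if near-parallel
# the apex is placed at the midpoint of the two anchor points.
#' @noRd
line_intersection <- function(p1, d1, p2, d2) {
  det <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(det) < 1e-12) return((p1 + p2) / 2)
  t <- ((p2[1] - p1[1]) * d2[2] - (p2[2] - p1[2]) * d2[1]) / det
  p1 + t * d1
}

#' Construct a planar view field directly
#'
#' @param apex cone apex (point).
#' @param central_dir central viewing direction.
#' @param half_angle cone half-angle, radians, in (0, pi/2].
#' @param boundary_rays optional 2 x 2 matrix of boundary directions; derived
#'   from `central_dir` and `half_angle` when omitted.
#' @param mode label (`"geometric"` or `"refractive"`).
#' @return A `view_field` object.
#' @export
view_field <- function(apex, central_dir, half_angle, boundary_rays = NULL,
                       mode = "geometric") {
  central_dir <- unit_vec(as.numeric(central_dir))
  if (!(half_angle > 0 && half_angle <= pi / 2)) {
    stop("half_angle must lie in (0, pi/2]", call. = FALSE)
  }
  if (is.null(boundary_rays)) {
    boundary_rays <- rbind(as.numeric(rot2(-half_angle) %*% central_dir),
                           as.numeric(rot2(half_angle) %*% central_dir))
  }
  structure(list(apex = as.numeric(apex), central_dir = central_dir,
                 half_angle = half_angle, boundary_rays = boundary_rays,
                 mode = mode),
            class = "view_field")
}

#' @export
print.view_field <- function(x, ...) {
  cat(sprintf("<view_field> apex (%.3g, %.3g), half-angle %.2f deg (%s)\n",
              x$apex[1], x$apex[2], x$half_angle * 180 / pi, x$mode))
  invisible(x)
}

#' Polygon of a view field clipped to a window
#'
#' The angular sector from the apex between the two boundary rays, clipped
#' to the rectangular window. Far-arc chord points are inserted so the
#' clipped polygon stays convex and covers the full angular extent.
#'
#' @param vf a `view_field`.
#' @param window 4 x 2 ccw rectangle (see [rect_polygon()]) or a convex ccw
#'   polygon matrix.
#' @return Vertex matrix (possibly empty).
#' @export
field_polygon <- function(vf, window) {
  stopifnot(inherits(vf, "view_field"))
  span <- 2 * max(abs(window)) + sqrt(sum(vf$apex^2))
  R <- 4 * span
  a_minus <- signed_angle_from(c(1, 0), vf$boundary_rays[1, ])
  a_plus <- a_minus + 2 * vf$half_angle
  angs <- seq(a_minus, a_plus, length.out = max(3, ceiling(2 * vf$half_angle /
                                                             (pi / 12)) + 1))
  far <- cbind(vf$apex[1] + R * cos(angs), vf$apex[2] + R * sin(angs))
  poly <- rbind(vf$apex, far)
  clip_polygon_convex(poly, window)
}

#' Rectangular clipping window
#'
#' @param xlim,ylim numeric length-2 ranges.
#' @return 4 x 2 ccw vertex matrix.
#' @export
rect_window <- function(xlim, ylim) rect_polygon(xlim, ylim)

#' Binocular overlap of two monocular fields
#'
#' Intersects the two field polygons inside the window. The overlap onset is
#' the distance from `origin` (by default the midpoint between the two field
#' apexes; in a head context, the anterior head margin on the midline) to the
#' nearest overlap point along the `midline` direction; `NA` if the region
#' is empty or the midline ray misses it.
#'
#' @param left,right `view_field` objects.
#' @param window convex ccw clipping polygon (see [rect_window()]).
#' @param origin reference point for the onset distance.
#' @param midline unit direction of the forward midline (default +y).
#' @return An object of class `binocular_field`: list with `region` (vertex
#'   matrix, possibly empty), `area`, `onset_distance`, `origin`, `midline`,
#'   and `relation_to_stylets` (`"none"` when empty, otherwise `NA` until
#'   [classify_overlap()] is applied).
#' @export
binocular_overlap <- function(left, right, window, origin = NULL,
                              midline = c(0, 1)) {
  stopifnot(inherits(left, "view_field"), inherits(right, "view_field"))
  midline <- unit_vec(as.numeric(midline))
  if (is.null(origin)) origin <- (left$apex + right$apex) / 2
  pl <- field_polygon(left, window)
  pr <- field_polygon(right, window)
  region <- if (nrow(pl) >= 3 && nrow(pr) >= 3) {
    clip_polygon_convex(pl, pr)
  } else {
    matrix(numeric(0), 0, 2)
  }
  area <- if (nrow(region) >= 3) abs(signed_area(region)) else 0
  if (area <= 1e-12 * max(1, max(abs(window))^2)) {
    region <- matrix(numeric(0), 0, 2)
    area <- 0
  }
  onset <- NA_real_
  if (nrow(region) >= 3) {
    onset <- ray_convex_entry(origin, midline, region)
  }
  structure(list(region = region, area = area, onset_distance = onset,
                 origin = origin, midline = midline,
                 relation_to_stylets = if (area == 0) "none" else NA_character_),
            class = "binocular_field")
}

#' @export
print.binocular_field <- function(x, ...) {
  if (x$area == 0) {
    cat("<binocular_field> empty (no stereoscopic region)\n")
  } else {
    cat(sprintf("<binocular_field> area %.4g, onset %.4g, relation %s\n",
                x$area, x$onset_distance, x$relation_to_stylets))
  }
  invisible(x)
}

#' Head layout: two eyes, head capsule, stylets
#'
#' @param left_eye,right_eye [eye_geometry] objects.
#' @param head_polygon ccw vertex matrix of the head capsule in dorsal view
#'   (anterior toward +y).
#' @param stylet_length reach of the stylets from their base midpoint.
#' @param stylet_base_points 2 x 2 matrix: left and right stylet base.
#' @param stylet_span_angle angular width of the open-stylet capture zone,
#'   radians (<= pi so the zone polygon is convex).
#' @param head_length anterior-posterior head capsule length (scale for
#'   windows and symmetry tolerances).
#' @param symmetric declare the layout mirror-symmetric about x = 0.
#' @return An object of class `head_layout`. `eyes_feasible` records whether
#'   both eye bodies (aperture and retina edges) lie within the head capsule;
#'   a layout violating this is constructible on purpose (e.g. an eye too
#'   long for the head) and is flagged rather than rejected.
#' @export
head_layout <- function(left_eye, right_eye, head_polygon, stylet_length,
                        stylet_base_points, stylet_span_angle,
                        head_length = NULL, symmetric = TRUE) {
  stopifnot(inherits(left_eye, "eye_geometry"),
            inherits(right_eye, "eye_geometry"))
  head_polygon <- as.matrix(head_polygon)
  if (signed_area(head_polygon) < 0) {
    head_polygon <- head_polygon[rev(seq_len(nrow(head_polygon))), ]
  }
  if (stylet_length <= 0) stop("stylet_length must be positive", call. = FALSE)
  if (!(stylet_span_angle > 0 && stylet_span_angle <= pi)) {
    stop("stylet_span_angle must be in (0, pi]", call. = FALSE)
  }
  if (is.null(head_length)) {
    head_length <- diff(range(head_polygon[, 2]))
  }
  anterior_y <- max(head_polygon[, 2])
  structure(list(left_eye = left_eye, right_eye = right_eye,
                 head_polygon = head_polygon, stylet_length = stylet_length,
                 stylet_base_points = as.matrix(stylet_base_points),
                 stylet_span_angle = stylet_span_angle,
                 head_length = head_length,
                 anterior_point = c(0, anterior_y),
                 symmetric = symmetric,
                 eyes_feasible = eye_in_head(left_eye, head_polygon) &&
                   eye_in_head(right_eye, head_polygon)),
            class = "head_layout")
}

# An eye "fits" if its four body corners (aperture and retina edges) lie in
# or on the head capsule polygon.
#' @noRd
eye_in_head <- function(eye, head_polygon) {
  pp <- eye_points(eye)
  corners <- rbind(pp$A_minus, pp$A_plus, pp$R_minus, pp$R_plus)
  tol <- 1e-7
  all(apply(corners, 1, point_in_polygon, poly = head_polygon, tol = tol))
}

#' Prey-capture zone spanned by the open stylets
#'
#' A circular sector of radius `stylet_length` and angular width
#' `stylet_span_angle`, centered on the forward midline, with its apex midway
#' between the stylet bases. The arc is discretized at 256 segments.
#'
#' @param layout a [head_layout].
#' @param arc_segments arc resolution (default 256).
#' @return ccw vertex matrix of the sector polygon.
#' @export
stylet_zone <- function(layout, arc_segments = 256) {
  stopifnot(inherits(layout, "head_layout"))
  apex <- colMeans(layout$stylet_base_points)
  half <- layout$stylet_span_angle / 2
  angs <- seq(pi / 2 - half, pi / 2 + half, length.out = arc_segments + 1)
  arc <- cbind(apex[1] + layout$stylet_length * cos(angs),
               apex[2] + layout$stylet_length * sin(angs))
  rbind(apex, arc)  # ccw: from the clockwise edge of the span to the ccw edge
}

#' Classify the binocular region against the stylet capture zone
#'
#' @param bin a `binocular_field`.
#' @param zone convex ccw polygon from [stylet_zone()].
#' @return List with `relation` (`"none"` if the binocular region is empty,
#'   `"between_stylets"` if it intersects the zone with positive area,
#'   `"beyond_stylets"` if nonempty but disjoint from the zone) and `area`
#'   (the intersection area).
#' @export
classify_overlap <- function(bin, zone) {
  stopifnot(inherits(bin, "binocular_field"))
  if (bin$area == 0) {
    return(list(relation = "none", area = 0))
  }
  inter <- convex_intersection_area(bin$region, as.matrix(zone))
  tol <- 1e-9 * max(1, max(abs(zone))^2)
  if (inter > tol) {
    list(relation = "between_stylets", area = inter)
  } else {
    list(relation = "beyond_stylets", area = 0)
  }
}

# Scenario table: eye dimensions in units of head length, mirroring the four
# alternative reconstructions (short flat baseline; long tapering eye; long
# eye protruding beyond the capsule; tilted inner axis).
#' @noRd
scenario_params <- function() {
  list(
    flat_short = list(depth = 0.35, aperture = 0.30, extent = 0.30, tilt = 0),
    tapering_long = list(depth = 0.90, aperture = 0.30, extent = 0.24, tilt = 0),
    long_clipped = list(depth = 1.30, aperture = 0.30, extent = 0.30, tilt = 0),
    tilted = list(depth = 0.90, aperture = 0.30, extent = 0.24,
                  tilt = 25 * pi / 180)
  )
}

# Replace the eyes of a layout with a scenario variant of the baseline eye.
# Tilt swings each retina toward the midline, so the fields toe outward.
#' @noRd
apply_scenario <- function(layout, scenario) {
  sp <- scenario_params()[[scenario]]
  if (is.null(sp)) {
    stop("unknown scenario '", scenario, "'; known: ",
         paste(names(scenario_params()), collapse = ", "), call. = FALSE)
  }
  L <- layout$head_length
  mk <- function(eye, side) {
    eye_geometry(lens_center = eye$lens_center,
                 lens_normal = eye$lens_normal,
                 lens_aperture = sp$aperture * L,
                 retina_depth = sp$depth * L,
                 retina_extent = sp$extent * L,
                 refractive_index = eye$refractive_index,
                 tilt = side * sp$tilt)
  }
  # retina swings toward the midline on both sides, so both fields toe outward
  layout$left_eye <- mk(layout$left_eye, +1)
  layout$right_eye <- mk(layout$right_eye, -1)
  layout$eyes_feasible <- eye_in_head(layout$left_eye, layout$head_polygon) &&
    eye_in_head(layout$right_eye, layout$head_polygon)
  layout
}

#' Evaluate alternative eye-geometry scenarios for a head layout
#'
#' For each named scenario (a retina depth/extent/tilt variant of the
#' baseline eye, see Details) and each optical mode, reconstructs both
#' monocular fields, their binocular overlap, its relation to the stylet
#' capture zone, and whether the eye bodies fit inside the head capsule.
#'
#' Scenarios: `flat_short` (short eye squarely behind a flat lens, the
#' baseline), `tapering_long` (longer eye that tapers strongly posteriorly),
#' `long_clipped` (longer untapered eye that protrudes beyond the head
#' capsule, expected infeasible), `tilted` (inner eye axis not perpendicular
#' to the lens, fields toeing outward).
#'
#' @param layout a [head_layout]; its eye positions/normals and stylets are
#'   kept, eye dimensions are set per scenario.
#' @param scenarios character vector of scenario names.
#' @param modes optical modes to evaluate.
#' @param window clipping window; default a square of 10 head lengths
#'   centered on the head.
#' @return An object of class `scenario_report`: data.frame with one row per
#'   scenario x mode (`scenario`, `mode`, `feasible`, `half_angle_deg`,
#'   `onset_distance`, `relation`, `overlap_area`, `zone_overlap_area`), with
#'   the full per-row objects in attribute `"details"`.
#' @export
evaluate_scenarios <- function(layout,
                               scenarios = names(scenario_params()),
                               modes = c("geometric", "refractive"),
                               window = NULL) {
  stopifnot(inherits(layout, "head_layout"))
  L <- layout$head_length
  if (is.null(window)) {
    cx <- mean(range(layout$head_polygon[, 1]))
    cy <- mean(range(layout$head_polygon[, 2]))
    window <- rect_window(cx + c(-5, 5) * L, cy + c(-5, 5) * L)
  }
  zone <- stylet_zone(layout)
  rows <- list()
  details <- list()
  for (sc in scenarios) {
    lay <- apply_scenario(layout, sc)
    for (mode in modes) {
      lf <- eye_field_of_view(lay$left_eye, mode)
      rf <- eye_field_of_view(lay$right_eye, mode)
      bin <- binocular_overlap(lf, rf, window,
                               origin = lay$anterior_point)
      cls <- classify_overlap(bin, zone)
      bin$relation_to_stylets <- cls$relation
      key <- paste(sc, mode, sep = ".")
      rows[[key]] <- data.frame(
        scenario = sc, mode = mode, feasible = lay$eyes_feasible,
        half_angle_deg = lf$half_angle * 180 / pi,
        onset_distance = bin$onset_distance,
        relation = cls$relation, overlap_area = bin$area,
        zone_overlap_area = cls$area, stringsAsFactors = FALSE)
      details[[key]] <- list(layout = lay, left = lf, right = rf,
                             binocular = bin)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "details") <- details
  class(out) <- c("scenario_report", class(out))
  out
}

#' @export
print.scenario_report <- function(x, ...) {
  print.data.frame(x, digits = 4)
  invisible(x)
}
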