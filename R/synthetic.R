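#' Parameters of a synthetic larval head outline
#'
#' Describes a head-capsule-plus-stylets silhouette in dorsal view: a
#' rounded rectangular capsule (anterior margin at y = 0, posterior at
#' y = -1, so head length is 1 and all other lengths are ratios to it), two
#' forward-projecting tapering stylets with inward curvature and optional
#' inner-margin teeth, optional anterolateral eye-protrusion bulges on the
#' anterior margin, and smooth bump noise along the outline normal.
#'
#' @param head_width_ratio capsule width / length (the new wide-headed
#'   morphotype is near 2).
#' @param stylet_length_ratio stylet length / head length (about 1.5 in the
#'   wide-headed larva).
#' @param stylet_curvature dimensionless inward deflection of the stylet
#'   tips (0 = straight blades).
#' @param tooth_size tooth height as a fraction of the proximal stylet
#'   width (0 = no teeth); two teeth sit at about 1/3 and 2/3 of the stylet.
#' @param eye_protrusion height of the anterolateral eye bulges as a
#'   fraction of the head half-width (0 = none).
#' @param noise_sd standard deviation of smooth outline perturbations, in
#'   head-length units.
#' @param seed integer seed making the outline deterministic.
#' @return A validated list of class `head_shape_params`.
#' @export
head_shape_params <- function(head_width_ratio = 1.2,
                              stylet_length_ratio = 1.3,
                              stylet_curvature = 0.35,
                              tooth_size = 0.3,
                              eye_protrusion = 0.12,
                              noise_sd = 0,
                              seed = 1L) {
  p <- list(head_width_ratio = head_width_ratio,
            stylet_length_ratio = stylet_length_ratio,
            stylet_curvature = stylet_curvature,
            tooth_size = tooth_size,
            eye_protrusion = eye_protrusion,
            noise_sd = noise_sd, seed = as.integer(seed))
  if (head_width_ratio <= 0 || stylet_length_ratio <= 0) {
    stop("head_width_ratio and stylet_length_ratio must be positive",
         call. = FALSE)
  }
  if (stylet_curvature < 0 || tooth_size < 0 || eye_protrusion < 0 ||
      noise_sd < 0) {
    stop("stylet_curvature, tooth_size, eye_protrusion and noise_sd must be nonnegative",
         call. = FALSE)
  }
  structure(p, class = "head_shape_params")
}

# Remove exact consecutive duplicates at piece junctions.
#' @noRd
drop_consecutive_dups <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(pts)
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 0)
  pts[keep, , drop = FALSE]
}

#' Generate a synthetic head outline
#'
#' Builds the right half of the silhouette from parametric pieces (anterior
#' margin, stylet inner/outer edges with teeth, eye bulge, lateral margin,
#' rounded posterior corner, posterior margin), mirrors it for an exactly
#' symmetric left half, orients the loop counterclockwise, resamples to
#' equal arc length, and finally adds seeded smooth Gaussian-bump noise
#' along the outward normal. Deterministic for fixed parameters and seed.
#'
#' @param params a [head_shape_params].
#' @param n_points points in the returned outline.
#' @param specimen_id,group,taxon_label metadata for the [outline].
#' @return An [outline] (single closed ccw loop).
#' @export
gen_head_outline <- function(params, n_points = 300, specimen_id = "synthetic",
                             group = "extant", taxon_label = NA_character_) {
  stopifnot(inherits(params, "head_shape_params"))
  hw <- params$head_width_ratio / 2
  S <- params$stylet_length_ratio
  bx <- 0.35 * hw          # stylet base center
  sw <- 0.10 * hw          # stylet proximal half-width
  rc <- 0.15 * min(1, hw)  # posterior corner radius
  cx_e <- 0.75 * hw        # eye-bulge center on the anterior margin
  sig_e <- 0.12 * hw
  he <- params$eye_protrusion * hw

  cl_x <- function(u) bx - 0.5 * params$stylet_curvature * S * u^2
  wid <- function(u) sw * (1 - 0.85 * u)
  tooth <- function(u) {
    if (params$tooth_size == 0) return(0 * u)
    amp <- params$tooth_size * 2 * sw
    amp * (exp(-0.5 * ((u - 0.38) / 0.04)^2) +
             exp(-0.5 * ((u - 0.64) / 0.04)^2))
  }

  u_up <- seq(0, 1, length.out = 90)
  pieces <- list(
    # anterior margin, midline to inner stylet base
    cbind(seq(0, bx - sw, length.out = 10), 0),
    # stylet inner edge (teeth protrude toward the midline)
    cbind(cl_x(u_up) - wid(u_up) - tooth(u_up), S * u_up),
    # tip
    cbind(cl_x(1), S + wid(1)),
    # stylet outer edge, tip to base
    cbind(cl_x(rev(u_up)) + wid(rev(u_up)), S * rev(u_up)),
    # anterior margin with eye bulge, outer stylet base to lateral corner
    {
      xs <- seq(bx + sw, hw, length.out = 45)
      cbind(xs, he * exp(-0.5 * ((xs - cx_e) / sig_e)^2))
    },
    # lateral margin
    cbind(hw, seq(-0.02, -1 + rc, length.out = 30)),
    # rounded posterior corner
    {
      phi <- seq(0, -pi / 2, length.out = 25)
      cbind(hw - rc + rc * cos(phi), -1 + rc + rc * sin(phi))
    },
    # posterior margin back to the midline
    cbind(seq(hw - rc, 0, length.out = 40), -1)
  )
  right <- drop_consecutive_dups(do.call(rbind, pieces))
  # exact mirror for the left half, reversed, endpoints on the axis not doubled
  inner <- right[-c(1, nrow(right)), , drop = FALSE]
  left <- cbind(-inner[, 1], inner[, 2])[rev(seq_len(nrow(inner))), ,
                                         drop = FALSE]
  loop <- drop_consecutive_dups(rbind(right, left))
  out <- outline(loop, specimen_id = specimen_id, group = group,
                 taxon_label = taxon_label)
  out <- normalize_orientation(out)
  out <- resample_equal_arclength(out, n_points)
  if (params$noise_sd > 0) {
    out$points <- withr::with_seed(params$seed,
                                   add_bump_noise(out$points, params$noise_sd))
  }
  out
}

# Smooth, circularly wrapped Gaussian-bump perturbation along the outward
# normal of a ccw loop.
#' @noRd
add_bump_noise <- function(pts, noise_sd, n_bumps = 8) {
  n <- nrow(pts)
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))[seq_len(n)]
  total <- sum(seg)
  centers <- stats::runif(n_bumps, 0, total)
  widths <- stats::runif(n_bumps, 0.02, 0.06) * total
  amps <- stats::rnorm(n_bumps, 0, noise_sd)
  disp <- numeric(n)
  for (k in seq_len(n_bumps)) {
    d <- abs(s - centers[k])
    d <- pmin(d, total - d)  # circular distance
    disp <- disp + amps[k] * exp(-0.5 * (d / widths[k])^2)
  }
  prev <- pts[c(n, 1:(n - 1)), , drop = FALSE]
  nxt <- pts[c(2:n, 1), , drop = FALSE]
  tang <- nxt - prev
  tang <- tang / sqrt(rowSums(tang^2))
  outward <- cbind(tang[, 2], -tang[, 1])  # for ccw loops
  pts + disp * outward
}

#' Population specification for synthetic outline sets
#'
#' Encodes the structure of the comparative dataset: a tight cluster of
#' extant larvae, a more dispersed fossil group (about three times the
#' relative parameter spread), and explicit outlier morphotypes appended
#' with group `"new"` — by default one wide-headed larva whose eye
#' protrusion lies 4 fossil standard deviations above the fossil mean.
#'
#' @param n_extant,n_fossil group sizes.
#' @param extant_rel_sd,fossil_rel_sd relative (coefficient-of-variation)
#'   spread of the shape parameters within each group.
#' @param outliers list of [head_shape_params] appended with group `"new"`,
#'   or `"default"` for the single wide-headed outlier.
#' @param mean_params group-mean shape parameters (a [head_shape_params]).
#' @param seed master seed; specimen i uses the derived seed
#'   `(seed * 7919 + i) mod (2^31 - 1)`.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(n_extant = 20, n_fossil = 20,
                            extant_rel_sd = 0.04, fossil_rel_sd = 0.12,
                            outliers = "default",
                            mean_params = head_shape_params(),
                            seed = 1L) {
  stopifnot(n_extant >= 0, n_fossil >= 0, extant_rel_sd >= 0,
            fossil_rel_sd >= 0)
  if (identical(outliers, "default")) {
    pro_sd <- fossil_rel_sd * mean_params$eye_protrusion
    outliers <- list(head_shape_params(
      head_width_ratio = 1.9,
      stylet_length_ratio = 1.5,
      stylet_curvature = mean_params$stylet_curvature,
      tooth_size = mean_params$tooth_size,
      eye_protrusion = mean_params$eye_protrusion + 4 * pro_sd,
      noise_sd = mean_params$noise_sd))
  }
  structure(list(n_extant = n_extant, n_fossil = n_fossil,
                 extant_rel_sd = extant_rel_sd, fossil_rel_sd = fossil_rel_sd,
                 outliers = outliers, mean_params = mean_params,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' @noRd
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i) %% 2147483647)
}

# Truncated-gaussian parameter draw: resample until inside physical bounds
# (clamped after 50 tries, which is essentially unreachable at these sds).
#' @noRd
rnorm_trunc <- function(mean, sd, lo, hi) {
  for (i in 1:50) {
    v <- stats::rnorm(1, mean, sd)
    if (v >= lo && v <= hi) return(v)
  }
  min(max(mean, lo), hi)
}

#' Generate a synthetic outline population
#'
#' Samples per-specimen shape parameters from truncated gaussians around the
#' group means (bounds: width ratio 0.4-3, stylet ratio 0.5-2.5, curvature
#' 0-1, tooth 0-0.8, protrusion 0-0.5) and builds one outline per specimen.
#' Extant specimens come first, then fossils, then outliers (group `"new"`).
#'
#' @param spec a [population_spec].
#' @param n_points points per outline.
#' @return An [outline_set].
#' @export
gen_population <- function(spec, n_points = 300) {
  stopifnot(inherits(spec, "population_spec"))
  mp <- spec$mean_params
  bounds <- list(head_width_ratio = c(0.4, 3),
                 stylet_length_ratio = c(0.5, 2.5),
                 stylet_curvature = c(0, 1),
                 tooth_size = c(0, 0.8),
                 eye_protrusion = c(0, 0.5))
  draw_params <- function(rel_sd, seed) {
    withr::with_seed(seed, {
      vals <- lapply(names(bounds), function(nm) {
        rnorm_trunc(mp[[nm]], rel_sd * mp[[nm]], bounds[[nm]][1],
                    bounds[[nm]][2])
      })
      names(vals) <- names(bounds)
      do.call(head_shape_params,
              c(vals, list(noise_sd = mp$noise_sd, seed = seed)))
    })
  }
  outs <- list()
  i <- 0L
  for (g in c("extant", "fossil")) {
    ng <- if (g == "extant") spec$n_extant else spec$n_fossil
    rel_sd <- if (g == "extant") spec$extant_rel_sd else spec$fossil_rel_sd
    for (k in seq_len(ng)) {
      i <- i + 1L
      p <- draw_params(rel_sd, child_seed(spec$seed, i))
      outs[[i]] <- gen_head_outline(p, n_points,
                                    specimen_id = sprintf("%s_%02d", g, k),
                                    group = g)
    }
  }
  for (k in seq_along(spec$outliers)) {
    i <- i + 1L
    p <- spec$outliers[[k]]
    p$seed <- child_seed(spec$seed, i)
    outs[[i]] <- gen_head_outline(p, n_points,
                                  specimen_id = sprintf("new_%02d", k),
                                  group = "new")
  }
  outline_set(outs, provenance = sprintf("gen_population(seed=%d)", spec$seed))
}

#' Generate a synthetic measurement table
#'
#' Head lengths are log-uniform over `head_range`; lens diameters follow
#' `lens = 10^(intercept + slope * log10(head) + eps)` with
#' `eps ~ N(0, sigma^2)`. Outlier records (appended last, ids
#' `outlier_<k>`) receive an additional log10 offset, emulating specimens
#' with disproportionately large eyes.
#'
#' @param n number of regular records (>= 3).
#' @param slope,intercept power-law parameters on log10 axes.
#' @param sigma residual standard deviation in log10 units.
#' @param outliers data.frame with columns `offset` (log10 units) and
#'   `group`, one row per outlier; or `NULL`.
#' @param head_range range of head lengths (same length units as diameters).
#' @param group group label for the regular records.
#' @param seed integer seed.
#' @return data.frame with columns `specimen_id`, `head_length`,
#'   `lens_diameter`, `group`.
#' @export
gen_measurements <- function(n = 50, slope = 0.8, intercept = -1,
                             sigma = 0.05, outliers = NULL,
                             head_range = c(0.3, 10), group = "extant",
                             seed = 1L) {
  stopifnot(n >= 3, sigma >= 0, all(head_range > 0))
  n_out <- if (is.null(outliers)) 0L else nrow(outliers)
  withr::with_seed(as.integer(seed), {
    lh <- stats::runif(n + n_out, log10(head_range[1]), log10(head_range[2]))
    eps <- stats::rnorm(n + n_out, 0, sigma)
  })
  offset <- c(rep(0, n), if (n_out) outliers$offset)
  ll <- intercept + slope * lh + eps + offset
  data.frame(
    specimen_id = c(sprintf("spec_%03d", seq_len(n)),
                    if (n_out) sprintf("outlier_%d", seq_len(n_out))),
    head_length = 10^lh,
    lens_diameter = 10^ll,
    group = c(rep(group, n), if (n_out) as.character(outliers$group)),
    stringsAsFactors = FALSE)
}

#' Generate a two-eye head layout for a vision scenario
#'
#' Builds the dorsal-plane layout used in the field-of-view reconstructions:
#' a head capsule twice as wide as long, forward-facing flat-lensed eyes on
#' the anterolateral corners (lens centers at x = +/-0.7 head lengths),
#' stylet bases at x = +/-0.3 with reach 1.5 head lengths and a 60 degree
#' capture span, and eye dimensions set by the named scenario (see
#' [evaluate_scenarios()]). All presets are mirror-symmetric.
#'
#' @param preset one of `"flat_short"`, `"tapering_long"`, `"long_clipped"`,
#'   `"tilted"`.
#' @param head_scale head length in absolute units (default 1).
#' @param refractive_index lens refractive index for refractive-mode fields.
#' @return A [head_layout].
#' @export
gen_layout <- function(preset = "flat_short", head_scale = 1,
                       refractive_index = 1.4) {
  if (!preset %in% names(scenario_params())) {
    stop("unknown preset '", preset, "'; known: ",
         paste(names(scenario_params()), collapse = ", "), call. = FALSE)
  }
  L <- head_scale
  head_poly <- rect_polygon(c(-1, 1) * L, c(-1, 0) * L)
  base_eye <- function(side) {
    eye_geometry(lens_center = c(side * 0.7 * L, 0),
                 lens_normal = c(0, 1),
                 lens_aperture = 0.3 * L, retina_depth = 0.35 * L,
                 retina_extent = 0.3 * L,
                 refractive_index = refractive_index)
  }
  layout <- head_layout(left_eye = base_eye(-1), right_eye = base_eye(1),
                        head_polygon = head_poly,
                        stylet_length = 1.5 * L,
                        stylet_base_points = rbind(c(-0.3 * L, 0),
                                                   c(0.3 * L, 0)),
                        stylet_span_angle = 60 * pi / 180,
                        head_length = L, symmetric = TRUE)
  apply_scenario(layout, preset)
}

#' Write inputs for a full synthetic analysis to disk
#'
#' Materializes everything the pipeline reads: per-specimen outline CSVs
#' plus a manifest, a measurement table with three implanted above-trend
#' outliers, and a layout JSON — all derived from one master seed.
#'
#' @param outdir output directory (created if needed).
#' @param seed master seed.
#' @param spec optional [population_spec]; default uses `seed`.
#' @return Invisibly, a list of the written file paths.
#' @export
simulate_inputs <- function(outdir, seed = 1L, spec = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(spec)) spec <- population_spec(seed = seed)
  set <- gen_population(spec)
  odir <- file.path(outdir, "outlines")
  dir.create(odir, showWarnings = FALSE)
  files <- character(length(set))
  for (i in seq_along(set$outlines)) {
    o <- set$outlines[[i]]
    files[i] <- file.path("outlines", paste0(o$specimen_id, ".csv"))
    write_outline_table(o, file.path(outdir, files[i]))
  }
  manifest <- file.path(outdir, "manifest.csv")
  utils::write.csv(data.frame(specimen_id = outline_ids(set),
                              group = outline_groups(set),
                              taxon_label = NA_character_,
                              file = files),
                   manifest, row.names = FALSE)
  meas <- gen_measurements(
    n = 47, sigma = 0.05, seed = child_seed(seed, 1001),
    outliers = data.frame(offset = rep(0.2, 3), group = "new"))
  meas_path <- file.path(outdir, "measurements.csv")
  utils::write.csv(meas, meas_path, row.names = FALSE)
  layout_path <- file.path(outdir, "layout.json")
  write_layout_json(gen_layout("flat_short"), layout_path)
  invisible(list(manifest = manifest, measurements = meas_path,
                 layout = layout_path))
}

#' Write / read a head layout as JSON
#'
#' @param layout a [head_layout].
#' @param path JSON file path.
#' @return `path` invisibly for write; a [head_layout] for read.
#' @export
write_layout_json <- function(layout, path) {
  stopifnot(inherits(layout, "head_layout"))
  ser_eye <- function(e) {
    list(lens_center = e$lens_center, lens_normal = e$lens_normal,
         lens_aperture = e$lens_aperture, retina_depth = e$retina_depth,
         retina_extent = e$retina_extent,
         refractive_index = e$refractive_index, tilt = e$tilt)
  }
  jsonlite::write_json(
    list(left_eye = ser_eye(layout$left_eye),
         right_eye = ser_eye(layout$right_eye),
         head_polygon = layout$head_polygon,
         stylet_length = layout$stylet_length,
         stylet_base_points = layout$stylet_base_points,
         stylet_span_angle = layout$stylet_span_angle,
         head_length = layout$head_length,
         symmetric = layout$symmetric),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_layout_json
#' @export
read_layout_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  de <- function(e) {
    eye_geometry(e$lens_center, e$lens_normal, e$lens_aperture,
                 e$retina_depth, e$retina_extent, e$refractive_index, e$tilt)
  }
  head_layout(de(j$left_eye), de(j$right_eye), j$head_polygon,
              j$stylet_length, j$stylet_base_points, j$stylet_span_angle,
              head_length = j$head_length, symmetric = j$symmetric)
}
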