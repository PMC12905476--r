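#' Analysis configuration
#'
#' Collects every tunable of the end-to-end analysis with its default:
#' harmonic-power threshold 0.99 (the fraction of outline variation the
#' retained harmonics must carry), PCA variance threshold 0.99, coefficient
#' normalization (center + scale, no rotation alignment), refractive index
#' 1.4, and the resampling density applied to every outline before
#' decomposition. Unknown fields are rejected so typos in config files fail
#' loudly.
#'
#' @param manifest,measurements,layout input paths (see [read_outline_set()],
#'   [read_measurements()], [read_layout_json()]).
#' @param outdir output directory.
#' @param harmonic_threshold,variance_threshold fractions in (0, 1].
#' @param max_harmonics cap for harmonic calibration.
#' @param resample_points outline registration density (0 = keep as-is).
#' @param center,scale,align normalization flags for [build_matrix()].
#' @param refractive_index lens refractive index for refractive-mode fields.
#' @param scenarios scenario names for [run_vision()].
#' @param allometry_threshold residual cutoff for [flag_above_line()].
#' @param seed master seed for any simulated inputs.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(manifest = NULL, measurements = NULL,
                            layout = NULL, outdir = "stemmorph-out",
                            harmonic_threshold = 0.99,
                            variance_threshold = 0.99,
                            max_harmonics = 32, resample_points = 300,
                            center = TRUE, scale = TRUE, align = FALSE,
                            refractive_index = 1.4,
                            scenarios = c("flat_short", "tapering_long",
                                          "long_clipped", "tilted"),
                            allometry_threshold = 0, seed = 1L) {
  cfg <- as.list(environment())
  for (th in c("harmonic_threshold", "variance_threshold")) {
    if (!(cfg[[th]] > 0 && cfg[[th]] <= 1)) {
      stop(th, " must be in (0, 1]", call. = FALSE)
    }
  }
  structure(cfg, class = "analysis_config")
}

#' Load an analysis configuration from YAML or JSON
#'
#' Fields absent from the file keep their [analysis_config()] defaults;
#' unknown fields are an error.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return An `analysis_config`.
#' @export
load_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(analysis_config, vals)
}

#' @noRd
write_log <- function(cfg, outdir, stage, extra = character(0)) {
  used <- vapply(names(cfg), function(nm) {
    v <- cfg[[nm]]
    sprintf("%s = %s", nm, paste(format(v), collapse = ","))
  }, character(1))
  writeLines(c(sprintf("stage: %s", stage), used, extra),
             file.path(outdir, paste0(stage, ".log")))
}

#' Run the outline-to-morphospace analysis
#'
#' Reads the manifest and outlines, enforces counterclockwise orientation,
#' resamples to the configured density, calibrates the harmonic count
#' against the power threshold, builds the coefficient matrix, runs the
#' covariance PCA, counts the components needed for the variance threshold,
#' and computes hull occupancy in the PC1/PC2 plane. Writes
#' `scores.csv`, `variance.csv`, `occupancy.json`, `morphospace.svg` and a
#' log of every resolved parameter. Reruns with the same config are
#' bit-identical.
#'
#' @param config an `analysis_config` (or path to one).
#' @return Invisibly, a list with `n_harmonics`, `pca`, `n_components`,
#'   `occupancy` and the output paths.
#' @export
run_morphometrics <- function(config) {
  cfg <- if (is.character(config)) load_config(config) else config
  if (is.null(cfg$manifest)) stop("config needs a manifest path", call. = FALSE)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  set <- read_outline_set(cfg$manifest)
  set$outlines <- lapply(set$outlines, function(o) {
    o <- normalize_orientation(o)
    if (cfg$resample_points >= 3) {
      o <- resample_equal_arclength(o, cfg$resample_points)
    }
    o
  })
  nh <- calibrate_harmonics(set, cfg$harmonic_threshold, cfg$max_harmonics)
  cm <- build_matrix(set, nh, center = cfg$center, scale = cfg$scale,
                     align = cfg$align)
  pca <- run_pca(cm)
  k <- count_components_for_threshold(pca, cfg$variance_threshold)
  occ <- morphospace_occupancy(pca, c(1, 2))
  scores_path <- file.path(cfg$outdir, "scores.csv")
  write_scores_csv(pca, scores_path)
  var_path <- file.path(cfg$outdir, "variance.csv")
  utils::write.csv(data.frame(component = seq_along(pca$eigenvalues),
                              eigenvalue = pca$eigenvalues,
                              variance_fraction = pca$variance_fraction),
                   var_path, row.names = FALSE)
  occ_path <- file.path(cfg$outdir, "occupancy.json")
  jsonlite::write_json(
    list(axes = occ$axes,
         hull_areas = lapply(occ$hulls, function(h)
           list(area = h$area, degenerate = h$degenerate)),
         overlap = occ$overlap,
         outside_all = as.list(stats::setNames(occ$outside_all, pca$ids))),
    occ_path, digits = NA, auto_unbox = TRUE)
  svg_path <- file.path(cfg$outdir, "morphospace.svg")
  render_morphospace_svg(pca, occ, svg_path)
  write_log(cfg, cfg$outdir, "morphometrics",
            c(sprintf("n_specimens = %d", length(set)),
              sprintf("calibrated_harmonics = %d", nh),
              sprintf("components_for_threshold = %d", k)))
  invisible(list(n_harmonics = as.integer(nh), pca = pca, n_components = k,
                 occupancy = occ,
                 paths = c(scores = scores_path, variance = var_path,
                           occupancy = occ_path, svg = svg_path)))
}

#' Run the allometry analysis
#'
#' Fits the log-log lens-diameter vs head-length trend, flags above-line
#' specimens at the configured residual threshold, and writes `fit.json`,
#' `residuals.csv` and `allometry.svg`.
#'
#' @param config an `analysis_config` (or path to one).
#' @return Invisibly, a list with `fit`, `flagged` and output paths.
#' @export
run_allometry <- function(config) {
  cfg <- if (is.character(config)) load_config(config) else config
  if (is.null(cfg$measurements)) {
    stop("config needs a measurements path", call. = FALSE)
  }
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  records <- read_measurements(cfg$measurements)
  fit <- fit_loglog(records)
  flagged <- flag_above_line(fit, cfg$allometry_threshold)
  fit_path <- file.path(cfg$outdir, "fit.json")
  jsonlite::write_json(list(slope = fit$slope, intercept = fit$intercept,
                            r_squared = fit$r_squared, method = fit$method,
                            n_fit = fit$n_fit, flagged = flagged),
                       fit_path, digits = NA, auto_unbox = TRUE)
  res_path <- file.path(cfg$outdir, "residuals.csv")
  utils::write.csv(data.frame(specimen_id = names(fit$residuals),
                              residual = unname(fit$residuals),
                              above = fit$residuals > cfg$allometry_threshold),
                   res_path, row.names = FALSE)
  svg_path <- file.path(cfg$outdir, "allometry.svg")
  render_allometry_svg(records, fit, svg_path)
  write_log(cfg, cfg$outdir, "allometry",
            c(sprintf("n_records = %d", nrow(records)),
              sprintf("n_flagged = %d", length(flagged))))
  invisible(list(fit = fit, flagged = flagged,
                 paths = c(fit = fit_path, residuals = res_path,
                           svg = svg_path)))
}

#' Run the visual-field scenario analysis
#'
#' Evaluates every configured eye-geometry scenario in both optical modes on
#' the configured layout (or the default preset layout when none is given),
#' writing `vision_report.json`, a per-scenario-and-mode SVG, and a summary
#' CSV of feasibility and stylet-zone relation.
#'
#' @param config an `analysis_config` (or path to one).
#' @return Invisibly, a list with the `scenario_report` and output paths.
#' @export
run_vision <- function(config) {
  cfg <- if (is.character(config)) load_config(config) else config
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  layout <- if (!is.null(cfg$layout)) {
    read_layout_json(cfg$layout)
  } else {
    gen_layout("flat_short", refractive_index = cfg$refractive_index)
  }
  rep <- evaluate_scenarios(layout, scenarios = cfg$scenarios)
  details <- attr(rep, "details")
  svg_paths <- character(0)
  for (key in names(details)) {
    d <- details[[key]]
    p <- file.path(cfg$outdir, sprintf("vision_%s.svg", gsub("\\.", "_", key)))
    render_vision_svg(d$layout, d$left, d$right, d$binocular, p)
    svg_paths[key] <- p
  }
  json_path <- file.path(cfg$outdir, "vision_report.json")
  jsonlite::write_json(lapply(seq_len(nrow(rep)), function(i) as.list(rep[i, ])),
                       json_path, digits = NA, auto_unbox = TRUE)
  sum_path <- file.path(cfg$outdir, "vision_summary.csv")
  utils::write.csv(as.data.frame(rep), sum_path, row.names = FALSE)
  write_log(cfg, cfg$outdir, "vision",
            sprintf("n_reports = %d", nrow(rep)))
  invisible(list(report = rep,
                 paths = c(json = json_path, summary = sum_path, svg_paths)))
}
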