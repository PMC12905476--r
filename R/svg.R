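# Minimal deterministic SVG writer for report figures (scatter plots,
# outlines, visual-field polygons).  Coordinates are mapped from data space
# (y up) to SVG space (y down); output is plain text with no timestamps so
# reruns are bit-identical.

#' @noRd
svg_scene <- function(xlim, ylim, width = 640, height = 640) {
  structure(list(xlim = xlim, ylim = ylim, width = width, height = height,
                 elements = character(0)),
            class = "svg_scene")
}

#' @noRd
svg_map <- function(scene, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  cbind((pts[, 1] - scene$xlim[1]) / diff(scene$xlim) * scene$width,
        (scene$ylim[2] - pts[, 2]) / diff(scene$ylim) * scene$height)
}

#' @noRd
svg_add <- function(scene, tag) {
  scene$elements <- c(scene$elements, tag)
  scene
}

#' @noRd
svg_polygon <- function(scene, pts, fill = "none", stroke = "black",
                        opacity = 1, stroke_width = 1) {
  if (nrow(pts) < 2) return(scene)
  m <- svg_map(scene, pts)
  svg_add(scene, sprintf(
    '<polygon points="%s" fill="%s" fill-opacity="%.3g" stroke="%s" stroke-width="%.3g"/>',
    paste(sprintf("%.3f,%.3f", m[, 1], m[, 2]), collapse = " "),
    fill, opacity, stroke, stroke_width))
}

#' @noRd
svg_points <- function(scene, pts, r = 3, fill = "black") {
  m <- svg_map(scene, pts)
  svg_add(scene, paste(sprintf(
    '<circle cx="%.3f" cy="%.3f" r="%.3g" fill="%s"/>', m[, 1], m[, 2], r,
    fill), collapse = "\n"))
}

#' @noRd
svg_line <- function(scene, p1, p2, stroke = "black", stroke_width = 1,
                     dash = NULL) {
  m <- svg_map(scene, rbind(p1, p2))
  svg_add(scene, sprintf(
    '<line x1="%.3f" y1="%.3f" x2="%.3f" y2="%.3f" stroke="%s" stroke-width="%.3g"%s/>',
    m[1, 1], m[1, 2], m[2, 1], m[2, 2], stroke, stroke_width,
    if (is.null(dash)) "" else sprintf(' stroke-dasharray="%s"', dash)))
}

#' @noRd
svg_text <- function(scene, p, label, size = 12) {
  m <- svg_map(scene, rbind(p))
  svg_add(scene, sprintf(
    '<text x="%.3f" y="%.3f" font-size="%d" font-family="sans-serif">%s</text>',
    m[1, 1], m[1, 2], size, label))
}

#' @noRd
svg_write <- function(scene, path) {
  writeLines(c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            scene$width, scene$height, scene$width, scene$height),
    '<rect width="100%" height="100%" fill="white"/>',
    scene$elements,
    "</svg>"), path)
  invisible(path)
}

group_colors <- c(extant = "#1b9e77", fossil = "#7570b3", new = "#d95f02")

#' Render a morphospace scatter with group hulls to SVG
#'
#' @param pca a `shape_pca`.
#' @param occ an `occupancy_report` for the same axes.
#' @param path output SVG path.
#' @return `path`, invisibly.
#' @export
render_morphospace_svg <- function(pca, occ, path) {
  pts <- pca$scores[, occ$axes, drop = FALSE]
  pad <- 0.08 * apply(pts, 2, function(v) diff(range(v)) + 1e-9)
  scene <- svg_scene(range(pts[, 1]) + c(-1, 1) * pad[1],
                     range(pts[, 2]) + c(-1, 1) * pad[2])
  for (g in names(occ$hulls)) {
    h <- occ$hulls[[g]]
    col <- group_colors[[g]] %||% "grey"
    if (!h$degenerate) {
      scene <- svg_polygon(scene, h$vertices, fill = col, opacity = 0.15,
                           stroke = col)
    }
  }
  for (g in unique(occ$groups)) {
    col <- group_colors[[g]] %||% "grey"
    scene <- svg_points(scene, pts[occ$groups == g, , drop = FALSE],
                        fill = col)
  }
  scene <- svg_text(scene, c(scene$xlim[1] + pad[1], scene$ylim[1] + pad[2]),
                    sprintf("PC%d vs PC%d", occ$axes[2], occ$axes[1]))
  svg_write(scene, path)
}

#' Render the log-log allometry scatter with trend line to SVG
#'
#' @param records measurement data.frame.
#' @param fit an `allometry_fit`.
#' @param path output SVG path.
#' @return `path`, invisibly.
#' @export
render_allometry_svg <- function(records, fit, path) {
  lx <- log10(records$head_length)
  ly <- log10(records$lens_diameter)
  pad <- c(0.08 * (diff(range(lx)) + 1e-9), 0.08 * (diff(range(ly)) + 1e-9))
  scene <- svg_scene(range(lx) + c(-1, 1) * pad[1],
                     range(ly) + c(-1, 1) * pad[2])
  x0 <- scene$xlim
  scene <- svg_line(scene, c(x0[1], fit$intercept + fit$slope * x0[1]),
                    c(x0[2], fit$intercept + fit$slope * x0[2]),
                    stroke = "grey", stroke_width = 2)
  grp <- if ("group" %in% names(records)) records$group else "extant"
  for (g in unique(grp)) {
    col <- group_colors[[g]] %||% "grey"
    scene <- svg_points(scene, cbind(lx, ly)[grp == g, , drop = FALSE],
                        fill = col)
  }
  scene <- svg_text(scene, c(scene$xlim[1] + pad[1], scene$ylim[1] + pad[2]),
                    "log10 lens diameter vs log10 head length")
  svg_write(scene, path)
}

#' Render a vision scenario (head, fields, overlap, stylet zone) to SVG
#'
#' @param layout a [head_layout] (after scenario application).
#' @param left,right `view_field` objects.
#' @param bin a `binocular_field`.
#' @param path output SVG path.
#' @return `path`, invisibly.
#' @export
render_vision_svg <- function(layout, left, right, bin, path) {
  L <- layout$head_length
  xl <- c(-2.5, 2.5) * L
  yl <- c(-1.5, 3.5) * L
  scene <- svg_scene(xl, yl, width = 500, height = 500)
  window <- rect_window(xl, yl)
  for (vf in list(left, right)) {
    fp <- field_polygon(vf, window)
    if (nrow(fp) >= 3) {
      scene <- svg_polygon(scene, fp, fill = "#ffd92f", opacity = 0.25,
                           stroke = "none")
    }
  }
  if (nrow(bin$region) >= 3) {
    scene <- svg_polygon(scene, bin$region, fill = "#d95f02", opacity = 0.45,
                         stroke = "none")
  }
  scene <- svg_polygon(scene, stylet_zone(layout), fill = "none",
                       stroke = "#7570b3")
  scene <- svg_polygon(scene, layout$head_polygon, fill = "#cccccc",
                       opacity = 0.8, stroke = "black")
  for (eye in list(layout$left_eye, layout$right_eye)) {
    pp <- eye_points(eye)
    scene <- svg_polygon(scene, rbind(pp$A_minus, pp$A_plus, pp$R_plus,
                                      pp$R_minus),
                         fill = "#1b9e77", opacity = 0.6, stroke = "black")
  }
  svg_write(scene, path)
}
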