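#' Closed specimen outlines
#'
#' An `outline` stores the digitized silhouette of one larval head (head
#' capsule plus stylets) as an ordered loop of planar coordinates. The loop is
#' stored *open*: the last point is not a duplicate of the first, closure is
#' implicit. Coordinates use a y-up convention with the anterior of the head
#' toward +y, so "forward-directed" is well defined downstream.
#'
#' @param points numeric matrix (or two-column data frame) of x, y vertices in
#'   order along the loop; at least 3 points, consecutive points distinct,
#'   nonzero enclosed area.
#' @param specimen_id character scalar identifying the specimen.
#' @param group one of `"extant"`, `"fossil"`, `"new"`.
#' @param taxon_label optional character label.
#' @return An object of class `outline` with elements `specimen_id`, `points`,
#'   `group`, `taxon_label`.
#' @examples
#' sq <- outline(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), "sq", "extant")
#' outline_area(sq)
#' @export
outline <- function(points, specimen_id = "specimen", group = "extant",
                    taxon_label = NA_character_) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2) {
    stop("outline points must be a numeric two-column matrix", call. = FALSE)
  }
  if (anyNA(points) || any(!is.finite(points))) {
    stop("outline points must be finite", call. = FALSE)
  }
  n <- nrow(points)
  if (n >= 2 && all(points[n, ] == points[1, ])) {
    points <- points[-n, , drop = FALSE]  # drop explicit closure duplicate
    n <- n - 1L
  }
  if (n < 3) stop("an outline needs at least 3 points", call. = FALSE)
  nxt <- points[c(2:n, 1), , drop = FALSE]
  if (any(rowSums((nxt - points)^2) == 0)) {
    stop("consecutive outline points must be distinct", call. = FALSE)
  }
  group <- match.arg(group, c("extant", "fossil", "new"))
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(
    list(specimen_id = as.character(specimen_id), points = points,
         group = group, taxon_label = taxon_label),
    class = "outline"
  )
}

#' @export
print.outline <- function(x, ...) {
  cat(sprintf("<outline> %s [%s], %d points, signed area %.4g\n",
              x$specimen_id, x$group, nrow(x$points), outline_area(x)))
  invisible(x)
}

#' Signed area enclosed by an outline
#'
#' Shoelace signed area of the implicitly closed loop; positive for
#' counterclockwise point order.
#'
#' @param x an [outline].
#' @return numeric scalar.
#' @export
outline_area <- function(x) signed_area(x$points)

#' Perimeter of an outline
#' @param x an [outline].
#' @return numeric scalar, length of the closed loop.
#' @export
outline_perimeter <- function(x) polygon_perimeter(x$points)

#' A set of outlines with unique specimen ids
#'
#' @param outlines list of [outline] objects with unique `specimen_id`s.
#' @param provenance free-text note on where the set came from.
#' @return An object of class `outline_set` (a list with elements `outlines`
#'   and `provenance`).
#' @export
outline_set <- function(outlines, provenance = "") {
  stopifnot(is.list(outlines), length(outlines) > 0)
  ok <- vapply(outlines, inherits, logical(1), "outline")
  if (!all(ok)) stop("all elements must be outlines", call. = FALSE)
  ids <- vapply(outlines, function(o) o$specimen_id, character(1))
  if (anyDuplicated(ids)) {
    stop("specimen ids must be unique: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  names(outlines) <- ids
  structure(list(outlines = outlines, provenance = provenance),
            class = "outline_set")
}

#' @export
print.outline_set <- function(x, ...) {
  grp <- table(outline_groups(x))
  cat(sprintf("<outline_set> %d specimens (%s)\n", length(x$outlines),
              paste(sprintf("%s: %d", names(grp), grp), collapse = ", ")))
  invisible(x)
}

#' @export
length.outline_set <- function(x) length(x$outlines)

#' Specimen ids / group labels of an outline set
#' @param x an [outline_set].
#' @return character vector, one entry per outline.
#' @export
outline_ids <- function(x) vapply(x$outlines, function(o) o$specimen_id, character(1))

#' @rdname outline_ids
#' @export
outline_groups <- function(x) vapply(x$outlines, function(o) o$group, character(1))

#' Read one outline from a coordinate table
#'
#' Reads a two-column (x, y) text table, one row per point, comma- or
#' whitespace-separated, with an optional header row. A final row duplicating
#' the first point (explicit closure) is dropped.
#'
#' @param path file path.
#' @param id specimen id to attach.
#' @param group group label (`"extant"`, `"fossil"`, `"new"`).
#' @param taxon_label optional taxon.
#' @return An [outline].
#' @export
read_outline_table <- function(path, id = basename(path), group = "extant",
                               taxon_label = NA_character_) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty outline file: ", path, call. = FALSE)
  split_row <- function(s) strsplit(s, "[,;\t ]+")[[1]]
  first <- suppressWarnings(as.numeric(split_row(lines[1])))
  if (anyNA(first)) lines <- lines[-1]  # header row
  if (length(lines) < 3) {
    stop("outline file has fewer than 3 coordinate rows: ", path, call. = FALSE)
  }
  pts <- matrix(NA_real_, length(lines), 2)
  for (i in seq_along(lines)) {
    vals <- suppressWarnings(as.numeric(split_row(lines[i])))
    if (length(vals) < 2 || anyNA(vals[1:2])) {
      stop(sprintf("non-numeric coordinate at row %d of %s", i, path),
           call. = FALSE)
    }
    pts[i, ] <- vals[1:2]
  }
  outline(pts, specimen_id = id, group = group, taxon_label = taxon_label)
}

#' Write an outline as a coordinate table
#'
#' Inverse of [read_outline_table()]: writes a `x,y` CSV with header. The
#' round trip preserves coordinates to full double precision.
#'
#' @param x an [outline].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_outline_table <- function(x, path) {
  stopifnot(inherits(x, "outline"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("x,y", con)
  writeLines(sprintf("%.17g,%.17g", x$points[, 1], x$points[, 2]), con)
  invisible(path)
}

#' Read outlines from a TPS-style outline file
#'
#' Parses the outline dialect of the TPS convention: each specimen is an
#' `OUTLINES=1` record followed by `POINTS=n`, `n` coordinate rows, and an
#' `ID=` record. Group labels are not part of the format; all outlines get
#' `group`.
#'
#' @param path file path.
#' @param group group label applied to every specimen in the file.
#' @return An [outline_set].
#' @export
read_tps_outlines <- function(path, group = "extant") {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  i <- 1L
  outs <- list()
  while (i <= length(lines)) {
    if (!grepl("^OUTLINES=", lines[i])) {
      stop("expected OUTLINES= record at line ", i, " of ", path, call. = FALSE)
    }
    i <- i + 1L
    if (i > length(lines) || !grepl("^POINTS=", lines[i])) {
      stop("expected POINTS= record in ", path, call. = FALSE)
    }
    npts <- as.integer(sub("^POINTS=", "", lines[i]))
    i <- i + 1L
    coord_rows <- character(0)
    while (i <= length(lines) && grepl("^[-+0-9.]", lines[i])) {
      coord_rows <- c(coord_rows, lines[i])
      i <- i + 1L
    }
    id <- sprintf("specimen_%d", length(outs) + 1L)
    if (i <= length(lines) && grepl("^ID=", lines[i])) {
      id <- sub("^ID=", "", lines[i])
      i <- i + 1L
    }
    if (length(coord_rows) != npts) {
      stop(sprintf("POINTS=%d but %d coordinate rows for specimen '%s' in %s",
                   npts, length(coord_rows), id, path), call. = FALSE)
    }
    pts <- do.call(rbind, lapply(strsplit(coord_rows, "[,\t ]+"), function(v) {
      as.numeric(v[1:2])
    }))
    if (anyNA(pts)) {
      stop("non-numeric coordinates for specimen '", id, "' in ", path,
           call. = FALSE)
    }
    outs[[length(outs) + 1L]] <- outline(pts, specimen_id = id, group = group)
    i <- i  # next OUTLINES record, if any
  }
  outline_set(outs, provenance = path)
}

#' Write an outline set in TPS outline format
#' @param x an [outline_set].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tps_outlines <- function(x, path) {
  stopifnot(inherits(x, "outline_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (o in x$outlines) {
    writeLines(c("OUTLINES=1", sprintf("POINTS=%d", nrow(o$points)),
                 sprintf("%.17g %.17g", o$points[, 1], o$points[, 2]),
                 sprintf("ID=%s", o$specimen_id)), con)
  }
  invisible(path)
}

#' Read an outline set via a manifest CSV
#'
#' The manifest has columns `specimen_id, group, taxon_label, file`; `file`
#' paths are resolved relative to the manifest's directory. Row order of the
#' manifest fixes specimen order in the set.
#'
#' @param path manifest CSV path.
#' @return An [outline_set].
#' @export
read_outline_set <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "group", "file")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns specimen_id, group, file", call. = FALSE)
  }
  dir <- dirname(path)
  outs <- lapply(seq_len(nrow(man)), function(i) {
    f <- man$file[i]
    if (!file.exists(f)) f <- file.path(dir, man$file[i])
    if (!file.exists(f)) {
      stop("manifest references missing outline file: ", man$file[i],
           call. = FALSE)
    }
    read_outline_table(f, id = man$specimen_id[i], group = man$group[i],
                       taxon_label = if ("taxon_label" %in% names(man))
                         man$taxon_label[i] else NA_character_)
  })
  outline_set(outs, provenance = path)
}

#' Read a head-length / lens-diameter measurement table
#'
#' CSV with columns `specimen_id, head_length, lens_diameter, group`
#' (analogous to a per-specimen eye-measurement table). Both measurements
#' must be strictly positive.
#'
#' @param path CSV path.
#' @return data.frame with validated columns.
#' @export
read_measurements <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "head_length", "lens_diameter", "group")
  if (!all(need %in% names(d))) {
    stop("measurement table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(d$head_length) | !is.finite(d$lens_diameter) |
                 d$head_length <= 0 | d$lens_diameter <= 0)
  if (length(bad)) {
    stop("nonpositive or missing measurement for specimen ",
         d$specimen_id[bad[1]], call. = FALSE)
  }
  d[, need]
}

#' Force counterclockwise orientation of an outline
#'
#' Reverses the point order if the signed area is negative; the starting
#' point is preserved. Consistent (ccw) orientation is a precondition for
#' stable elliptical-Fourier coefficient signs.
#'
#' @param x an [outline].
#' @return An [outline] with positive signed area.
#' @export
normalize_orientation <- function(x) {
  stopifnot(inherits(x, "outline"))
  a <- signed_area(x$points)
  scale <- max(abs(x$points))^2
  if (abs(a) <= 1e-12 * max(1, scale)) {
    stop("degenerate outline: zero signed area for ", x$specimen_id,
         call. = FALSE)
  }
  if (a < 0) {
    n <- nrow(x$points)
    x$points <- x$points[c(1L, n:2L), , drop = FALSE]
  }
  x
}

#' Resample an outline to equal arc-length spacing
#'
#' Places `n_points` points equally spaced by arc length along the closed
#' polygonal loop, starting at the original first point. Digitized outlines
#' of different sources are registered to a common density this way before
#' Fourier decomposition.
#'
#' @param x an [outline].
#' @param n_points number of points (>= 3).
#' @return An [outline] with exactly `n_points` points.
#' @export
resample_equal_arclength <- function(x, n_points) {
  stopifnot(inherits(x, "outline"))
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 3) {
    stop("n_points must be an integer >= 3", call. = FALSE)
  }
  pts <- x$points
  n <- nrow(pts)
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[n + 1]
  s <- total * (seq_len(n_points) - 1) / n_points
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx > n] <- n
  frac <- (s - cum[idx]) / seg[idx]
  new_pts <- closed[idx, , drop = FALSE] +
    frac * (closed[idx + 1, , drop = FALSE] - closed[idx, , drop = FALSE])
  x$points <- new_pts
  x
}
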