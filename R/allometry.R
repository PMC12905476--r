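#' Fit the log-log trend of lens diameter against head length
#'
#' Eye size scales with body size approximately as a power law, so the trend
#' of largest-lens diameter against head length is fitted on log10-log10
#' axes. Default is ordinary least squares of `log10(lens_diameter)` on
#' `log10(head_length)`; major-axis regression (`method = "ma"`), which
#' treats both measurements as error-prone, is available as an option.
#' Residuals (signed vertical distances in log10 space) are stored for every
#' record, including records excluded from the fit via `fit_groups`.
#'
#' @param records data.frame with columns `specimen_id`, `head_length`,
#'   `lens_diameter`, `group` (see [read_measurements()]).
#' @param method `"ols"` (default) or `"ma"` (major axis).
#' @param fit_groups optional character vector; if given, only records in
#'   these groups inform the fitted line (e.g. `"extant"`), while residuals
#'   are still reported for all records.
#' @return An object of class `allometry_fit`: list with `slope`,
#'   `intercept` (log10 units), named `residuals`, `r_squared`, `method`,
#'   `n_fit`.
#' @export
fit_loglog <- function(records, method = c("ols", "ma"), fit_groups = NULL) {
  method <- match.arg(method)
  need <- c("specimen_id", "head_length", "lens_diameter")
  if (!all(need %in% names(records))) {
    stop("records must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(records$head_length <= 0 | records$lens_diameter <= 0 |
                 !is.finite(records$head_length) |
                 !is.finite(records$lens_diameter))
  if (length(bad)) {
    stop("nonpositive measurement for specimen ", records$specimen_id[bad[1]],
         call. = FALSE)
  }
  use <- rep(TRUE, nrow(records))
  if (!is.null(fit_groups)) use <- records$group %in% fit_groups
  if (sum(use) < 3) stop("at least 3 records are needed to fit the trend",
                         call. = FALSE)
  lx <- log10(records$head_length)
  ly <- log10(records$lens_diameter)
  if (method == "ols") {
    fit <- stats::lm(ly ~ lx, subset = use)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    ss_tot <- sum((ly[use] - mean(ly[use]))^2)
    r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else 1
  } else {
    cv <- stats::cov(cbind(lx[use], ly[use]))
    e <- eigen(cv, symmetric = TRUE)
    v <- e$vectors[, 1]
    slope <- v[2] / v[1]
    intercept <- mean(ly[use]) - slope * mean(lx[use])
    r2 <- stats::cor(lx[use], ly[use])^2
  }
  res <- ly - (intercept + slope * lx)
  names(res) <- records$specimen_id
  structure(list(slope = slope, intercept = intercept, residuals = res,
                 r_squared = r2, method = method, n_fit = sum(use)),
            class = "allometry_fit")
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat(sprintf(
    "<allometry_fit> log10(lens) = %.4f + %.4f * log10(head)  (%s, n = %d, r^2 = %.4f)\n",
    x$intercept, x$slope, x$method, x$n_fit, x$r_squared))
  invisible(x)
}

#' Specimens lying above the allometric trend line
#'
#' Specimens whose eyes are disproportionately large for their head length
#' have positive residuals; this returns ids with residual above a cutoff,
#' largest first.
#'
#' @param fit an `allometry_fit`.
#' @param threshold residual cutoff in log10 units (default 0: any point
#'   above the line).
#' @return Character vector of specimen ids sorted by residual, descending.
#' @export
flag_above_line <- function(fit, threshold = 0) {
  stopifnot(inherits(fit, "allometry_fit"))
  # small guard so floating-point-zero residuals never count as "above"
  above <- fit$residuals[fit$residuals > threshold + 1e-10]
  names(sort(above, decreasing = TRUE))
}
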