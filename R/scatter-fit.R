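#' Two-channel voxel scatter fit (accuracy/precision analysis)
#'
#' Fits a line to the two-channel scatter of normalized voxel intensities
#' from redundant detection of one target. If amplified signal scales
#' linearly with target abundance, the scatter is a tight line through the
#' origin: the fitted intercept measures accuracy (departure from zero
#' intercept), the Pearson correlation and the root-mean-square orthogonal
#' distance to the line measure precision (scatter around the line).
#'
#' The default fit is total least squares (orthogonal regression): both
#' channels carry comparable measurement noise under redundant detection,
#' so perpendicular — not vertical — distances are minimized. The TLS line
#' passes through the centroid along the principal eigenvector of the
#' 2x2 sample covariance. Ordinary least squares of `ch2` on `ch1` is
#' available for comparison.
#'
#' @param ch1,ch2 Normalized [bin_voxels()] grids of identical shape, or
#'   plain numeric vectors of equal length.
#' @param mask Optional logical matrix/vector selecting the voxels to fit
#'   (e.g. from [expressing_mask()]); default all.
#' @param method `"tls"` (orthogonal regression, default) or `"ols"`.
#' @return An object of class `qhcr_scatter` with components `slope`,
#'   `intercept`, `pearson_r`, `orth_rms` (RMS perpendicular distance),
#'   `n_voxels`, `mask_fraction`, `method` and the fitted points `x`, `y`.
#' @seealso [crowding_diagnostic()] for the density-stratified
#'   slope-consistency check.
#' @export
fit_scatter <- function(ch1, ch2, mask = NULL, method = c("tls", "ols")) {
  method <- match.arg(method)
  g1 <- if (inherits(ch1, "qhcr_voxels")) ch1$intensities else ch1
  g2 <- if (inherits(ch2, "qhcr_voxels")) ch2$intensities else ch2
  if (length(g1) != length(g2)) {
    stop("channels have different numbers of voxels", call. = FALSE)
  }
  if (inherits(ch1, "qhcr_voxels") && inherits(ch2, "qhcr_voxels") &&
      (!ch1$normalized || !ch2$normalized)) {
    stop("voxel grids must be normalized before fitting; see normalize_voxels()",
         call. = FALSE)
  }
  n_total <- length(g1)
  if (is.null(mask)) mask <- rep(TRUE, n_total)
  if (length(mask) != n_total) {
    stop("mask shape does not match the voxel grids", call. = FALSE)
  }
  x <- as.numeric(g1)[as.logical(mask)]
  y <- as.numeric(g2)[as.logical(mask)]
  n <- length(x)
  if (n < 2L) stop("need at least 2 masked voxels", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in a channel: correlation and line undefined",
         call. = FALSE)
  }
  fit <- tls_line(x, y, method = method)
  d <- (y - fit$intercept - fit$slope * x) / sqrt(1 + fit$slope^2)
  structure(list(slope = fit$slope, intercept = fit$intercept,
                 pearson_r = stats::cor(x, y),
                 orth_rms = sqrt(mean(d^2)),
                 n_voxels = n, mask_fraction = n / n_total,
                 method = method, x = x, y = y),
            class = "qhcr_scatter")
}

# Line fit on raw vectors; TLS via the principal axis of the covariance.
tls_line <- function(x, y, method = "tls") {
  if (method == "ols") {
    slope <- stats::cov(x, y) / stats::var(x)
    return(list(slope = slope, intercept = mean(y) - slope * mean(x)))
  }
  cv <- stats::cov(cbind(x, y))
  e <- eigen(cv, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (abs(v[1]) < 1e-12) {
    stop("degenerate scatter: fitted line is vertical", call. = FALSE)
  }
  slope <- v[2] / v[1]
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' @export
print.qhcr_scatter <- function(x, digits = 4, ...) {
  cat(sprintf("qHCR two-channel scatter fit (%s)\n", toupper(x$method)))
  cat(sprintf("  slope      %s\n  intercept  %s\n  Pearson r  %s\n  orth. RMS  %s\n",
              format(x$slope, digits = digits),
              format(x$intercept, digits = digits),
              format(x$pearson_r, digits = digits),
              format(x$orth_rms, digits = digits)))
  cat(sprintf("  %d voxels fitted (%.1f%% of grid)\n",
              x$n_voxels, 100 * x$mask_fraction))
  invisible(x)
}

#' @export
summary.qhcr_scatter <- function(object, ...) {
  structure(list(fit = object,
                 accuracy_zero_intercept = abs(object$intercept) <= 0.05,
                 r_squared = object$pearson_r^2),
            class = "summary.qhcr_scatter")
}

#' @export
print.summary.qhcr_scatter <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  r^2 = %.4f; |intercept| %s 0.05 (zero-intercept accuracy %s)\n",
              x$r_squared, if (x$accuracy_zero_intercept) "<=" else ">",
              if (x$accuracy_zero_intercept) "met" else "not met"))
  invisible(x)
}

#' @export
coef.qhcr_scatter <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.qhcr_scatter <- function(object, ...) {
  (object$y - object$intercept - object$slope * object$x) /
    sqrt(1 + object$slope^2)
}

#' @importFrom graphics abline plot.default
#' @export
plot.qhcr_scatter <- function(x, xlab = "channel 1 (normalized)",
                              ylab = "channel 2 (normalized)", ...) {
  plot.default(x$x, x$y, xlab = xlab, ylab = ylab,
               pch = 16, cex = 0.4, col = "#00000055", ...)
  abline(x$intercept, x$slope, col = "red3", lwd = 2)
  invisible(x)
}
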