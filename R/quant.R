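#' Largest commensurate voxel size
#'
#' Subcellular voxels must span an integer number of pixels per dimension.
#' Microscope pixel sizes (e.g. 0.16 um) rarely divide a round requested
#' voxel size (e.g. 2 um) exactly, so this helper applies the package's
#' convention: the largest integer pixel block whose physical size does not
#' exceed the request. [bin_voxels()] itself is strict and errors on
#' non-commensurate sizes; pass the realized size from here.
#'
#' @param pixel_size Pixel size, micrometres.
#' @param requested_voxel_size Requested voxel size, micrometres.
#' @return Named list: `pixels_per_voxel` (integer) and `voxel_size`
#'   (realized size, micrometres).
#' @export
realized_voxel_size <- function(pixel_size, requested_voxel_size) {
  check_scalar(pixel_size, "pixel_size", lower = 1e-12)
  check_scalar(requested_voxel_size, "requested_voxel_size",
               lower = pixel_size)
  b <- max(1L, as.integer(floor(requested_voxel_size / pixel_size + 1e-9)))
  list(pixels_per_voxel = b, voxel_size = b * pixel_size)
}

#' Bin an image into subcellular voxels
#'
#' Aggregates non-overlapping pixel blocks into voxels of the given
#' physical size. The voxel size must be an integer multiple of the pixel
#' size in each dimension (to within 1e-6 relative); trailing partial
#' blocks are discarded. The mapping back to pixel space is retained so
#' voxels can be projected onto anatomical masks.
#'
#' @param image Numeric matrix (one channel).
#' @param pixel_size Pixel size, micrometres.
#' @param voxel_size Voxel size, micrometres; scalar or length 2
#'   `c(rows, cols)`. See [realized_voxel_size()] for the convention used
#'   when a requested size is not commensurate.
#' @param aggregator `"mean"` (default; keeps intensity units) or `"sum"`
#'   (conserves the included-pixel total exactly).
#' @return An object of class `qhcr_voxels`: list with `intensities`
#'   (voxel matrix), `voxel_size` (um, length 2), `pixels_per_voxel`
#'   (integer, length 2), `origin_pixel` (0-based pixel coordinates of
#'   voxel (1,1)'s corner), `pixel_size`, `aggregator` and `normalized`.
#' @export
bin_voxels <- function(image, pixel_size, voxel_size,
                       aggregator = c("mean", "sum")) {
  aggregator <- match.arg(aggregator)
  stopifnot(is.matrix(image), is.numeric(image))
  check_scalar(pixel_size, "pixel_size", lower = 1e-12)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 2L)
  stopifnot(length(voxel_size) == 2L, all(voxel_size > 0))
  ratio <- voxel_size / pixel_size
  b <- round(ratio)
  if (any(abs(ratio - b) > 1e-6 * ratio) || any(b < 1)) {
    stop(sprintf(paste0("voxel size (%s um) is not an integer multiple of ",
                        "pixel size (%g um): %s pixels/voxel; see ",
                        "realized_voxel_size()"),
                 paste(format(voxel_size), collapse = " x "), pixel_size,
                 paste(format(ratio), collapse = " x ")), call. = FALSE)
  }
  b <- as.integer(b)
  nv <- dim(image) %/% b
  if (any(nv < 1L)) {
    stop("image smaller than one voxel", call. = FALSE)
  }
  sub <- image[seq_len(nv[1] * b[1]), seq_len(nv[2] * b[2]), drop = FALSE]
  # block-sum via dimension folding
  a <- array(sub, dim = c(b[1], nv[1], b[2], nv[2]))
  v <- apply(a, c(2, 4), sum)
  if (aggregator == "mean") v <- v / prod(b)
  structure(list(intensities = v,
                 voxel_size = b * pixel_size,
                 pixels_per_voxel = b,
                 origin_pixel = c(0L, 0L),
                 pixel_size = pixel_size,
                 aggregator = aggregator,
                 normalized = FALSE),
            class = "qhcr_voxels")
}

#' @export
print.qhcr_voxels <- function(x, ...) {
  cat(sprintf("qHCR voxel grid: %d x %d voxels of %.4g x %.4g um (%d x %d px), %s%s\n",
              nrow(x$intensities), ncol(x$intensities),
              x$voxel_size[1], x$voxel_size[2],
              x$pixels_per_voxel[1], x$pixels_per_voxel[2], x$aggregator,
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Normalize voxel intensities
#'
#' Subtracts the instrument dark offset and the estimated background level,
#' clips at zero, and divides by an upper percentile of the remaining voxel
#' values so that intensities land on a common \[0, 1\] scale for
#' two-channel comparison. A percentile slightly below the maximum (default
#' 0.995) keeps a single hot voxel from compressing the whole scale; values
#' above 1 are clipped.
#'
#' @param grid A [bin_voxels()] result (not yet normalized).
#' @param background_level Background intensity to subtract (same units as
#'   the grid).
#' @param dark_offset Instrument dark level to subtract.
#' @param percentile Upper quantile used as the normalization scale, in
#'   (0, 1].
#' @return The grid with `normalized = TRUE`, values in \[0, 1\], and the
#'   normalization scale stored as `norm_scale`.
#' @export
normalize_voxels <- function(grid, background_level = 0, dark_offset = 0,
                             percentile = 0.995) {
  stopifnot(inherits(grid, "qhcr_voxels"))
  if (grid$normalized) stop("grid is already normalized", call. = FALSE)
  check_scalar(background_level, "background_level")
  check_scalar(dark_offset, "dark_offset")
  check_scalar(percentile, "percentile", lower = 1e-12, upper = 1)
  v <- pmax(grid$intensities - dark_offset - background_level, 0)
  q <- as.numeric(stats::quantile(v, percentile, names = FALSE))
  if (!is.finite(q) || q <= 0) {
    stop("normalization scale is zero: no voxel intensity above background",
         call. = FALSE)
  }
  grid$intensities <- pmin(v / q, 1)
  grid$normalized <- TRUE
  grid$norm_scale <- q
  grid
}

#' Mask of expressing voxels
#'
#' Marks voxels whose raw (pre-normalization) intensity exceeds
#' `background_mean + k * background_sd` in at least one channel. Empty
#' extracellular voxels otherwise dominate a two-channel correlation with a
#' dense blob at the origin; restricting the fit to expressing voxels keeps
#' the accuracy/precision readout about the signal.
#'
#' @param grids A single [bin_voxels()] grid or a list of grids with
#'   identical shapes (raw intensities).
#' @param background_sd Background standard deviation on the voxel scale.
#' @param k Threshold multiplier (default 2).
#' @param background_mean Background mean on the voxel scale (default 0).
#' @return Logical voxel matrix.
#' @export
expressing_mask <- function(grids, background_sd, k = 2,
                            background_mean = 0) {
  if (inherits(grids, "qhcr_voxels")) grids <- list(grids)
  stopifnot(length(grids) >= 1L,
            all(vapply(grids, inherits, TRUE, "qhcr_voxels")))
  check_scalar(background_sd, "background_sd", lower = 0)
  check_scalar(k, "k", lower = 0)
  check_scalar(background_mean, "background_mean")
  d1 <- dim(grids[[1]]$intensities)
  if (!all(vapply(grids, function(g) identical(dim(g$intensities), d1),
                  TRUE))) {
    stop("voxel grids have mismatched shapes", call. = FALSE)
  }
  thr <- background_mean + k * background_sd
  mask <- matrix(FALSE, d1[1], d1[2])
  for (g in grids) mask <- mask | (g$intensities > thr)
  mask
}

# Pixel-row/col ranges of voxel (i, j)'s footprint.
voxel_footprint <- function(grid, i, j) {
  b <- grid$pixels_per_voxel
  list(rows = ((i - 1L) * b[1] + 1L):(i * b[1]) + grid$origin_pixel[1],
       cols = ((j - 1L) * b[2] + 1L):(j * b[2]) + grid$origin_pixel[2])
}

#' Read out a region into expression space
#'
#' Maps an anatomical (pixel-space) region onto the voxel grid and returns
#' the normalized two-channel intensity pairs of every voxel whose pixel
#' footprint intersects the region — the read-out from anatomical space to
#' expression space.
#'
#' @param region Logical pixel matrix (the anatomical region), with the
#'   dimensions of the image the grids were binned from.
#' @param ch1,ch2 Two [bin_voxels()] grids of identical geometry.
#' @return A numeric matrix with columns `x1`, `x2` (possibly 0 rows) and
#'   attribute `voxels` (the 2-column voxel indices).
#' @export
read_out <- function(region, ch1, ch2) {
  stopifnot(is.matrix(region), is.logical(region),
            inherits(ch1, "qhcr_voxels"), inherits(ch2, "qhcr_voxels"))
  if (!identical(dim(ch1$intensities), dim(ch2$intensities)) ||
      !identical(ch1$pixels_per_voxel, ch2$pixels_per_voxel)) {
    stop("channel grids have mismatched geometry", call. = FALSE)
  }
  b <- ch1$pixels_per_voxel
  nv <- dim(ch1$intensities)
  if (any(dim(region) < nv * b)) {
    stop("region does not cover the voxel grid's pixel footprint",
         call. = FALSE)
  }
  # voxel intersects region <=> block-sum of region over its footprint > 0
  hits <- bin_voxels(region[seq_len(nv[1] * b[1]),
                            seq_len(nv[2] * b[2]), drop = FALSE] * 1,
                     ch1$pixel_size, b * ch1$pixel_size,
                     aggregator = "sum")$intensities > 0
  idx <- which(hits, arr.ind = TRUE)
  out <- cbind(x1 = ch1$intensities[hits], x2 = ch2$intensities[hits])
  attr(out, "voxels") <- idx
  out
}

#' Read in an expression-space gate onto anatomy
#'
#' Marks the pixel footprint of every voxel whose two-channel intensity
#' pair falls inside a polygonal gate drawn in expression space (boundary
#' counted as inside) — the read-in from expression space to anatomical
#' space.
#'
#' @param gate Simple polygon: numeric matrix of `(x1, x2)` vertices
#'   (>= 3 rows, 2 columns). Self-intersecting polygons are rejected.
#' @param ch1,ch2 Two [bin_voxels()] grids of identical geometry.
#' @param mask Optional logical voxel matrix restricting which voxels are
#'   considered (e.g. from [expressing_mask()]).
#' @return Logical pixel matrix covering the grids' pixel footprint.
#' @export
read_in <- function(gate, ch1, ch2, mask = NULL) {
  stopifnot(inherits(ch1, "qhcr_voxels"), inherits(ch2, "qhcr_voxels"))
  if (!identical(dim(ch1$intensities), dim(ch2$intensities)) ||
      !identical(ch1$pixels_per_voxel, ch2$pixels_per_voxel)) {
    stop("channel grids have mismatched geometry", call. = FALSE)
  }
  gate <- as.matrix(gate)
  validate_simple_polygon(gate)
  nv <- dim(ch1$intensities)
  b <- ch1$pixels_per_voxel
  consider <- if (is.null(mask)) matrix(TRUE, nv[1], nv[2]) else mask
  stopifnot(identical(dim(consider), nv))
  idx <- which(consider, arr.ind = TRUE)
  out <- matrix(FALSE, nv[1] * b[1], nv[2] * b[2])
  if (nrow(idx) == 0L) return(out)
  inside <- point_in_polygon(ch1$intensities[consider],
                             ch2$intensities[consider], gate)
  for (r in which(inside)) {
    fp <- voxel_footprint(ch1, idx[r, 1], idx[r, 2])
    out[fp$rows, fp$cols] <- TRUE
  }
  out
}
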