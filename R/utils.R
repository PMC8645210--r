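#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rpois rbinom rnbinom quantile median cor sd var
#' @importFrom utils modifyList
NULL

# Gaussian blur wrapper around EBImage::gblur. sigma is in pixels; sigma <= 0
# (or a blur narrower than a tenth of a pixel) is the identity. The default
# circular boundary conserves the image total exactly, which the rendering
# model relies on for its closed-form intensity budget.
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0.1) return(x)
  # kernel size capped at the image: truncates very wide kernels on small fields
  radius <- min(2L * as.integer(ceiling(3 * sigma)) + 1L,
                2L * ((min(dim(x)) - 1L) %/% 2L) + 1L)
  out <- EBImage::gblur(x, sigma = sigma, radius = radius)
  matrix(as.numeric(EBImage::imageData(out)), nrow(x), ncol(x))
}

# Derive independent substream seeds from one master seed. All randomness in
# a simulation flows through seeds drawn here, so one master seed fixes every
# stage and every control image.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stop(sprintf("'%s' must be supplied", name), call. = FALSE)
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' must be in [%s, %s], got %s", name,
                 format(lower), format(upper), format(x)), call. = FALSE)
  }
  if (integer && abs(x - round(x)) > 1e-9) {
    stop(sprintf("'%s' must be an integer, got %s", name, format(x)),
         call. = FALSE)
  }
  invisible(NULL)
}

## ---- polygon utilities (expression-space gating) -------------------------

# Squared cross product sign helper for segment orientation.
.orient <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

.on_segment <- function(ax, ay, bx, by, px, py, eps = 1e-12) {
  if (abs(.orient(ax, ay, bx, by, px, py)) > eps *
      max(1, abs(ax), abs(ay), abs(bx), abs(by))) {
    return(FALSE)
  }
  px >= min(ax, bx) - eps && px <= max(ax, bx) + eps &&
    py >= min(ay, by) - eps && py <= max(ay, by) + eps
}

# Proper or improper intersection of segments (a,b) and (c,d), used to reject
# self-intersecting gates. Shared endpoints of adjacent edges are excluded by
# the caller.
.segments_intersect <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  d1 <- .orient(cx, cy, dx, dy, ax, ay)
  d2 <- .orient(cx, cy, dx, dy, bx, by)
  d3 <- .orient(ax, ay, bx, by, cx, cy)
  d4 <- .orient(ax, ay, bx, by, dx, dy)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
    return(TRUE)
  }
  .on_segment(cx, cy, dx, dy, ax, ay) || .on_segment(cx, cy, dx, dy, bx, by) ||
    .on_segment(ax, ay, bx, by, cx, cy) || .on_segment(ax, ay, bx, by, dx, dy)
}

validate_simple_polygon <- function(poly) {
  if (!is.matrix(poly) || ncol(poly) != 2L || nrow(poly) < 3L ||
      !is.numeric(poly)) {
    stop("gate must be a numeric matrix with >= 3 rows and 2 columns",
         call. = FALSE)
  }
  n <- nrow(poly)
  for (i in seq_len(n)) {
    i2 <- if (i == n) 1L else i + 1L
    for (j in seq_len(n)) {
      if (j <= i) next
      j2 <- if (j == n) 1L else j + 1L
      # skip adjacent edges (share a vertex)
      if (i2 == j || j2 == i || (i == 1L && j == n)) next
      if (.segments_intersect(poly[i, 1], poly[i, 2], poly[i2, 1], poly[i2, 2],
                              poly[j, 1], poly[j, 2], poly[j2, 1], poly[j2, 2])) {
        stop("gate polygon is self-intersecting", call. = FALSE)
      }
    }
  }
  invisible(poly)
}

# Even-odd point-in-polygon test with the boundary counted as inside.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  m <- length(px)
  inside <- logical(m)
  for (k in seq_len(m)) {
    x <- px[k]; y <- py[k]
    on_bd <- FALSE
    inv <- FALSE
    j <- n
    for (i in seq_len(n)) {
      if (.on_segment(xs[j], ys[j], xs[i], ys[i], x, y)) {
        on_bd <- TRUE
        break
      }
      if ((ys[i] > y) != (ys[j] > y)) {
        xint <- xs[i] + (y - ys[i]) / (ys[j] - ys[i]) * (xs[j] - xs[i])
        if (x < xint) inv <- !inv
      }
      j <- i
    }
    inside[k] <- on_bd || inv
  }
  inside
}
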