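#' Mean signal-plus-background in a region
#'
#' Mean of dark-subtracted pixel intensities over a mask; pixels below the
#' dark offset clip to zero. This is the raw signal-plus-background level;
#' subtract an estimated background (see
#' [estimate_background_components()]) to obtain signal.
#'
#' @param image Numeric matrix.
#' @param signal_mask Logical matrix, nonempty.
#' @param dark_offset Constant instrument level to subtract.
#' @return Mean intensity (scalar).
#' @export
estimate_signal <- function(image, signal_mask, dark_offset = 0) {
  stopifnot(is.matrix(image), is.matrix(signal_mask) || is.logical(signal_mask))
  check_scalar(dark_offset, "dark_offset", lower = 0)
  if (!any(signal_mask)) stop("signal mask is empty", call. = FALSE)
  mean(pmax(image[signal_mask] - dark_offset, 0))
}

#' Decompose background into AF, NSD and NSA components
#'
#' Sequential subtraction over matched control images:
#' autofluorescence (AF) from the unstained control, nonspecific
#' amplification (NSA) from the hairpins-only control (no probes, so any
#' excess over AF is nonspecifically bound single hairpins), and
#' nonspecific detection (NSD) from a non-expressing region of the
#' experiment itself. Component estimates are clipped at zero with a
#' warning. A missing control leaves its component (and every component
#' downstream of it) unresolved — reported as `NA`, never silently zero.
#'
#' Autofluorescence varies across the field, so control means are taken
#' over the region the background estimate will be applied to: pass the
#' signal region as `region` when the result feeds a signal-to-background
#' or gain estimate. The NSD step is always region-matched internally — AF
#' and NSA are re-measured on the non-expressing mask before subtraction —
#' so spatial AF structure does not leak into NSD.
#'
#' @param experiment Experiment image (matrix).
#' @param unstained Unstained control image, or `NULL` if unavailable.
#' @param hairpins_only Hairpins-only control image, or `NULL`.
#' @param nonexpressing_mask Logical matrix marking pixels free of target
#'   expression in the experiment.
#' @param dark_offset Constant instrument level.
#' @param region Logical matrix: region over which the reported AF and NSA
#'   means are measured (default the whole image).
#' @return Object of class `qhcr_sb_components`: `AF`, `NSA`, `NSD`,
#'   `background_total` (their sum; `NA` if any component is unresolved)
#'   and `unresolved` (character vector of missing components).
#' @export
estimate_background_components <- function(experiment, unstained = NULL,
                                           hairpins_only = NULL,
                                           nonexpressing_mask = NULL,
                                           dark_offset = 0, region = NULL) {
  stopifnot(is.matrix(experiment))
  check_scalar(dark_offset, "dark_offset", lower = 0)
  if (is.null(region)) region <- array(TRUE, dim(experiment))
  stopifnot(identical(dim(region), dim(experiment)), any(region))
  unresolved <- character()
  clip0 <- function(x, name) {
    if (is.na(x)) return(x)
    if (x < 0) {
      warning(sprintf("%s component estimate %.4g clipped to 0", name, x),
              call. = FALSE)
      x <- 0
    }
    x
  }
  af_in <- function(msk) mean(unstained[msk]) - dark_offset
  nsa_in <- function(msk) mean(hairpins_only[msk]) - dark_offset - af_in(msk)
  AF <- NA_real_; NSA <- NA_real_; NSD <- NA_real_
  if (!is.null(unstained)) {
    stopifnot(identical(dim(unstained), dim(experiment)))
    AF <- clip0(af_in(region), "AF")
  } else {
    unresolved <- c(unresolved, "AF")
  }
  if (!is.null(hairpins_only) && !is.na(AF)) {
    stopifnot(identical(dim(hairpins_only), dim(experiment)))
    NSA <- clip0(nsa_in(region), "NSA")
  } else {
    unresolved <- c(unresolved, "NSA")
  }
  if (!is.null(nonexpressing_mask) && !is.na(AF) && !is.na(NSA)) {
    stopifnot(identical(dim(nonexpressing_mask), dim(experiment)))
    if (!any(nonexpressing_mask)) {
      stop("non-expressing mask is empty", call. = FALSE)
    }
    NSD <- clip0(mean(experiment[nonexpressing_mask]) - dark_offset -
                   af_in(nonexpressing_mask) - nsa_in(nonexpressing_mask),
                 "NSD")
  } else {
    unresolved <- c(unresolved, "NSD")
  }
  total <- if (length(unresolved)) NA_real_ else AF + NSD + NSA
  structure(list(AF = AF, NSD = NSD, NSA = NSA,
                 background_total = total, unresolved = unresolved),
            class = "qhcr_sb_components")
}

#' @export
print.qhcr_sb_components <- function(x, digits = 4, ...) {
  cat("qHCR background components (intensity units)\n")
  cat(sprintf("  AF  %s\n  NSD %s\n  NSA %s\n  total %s\n",
              format(x$AF, digits = digits), format(x$NSD, digits = digits),
              format(x$NSA, digits = digits),
              format(x$background_total, digits = digits)))
  if (length(x$unresolved)) {
    cat("  unresolved (missing control):",
        paste(x$unresolved, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Signal-to-background ratio
#'
#' Background-subtracted signal over total background for one channel. The
#' signal mean is [estimate_signal()] minus `background_total`; a negative
#' difference clips to zero with a warning.
#'
#' @param experiment Experiment image (matrix).
#' @param signal_mask Logical matrix marking signal pixels.
#' @param sb_components An [estimate_background_components()] result (with
#'   all components resolved), or a single nonnegative number taken as
#'   `background_total`.
#' @param dark_offset Constant instrument level.
#' @return Object of class `qhcr_sb`: `signal_mean`, `background_total`,
#'   `components`, `ratio`.
#' @export
signal_to_background <- function(experiment, signal_mask, sb_components,
                                 dark_offset = 0) {
  if (is.numeric(sb_components) && length(sb_components) == 1L) {
    sb_components <- structure(
      list(AF = NA_real_, NSD = NA_real_, NSA = NA_real_,
           background_total = sb_components, unresolved = character()),
      class = "qhcr_sb_components")
  }
  stopifnot(inherits(sb_components, "qhcr_sb_components"))
  total <- sb_components$background_total
  if (is.na(total) || length(sb_components$unresolved)) {
    stop("background components unresolved: cannot form a ratio",
         call. = FALSE)
  }
  if (total <= 0) {
    stop("background_total must be > 0: ratio undefined", call. = FALSE)
  }
  sig <- estimate_signal(experiment, signal_mask, dark_offset) - total
  if (sig < 0) {
    warning(sprintf("background-subtracted signal %.4g clipped to 0", sig),
            call. = FALSE)
    sig <- 0
  }
  structure(list(signal_mean = sig, background_total = total,
                 components = sb_components, ratio = sig / total),
            class = "qhcr_sb")
}

#' @export
print.qhcr_sb <- function(x, digits = 4, ...) {
  cat(sprintf("qHCR signal-to-background: SIG %s / BG %s = %s\n",
              format(x$signal_mean, digits = digits),
              format(x$background_total, digits = digits),
              format(x$ratio, digits = digits)))
  invisible(x)
}

#' Estimate HCR amplification gain (mean polymer length)
#'
#' Compares background-subtracted signal between a paired-hairpin
#' experiment (h1 + h2, polymerization proceeds) and a matched h1-only
#' experiment (each initiator binds a single hairpin, so the signal is one
#' hairpin per initiator). Their ratio is the mean number of hairpins per
#' polymer — the amplification gain — assuming equal fluorophores per
#' hairpin in both arms. Background is subtracted per arm.
#'
#' @param paired_img Paired-hairpin experiment image.
#' @param h1_only_img Matched h1-only image.
#' @param signal_mask Logical matrix applicable to both images.
#' @param sb_paired,sb_h1only Background for each arm: an
#'   [estimate_background_components()] result or a single number
#'   (`background_total`); 0 for background-free simulations.
#' @param dark_offset Constant instrument level.
#' @return List of class `qhcr_gain_entry`: `signal_paired`,
#'   `signal_h1_only`, `gain` (hairpins per polymer).
#' @export
estimate_gain <- function(paired_img, h1_only_img, signal_mask,
                          sb_paired = 0, sb_h1only = 0, dark_offset = 0) {
  bg_of <- function(x) {
    if (inherits(x, "qhcr_sb_components")) {
      if (length(x$unresolved)) {
        stop("background components unresolved in a gain arm", call. = FALSE)
      }
      x$background_total
    } else {
      check_scalar(x, "background", lower = 0)
      x
    }
  }
  sp <- estimate_signal(paired_img, signal_mask, dark_offset) -
    bg_of(sb_paired)
  sh <- estimate_signal(h1_only_img, signal_mask, dark_offset) -
    bg_of(sb_h1only)
  if (sh <= 0) {
    stop("nonpositive h1-only signal: amplification gain unidentifiable",
         call. = FALSE)
  }
  structure(list(signal_paired = sp, signal_h1_only = sh, gain = sp / sh),
            class = "qhcr_gain_entry")
}

#' Median amplification gain across scenarios
#'
#' @param entries List of [estimate_gain()] entries, or a numeric vector of
#'   gains. For an even count the median is the mean of the middle two.
#' @return Median gain in hairpins per polymer.
#' @export
median_gain <- function(entries) {
  if (is.list(entries)) {
    if (inherits(entries, "qhcr_gain_entry")) entries <- list(entries)
    entries <- vapply(entries, function(e) {
      if (inherits(e, "qhcr_gain_entry")) e$gain else as.numeric(e)
    }, 0)
  }
  if (length(entries) < 1L) stop("no gain entries", call. = FALSE)
  stats::median(as.numeric(entries))
}

#' Crowding diagnostic: density-stratified slope consistency
#'
#' A systematic crowding effect (e.g. saturation at high local polymer
#' density) could let pairwise voxel intensities slide along a line and
#' mimic linearity. This diagnostic stratifies the masked voxels into
#' quantile bins of total intensity `(x1 + x2)`, fits the TLS slope within
#' each stratum, and flags the comparison when any stratum slope deviates
#' from the global slope by more than `threshold` (relative).
#'
#' @param ch1,ch2 Normalized [bin_voxels()] grids (or numeric vectors).
#' @param mask Logical mask of voxels to analyze; at least
#'   `n_strata * 10` voxels must be masked.
#' @param n_strata Number of quantile strata (>= 2, default 4).
#' @param threshold Relative slope deviation that triggers the flag
#'   (default 0.2).
#' @return Object of class `qhcr_crowding`: `strata` (data frame with
#'   intensity range, slope and voxel count per stratum; slope `NA` for
#'   degenerate strata that were dropped), `slope_all`,
#'   `max_rel_slope_dev`, `flagged`, `dropped_strata`.
#' @export
crowding_diagnostic <- function(ch1, ch2, mask = NULL, n_strata = 4,
                                threshold = 0.2) {
  check_scalar(n_strata, "n_strata", lower = 2, integer = TRUE)
  check_scalar(threshold, "threshold", lower = 0)
  g1 <- if (inherits(ch1, "qhcr_voxels")) ch1$intensities else ch1
  g2 <- if (inherits(ch2, "qhcr_voxels")) ch2$intensities else ch2
  if (is.null(mask)) mask <- rep(TRUE, length(g1))
  x <- as.numeric(g1)[as.logical(mask)]
  y <- as.numeric(g2)[as.logical(mask)]
  n <- length(x)
  if (n < n_strata * 10) {
    stop(sprintf("need at least %d masked voxels for %d strata, got %d",
                 n_strata * 10, n_strata, n), call. = FALSE)
  }
  slope_all <- tls_line(x, y)$slope
  tot <- x + y
  brks <- unique(stats::quantile(tot, probs = seq(0, 1, length.out = n_strata + 1)))
  bin <- cut(tot, breaks = brks, include.lowest = TRUE)
  levs <- levels(bin)
  slopes <- rep(NA_real_, length(levs))
  lo <- hi <- numeric(length(levs))
  nvox <- integer(length(levs))
  for (s in seq_along(levs)) {
    in_s <- which(bin == levs[s])
    nvox[s] <- length(in_s)
    lo[s] <- if (nvox[s]) min(tot[in_s]) else NA_real_
    hi[s] <- if (nvox[s]) max(tot[in_s]) else NA_real_
    if (nvox[s] >= 2 && stats::sd(x[in_s]) > 0 && stats::sd(y[in_s]) > 0) {
      slopes[s] <- tls_line(x[in_s], y[in_s])$slope
    }
  }
  dropped <- which(is.na(slopes))
  devs <- abs(slopes - slope_all) / abs(slope_all)
  max_dev <- if (all(is.na(devs))) NA_real_ else max(devs, na.rm = TRUE)
  structure(list(strata = data.frame(lower = lo, upper = hi,
                                     slope = slopes, n_voxels = nvox),
                 slope_all = slope_all,
                 max_rel_slope_dev = max_dev,
                 flagged = isTRUE(max_dev > threshold),
                 threshold = threshold,
                 dropped_strata = dropped),
            class = "qhcr_crowding")
}

#' @export
print.qhcr_crowding <- function(x, digits = 4, ...) {
  cat(sprintf("qHCR crowding diagnostic: global slope %s, max relative deviation %s\n",
              format(x$slope_all, digits = digits),
              format(x$max_rel_slope_dev, digits = digits)))
  print(x$strata, digits = digits)
  cat(if (x$flagged) {
    sprintf("FLAGGED: stratum slope deviates > %g from global\n", x$threshold)
  } else {
    "no crowding signature detected\n"
  })
  if (length(x$dropped_strata)) {
    cat("  dropped degenerate strata:",
        paste(x$dropped_strata, collapse = ", "), "\n")
  }
  invisible(x)
}
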