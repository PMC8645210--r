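#' Generate a ground-truth target map
#'
#' Places `n_cells` axis-aligned elliptical cells in the field and fills
#' them with target molecules according to the configured abundance law.
#' Each unique `target_id` among the channels gets its own molecule field;
#' channels sharing a `target_id` (redundant detection) share one field.
#' Where cells overlap, the later-placed cell overwrites labels and counts.
#'
#' @param config A [sim_config()] object.
#' @param cells Optional explicit cell table overriding random placement: a
#'   data frame with columns `row`, `col` (centre, 1-based pixel units),
#'   `ry`, `rx` (semi-axes in pixels). Densities are still drawn from the
#'   abundance law.
#' @return An object of class `qhcr_truth`: list with `molecule_counts`
#'   (named list of integer matrices, one per unique target), `cell_labels`
#'   (integer matrix, 0 = extracellular), `target_ids`, `pixel_size`.
#' @export
generate_truth <- function(config, cells = NULL) {
  stopifnot(inherits(config, "qhcr_config"))
  nr <- config$image_shape[1]; nc <- config$image_shape[2]
  targets <- unique(vapply(config$channels, `[[`, "", "target_id"))
  seeds <- derive_seeds(config$seed, 2L)
  labels <- matrix(0L, nr, nc)
  counts <- lapply(targets, function(t) matrix(0L, nr, nc))
  names(counts) <- targets

  if (config$n_cells > 0L || !is.null(cells)) {
    r_px <- config$cell_radius_um / config$pixel_size
    if (is.null(cells)) {
      cells <- with_seed(seeds[1], {
        ry <- stats::runif(config$n_cells, 0.7, 1.3) * r_px
        rx <- stats::runif(config$n_cells, 0.7, 1.3) * r_px
        if (2 * max(ry) + 1 > nr) {
          stop(sprintf("cell of semi-axis %.3g px cannot fit %d rows",
                       max(ry), nr), call. = FALSE)
        }
        if (2 * max(rx) + 1 > nc) {
          stop(sprintf("cell of semi-axis %.3g px cannot fit %d cols",
                       max(rx), nc), call. = FALSE)
        }
        data.frame(
          row = stats::runif(config$n_cells, 1 + ry, nr - ry),
          col = stats::runif(config$n_cells, 1 + rx, nc - rx),
          ry = ry, rx = rx
        )
      })
    } else {
      stopifnot(is.data.frame(cells),
                all(c("row", "col", "ry", "rx") %in% names(cells)))
    }

    law <- config$abundance_law
    n_cell <- nrow(cells)
    dens <- with_seed(seeds[2], {
      if (law$law == "deterministic") {
        matrix(law$density, n_cell, length(targets))
      } else {
        matrix(stats::rlnorm(n_cell * length(targets),
                             law$meanlog, law$sdlog),
               n_cell, length(targets))
      }
    })
    row_idx <- matrix(seq_len(nr), nr, nc)
    col_idx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    pix_seeds <- derive_seeds(seeds[2] + 1L, max(1L, n_cell))
    for (i in seq_len(n_cell)) {
      inside <- ((row_idx - cells$row[i]) / cells$ry[i])^2 +
        ((col_idx - cells$col[i]) / cells$rx[i])^2 <= 1
      npx <- sum(inside)
      if (npx == 0L) next
      labels[inside] <- i
      for (t in seq_along(targets)) {
        if (law$law == "deterministic") {
          counts[[t]][inside] <- as.integer(round(dens[i, t]))
        } else {
          counts[[t]][inside] <- with_seed(
            pix_seeds[i] + t, stats::rpois(npx, dens[i, t])
          )
        }
      }
    }
  }
  structure(list(molecule_counts = counts, cell_labels = labels,
                 target_ids = targets, pixel_size = config$pixel_size,
                 cells = cells),
            class = "qhcr_truth")
}

#' @export
print.qhcr_truth <- function(x, ...) {
  cat(sprintf("qHCR ground truth: %d x %d px, %d cell(s), targets: %s\n",
              nrow(x$cell_labels), ncol(x$cell_labels),
              length(unique(x$cell_labels[x$cell_labels > 0])),
              paste(x$target_ids, collapse = ", ")))
  for (t in x$target_ids) {
    cat(sprintf("  %s: %s molecules total\n", t,
                format(sum(x$molecule_counts[[t]]))))
  }
  invisible(x)
}

#' Simulate probe detection
#'
#' Converts a molecule-count field into a field of triggered HCR
#' initiators. Each molecule offers `initiators_per_probe` initiator slots;
#' each slot triggers independently with the channel's effective
#' probability: `binding_efficiency * (1 - interference)` for antibody
#' probes carrying a full initiator, and `binding_efficiency^2 *
#' (1 - interference)` for split-initiator pairs, where both half-probes
#' must bind adjacently to colocalize a functional initiator.
#'
#' @param molecules Integer matrix of molecules per pixel (a single target's
#'   field from [generate_truth()]), or a `qhcr_truth` object (the channel's
#'   target field is selected by `target_id`).
#' @param channel A [channel_spec()] object.
#' @param seed Integer seed.
#' @return Integer matrix of triggered initiators per pixel.
#' @export
simulate_detection <- function(molecules, channel, seed) {
  stopifnot(inherits(channel, "qhcr_channel"))
  if (inherits(molecules, "qhcr_truth")) {
    molecules <- molecules$molecule_counts[[channel$target_id]]
  }
  stopifnot(is.matrix(molecules), all(molecules >= 0))
  p <- effective_trigger_prob(channel)
  n_slots <- as.numeric(molecules) * channel$initiators_per_probe
  out <- with_seed(seed, stats::rbinom(length(n_slots), size = n_slots,
                                       prob = p))
  matrix(as.integer(out), nrow(molecules), ncol(molecules))
}

# Draw total hairpins for a vector of initiator counts. Geometric polymer
# length (support >= 1, mean m) is 1 + Geom0(p = 1/m); the sum over n
# initiators is n + NegBinomial(size = n, prob = 1/m).
sample_polymer_hairpins <- function(initiators, amp) {
  n <- as.numeric(initiators)
  if (amp$hairpin_mode == "h1_only") return(n)
  if (amp$length_law == "deterministic") return(n * amp$mean_polymer_length)
  p <- 1 / amp$mean_polymer_length
  extra <- numeric(length(n))
  pos <- n > 0
  if (any(pos)) {
    extra[pos] <- stats::rnbinom(sum(pos), size = n[pos], prob = p)
  }
  n + extra
}

#' Simulate HCR amplification
#'
#' Grows one amplification polymer per triggered initiator. Polymer length
#' in hairpins follows the channel's length law: geometric with support
#' ge 1 and the configured mean (mean `1/p`, variance `(1-p)/p^2` with
#' `p = 1/mean`), or deterministic. In `h1_only` mode each initiator binds
#' exactly one hairpin (polymerization cannot proceed), so the length is 1.
#'
#' @param initiators Matrix of triggered initiators per pixel (>= 0).
#' @param amp An [amplifier_params()] object.
#' @param seed Integer seed.
#' @return Numeric matrix of fluorophores per pixel
#'   (`hairpins * fluors_per_hairpin`).
#' @export
simulate_amplification <- function(initiators, amp, seed) {
  stopifnot(inherits(amp, "qhcr_amplifier"), is.matrix(initiators),
            all(initiators >= 0))
  hairpins <- with_seed(seed, sample_polymer_hairpins(initiators, amp))
  matrix(hairpins * amp$fluors_per_hairpin,
         nrow(initiators), ncol(initiators))
}

#' Simulate background components
#'
#' Generates the three background components for one channel, in
#' fluorophore-equivalent units, and their sum:
#' \describe{
#'   \item{AF}{autofluorescence: Gaussian-filtered white noise with mean
#'     `af_mean`, relative spread `af_rel_sd` and correlation length
#'     `af_corr_length`, clipped at zero.}
#'   \item{NSD}{nonspecific detection: `Poisson(nsd_rate)` probes per
#'     pixel. On antibody channels each carries a full initiator and is
#'     amplified under the channel's hairpin mode; on split-initiator
#'     channels a lone half-probe cannot trigger HCR and contributes only
#'     single-hairpin-scale signal.}
#'   \item{NSA}{nonspecific amplification: `Poisson(nsa_rate)` single
#'     hairpins per pixel (a nonspecifically bound hairpin never nucleates
#'     a polymer).}
#' }
#'
#' @param shape Integer `c(rows, cols)`.
#' @param channel A [channel_spec()] object.
#' @param seed Integer seed.
#' @param pixel_size Pixel size in micrometres (converts `af_corr_length`
#'   to pixels).
#' @return List with matrices `AF`, `NSD`, `NSA` and `total`
#'   (`AF + NSD + NSA`).
#' @export
simulate_background <- function(shape, channel, seed, pixel_size = 1) {
  stopifnot(inherits(channel, "qhcr_channel"), length(shape) == 2L)
  bg <- channel$background
  nr <- shape[1]; nc <- shape[2]
  seeds <- derive_seeds(seed, 4L)

  AF <- matrix(0, nr, nc)
  if (bg$af_mean > 0) {
    z <- with_seed(seeds[1], matrix(stats::rnorm(nr * nc), nr, nc))
    sigma_px <- bg$af_corr_length / pixel_size
    z <- gaussian_blur(z, sigma_px)
    s <- stats::sd(z)
    if (s > 0) z <- (z - mean(z)) / s
    AF <- pmax(bg$af_mean * (1 + bg$af_rel_sd * z), 0)
  }

  NSD <- matrix(0, nr, nc)
  if (bg$nsd_rate > 0) {
    probes <- with_seed(seeds[2],
                        matrix(stats::rpois(nr * nc, bg$nsd_rate), nr, nc))
    if (channel$probe_kind == "antibody_full_initiator") {
      init <- probes * channel$initiators_per_probe
      NSD <- simulate_amplification(init, channel$amplifier, seeds[3])
    } else {
      # lone half-probes: single-hairpin-scale contribution
      NSD <- probes * channel$amplifier$fluors_per_hairpin
    }
  }

  NSA <- matrix(0, nr, nc)
  if (bg$nsa_rate > 0) {
    NSA <- with_seed(seeds[4],
                     matrix(stats::rpois(nr * nc, bg$nsa_rate), nr, nc)) *
      channel$amplifier$fluors_per_hairpin
  }

  list(AF = AF, NSD = NSD, NSA = NSA, total = AF + NSD + NSA)
}

#' Render a fluorophore field to a camera image
#'
#' Microscope forward model: the total fluorophore field (signal plus
#' background) is convolved with a Gaussian PSF (`sigma` in pixels =
#' `psf_sigma / pixel_size`), converted to photons by `photon_scale`,
#' subjected to Poisson shot noise if enabled, then Gaussian read noise and
#' the constant dark offset are added and the image is clipped at zero.
#'
#' @param fluor Matrix of signal fluorophores per pixel.
#' @param background Matrix of background fluorophores per pixel (same
#'   shape), or `NULL` for none.
#' @param optics An [optics_params()] object.
#' @param seed Integer seed (used only when noise is enabled).
#' @param pixel_size Pixel size in micrometres.
#' @return Numeric matrix of camera counts.
#' @export
render_channel <- function(fluor, background = NULL, optics = optics_params(),
                           seed = 1L, pixel_size = 1) {
  stopifnot(inherits(optics, "qhcr_optics"), is.matrix(fluor))
  total <- fluor
  if (!is.null(background)) {
    if (!identical(dim(fluor), dim(background))) {
      stop("signal and background fields must have the same shape",
           call. = FALSE)
    }
    total <- total + background
  }
  total <- gaussian_blur(total, optics$psf_sigma / pixel_size)
  photons <- total * optics$photon_scale
  seeds <- derive_seeds(seed, 2L)
  if (optics$shot_noise) {
    photons <- with_seed(seeds[1],
                         matrix(stats::rpois(length(photons),
                                             pmax(photons, 0)),
                                nrow(photons), ncol(photons)))
  }
  if (optics$read_noise_sd > 0) {
    photons <- photons + with_seed(seeds[2],
                                   matrix(stats::rnorm(length(photons),
                                                       sd = optics$read_noise_sd),
                                          nrow(photons), ncol(photons)))
  }
  pmax(photons + optics$dark_offset, 0)
}

#' Simulate a full qHCR experiment
#'
#' Composes the whole pipeline for every channel — truth, detection,
#' amplification, background, rendering — and renders the matched control
#' images from the same truth and per-stage seeds:
#' \describe{
#'   \item{unstained}{autofluorescence only (plus dark offset / noise).}
#'   \item{hairpins_only}{autofluorescence + nonspecific amplification (no
#'     probes, so no signal and no NSD).}
#'   \item{h1_only}{the full experiment with every amplifier forced to
#'     `h1_only` mode: one hairpin per initiator, NSD amplification
#'     suppressed likewise.}
#' }
#'
#' @param config A [sim_config()] object. Redundant-pair analyses require
#'   exactly two channels sharing one `target_id`.
#' @param cells Optional explicit cell table, see [generate_truth()].
#' @return A list of class `qhcr_experiment`: `stack` (the rendered
#'   [qhcr_stack()]), `truth`, `controls` (named list of stacks:
#'   `unstained`, `hairpins_only`, `h1_only`), `components` (per channel,
#'   the AF/NSD/NSA fluorophore fields and the signal fluorophore field),
#'   and `config`.
#' @export
simulate_experiment <- function(config, cells = NULL) {
  stopifnot(inherits(config, "qhcr_config"))
  truth <- generate_truth(config, cells = cells)
  n_ch <- length(config$channels)
  # substreams: 1 for truth (consumed inside generate_truth via config$seed),
  # then 4 per channel: detection, amplification, background, render
  seeds <- matrix(derive_seeds(config$seed + 1L, 4L * n_ch), nrow = 4L)
  shape <- config$image_shape
  ps <- config$pixel_size

  imgs <- ctrl_unst <- ctrl_hp <- ctrl_h1 <- vector("list", n_ch)
  comps <- vector("list", n_ch)
  for (i in seq_len(n_ch)) {
    ch <- config$channels[[i]]
    init <- simulate_detection(truth, ch, seeds[1, i])
    fluor <- simulate_amplification(init, ch$amplifier, seeds[2, i])
    bg <- simulate_background(shape, ch, seeds[3, i], pixel_size = ps)

    # h1-only arm: same initiators, same stage seeds, amplification (signal
    # and NSD alike) forced to single-hairpin mode
    ch_h1 <- ch
    ch_h1$amplifier$hairpin_mode <- "h1_only"
    fluor_h1 <- simulate_amplification(init, ch_h1$amplifier, seeds[2, i])
    bg_h1 <- simulate_background(shape, ch_h1, seeds[3, i], pixel_size = ps)

    zero <- matrix(0, shape[1], shape[2])
    imgs[[i]] <- render_channel(fluor, bg$total, config$optics,
                                seeds[4, i], ps)
    ctrl_unst[[i]] <- render_channel(zero, bg$AF, config$optics,
                                     seeds[4, i], ps)
    ctrl_hp[[i]] <- render_channel(zero, bg$AF + bg$NSA, config$optics,
                                   seeds[4, i], ps)
    ctrl_h1[[i]] <- render_channel(fluor_h1, bg_h1$total, config$optics,
                                   seeds[4, i], ps)
    comps[[i]] <- list(signal_fluor = fluor, signal_fluor_h1 = fluor_h1,
                       initiators = init,
                       AF = bg$AF, NSD = bg$NSD, NSA = bg$NSA)
  }
  ch_names <- names(config$channels)
  names(comps) <- ch_names
  mk <- function(lst) qhcr_stack(stats::setNames(lst, ch_names), ps)
  structure(list(stack = mk(imgs), truth = truth,
                 controls = list(unstained = mk(ctrl_unst),
                                 hairpins_only = mk(ctrl_hp),
                                 h1_only = mk(ctrl_h1)),
                 components = comps, config = config),
            class = "qhcr_experiment")
}

#' @export
print.qhcr_experiment <- function(x, ...) {
  cat("qHCR synthetic experiment\n")
  print(x$config)
  invisible(x)
}
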