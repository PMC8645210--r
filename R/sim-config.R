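#' Amplifier parameters
#'
#' Describes the HCR amplification polymer for one channel. Polymer length is
#' the number of fluorophore-labeled hairpins incorporated per triggered
#' initiator. Under the paired-hairpin mode (h1 + h2) the polymer grows to a
#' random (geometric, support >= 1) or fixed (deterministic) length; under
#' `h1_only` each initiator binds exactly one hairpin and polymerization
#' cannot proceed, so the realized length is 1 regardless of `length_law`.
#'
#' @param mean_polymer_length Mean polymer length in hairpins (>= 1).
#' @param length_law `"geometric"` (memoryless hairpin addition, support
#' ge 1) or `"deterministic"` (every polymer exactly `mean_polymer_length`
#'   hairpins, which must then be an integer).
#' @param fluors_per_hairpin Fluorophores carried per hairpin (>= 1).
#' @param hairpin_mode `"paired"` (h1 + h2, full amplification) or
#'   `"h1_only"` (single hairpin per initiator).
#' @return An object of class `qhcr_amplifier`.
#' @export
amplifier_params <- function(mean_polymer_length = 180,
                             length_law = c("geometric", "deterministic"),
                             fluors_per_hairpin = 1,
                             hairpin_mode = c("paired", "h1_only")) {
  length_law <- match.arg(length_law)
  hairpin_mode <- match.arg(hairpin_mode)
  check_scalar(mean_polymer_length, "mean_polymer_length", lower = 1)
  check_scalar(fluors_per_hairpin, "fluors_per_hairpin", lower = 1,
               integer = TRUE)
  if (length_law == "deterministic" &&
      abs(mean_polymer_length - round(mean_polymer_length)) > 1e-9) {
    stop("deterministic 'mean_polymer_length' must be an integer",
         call. = FALSE)
  }
  structure(list(mean_polymer_length = mean_polymer_length,
                 length_law = length_law,
                 fluors_per_hairpin = as.integer(fluors_per_hairpin),
                 hairpin_mode = hairpin_mode),
            class = "qhcr_amplifier")
}

#' Background parameters
#'
#' Three background components in fluorophore-equivalent units:
#' autofluorescence (AF), a smooth nonnegative random field; nonspecific
#' detection (NSD), probes bound off-target at a Poisson per-pixel rate; and
#' nonspecific amplification (NSA), single hairpins bound off-target at a
#' Poisson per-pixel rate. NSD is amplified for antibody channels (a
#' nonspecifically bound antibody probe still carries a full initiator) but
#' stays at single-hairpin scale for split-initiator channels, where an
#' individual half-probe cannot colocalize a functional initiator.
#'
#' @param af_mean Mean autofluorescence, fluorophore equivalents per pixel.
#' @param af_corr_length Autofluorescence correlation length, micrometres.
#' @param nsd_rate Nonspecifically bound probes per pixel (Poisson mean).
#' @param nsa_rate Nonspecifically bound single hairpins per pixel
#'   (Poisson mean).
#' @param af_rel_sd Relative standard deviation of the autofluorescence
#'   field around `af_mean` (the field is clipped at zero).
#' @return An object of class `qhcr_background`.
#' @export
background_params <- function(af_mean = 0, af_corr_length = 0,
                              nsd_rate = 0, nsa_rate = 0,
                              af_rel_sd = 0.3) {
  check_scalar(af_mean, "af_mean", lower = 0)
  check_scalar(af_corr_length, "af_corr_length", lower = 0)
  check_scalar(nsd_rate, "nsd_rate", lower = 0)
  check_scalar(nsa_rate, "nsa_rate", lower = 0)
  check_scalar(af_rel_sd, "af_rel_sd", lower = 0)
  structure(list(af_mean = af_mean, af_corr_length = af_corr_length,
                 nsd_rate = nsd_rate, nsa_rate = nsa_rate,
                 af_rel_sd = af_rel_sd),
            class = "qhcr_background")
}

#' Optics and camera parameters
#'
#' Forward model of the microscope: Gaussian point spread function,
#' conversion from fluorophores to camera counts, Poisson shot noise,
#' additive Gaussian read noise and a constant instrument dark offset. With
#' `shot_noise = FALSE` and `read_noise_sd = 0` rendering is deterministic
#' given the fluorophore field.
#'
#' @param psf_sigma PSF standard deviation, micrometres (>= 0).
#' @param photon_scale Camera counts per fluorophore.
#' @param read_noise_sd Read noise standard deviation, counts.
#' @param dark_offset Constant instrument level, counts (>= 0).
#' @param shot_noise Apply Poisson shot noise to photon counts?
#' @return An object of class `qhcr_optics`.
#' @export
optics_params <- function(psf_sigma = 0, photon_scale = 1,
                          read_noise_sd = 0, dark_offset = 0,
                          shot_noise = TRUE) {
  check_scalar(psf_sigma, "psf_sigma", lower = 0)
  check_scalar(photon_scale, "photon_scale", lower = 0)
  check_scalar(read_noise_sd, "read_noise_sd", lower = 0)
  check_scalar(dark_offset, "dark_offset", lower = 0)
  stopifnot(is.logical(shot_noise), length(shot_noise) == 1L)
  structure(list(psf_sigma = psf_sigma, photon_scale = photon_scale,
                 read_noise_sd = read_noise_sd, dark_offset = dark_offset,
                 shot_noise = shot_noise),
            class = "qhcr_optics")
}

#' Channel specification
#'
#' One imaging channel: the target it detects, the probe chemistry
#' (antibody probes carry a full HCR initiator; split-initiator probe pairs
#' must both bind adjacently to colocalize one), binding efficiency,
#' optional epitope interference between redundant probes, the amplifier and
#' the background model. For split-initiator pairs the effective trigger
#' probability is the product of the two half-probe efficiencies
#' (`binding_efficiency^2`).
#'
#' @param target_id Name of the detected target; two channels sharing a
#'   `target_id` detect the same molecule field (redundant detection).
#' @param probe_kind `"antibody_full_initiator"` or `"split_initiator_pair"`.
#' @param initiators_per_probe HCR initiators carried per bound probe (>= 1).
#' @param binding_efficiency Per-molecule binding probability in \[0, 1\]
#'   (per half-probe for split-initiator pairs).
#' @param interference Probability in \[0, 1\] that binding is blocked by the
#'   partner probe of a redundant pair competing for the epitope.
#' @param amplifier An [amplifier_params()] object.
#' @param background A [background_params()] object.
#' @return An object of class `qhcr_channel`.
#' @export
channel_spec <- function(target_id,
                         probe_kind = c("antibody_full_initiator",
                                        "split_initiator_pair"),
                         initiators_per_probe = 1,
                         binding_efficiency = 1,
                         interference = 0,
                         amplifier = amplifier_params(),
                         background = background_params()) {
  probe_kind <- match.arg(probe_kind)
  stopifnot(is.character(target_id), length(target_id) == 1L,
            nzchar(target_id))
  check_scalar(initiators_per_probe, "initiators_per_probe", lower = 1,
               integer = TRUE)
  check_scalar(binding_efficiency, "binding_efficiency", 0, 1)
  check_scalar(interference, "interference", 0, 1)
  stopifnot(inherits(amplifier, "qhcr_amplifier"),
            inherits(background, "qhcr_background"))
  structure(list(target_id = target_id, probe_kind = probe_kind,
                 initiators_per_probe = as.integer(initiators_per_probe),
                 binding_efficiency = binding_efficiency,
                 interference = interference,
                 amplifier = amplifier, background = background),
            class = "qhcr_channel")
}

# Effective per-(molecule x initiator-slot) trigger probability.
effective_trigger_prob <- function(channel) {
  p <- channel$binding_efficiency
  if (channel$probe_kind == "split_initiator_pair") p <- p^2
  p * (1 - channel$interference)
}

#' Simulation configuration
#'
#' Full description of one synthetic multichannel experiment: field
#' geometry, cell population, per-cell target abundance law, the channel
#' list and the shared optics. One master `seed` fixes all downstream
#' randomness, including the control images.
#'
#' @param image_shape Integer vector `c(rows, cols)` in pixels (each >= 1).
#' @param pixel_size Physical pixel size, micrometres (> 0).
#' @param n_cells Number of elliptical cells to place (>= 0).
#' @param abundance_law Per-cell molecule density law: either
#'   `list(law = "lognormal", meanlog =, sdlog =)` (density in
#'   molecules/pixel drawn per cell and target, per-pixel counts Poisson) or
#'   `list(law = "deterministic", density =)` (every cell pixel carries
#'   `round(density)` molecules exactly).
#' @param channels List of [channel_spec()] objects (>= 1).
#' @param optics An [optics_params()] object shared by all channels.
#' @param seed Master seed (integer).
#' @param cell_radius_um Nominal cell semi-axis, micrometres; realized
#'   semi-axes are drawn uniformly in +/- 30% of this.
#' @return An object of class `qhcr_config`.
#' @export
sim_config <- function(image_shape, pixel_size, n_cells,
                       abundance_law = list(law = "lognormal",
                                            meanlog = log(20), sdlog = 0.5),
                       channels, optics = optics_params(), seed = 1L,
                       cell_radius_um = 3) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 1),
            all(abs(image_shape - round(image_shape)) < 1e-9))
  check_scalar(pixel_size, "pixel_size", lower = 1e-12)
  check_scalar(n_cells, "n_cells", lower = 0, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  check_scalar(cell_radius_um, "cell_radius_um", lower = 1e-12)
  if (!is.list(abundance_law) || is.null(abundance_law$law) ||
      !abundance_law$law %in% c("lognormal", "deterministic")) {
    stop("abundance_law$law must be 'lognormal' or 'deterministic'",
         call. = FALSE)
  }
  if (abundance_law$law == "lognormal") {
    check_scalar(abundance_law$meanlog, "abundance_law$meanlog")
    check_scalar(abundance_law$sdlog, "abundance_law$sdlog", lower = 0)
  } else {
    check_scalar(abundance_law$density, "abundance_law$density", lower = 0)
  }
  if (inherits(channels, "qhcr_channel")) channels <- list(channels)
  stopifnot(length(channels) >= 1L,
            all(vapply(channels, inherits, TRUE, "qhcr_channel")),
            inherits(optics, "qhcr_optics"))
  if (is.null(names(channels)) || any(!nzchar(names(channels)))) {
    names(channels) <- make.unique(
      vapply(channels, `[[`, "", "target_id"), sep = "."
    )
  }
  structure(list(image_shape = as.integer(round(image_shape)),
                 pixel_size = pixel_size,
                 n_cells = as.integer(n_cells),
                 abundance_law = abundance_law,
                 channels = channels, optics = optics,
                 seed = as.integer(seed),
                 cell_radius_um = cell_radius_um),
            class = "qhcr_config")
}

#' @export
print.qhcr_config <- function(x, ...) {
  cat(sprintf("qHCR simulation config: %d x %d px (%.3g um/px), %d cells, %d channel(s)\n",
              x$image_shape[1], x$image_shape[2], x$pixel_size, x$n_cells,
              length(x$channels)))
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    cat(sprintf("  %s: %s, eff %.3g, amp %s mean %.4g (%s)\n",
                nm, ch$probe_kind, ch$binding_efficiency,
                ch$amplifier$length_law, ch$amplifier$mean_polymer_length,
                ch$amplifier$hairpin_mode))
  }
  invisible(x)
}

## ---- config <-> plain list (YAML/JSON echo) ------------------------------

#' Convert a simulation configuration to a plain nested list
#'
#' Strips classes so the configuration can be serialized to YAML or JSON
#' (the parameter echo every command-line run writes). Inverse of
#' [config_from_list()].
#'
#' @param config A [sim_config()] object.
#' @return A nested list of plain vectors.
#' @export
config_to_list <- function(config) {
  stopifnot(inherits(config, "qhcr_config"))
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  strip(config)
}

#' Build a simulation configuration from a plain list
#'
#' Inverse of the JSON/YAML parameter echo written by the command-line
#' interface: reconstructs a [sim_config()] from nested lists. Unknown keys
#' at any level are rejected.
#'
#' @param x Nested list, e.g. from [yaml::read_yaml()] or
#'   [jsonlite::read_json()].
#' @return A `qhcr_config` object.
#' @export
config_from_list <- function(x) {
  known_top <- c("image_shape", "pixel_size", "n_cells", "abundance_law",
                 "channels", "optics", "seed", "cell_radius_um")
  .reject_unknown(x, known_top, "config")
  chans <- lapply(x$channels, function(ch) {
    .reject_unknown(ch, c("target_id", "probe_kind", "initiators_per_probe",
                          "binding_efficiency", "interference", "amplifier",
                          "background"), "channel")
    amp <- ch$amplifier %||% list()
    .reject_unknown(amp, c("mean_polymer_length", "length_law",
                           "fluors_per_hairpin", "hairpin_mode"), "amplifier")
    bg <- ch$background %||% list()
    .reject_unknown(bg, c("af_mean", "af_corr_length", "nsd_rate",
                          "nsa_rate", "af_rel_sd"), "background")
    channel_spec(
      target_id = ch$target_id,
      probe_kind = ch$probe_kind %||% "antibody_full_initiator",
      initiators_per_probe = ch$initiators_per_probe %||% 1,
      binding_efficiency = ch$binding_efficiency %||% 1,
      interference = ch$interference %||% 0,
      amplifier = do.call(amplifier_params, amp),
      background = do.call(background_params, bg)
    )
  })
  opt <- x$optics %||% list()
  .reject_unknown(opt, c("psf_sigma", "photon_scale", "read_noise_sd",
                         "dark_offset", "shot_noise"), "optics")
  sim_config(
    image_shape = unlist(x$image_shape),
    pixel_size = x$pixel_size,
    n_cells = x$n_cells,
    abundance_law = x$abundance_law %||%
      list(law = "lognormal", meanlog = log(20), sdlog = 0.5),
    channels = chans,
    optics = do.call(optics_params, opt),
    seed = x$seed %||% 1L,
    cell_radius_um = x$cell_radius_um %||% 3
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.reject_unknown <- function(x, known, what) {
  extra <- setdiff(names(x), known)
  if (length(extra)) {
    stop(sprintf("unknown %s key(s): %s", what,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  invisible(NULL)
}
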