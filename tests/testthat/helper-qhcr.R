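# Brute-force total-least-squares oracle: grid search over line angle and
# intercept minimizing the orthogonal sum of squares, refined around the
# best cell. Independent of the package's eigendecomposition route.
brute_tls <- function(x, y, n_grid = 181, n_refine = 4) {
  osse <- function(theta, b) {
    m <- tan(theta)
    sum((y - b - m * x)^2) / (1 + m^2)
  }
  th_lo <- -pi / 2 + 0.01; th_hi <- pi / 2 - 0.01
  b_lo <- min(y) - diff(range(y)) - 1; b_hi <- max(y) + diff(range(y)) + 1
  best <- c(NA, NA); best_v <- Inf
  for (r in seq_len(n_refine)) {
    ths <- seq(th_lo, th_hi, length.out = n_grid)
    bs <- seq(b_lo, b_hi, length.out = n_grid)
    for (th in ths) for (b in bs) {
      v <- osse(th, b)
      if (v < best_v) { best_v <- v; best <- c(th, b) }
    }
    dth <- (th_hi - th_lo) / (n_grid - 1)
    db <- (b_hi - b_lo) / (n_grid - 1)
    th_lo <- best[1] - 2 * dth; th_hi <- best[1] + 2 * dth
    b_lo <- best[2] - 2 * db; b_hi <- best[2] + 2 * db
  }
  list(slope = tan(best[1]), intercept = best[2])
}

# Minimal deterministic channel: certain binding, fixed polymer length.
det_channel <- function(target = "t", length = 20, eff = 1,
                        kind = "antibody_full_initiator",
                        background = background_params()) {
  channel_spec(target, probe_kind = kind, binding_efficiency = eff,
               amplifier = amplifier_params(length, "deterministic"),
               background = background)
}

noise_free_optics <- function(psf_sigma = 0, dark = 0, scale = 1) {
  optics_params(psf_sigma = psf_sigma, photon_scale = scale,
                read_noise_sd = 0, dark_offset = dark, shot_noise = FALSE)
}

# Redundant-pair config used by several tests: two identical channels on
# one target, certain binding, deterministic amplification, noise off.
exact_pair_config <- function(seed = 1, shape = c(96, 96), n_cells = 6,
                              length = 20, psf = 0, noise = FALSE,
                              read_noise = 0, af = 0) {
  bg <- background_params(af_mean = af, af_corr_length = 1)
  sim_config(shape, pixel_size = 0.5, n_cells = n_cells,
             abundance_law = list(law = "lognormal", meanlog = log(20),
                                  sdlog = 0.5),
             channels = list(ch1 = det_channel("t", length, background = bg),
                             ch2 = det_channel("t", length, background = bg)),
             optics = optics_params(psf_sigma = psf, photon_scale = 1,
                                    read_noise_sd = read_noise,
                                    dark_offset = 0, shot_noise = noise),
             seed = seed, cell_radius_um = 4)
}
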