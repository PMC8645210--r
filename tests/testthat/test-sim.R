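test_that("ground truth handles empty fields, hand-countable cells and determinism", {
  cfg0 <- sim_config(c(8, 8), 0.5, 0, channels = det_channel(), seed = 3)
  tr0 <- generate_truth(cfg0)
  expect_true(all(tr0$molecule_counts[[1]] == 0))
  expect_true(all(tr0$cell_labels == 0))

  # one ellipse of semi-axes 1 px centred between four pixels: exactly the
  # 4 nearest pixel centres fall inside, at 5 molecules/pixel -> 20 total
  cfg <- sim_config(c(8, 8), 0.5, 1,
                    abundance_law = list(law = "deterministic", density = 5),
                    channels = det_channel(), seed = 3)
  tr <- generate_truth(cfg, cells = data.frame(row = 4.5, col = 4.5,
                                               ry = 1, rx = 1))
  expect_identical(sum(tr$cell_labels > 0), 4L)
  expect_identical(sum(tr$molecule_counts[[1]]), 20L)

  cfg2 <- sim_config(c(32, 32), 0.5, 4, channels = det_channel(), seed = 11)
  expect_identical(generate_truth(cfg2), generate_truth(cfg2))

  # a cell wider than the field names the offending dimension
  cfg3 <- sim_config(c(10, 200), 0.5, 1, channels = det_channel(),
                     seed = 1, cell_radius_um = 40)
  expect_error(generate_truth(cfg3), "rows")
})

test_that("detection follows the effective trigger probability", {
  mol <- matrix(10L, 2, 2)
  certain <- det_channel(eff = 1)
  expect_identical(simulate_detection(mol, certain, 1), matrix(10L, 2, 2))

  blocked <- channel_spec("t", binding_efficiency = 1, interference = 1)
  expect_true(all(simulate_detection(mol, blocked, 1) == 0))

  # split-initiator pair: both halves must bind, p_eff = 0.5^2 = 0.25
  split <- channel_spec("t", probe_kind = "split_initiator_pair",
                        binding_efficiency = 0.5)
  big <- matrix(10000L, 1, 1)
  draws <- vapply(1:100, function(s) simulate_detection(big, split, s)[1, 1], 0L)
  se <- sqrt(10000 * 0.25 * 0.75) / sqrt(100)
  expect_lt(abs(mean(draws) - 2500), 3 * se)

  expect_error(channel_spec("t", binding_efficiency = 1.2), "binding_efficiency")
})

test_that("amplification honours h1-only, deterministic and geometric laws", {
  init <- matrix(c(7L, 0L), 1, 2)
  h1 <- amplifier_params(180, "geometric", hairpin_mode = "h1_only")
  expect_equal(simulate_amplification(init, h1, 1), matrix(c(7, 0), 1, 2))

  det <- amplifier_params(180, "deterministic")
  expect_equal(simulate_amplification(matrix(1L), det, 1), matrix(180))

  # geometric mean 50: one pixel with 1e4 initiators, mean length within 3 SE
  geo <- amplifier_params(50, "geometric")
  tot <- simulate_amplification(matrix(10000L), geo, 7)[1, 1]
  se <- sqrt((1 - 1 / 50) / (1 / 50)^2 / 10000)
  expect_lt(abs(tot / 10000 - 50), 3 * se)

  expect_error(amplifier_params(0.5), "mean_polymer_length")
})

test_that("geometric length sampler matches closed-form mean and variance", {
  p <- 1 / 40
  draws <- simulate_amplification(matrix(1L, 500, 200),
                                  amplifier_params(40, "geometric"), 12)
  n <- length(draws)
  expect_gte(n, 1e5)
  se_mean <- sqrt((1 - p) / p^2 / n)
  expect_lt(abs(mean(draws) - 1 / p), 3 * se_mean)
  # empirical SE of the variance from 20 batch estimates
  batches <- split(as.numeric(draws), rep(1:20, length.out = n))
  bvars <- vapply(batches, var, 0)
  se_var <- sd(bvars) / sqrt(20)
  expect_lt(abs(var(as.numeric(draws)) - (1 - p) / p^2), 3 * se_var)
})

test_that("background components respect rates and the suppression asymmetry", {
  quiet <- channel_spec("t")
  bg0 <- simulate_background(c(16, 16), quiet, 1)
  expect_true(all(bg0$total == 0) && all(bg0$AF == 0) &&
                all(bg0$NSD == 0) && all(bg0$NSA == 0))

  # antibody NSD is amplified (deterministic length 100); split NSD is not
  amp100 <- amplifier_params(100, "deterministic")
  bgp <- background_params(nsd_rate = 1)
  ab <- channel_spec("t", "antibody_full_initiator", amplifier = amp100,
                     background = bgp)
  sp <- channel_spec("t", "split_initiator_pair", amplifier = amp100,
                     background = bgp)
  bg_ab <- simulate_background(c(100, 100), ab, 5)
  bg_sp <- simulate_background(c(100, 100), sp, 5)
  expect_lt(abs(sum(bg_ab$NSD) - 1e6), 3 * 100 * sqrt(1e4))
  expect_lt(abs(sum(bg_sp$NSD) - 1e4), 3 * sqrt(1e4))

  af <- channel_spec("t", background = background_params(af_mean = 5,
                                                         af_corr_length = 2))
  bg_af <- simulate_background(c(100, 100), af, 9, pixel_size = 1)
  expect_lt(abs(mean(bg_af$AF) - 5), 0.05)
  expect_true(all(bg_af$AF >= 0))

  expect_error(background_params(nsd_rate = -1), "nsd_rate")
})

test_that("rendering applies dark offset, conserves PSF mass and scales photons", {
  zero <- matrix(0, 8, 8)
  img <- render_channel(zero, optics = noise_free_optics(dark = 100), seed = 1)
  expect_equal(img, matrix(100, 8, 8))

  # interior point source: convolution conserves total counts
  spot <- matrix(0, 65, 65); spot[33, 33] <- 1000
  out <- render_channel(spot, optics = noise_free_optics(psf_sigma = 3),
                        seed = 1, pixel_size = 1)
  expect_lt(abs(sum(out) - 1000) / 1000, 1e-6)

  one <- matrix(0, 5, 5); one[3, 3] <- 10
  got <- render_channel(one, optics = noise_free_optics(dark = 7, scale = 2),
                        seed = 1)
  expect_equal(got[3, 3], 27)
  expect_equal(got[1, 1], 7)
})

test_that("noise-free deterministic rendering is affine in molecule totals", {
  # certain binding + deterministic length: closed-form intensity budget
  L <- 15; Fh <- 2; scale <- 3; ipp <- 2; dark <- 50; af <- 4
  ch <- channel_spec("t", binding_efficiency = 1,
                     initiators_per_probe = ipp,
                     amplifier = amplifier_params(L, "deterministic",
                                                  fluors_per_hairpin = Fh))
  cfg <- sim_config(c(64, 64), 0.5, 5,
                    abundance_law = list(law = "lognormal",
                                         meanlog = log(10), sdlog = 0.4),
                    channels = ch,
                    optics = optics_params(psf_sigma = 1, photon_scale = scale,
                                           read_noise_sd = 0,
                                           dark_offset = dark,
                                           shot_noise = FALSE),
                    seed = 21, cell_radius_um = 3)
  exp1 <- simulate_experiment(cfg)
  total_mol <- sum(exp1$truth$molecule_counts[[1]])
  predicted <- (ipp * L * Fh * scale * total_mol) / 64^2 + dark
  expect_lt(abs(mean(exp1$stack$channels[[1]]) - predicted) / predicted, 1e-6)

  # psf = 0: the affine budget holds per arbitrary region too
  cfg$optics$psf_sigma <- 0
  exp2 <- simulate_experiment(cfg)
  region <- matrix(FALSE, 64, 64); region[10:40, 5:60] <- TRUE
  mol_r <- sum(exp2$truth$molecule_counts[[1]][region])
  pred_r <- (ipp * L * Fh * scale * mol_r) / sum(region) + dark
  expect_lt(abs(mean(exp2$stack$channels[[1]][region]) - pred_r) /
              pred_r, 1e-6)
})

test_that("experiments are deterministic and redundant pairs share truth", {
  cfg <- exact_pair_config(seed = 5, psf = 0.5)
  e1 <- simulate_experiment(cfg)
  e2 <- simulate_experiment(cfg)
  expect_identical(e1$stack, e2$stack)
  expect_identical(e1$controls, e2$controls)

  # identical channel specs with certain binding: channels equal exactly
  expect_equal(e1$stack$channels[[1]], e1$stack$channels[[2]])

  # unstained control is the AF component alone (noise off, dark 0)
  cfg_af <- exact_pair_config(seed = 5, af = 6)
  e3 <- simulate_experiment(cfg_af)
  expect_equal(e3$controls$unstained$channels[[1]],
               e3$components[[1]]$AF)

  # h1-only control carries ~1/length of the paired signal
  expect_equal(e1$controls$h1_only$channels[[1]] * 20,
               e1$stack$channels[[1]])
})
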