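test_that("signal estimation subtracts dark and clips below zero", {
  img <- matrix(110, 4, 4)
  all_m <- matrix(TRUE, 4, 4)
  expect_equal(estimate_signal(img, all_m, dark_offset = 10), 100)

  two <- matrix(c(40, 60, 0, 0), 2, 2)
  m2 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(estimate_signal(two, m2), 50)

  dim_img <- matrix(5, 3, 3)
  expect_equal(estimate_signal(dim_img, matrix(TRUE, 3, 3),
                               dark_offset = 10), 0)
  expect_error(estimate_signal(img, matrix(FALSE, 4, 4)), "empty")
})

test_that("background decomposition follows sequential subtraction", {
  m <- function(v) matrix(v, 10, 10)
  nonexpr <- matrix(TRUE, 10, 10)
  comp <- estimate_background_components(m(15), m(10), m(12), nonexpr)
  expect_equal(comp$AF, 10)
  expect_equal(comp$NSA, 2)
  expect_equal(comp$NSD, 3)
  expect_equal(comp$background_total, 15)
  # component additivity is exact
  expect_identical(comp$AF + comp$NSD + comp$NSA, comp$background_total)

  same <- estimate_background_components(m(8), m(8), m(8), nonexpr)
  expect_equal(same$NSA, 0)
  expect_equal(same$NSD, 0)

  # missing control: unresolved, never silently zero
  partial <- estimate_background_components(m(15), m(10), NULL, nonexpr)
  expect_equal(partial$AF, 10)
  expect_true(is.na(partial$NSA) && is.na(partial$NSD))
  expect_setequal(partial$unresolved, c("NSA", "NSD"))
  expect_true(is.na(partial$background_total))

  expect_warning(
    estimate_background_components(m(15), m(10), m(9), nonexpr),
    "clipped"
  )
})

test_that("background components are recovered from simulated controls", {
  ch <- channel_spec("t", binding_efficiency = 1,
                     amplifier = amplifier_params(20, "deterministic"),
                     background = background_params(af_mean = 20,
                                                    af_corr_length = 1,
                                                    nsd_rate = 0.5,
                                                    nsa_rate = 1))
  cfg <- sim_config(c(256, 256), 0.5, 6,
                    abundance_law = list(law = "lognormal",
                                         meanlog = log(25), sdlog = 0.4),
                    channels = list(ch1 = ch),
                    optics = optics_params(psf_sigma = 0.25, photon_scale = 1,
                                           read_noise_sd = 2,
                                           dark_offset = 50,
                                           shot_noise = TRUE),
                    seed = 7, cell_radius_um = 4)
  e <- simulate_experiment(cfg)
  cells <- e$truth$cell_labels > 0
  nonexpr <- !(EBImage::dilate(cells * 1,
                               EBImage::makeBrush(9, "disc")) > 0.5)
  comp <- estimate_background_components(
    e$stack$channels[[1]], e$controls$unstained$channels[[1]],
    e$controls$hairpins_only$channels[[1]], nonexpr, dark_offset = 50)
  expect_lt(abs(comp$AF - 20) / 20, 0.10)
  expect_lt(abs(comp$NSD - 0.5 * 20) / 10, 0.10)
  expect_lt(abs(comp$NSA - 1) / 1, 0.10)
})

test_that("signal-to-background forms the ratio and is scale invariant", {
  img <- matrix(101, 6, 6)
  all_m <- matrix(TRUE, 6, 6)
  sb <- signal_to_background(img, all_m, 1)
  expect_equal(sb$signal_mean, 100)
  expect_equal(sb$ratio, 100)

  flat <- signal_to_background(matrix(3, 6, 6), all_m, 3)
  expect_equal(flat$ratio, 0)

  expect_error(signal_to_background(img, all_m, 0), "background_total")

  set.seed(5)
  ximg <- matrix(rpois(400, 40), 20, 20)
  msk <- matrix(rep(c(TRUE, FALSE), each = 200), 20, 20)
  r1 <- signal_to_background(ximg, msk, 7)$ratio
  for (c_mult in c(0.25, 3, 1e4)) {
    rc <- signal_to_background(ximg * c_mult, msk, 7 * c_mult)$ratio
    expect_lt(abs(rc - r1) / r1, 1e-6)
  }
})

test_that("S/B grows with polymer length on split-initiator channels", {
  ratios <- vapply(c(5, 20, 80), function(L) {
    ch <- channel_spec("t", probe_kind = "split_initiator_pair",
                       binding_efficiency = 1,
                       amplifier = amplifier_params(L, "deterministic"),
                       background = background_params(af_mean = 10,
                                                      af_corr_length = 1,
                                                      nsd_rate = 0.5,
                                                      nsa_rate = 0.5))
    cfg <- sim_config(c(96, 96), 0.5, 4,
                      abundance_law = list(law = "deterministic", density = 10),
                      channels = list(ch1 = ch),
                      optics = noise_free_optics(psf_sigma = 0.25),
                      seed = 3, cell_radius_um = 4)
    e <- simulate_experiment(cfg)
    cells <- e$truth$cell_labels > 0
    nonexpr <- !(EBImage::dilate(cells * 1,
                                 EBImage::makeBrush(9, "disc")) > 0.5)
    comp <- estimate_background_components(
      e$stack$channels[[1]], e$controls$unstained$channels[[1]],
      e$controls$hairpins_only$channels[[1]], nonexpr, region = cells)
    signal_to_background(e$stack$channels[[1]], cells, comp)$ratio
  }, 0)
  expect_true(all(diff(ratios) > 0))
})

test_that("gain estimation divides paired by h1-only signal", {
  all_m <- matrix(TRUE, 3, 3)
  g <- estimate_gain(matrix(900, 3, 3), matrix(9, 3, 3), all_m)
  expect_equal(g$gain, 100)
  expect_error(estimate_gain(matrix(900, 3, 3), matrix(0, 3, 3), all_m),
               "unidentifiable")

  # deterministic length 180, no background, no noise: gain exact
  cfg <- exact_pair_config(seed = 19, shape = c(96, 96), n_cells = 5,
                           length = 180, psf = 0.4)
  e <- simulate_experiment(cfg)
  cells <- e$truth$cell_labels > 0
  gd <- estimate_gain(e$stack$channels[[1]],
                      e$controls$h1_only$channels[[1]], cells)
  expect_equal(gd$gain, 180, tolerance = 1e-9)
})

test_that("gain recovers a geometric mean length over many seeds", {
  gains <- vapply(1:20, function(s) {
    ch <- channel_spec("t", binding_efficiency = 0.6,
                       amplifier = amplifier_params(50, "geometric"))
    cfg <- sim_config(c(96, 96), 0.5, 5,
                      abundance_law = list(law = "lognormal",
                                           meanlog = log(25), sdlog = 0.4),
                      channels = list(ch1 = ch),
                      optics = optics_params(psf_sigma = 0.25,
                                             photon_scale = 1,
                                             read_noise_sd = 1,
                                             dark_offset = 0,
                                             shot_noise = TRUE),
                      seed = s, cell_radius_um = 4)
    e <- simulate_experiment(cfg)
    cells <- e$truth$cell_labels > 0
    estimate_gain(e$stack$channels[[1]],
                  e$controls$h1_only$channels[[1]], cells)$gain
  }, 0)
  se <- sd(gains) / sqrt(length(gains))
  expect_lt(abs(mean(gains) - 50), 3 * se)
})

test_that("median gain follows the even/odd count conventions", {
  expect_equal(median_gain(100), 100)
  expect_equal(median_gain(c(120, 180, 240)), 180)
  expect_equal(median_gain(c(100, 200)), 150)
  e1 <- structure(list(signal_paired = 900, signal_h1_only = 9, gain = 100),
                  class = "qhcr_gain_entry")
  e2 <- structure(list(signal_paired = 600, signal_h1_only = 3, gain = 200),
                  class = "qhcr_gain_entry")
  expect_equal(median_gain(list(e1, e2)), 150)
  expect_error(median_gain(numeric(0)), "no gain")
})

test_that("crowding diagnostic flags saturation but not linear data", {
  set.seed(3)
  x <- runif(400, 0.05, 1)
  lin <- crowding_diagnostic(x, 0.9 * x, n_strata = 4)
  expect_false(lin$flagged)
  expect_lt(lin$max_rel_slope_dev, 1e-9)

  y_sat <- pmin(x, 0.55) + rnorm(400, sd = 0.01)
  sat <- crowding_diagnostic(x, y_sat, n_strata = 4)
  expect_true(sat$flagged)

  expect_error(crowding_diagnostic(x[1:30], x[1:30], n_strata = 4),
               "at least 40")

  # a zero-variance stratum is dropped and reported, not fatal
  x2 <- c(rep(0.2, 50), runif(150, 0.4, 1))
  y2 <- c(rep(0.2, 50), 0.9 * runif(150, 0.4, 1))
  cd <- crowding_diagnostic(x2, y2, n_strata = 4)
  expect_true(length(cd$dropped_strata) >= 1)
})
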