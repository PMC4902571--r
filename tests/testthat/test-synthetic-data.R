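test_that("oligomer mixtures validate their invariants", {
  m <- oligomer_mixture(c(`1` = 0.5, `2` = 0.2, `4` = 0.3), p_dark = 0.3)
  expect_equal(sum(m$weights), 1, tolerance = 1e-9)
  expect_error(oligomer_mixture(c(`1` = 0.6, `2` = 0.3)), "sum to 1")
  expect_error(oligomer_mixture(c(`0` = 1)), "positive integers")
  expect_error(oligomer_mixture(c(`1` = 1), p_dark = 1.2), "probability")
})

test_that("spot fields at vanishing density are pure unmerged monomers", {
  fld <- sample_spot_field(oligomer_mixture(c(`1` = 1), p_dark = 0),
                           coloc_model(density = 0.001, merge_radius = 0.1),
                           field_size = 300, seed = 11)
  expect_true(all(fld$n_total == 1L))
  expect_true(all(fld$origin == "true_oligomer"))
  expect_true(all(fld$n_visible == fld$n_total))  # p_dark = 0: no loss
})

test_that("visible counts in a tetramer field follow the conditioned binomial", {
  fld <- sample_spot_field(oligomer_mixture(c(`4` = 1), p_dark = 0.3),
                           coloc_model(density = 0.01, merge_radius = 0.1),
                           field_size = 2000, seed = 12)
  # enumeration oracle: Binomial(4, 0.7) conditioned on >= 1 visible
  pk <- dbinom(1:4, 4, 0.7) / (1 - 0.3^4)
  obs <- tabulate(fld$n_visible, 4) / nrow(fld)
  for (k in 1:4)
    expect_fraction_close(obs[k], pk[k], nrow(fld),
                          label = paste("P(", k, "visible)"))
  expect_equal(sum(pk), 1, tolerance = 1e-12)
})

test_that("random colocalization produces the predicted two-step fraction", {
  mc <- coloc_two_step_mc(4, 0.1, p_dark = 0.3, field_size = 400, seed = 13)
  expect_equal(mc$analytic, 0.0308, tolerance = 0.002)
  expect_lt(abs(mc$per_spot - 0.03), 0.005)
  expect_equal(expected_pair_fraction(4, 0.1, 0), 0.0628, tolerance = 0.002)
  expect_error(expected_pair_fraction(30, 0.1, 0.3), "invalid")
})

test_that("pair-fraction formula matches Monte-Carlo within 3 SE at low crowding", {
  for (density in c(1, 3)) {
    mc <- coloc_two_step_mc(density, 0.1, p_dark = 0.3, field_size = 400,
                            seed = 20 + density)
    se <- sqrt(mc$analytic / mc$n_spots)
    expect_lt(abs(mc$per_spot - mc$analytic), 3 * se + 0.1 * mc$analytic)
  }
})

test_that("noiseless traces are exact staircases with ground-truth drops", {
  acq <- acq_params(shot = FALSE, read_sd = 0, unit_brightness = 100,
                    bleach_rate = 0.02)
  tr1 <- simulate_trace(1, acq, seed = 30)
  bf <- tr1$truth$bleach_frames[tr1$truth$bleach_frames < acq$n_frames]
  d1 <- diff(tr1$intensity)
  expect_equal(unique(d1[d1 != 0]), rep(-100, length(bf)))
  expect_equal(which(d1 != 0), bf)
  tr2 <- simulate_trace(2, acq, seed = 31)
  expect_equal(tr2$intensity[length(tr2$intensity)],
               100 * sum(tr2$truth$bleach_frames > acq$n_frames))
  drops <- tr2$truth$bleach_frames[tr2$truth$bleach_frames < acq$n_frames]
  expect_equal(sum(diff(tr2$intensity) != 0), length(unique(drops)))
  expect_error(simulate_trace(0, acq), "visible")
})

test_that("single-fluorophore bleach completion matches the closed form", {
  acq <- acq_params(shot = FALSE, read_sd = 0, bleach_rate = 0.005,
                    n_frames = 500)
  traces <- simulate_trace_set(rep(1L, 4000), acq, seed = 32)
  done <- vapply(traces, function(tr) tr$truth$bleach_frames <= 500, logical(1))
  expect_fraction_close(mean(done), 1 - 0.995^500, 4000, "bleached by end")
})

test_that("rendered movies conserve photon flux and honor the noise model", {
  acq <- acq_params(shot = FALSE, read_sd = 0, field_size = c(4, 4),
                    n_frames = 100, unit_brightness = 200, baseline = 0,
                    bleach_rate = 1e-4)
  fld <- data.frame(x = 2, y = 2, n_total = 3L, n_visible = 3L,
                    origin = "true_oligomer")
  mv <- render_movie(fld, acq, seed = 40)
  expect_equal(dim(mv$frames), c(40, 40, 100))
  expect_equal(sum(mv$frames[, , 1]), 3 * 200, tolerance = 1e-6)
  # empty field: pure-noise stack at the camera baseline
  acq2 <- acq_params(shot = FALSE, read_sd = 2, field_size = c(4, 4),
                     n_frames = 100, baseline = 50)
  mv2 <- render_movie(NULL, acq2, seed = 41)
  expect_equal(mean(mv2$frames), 50, tolerance = 0.1)
  expect_equal(sd(as.vector(mv2$frames)), 2, tolerance = 0.1)
  expect_error(render_movie(data.frame(x = 99, y = 2, n_visible = 1L), acq),
               "inside the field")
})

test_that("movies survive a TIFF write-read round trip", {
  acq <- acq_params(shot = FALSE, read_sd = 0, field_size = c(3, 3),
                    n_frames = 100, unit_brightness = 150)
  fld <- data.frame(x = 1.5, y = 1.5, n_visible = 2L)
  mv <- render_movie(fld, acq, seed = 42)
  path <- tempfile(fileext = ".tif")
  scale <- write_movie_tiff(mv, path)
  back <- read_movie_tiff(path, scale = scale, pixel_size = acq$pixel_size,
                          frame_rate = acq$frame_rate)
  expect_equal(dim(back$frames), dim(mv$frames))
  expect_lt(max(abs(back$frames - mv$frames)) / max(mv$frames), 1e-6)
  unlink(path)
})

test_that("photon streams respect PIE timing invariants", {
  cfg <- membrane_sim_config(duration = 2, n_in_focus = 3, crosstalk = 0.1,
                             background_rate = 500)
  st <- simulate_dual_color_streams(cfg, pie_config(), seed = 50)
  for (ch in list(st$green, st$red)) {
    expect_true(all(diff(ch$arrival_time_s) >= 0))
    expect_true(all(ch$microtime_ns >= 0 & ch$microtime_ns < 100))
  }
  expect_true(all(st$red$pulse_origin[st$red$origin_class == "crosstalk"] == "488"))
  expect_true(all(st$red$pulse_origin[st$red$origin_class == "signal"] == "561"))
})

test_that("autocorrelation decay time scales inversely with D", {
  half_decay <- function(D, seed) {
    cfg <- membrane_sim_config(diffusion_coeff = D, duration = 15,
                               n_in_focus = 5)
    st <- simulate_dual_color_streams(cfg, seed = seed)
    gt <- gate_photons(st$green, st$red, duration = 15)
    fit <- fit_2d_diffusion(multi_tau_correlate(gt$green, gt$green), 0.25)
    fit$tau_D
  }
  t1 <- half_decay(0.25, 60)
  t2 <- half_decay(0.50, 60)
  expect_gt(t1 / t2, 1.4)  # doubling D roughly halves tau_D
  expect_lt(t1 / t2, 2.9)
  # closed form: tau_D = w^2 / (4 D) = 31 ms at D = 0.5, w = 0.25
  expect_equal(t2, 0.25^2 / (4 * 0.5), tolerance = 0.35)
})
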