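# PIE gating, multi-tau correlation, diffusion fitting, fraction
# correlated, per-cell protocol and population summaries.

tiny_stream <- function(micro, origin, channel, t = seq_along(micro) * 1e-3) {
  data.frame(arrival_time_s = t, microtime_ns = micro, channel = channel,
             pulse_origin = origin)
}

test_that("gating rejects wrong-pulse photons inside the window only", {
  red <- tiny_stream(c(20, 20, 60), c("488", "561", "488"), "red_detector")
  green <- tiny_stream(c(20, 20), c("488", "561"), "green_detector")
  gt <- gate_photons(green, red, pie_config(), bin_width = 1e-3, duration = 0.01)
  # red: 20 ns after 488 rejected; 20 ns after 561 kept; 60 ns after 488 kept
  expect_equal(unname(gt$rejected["red"]), 1)
  expect_equal(sum(gt$red), 2)
  # green: 20 ns after 561 rejected, 20 ns after 488 kept
  expect_equal(unname(gt$rejected["green"]), 1)
  expect_equal(sum(gt$green), 1)
  expect_error(gate_photons(green[, 1:2], red, pie_config()), "pulse tags")
})

test_that("gating removes all in-window crosstalk photons from simulations", {
  cfg <- membrane_sim_config(duration = 3, n_in_focus = 4, crosstalk = 0.1)
  st <- simulate_dual_color_streams(cfg, seed = 70)
  n_cross <- sum(st$red$origin_class == "crosstalk")
  expect_gt(n_cross, 100)
  keep <- !(st$red$pulse_origin == "488" & st$red$microtime_ns < 50)
  expect_equal(sum(st$red$origin_class[keep] == "crosstalk"), 0)
  # surviving red trace: crosstalk fraction far below the injected 10%
  gt <- gate_photons(st$green, st$red, duration = 3)
  expect_lt(1 - sum(gt$red) / sum(keep & st$red$origin_class != "crosstalk") , 0.005)
})

test_that("multi-tau equals the direct-sum oracle on white-noise traces", {
  set.seed(71)
  a <- rpois(10000, 4)
  b <- rpois(10000, 3)
  got_auto <- multi_tau_correlate(a, a, bin_width = 1e-4, max_lag = 64e-4)
  got_cross <- multi_tau_correlate(a, b, bin_width = 1e-4, max_lag = 64e-4)
  want_auto <- direct_multi_tau(a, a, 1e-4, max_lag = 64e-4)
  want_cross <- direct_multi_tau(a, b, 1e-4, max_lag = 64e-4)
  expect_equal(got_auto$lag, want_auto$lag)
  expect_lt(max(abs(got_auto$G - want_auto$G)), 1e-12)
  expect_lt(max(abs(got_cross$G - want_cross$G)), 1e-12)
  # white noise: all positive lags are zero up to sampling error
  expect_lt(max(abs(got_auto$G[got_auto$lag > 1e-4])), 0.05)
})

test_that("constant signals have zero correlation and zero-mean traces error", {
  g <- multi_tau_correlate(rep(5, 5000), rep(5, 5000), 1e-4, max_lag = 0.01)
  expect_true(all(abs(g$G) < 1e-14))
  expect_error(multi_tau_correlate(rep(0, 5000), rep(0, 5000), 1e-4,
                                   max_lag = 0.01), "zero-mean")
  expect_error(multi_tau_correlate(1:100, 1:99, 1e-4), "equal length")
})

test_that("correlation amplitude reflects the in-focus particle number", {
  cfg <- membrane_sim_config(diffusion_coeff = 0.5, n_in_focus = 5,
                             duration = 15)
  st <- simulate_dual_color_streams(cfg, seed = 72)
  gt <- gate_photons(st$green, st$red, duration = 15)
  fit <- fit_2d_diffusion(multi_tau_correlate(gt$green), waist = 0.25)
  expect_equal(fit$G0, 0.2, tolerance = 0.15)
})

test_that("the 2D diffusion fit inverts noiseless model curves exactly", {
  lag <- exp(seq(log(1e-4), log(1), length.out = 80))
  curve <- data.frame(lag = lag, G = 0.2 / (1 + lag / 0.031))
  fit <- fit_2d_diffusion(curve, waist = 0.25)
  expect_equal(fit$G0, 0.2, tolerance = 1e-6)
  expect_equal(fit$tau_D, 0.031, tolerance = 1e-6)
  expect_equal(fit$D, 0.25^2 / (4 * 0.031), tolerance = 1e-5)
  expect_equal(fit$N_effective, 5, tolerance = 1e-5)
  # a non-decaying curve must be flagged, with no numbers reported
  flat <- data.frame(lag = lag, G = rep(0.001, 80) + 1e-5 * seq_len(80))
  fit2 <- fit_2d_diffusion(flat, waist = 0.25)
  expect_true(fit2$failed)
  expect_true(is.na(fit2$D))
  expect_error(fit_2d_diffusion(curve[1:10, ]), "20 lag points")
})

test_that("fraction correlated follows its amplitude definition", {
  expect_equal(as.numeric(fraction_correlated(0.1, 0.2, 0.25)), 0.4)
  expect_equal(as.numeric(fraction_correlated(0.1, 0.2, 0.25,
                                              denominator = "min")), 0.5)
  und <- fraction_correlated(0.1, -0.01, 0.2)
  expect_true(is.na(und))
  expect_equal(attr(und, "flag"), "undefined_autocorrelation")
})

test_that("f_c rises monotonically with the true co-diffusing fraction", {
  med_fc <- function(phi) {
    cfg <- membrane_sim_config(diffusion_coeff = 0.4,
                               co_diffusing_fraction = phi,
                               n_in_focus = 4, duration = 15)
    st <- simulate_dual_color_streams(cfg, seed = 80 + round(100 * phi))
    suppressWarnings(analyze_cell(st, waist = 0.25))$f_c
  }
  fcs <- vapply(c(0, 0.5, 1), med_fc, numeric(1))
  expect_true(all(diff(fcs) > 0))
  expect_lt(fcs[1], 0.08)
  expect_gt(fcs[3], 0.7)
})

test_that("fully co-diffusing particles give strongly correlated gated traces", {
  cfg <- membrane_sim_config(diffusion_coeff = 0.4, co_diffusing_fraction = 1,
                             n_in_focus = 4, duration = 10)
  st <- simulate_dual_color_streams(cfg, seed = 81)
  gt <- gate_photons(st$green, st$red, bin_width = 1e-3, duration = 10)
  expect_gt(cor(gt$green, gt$red), 0.5)
})

test_that("independent species have cross-correlation consistent with zero", {
  # low-lag cross amplitude per independent replicate, then a t-like bound:
  # |mean| < 3 SE (replicates, not sub-blocks — slow box-scale density
  # fluctuations persist within one acquisition)
  amps <- vapply(1:5, function(r) {
    cfg <- membrane_sim_config(diffusion_coeff = 0.4, co_diffusing_fraction = 0,
                               n_in_focus = 4, duration = 6)
    st <- simulate_dual_color_streams(cfg, seed = 82 + r)
    gt <- gate_photons(st$green, st$red, duration = 6)
    gx <- multi_tau_correlate(gt$green, gt$red, max_lag = 0.3)
    mean(gx$G[gx$lag <= 5e-3])
  }, numeric(1))
  se <- sd(amps) / sqrt(length(amps))
  expect_lt(abs(mean(amps)), 3 * se + 1e-3)
})

test_that("segment averaging over identical segments reproduces one segment", {
  cfg <- membrane_sim_config(diffusion_coeff = 0.4, co_diffusing_fraction = 0.5,
                             n_in_focus = 4, duration = 15)
  st <- simulate_dual_color_streams(cfg, seed = 83)
  rep5 <- function(df) {
    out <- do.call(rbind, lapply(0:4, function(s) {
      d <- df; d$arrival_time_s <- d$arrival_time_s + 15 * s; d
    }))
    out
  }
  cs <- suppressWarnings(analyze_cell(rep5(st$green), rep5(st$red), waist = 0.25))
  one <- suppressWarnings(analyze_cell(st$green, st$red, waist = 0.25))
  expect_equal(cs$n_segments_used, 5)
  expect_equal(cs$curves$G_gg, one$curves$G_gg, tolerance = 1e-10)
  expect_equal(cs$f_c, one$f_c, tolerance = 1e-6)
  expect_true(all(cs$curves$se_gg < 1e-10))  # identical segments: zero spread
})

test_that("population summaries report quartiles, outliers and the t-test", {
  s <- summarize_population(rep(0.2, 6))
  expect_equal(s$conditions$all$median, 0.2)
  expect_equal(s$conditions$all$q75 - s$conditions$all$q25, 0)
  vals <- c(0.1, 0.11, 0.12, 0.13, 0.14, 0.6)
  s2 <- summarize_population(vals)
  expect_equal(s2$conditions$all$outliers, 0.6)
  set.seed(84)
  fc1 <- rnorm(30, 0.13, 0.02); fc2 <- rnorm(30, 0.19, 0.02)
  s3 <- summarize_population(c(fc1, fc2),
                             condition = rep(c("dimer", "egf"), each = 30))
  expect_lt(s3$t_test$p.value, 0.001)
  expect_error(summarize_population(c(0.1, 0.2)), "at least 5")
})

test_that("photon CSV round trip preserves the stream", {
  cfg <- membrane_sim_config(duration = 0.5, n_in_focus = 3)
  st <- simulate_dual_color_streams(cfg, seed = 85)
  path <- tempfile(fileext = ".csv")
  write_photon_csv(st$green, path)
  back <- read_photon_csv(path)
  expect_equal(nrow(back), nrow(st$green))
  expect_equal(back$arrival_time_s, st$green$arrival_time_s, tolerance = 1e-9)
  expect_equal(back$pulse_origin, as.character(st$green$pulse_origin))
  unlink(path)
})
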