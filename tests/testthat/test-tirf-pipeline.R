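# Detector, spot filtering, trace extraction and step counting, validated
# against the ground truth carried by the synthetic generators.

make_grid_field <- function(nx = 5, ny = 5, spacing = 1.5, jitter = 0.15,
                            n_visible = 1L, seed = 1) {
  set.seed(seed)
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  data.frame(x = g$x * spacing + runif(nrow(g), -jitter, jitter),
             y = g$y * spacing + runif(nrow(g), -jitter, jitter),
             n_total = n_visible, n_visible = n_visible,
             origin = "true_oligomer")
}

test_that("detector recovers well-separated spots with high recall and precision", {
  fld <- make_grid_field(7, 7, spacing = 1.6, seed = 2)
  acq <- acq_params(field_size = c(13, 13), n_frames = 60, shot = TRUE,
                    read_sd = 1, unit_brightness = 120, bleach_rate = 1e-5)
  mv <- render_movie(fld, acq, seed = 3)
  cand <- detect_spots(mv, psf_sigma = acq$psf_sigma, threshold_sd = 5)
  dmat <- outer(cand$x, fld$x, `-`)^2 + outer(cand$y, fld$y, `-`)^2
  matched <- sqrt(apply(dmat, 2, min)) < acq$pixel_size  # 1 px tolerance
  recall <- mean(matched)
  precision <- mean(sqrt(apply(dmat, 1, min)) < acq$pixel_size)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("pure-noise stacks yield no candidates at a 5-sigma threshold", {
  for (seed in 1:3) {
    acq <- acq_params(field_size = c(6, 6), n_frames = 60, shot = FALSE,
                      read_sd = 3, baseline = 100)
    mv <- render_movie(NULL, acq, seed = seed)
    expect_equal(nrow(detect_spots(mv, threshold_sd = 5)), 0)
  }
})

test_that("a sub-diffraction pair is detected as a single candidate", {
  fld <- data.frame(x = c(2.0, 2.05), y = c(2, 2), n_visible = 1L)
  acq <- acq_params(field_size = c(4, 4), n_frames = 60, shot = FALSE,
                    read_sd = 0.5, unit_brightness = 200, bleach_rate = 1e-5)
  mv <- render_movie(fld, acq, seed = 4)
  expect_equal(nrow(detect_spots(mv, threshold_sd = 5)), 1)
})

test_that("overlapping and bright/irregular candidates are filtered with reasons", {
  cand <- data.frame(x = c(1, 1.3, 5, 8, 10), y = c(1, 1, 5, 8, 10),
                     peak = c(100, 110, 95, 1000, 105),
                     width = c(0.12, 0.13, 0.12, 0.30, 0.12),
                     px = 1:5, py = 1:5)
  out <- filter_spots(cand, psf_sigma = 0.125, min_separation = 0.5,
                      brightness_cap = 5, width_cap = 1.5)
  expect_equal(nrow(out$accepted), 2)  # pair removed both; aggregate removed
  expect_setequal(out$rejections$reason[1:2], c("overlapping", "overlapping"))
  expect_true("bright_irregular" %in% out$rejections$reason)
})

test_that("injected aggregates are rejected while normal spots survive", {
  fld <- make_grid_field(6, 6, spacing = 1.8, seed = 5)
  agg <- sample(nrow(fld), 2)  # ~5% bright, wide aggregates
  fld$n_visible[agg] <- 10L
  acq <- acq_params(field_size = c(13, 13), n_frames = 60, shot = TRUE,
                    read_sd = 1, unit_brightness = 120, bleach_rate = 1e-5,
                    psf_sigma = 0.125)
  # widen the aggregates by rendering them with a larger PSF
  mv_n <- render_movie(fld[-agg, ], acq, seed = 6)
  acq_w <- acq; acq_w$psf_sigma <- 0.25
  mv_a <- render_movie(fld[agg, ], acq_w, seed = 7)
  mv <- mv_n; mv$frames <- mv_n$frames + mv_a$frames
  cand <- detect_spots(mv, psf_sigma = 0.125, threshold_sd = 5)
  out <- filter_spots(cand, psf_sigma = 0.125)
  near_agg <- function(df) {
    d2 <- outer(df$x, fld$x[agg], `-`)^2 + outer(df$y, fld$y[agg], `-`)^2
    apply(sqrt(d2), 1, min) < 0.3
  }
  expect_equal(sum(near_agg(out$accepted)), 0)       # all aggregates rejected
  normal_rejected <- if (nrow(out$rejections)) sum(!near_agg(out$rejections)) else 0
  expect_lte(normal_rejected / (nrow(fld) - 2), 0.05)
})

test_that("extracted traces track per-spot ground truth", {
  fld <- make_grid_field(4, 4, spacing = 2.2, n_visible = 2L, seed = 8)
  acq <- acq_params(field_size = c(11, 11), n_frames = 200, shot = FALSE,
                    read_sd = 0.3, unit_brightness = 150, bleach_rate = 0.01)
  mv <- render_movie(fld, acq, seed = 9)
  ext <- extract_traces(mv, fld, psf_sigma = acq$psf_sigma)
  expect_equal(length(ext$traces), nrow(fld))
  r2 <- vapply(seq_along(ext$traces), function(i) {
    truth <- mv$truth[[i]]
    lvl <- 150 * vapply(seq_len(200),
                        function(f) sum(truth$bleach_frames > f - 1L), numeric(1))
    cor(ext$traces[[i]]$intensity, lvl)^2
  }, numeric(1))
  expect_gt(median(r2), 0.99)
  expect_gt(min(r2), 0.95)
  # spot at the field edge is skipped with a log entry
  edge <- data.frame(x = 0.05, y = 5, n_visible = 1L)
  ext2 <- extract_traces(mv, edge, psf_sigma = acq$psf_sigma)
  expect_equal(length(ext2$traces), 0)
  expect_equal(nrow(ext2$skipped), 1)
})

test_that("noiseless staircases are segmented exactly", {
  acq <- acq_params(shot = FALSE, read_sd = 0)
  tr <- simulate_trace(2, acq, seed = 10)
  cs <- count_steps(tr)
  drops <- tr$truth$bleach_frames[tr$truth$bleach_frames < acq$n_frames]
  expect_equal(cs$n_steps, length(drops))
  expect_equal(cs$step_frames, drops)
  expect_equal(cs$category, c("one_step", "two_step")[length(drops)])
})

test_that("flat noise traces are rejected as poor fits", {
  set.seed(11)
  cs <- count_steps(rnorm(300, 50, 5))
  expect_equal(cs$n_steps, 0L)
  expect_equal(cs$category, "rejected")
  expect_equal(cs$reject_reason, "poor_fit")
  expect_error(count_steps(c(rep(1, 200), NA)), "non-finite")
  expect_error(count_steps(rnorm(50)), "100 frames")
})

test_that("segmentation is symmetric under time reversal on noiseless staircases", {
  acq <- acq_params(shot = FALSE, read_sd = 0, bleach_rate = 0.02)
  for (seed in c(17, 18)) {
    tr <- simulate_trace(3, acq, seed = seed)
    y <- tr$intensity
    sig <- max(median(abs(diff(y))) / (sqrt(2) * qnorm(0.75)), 1e-8 * max(abs(y), 1))
    pen <- 3 * sig^2 * log(length(y))
    fwd <- oligocount:::.oc_segment_trace(y, pen)
    bwd <- oligocount:::.oc_segment_trace(rev(y), pen)
    expect_equal(length(fwd), length(bwd))
    expect_equal(sort(length(y) - bwd), fwd)
  }
})

test_that("step counting is invariant to affine intensity rescaling", {
  acq <- acq_params(shot = FALSE, read_sd = 20)
  for (seed in c(12, 13, 14)) {
    tr <- simulate_trace(3, acq, seed = seed)
    a <- count_steps(tr)
    b <- count_steps(tr$intensity * 7.3 + 250, baseline_level = 250)
    expect_equal(a$n_steps, b$n_steps)
    expect_equal(a$step_frames, b$step_frames)
  }
})

test_that("detector reaches 90% exact-count accuracy at a 5-sigma step size", {
  acq <- acq_params(shot = FALSE, read_sd = 20)  # step = 5 x noise SD
  set.seed(15)
  nv <- sample(1:4, 400, replace = TRUE)
  traces <- simulate_trace_set(nv, acq)
  called <- vapply(traces, function(tr) count_steps(tr)$n_steps, integer(1))
  truth <- vapply(traces, steps_in_window, numeric(1))
  ok <- truth > 0
  expect_gte(mean(called[ok] == truth[ok]), 0.90)
  two <- truth == 2
  expect_lte(mean(called[two] == 1), 0.05)  # two-step -> one-step confusion
})

test_that("expected detected steps grow with true fluorophore number", {
  acq <- acq_params(shot = FALSE, read_sd = 20)
  set.seed(16)
  means <- vapply(1:5, function(nv) {
    mean(vapply(simulate_trace_set(rep(nv, 60), acq),
                function(tr) count_steps(tr)$n_steps, integer(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("histograms tally categories with Wilson intervals", {
  h <- step_histogram_from_counts(c(one_step = 94, two_step = 6, multistep = 0))
  expect_equal(unname(h$fractions), c(0.94, 0.06, 0))
  expect_equal(sum(h$fractions), 1, tolerance = 1e-9)
  h2 <- step_histogram_from_counts(c(one_step = 1, two_step = 0, multistep = 0))
  expect_gt(diff(h2$ci[, "one_step"]), 0.5)  # single spot: very wide CI
  h3 <- step_histogram_from_counts(c(one_step = 250, two_step = 250,
                                     multistep = 500))
  expect_equal(unname(h3$fractions), c(0.25, 0.25, 0.5))
  expect_equal(unname(diff(h3$ci[, "multistep"])) / 2, 0.031, tolerance = 0.005)
  calls <- list(structure(list(category = "one_step"), class = "step_call"),
                structure(list(category = "rejected"), class = "step_call"))
  h4 <- build_histogram(calls)
  expect_equal(h4$n_analyzed, 1)
  expect_equal(h4$n_rejected, 1L)
  expect_error(build_histogram(calls[2]), "rejected")
})
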