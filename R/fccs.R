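#' Time-gate PIE photon streams and bin them into intensity traces
#'
#' Applies the pulsed-interleaved-excitation rejection rule: red-detector
#' photons whose preceding pulse is the 488 nm (green) pulse and whose
#' microtime falls inside the gate window are rejected — these are
#' green-to-red bleed-through, FRET, or direct red excitation by the blue
#' laser — and symmetrically green-detector photons tied to the 561 nm
#' pulse. Survivors are binned at `bin_width`.
#'
#' @param green_stream,red_stream photon data.frames (see
#'   [simulate_dual_color_streams()] / [read_photon_csv()]).
#' @param pie a [pie_config()].
#' @param bin_width bin width in seconds.
#' @param duration total trace duration, s (default: covers the last photon).
#' @return An object of class `gated_traces`: `green`, `red` (counts per
#'   bin), `bin_width`, `rejected` (named counts), `n_bins`.
#' @export
gate_photons <- function(green_stream, red_stream, pie = pie_config(),
                         bin_width = 1e-4, duration = NULL) {
  for (df in list(green_stream, red_stream)) {
    if (!all(c("microtime_ns", "pulse_origin", "arrival_time_s") %in% names(df)))
      stop("photon records must carry microtime and pulse tags", call. = FALSE)
  }
  gw <- pie$gate_window
  keep_g <- !(green_stream$pulse_origin == "561" & green_stream$microtime_ns < gw)
  keep_r <- !(red_stream$pulse_origin == "488" & red_stream$microtime_ns < gw)
  dur <- duration %||% max(green_stream$arrival_time_s[nrow(green_stream)],
                           red_stream$arrival_time_s[nrow(red_stream)])
  n_bins <- ceiling(dur / bin_width)
  bin_of <- function(t) pmin(floor(t / bin_width) + 1L, n_bins)
  structure(list(
    green = tabulate(bin_of(green_stream$arrival_time_s[keep_g]), n_bins),
    red = tabulate(bin_of(red_stream$arrival_time_s[keep_r]), n_bins),
    bin_width = bin_width,
    rejected = c(green = sum(!keep_g), red = sum(!keep_r)),
    n_bins = n_bins), class = "gated_traces")
}

#' Multi-tau correlation of two intensity traces
#'
#' Computes the normalized correlation
#' \deqn{G(\tau) = \langle \delta F_a(t)\, \delta F_b(t+\tau) \rangle /
#'   (\langle F_a \rangle \langle F_b \rangle)}
#' on a quasi-logarithmic lag grid: `m` linearly spaced lags at the base
#' resolution, then `m/2` lags per octave after each successive 2x
#' rebinning, up to `max_lag`. Symmetric normalization divides by the means
#' of the two traces over their overlapping windows at each lag, which
#' removes the bias a drifting mean would otherwise introduce. Auto- and
#' cross-correlation use the same code path (`a == b` for auto).
#'
#' @param a,b equal-length numeric count traces.
#' @param bin_width base bin width, s.
#' @param m lags per stage (default 16).
#' @param max_lag largest lag, s.
#' @return data.frame with `lag` (s) and `G`.
#' @export
multi_tau_correlate <- function(a, b = a, bin_width = 1e-4, m = 16,
                                max_lag = 1) {
  if (length(a) != length(b)) stop("traces must have equal length", call. = FALSE)
  if (mean(a) == 0 || mean(b) == 0)
    stop("zero-mean trace: correlation normalization undefined", call. = FALSE)
  if (max_lag > length(a) * bin_width / 10)
    stop("`max_lag` must be below a tenth of the trace duration", call. = FALSE)
  lag <- numeric(0); G <- numeric(0)
  cur_a <- as.numeric(a); cur_b <- as.numeric(b)
  width <- bin_width
  stage <- 0L
  done <- FALSE
  repeat {
    ks <- if (stage == 0L) seq_len(m) else (m / 2 + 1):m
    for (k in ks) {
      tau <- k * width
      n <- length(cur_a)
      if (tau > max_lag || n - k < 2 * m) { done <- TRUE; break }
      x <- cur_a[1:(n - k)]; y <- cur_b[(1 + k):n]
      mx <- mean(x); my <- mean(y)
      if (mx == 0 || my == 0) { done <- TRUE; break }
      lag <- c(lag, tau)
      G <- c(G, mean(x * y) / (mx * my) - 1)
    }
    if (done || length(cur_a) < 4 * m) break
    # rebin by 2 for the next octave
    idx <- seq_len(floor(length(cur_a) / 2)) * 2L
    cur_a <- cur_a[idx - 1L] + cur_a[idx]
    cur_b <- cur_b[idx - 1L] + cur_b[idx]
    width <- width * 2
    stage <- stage + 1L
  }
  data.frame(lag = lag, G = G)
}

#' Fit a single-component 2D membrane-diffusion model to a correlation curve
#'
#' Least-squares fit of \deqn{G(\tau) = G_0 (1 + \tau/\tau_D)^{-1} + B,}
#' the correlation decay of free 2D Brownian diffusion through a Gaussian
#' detection area plus a small free baseline B, and conversion to a
#' diffusion coefficient via
#' \eqn{D = w^2 / (4 \tau_D)} for beam waist w. Zero-lag amplitudes used
#' downstream are the fit-extrapolated \eqn{G_0}, not the raw first lag bin,
#' which makes them immune to shot noise and detector afterpulsing.
#'
#' The baseline term absorbs the small uniform negative offset that
#' finite-duration mean normalization imprints on correlation estimates
#' (about \eqn{-(2/T)\int_0^T G}, a few percent of G0 for 15 s segments
#' but a large fraction of the tail), which otherwise masquerades as a
#' faster decay and biases D upward; `offset = FALSE` forces B = 0. The
#' fit is also two-pass: after an initial fit over all lags, the range is
#' restricted to lags up to `range_factor` times the first-pass diffusion
#' time (keeping at least 20 points) and refitted, so the estimate is not
#' dominated by the long-lag tail where the single-component model is most
#' sensitive to slow instrumental and finite-field artifacts.
#'
#' When the curve carries an `se` column the fit is weighted by 1/se^2;
#' note that empirical per-lag errors estimated from only a handful of
#' segments are noisy enough to bias weighted fits, so the per-cell
#' protocol ([analyze_cell()]) fits its averaged curves unweighted.
#'
#' @param curve data.frame with `lag` and `G` (and optionally `se` used as
#'   weights 1/se^2).
#' @param waist 1/e^2 beam waist, micron.
#' @param range_factor multiple of the first-pass tau_D defining the second
#'   pass fit range; `Inf` disables the restriction.
#' @param offset include the free baseline term B (default `TRUE`).
#' @return An object of class `fcs_fit`: `G0`, `tau_D` (s), `D`
#'   (micron^2/s), `N_effective` (= 1/G0), `ci` (95% per-parameter), `fit`
#'   (the `nls` object), `failed` flag.
#' @export
fit_2d_diffusion <- function(curve, waist = 0.25, range_factor = 8,
                             offset = TRUE) {
  curve <- curve[is.finite(curve$G) & curve$lag > 0, , drop = FALSE]
  if (nrow(curve) < 20)
    stop("need at least 20 lag points to fit the diffusion model", call. = FALSE)
  fit_once <- function(d, nudge = 1) {
    w <- if (!is.null(d$se) && all(is.finite(d$se)) && all(d$se > 0))
      1 / d$se^2 else rep(1, nrow(d))
    g0_start <- max(mean(head(d$G, 4)), 1e-4) * nudge
    below <- which(d$G <= g0_start / 2)
    tau_start <- (if (length(below)) d$lag[min(below)] else median(d$lag)) * nudge
    tryCatch({
      if (offset)
        minpack.lm::nlsLM(G ~ G0 / (1 + lag / tauD) + B, data = d,
                          start = list(G0 = g0_start, tauD = tau_start, B = 0),
                          weights = w,
                          lower = c(1e-8, 1e-7, -0.1), upper = c(10, 100, 0.1),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      else
        minpack.lm::nlsLM(G ~ G0 / (1 + lag / tauD), data = d,
                          start = list(G0 = g0_start, tauD = tau_start),
                          weights = w,
                          lower = c(1e-8, 1e-7), upper = c(10, 100),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
    }, error = function(e) NULL)
  }
  fit <- fit_once(curve)
  # a start landing exactly on the optimum can trip LM's initial gradient
  # check on noiseless data; retry from a nudged start
  if (is.null(fit)) fit <- fit_once(curve, nudge = 1.3)
  if (!is.null(fit) && is.finite(range_factor)) {
    cut <- range_factor * coef(fit)[["tauD"]]
    keep <- curve$lag <= cut
    if (sum(keep) >= 20 && sum(keep) < nrow(curve)) {
      fit2 <- fit_once(curve[keep, , drop = FALSE])
      if (is.null(fit2)) fit2 <- fit_once(curve[keep, , drop = FALSE], nudge = 1.3)
      if (!is.null(fit2)) fit <- fit2
    }
  }
  failed <- is.null(fit)
  if (!failed) {
    p <- coef(fit)
    decaying <- p[["G0"]] > 0 && p[["tauD"]] < 90 &&
      mean(head(curve$G, 5)) > mean(utils::tail(curve$G, 5))
    failed <- !decaying
  }
  if (failed) {
    return(structure(list(G0 = NA_real_, tau_D = NA_real_, D = NA_real_,
                          N_effective = NA_real_, offset = NA_real_,
                          ci = NULL, fit = fit,
                          waist = waist, failed = TRUE), class = "fcs_fit"))
  }
  p <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 2))
  ci <- rbind(G0 = p[["G0"]] + c(-1, 1) * 1.96 * se[1],
              tau_D = p[["tauD"]] + c(-1, 1) * 1.96 * se[2])
  colnames(ci) <- c("lower", "upper")
  structure(list(G0 = p[["G0"]], tau_D = p[["tauD"]],
                 D = waist^2 / (4 * p[["tauD"]]),
                 N_effective = 1 / p[["G0"]],
                 offset = if (offset) p[["B"]] else 0,
                 ci = ci, fit = fit, waist = waist, failed = FALSE),
            class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  if (x$failed) { cat("FCS fit: FAILED (non-decaying curve)\n"); return(invisible(x)) }
  cat(sprintf("FCS 2D-diffusion fit: G0 = %.4f (N_eff = %.1f), tau_D = %.1f ms, D = %.3f um^2/s\n",
              x$G0, x$N_effective, 1e3 * x$tau_D, x$D))
  invisible(x)
}

#' @export
coef.fcs_fit <- function(object, ...) {
  c(G0 = object$G0, tau_D = object$tau_D, D = object$D)
}

#' @export
predict.fcs_fit <- function(object, lag, ...) {
  object$G0 / (1 + lag / object$tau_D)
}

#' Fraction correlated from zero-lag amplitudes
#'
#' \deqn{f_c = G_x(0) / \max(G_{gg}(0), G_{rr}(0)).} The max-denominator
#' convention keeps the ideal range `[0, 1]` and makes the value insensitive
#' to which color is in excess; alternatives are available via
#' `denominator`. Amplitudes should come from fitted curves
#' ([fit_2d_diffusion()]), not raw first-lag bins.
#'
#' @param G_x0 fitted zero-lag cross-correlation amplitude.
#' @param G_gg0,G_rr0 fitted autocorrelation amplitudes.
#' @param denominator `"max"` (default), `"min"`, `"green"`, or `"red"`.
#' @return `f_c`, or `NA` (flagged via attribute `"flag"`) when either
#'   autocorrelation amplitude is non-positive.
#' @export
fraction_correlated <- function(G_x0, G_gg0, G_rr0,
                                denominator = c("max", "min", "green", "red")) {
  denominator <- match.arg(denominator)
  if (!is.finite(G_gg0) || !is.finite(G_rr0) || G_gg0 <= 0 || G_rr0 <= 0)
    return(structure(NA_real_, flag = "undefined_autocorrelation"))
  den <- switch(denominator, max = max(G_gg0, G_rr0), min = min(G_gg0, G_rr0),
                green = G_gg0, red = G_rr0)
  structure(G_x0 / den, denominator = denominator)
}

#' Analyze one cell's PIE-FCCS acquisition
#'
#' Implements the standard per-cell protocol: the two photon streams are
#' split into successive segments (15 s by default), each segment is gated,
#' binned, linearly detrended (removing slow photobleaching drift within the
#' segment), and correlated; segments whose total intensity trends by more
#' than `max_trend` (relative) are dropped. The per-segment auto- and
#' cross-correlation curves are averaged and the averaged autocorrelations
#' are fitted with the 2D diffusion model ([fit_2d_diffusion()]).
#'
#' The cross-correlation amplitude is estimated by linear projection: the
#' decay shape is fixed to the autocorrelations' fitted diffusion time
#' (co-diffusing complexes share the mobility of their constituents), and
#' `G_x(tau) = G_x0 / (1 + tau/tau_x) + B` is solved by ordinary least
#' squares with `G_x0` unconstrained in sign. Leaving the sign free matters:
#' a positivity-constrained fit cannot average away noise for truly
#' independent species, and its clipped amplitudes would bias the
#' population median of f_c upward by several hundredths. The reported
#' per-cell `f_c` is clipped to `[0, 1.5]` (flagged outside `[0, 1]`);
#' per-segment f_c values computed the same way are retained for dispersion
#' diagnostics.
#'
#' @param green_stream,red_stream photon data.frames.
#' @param pie a [pie_config()].
#' @param waist beam waist, micron.
#' @param segment_duration s (default 15; five segments in the standard
#'   75 s protocol).
#' @param bin_width correlator base bin, s.
#' @param max_lag largest correlation lag, s.
#' @param detrend linearly detrend each segment (default `TRUE`).
#' @param max_trend relative intensity change within a segment above which
#'   the segment is dropped as bleaching-contaminated.
#' @param denominator passed to [fraction_correlated()].
#' @return An object of class `cell_summary`: `f_c`, `D_g`, `D_r`,
#'   `segment_f_c`, `curves` (lag, G_gg, G_rr, G_x, se_*), `fits`, `flags`,
#'   `n_segments_used`, `rejected_photons`.
#' @export
analyze_cell <- function(green_stream, red_stream, pie = pie_config(),
                         waist = 0.25, segment_duration = 15,
                         bin_width = 1e-4, max_lag = 1, detrend = TRUE,
                         max_trend = 0.5,
                         denominator = c("max", "min", "green", "red")) {
  denominator <- match.arg(denominator)
  if (inherits(green_stream, "photon_streams")) {
    red_stream <- green_stream$red; green_stream <- green_stream$green
  }
  dur <- max(green_stream$arrival_time_s[nrow(green_stream)],
             red_stream$arrival_time_s[nrow(red_stream)])
  # a segment missing less than 2% of its tail (acquisition ends at the last
  # photon, not the nominal duration) still counts as complete
  n_seg <- floor(dur / segment_duration + 0.02)
  flags <- character(0)
  if (n_seg < 1) stop("streams shorter than one segment", call. = FALSE)
  if (n_seg < 5) {
    warning("fewer than 5 segments available (", n_seg, ")")
    flags <- c(flags, "short_acquisition")
  }
  seg_curves <- list(); rejected <- c(green = 0, red = 0)
  dropped <- 0L
  for (s in seq_len(n_seg)) {
    t0 <- (s - 1) * segment_duration; t1 <- s * segment_duration
    gs <- green_stream[green_stream$arrival_time_s >= t0 &
                         green_stream$arrival_time_s < t1, , drop = FALSE]
    rs <- red_stream[red_stream$arrival_time_s >= t0 &
                       red_stream$arrival_time_s < t1, , drop = FALSE]
    gs$arrival_time_s <- gs$arrival_time_s - t0
    rs$arrival_time_s <- rs$arrival_time_s - t0
    gt <- gate_photons(gs, rs, pie, bin_width, duration = segment_duration)
    rejected <- rejected + gt$rejected
    if (max(abs(trend_fraction(gt$green)), abs(trend_fraction(gt$red))) >
          max_trend) {
      dropped <- dropped + 1L
      next
    }
    a <- if (detrend) detrend_counts(gt$green) else gt$green
    b <- if (detrend) detrend_counts(gt$red) else gt$red
    gg <- multi_tau_correlate(a, a, bin_width, max_lag = max_lag)
    rr <- multi_tau_correlate(b, b, bin_width, max_lag = max_lag)
    gx <- multi_tau_correlate(a, b, bin_width, max_lag = max_lag)
    seg_curves[[length(seg_curves) + 1L]] <-
      data.frame(lag = gg$lag, G_gg = gg$G, G_rr = rr$G, G_x = gx$G)
  }
  if (dropped > 0) flags <- c(flags, sprintf("%d_segments_dropped_bleaching", dropped))
  if (length(seg_curves) == 0L) stop("all segments dropped", call. = FALSE)
  lags <- seg_curves[[1]]$lag
  avg <- function(col) rowMeans(sapply(seg_curves, `[[`, col))
  sdv <- function(col) apply(sapply(seg_curves, `[[`, col), 1, sd)
  nseg_used <- length(seg_curves)
  curves <- data.frame(lag = lags,
                       G_gg = avg("G_gg"), G_rr = avg("G_rr"), G_x = avg("G_x"),
                       se_gg = sdv("G_gg") / sqrt(nseg_used),
                       se_rr = sdv("G_rr") / sqrt(nseg_used),
                       se_x = sdv("G_x") / sqrt(nseg_used))
  fit_g <- fit_2d_diffusion(data.frame(lag = lags, G = curves$G_gg), waist)
  fit_r <- fit_2d_diffusion(data.frame(lag = lags, G = curves$G_rr), waist)
  taus <- c(fit_g$tau_D, fit_r$tau_D)
  tau_x <- if (all(is.na(taus))) NA_real_ else mean(taus, na.rm = TRUE)
  fit_x <- tryCatch(
    fit_2d_diffusion(data.frame(lag = lags, G = curves$G_x), waist),
    error = function(e) NULL)
  gx0 <- if (is.finite(tau_x))
    project_amplitude(lags, curves$G_x, tau_x)
  else if (!is.null(fit_x) && !fit_x$failed) fit_x$G0 else NA_real_
  # Cauchy-Schwarz-style amplitude bound: flag violations beyond noise
  if (is.finite(gx0) && !fit_g$failed && !fit_r$failed &&
      gx0^2 > 1.2 * fit_g$G0 * fit_r$G0)
    flags <- c(flags, "cross_amplitude_exceeds_bound")
  fc <- as.numeric(fraction_correlated(gx0, fit_g$G0, fit_r$G0, denominator))
  if (is.finite(fc)) {
    if (fc < 0 || fc > 1) flags <- c(flags, "f_c_outside_unit_interval")
    fc <- min(max(fc, 0), 1.5)
  } else flags <- c(flags, "f_c_undefined")
  # per-segment f_c with shapes fixed at the pooled decay times
  seg_fc <- if (is.finite(tau_x) && !fit_g$failed && !fit_r$failed) {
    vapply(seg_curves, function(sc) {
      a0 <- project_amplitude(sc$lag, sc$G_gg, fit_g$tau_D)
      r0 <- project_amplitude(sc$lag, sc$G_rr, fit_r$tau_D)
      x0 <- project_amplitude(sc$lag, sc$G_x, tau_x)
      if (a0 <= 0 || r0 <= 0) return(NA_real_)
      x0 / switch(denominator, max = max(a0, r0), min = min(a0, r0),
                  green = a0, red = r0)
    }, numeric(1))
  } else rep(NA_real_, nseg_used)
  structure(list(f_c = fc, D_g = fit_g$D, D_r = fit_r$D,
                 segment_f_c = seg_fc, curves = curves,
                 fits = list(green = fit_g, red = fit_r, cross = fit_x),
                 flags = flags, n_segments_used = nseg_used,
                 rejected_photons = rejected),
            class = "cell_summary")
}

# amplitude of a correlation curve for a known decay shape: ordinary least
# squares on G(tau) = A / (1 + tau/tau_D) + B, A unconstrained in sign.
# Restricted to lags <= range_factor * tau_D, the same window the
# two-pass autocorrelation fits use, so auto and cross amplitudes see the
# same portion of the decay.
project_amplitude <- function(lag, G, tau_D, range_factor = 8) {
  keep <- is.finite(G) & lag <= range_factor * tau_D
  if (sum(keep) < 10) keep <- is.finite(G)
  f <- 1 / (1 + lag[keep] / tau_D)
  X <- cbind(f, 1)
  as.numeric(stats::lm.fit(X, G[keep])$coefficients[1])
}

# relative intensity change over a segment from a linear fit
trend_fraction <- function(counts) {
  n <- length(counts)
  t <- seq_len(n)
  sl <- cov(t, counts) / var(t)
  mu <- mean(counts)
  if (mu <= 0) return(0)
  sl * n / mu
}

detrend_counts <- function(counts) {
  n <- length(counts)
  t <- seq_len(n)
  sl <- cov(t, counts) / var(t)
  counts - sl * (t - mean(t))
}

#' @export
print.cell_summary <- function(x, ...) {
  cat(sprintf("Cell summary: f_c = %.3f, D_green = %.3f, D_red = %.3f um^2/s (%d segments)\n",
              x$f_c, x$D_g, x$D_r, x$n_segments_used))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Summarize fraction-correlated values across a cell population
#'
#' Box-plot-style summary per condition — median, quartiles, whiskers (full
#' range) and outliers by the 1.5 x IQR rule — plus a two-sample Student's
#' t-test between the first two conditions when two are supplied.
#'
#' @param cells list of `cell_summary` objects, or a numeric vector of f_c
#'   values.
#' @param condition optional factor/character of the same length splitting
#'   cells into conditions.
#' @return An object of class `population_summary`: per-condition stats and,
#'   when applicable, `t_test`.
#' @export
summarize_population <- function(cells, condition = NULL) {
  vals <- if (is.numeric(cells)) cells else
    vapply(cells, function(x) x$f_c, numeric(1))
  if (length(vals) < 5) stop("need at least 5 cells", call. = FALSE)
  condition <- condition %||% rep("all", length(vals))
  stats_one <- function(v) {
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    out_lo <- v < q[1] - 1.5 * iqr
    out_hi <- v > q[3] + 1.5 * iqr
    list(n = length(v), median = q[2], q25 = q[1], q75 = q[3],
         whisker_low = min(v), whisker_high = max(v),
         outliers = v[out_lo | out_hi])
  }
  by_cond <- lapply(split(vals, condition), stats_one)
  tt <- NULL
  lv <- unique(condition)
  if (length(lv) == 2) {
    tt <- t.test(vals[condition == lv[1]], vals[condition == lv[2]],
                 var.equal = TRUE)
  }
  structure(list(conditions = by_cond, values = split(vals, condition),
                 t_test = tt), class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat("Population summary\n")
  for (nm in names(x$conditions)) {
    s <- x$conditions[[nm]]
    cat(sprintf("  %s: n = %d, median = %.3f [%.3f, %.3f], range [%.3f, %.3f], %d outlier(s)\n",
                nm, s$n, s$median, s$q25, s$q75, s$whisker_low, s$whisker_high,
                length(s$outliers)))
  }
  if (!is.null(x$t_test))
    cat(sprintf("  two-sample t-test: t = %.2f, p = %.3g\n",
                x$t_test$statistic, x$t_test$p.value))
  invisible(x)
}
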