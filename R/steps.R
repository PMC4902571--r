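#' Count photobleaching steps in an intensity trace
#'
#' Automated replacement for manual step counting. The trace is segmented
#' into a piecewise-constant fit by penalized least squares (optimal
#' partitioning with a per-changepoint penalty proportional to
#' \eqn{\hat\sigma^2 \log n}); retained changepoints must be *downward* with
#' magnitude at least `min_step_sd` times the noise SD — photobleaching is
#' irreversible, so upward transitions (blinking, noise) are never counted.
#' The noise SD is estimated robustly from the median absolute first
#' difference. A trace whose final fitted level is more than two noise SDs
#' above the expected baseline has not fully bleached; depending on
#' `censored`, such traces are classified by the steps observed (and
#' flagged) or rejected.
#'
#' @param trace a `fluor_trace`, or a bare numeric intensity vector.
#' @param penalty penalty multiplier on `sigma^2 * log(n)` per changepoint.
#' @param min_step_sd minimum retained step size in noise SDs.
#' @param max_steps cap on the reported number of steps.
#' @param baseline_level expected post-bleach intensity (counts).
#' @param censored `"classify"` (default) to keep not-fully-bleached traces,
#'   classified by observed steps and flagged; `"reject"` to reject them
#'   with reason `poor_fit`.
#' @return An object of class `step_call`: list with `n_steps`,
#'   `step_frames`, `step_sizes`, `category` (`one_step`, `two_step`,
#'   `multistep`, `rejected`), `reject_reason`, `censored`, `sigma`.
#' @examples
#' tr <- simulate_trace(2, acq_params(shot = FALSE, read_sd = 4), seed = 2)
#' count_steps(tr)
#' @export
count_steps <- function(trace, penalty = 3, min_step_sd = 3, max_steps = 8,
                        baseline_level = 0, censored = c("classify", "reject")) {
  censored <- match.arg(censored)
  y <- if (inherits(trace, "fluor_trace")) trace$intensity else as.numeric(trace)
  if (any(!is.finite(y))) stop("trace contains non-finite values", call. = FALSE)
  n <- length(y)
  if (n < 100L) stop("trace must have at least 100 frames", call. = FALSE)
  sigma <- median(abs(diff(y))) / (sqrt(2) * qnorm(0.75))
  scale <- max(abs(y - baseline_level), 1)
  sigma_eff <- max(sigma, 1e-8 * max(scale))
  cps <- .oc_segment_trace(y, penalty * sigma_eff^2 * log(n))

  res <- prune_steps(y, cps, min_step_sd * sigma_eff)
  n_steps <- length(res$cps)
  final_level <- if (n_steps > 0) res$means[length(res$means)] else mean(y)
  is_censored <- final_level > baseline_level + 2 * sigma_eff

  category <- "rejected"; reject_reason <- NA_character_
  if (n_steps == 0L) {
    reject_reason <- "poor_fit"
  } else if (is_censored && censored == "reject") {
    reject_reason <- "poor_fit"
  } else {
    category <- if (n_steps == 1L) "one_step" else
      if (n_steps == 2L) "two_step" else "multistep"
  }
  structure(list(n_steps = as.integer(min(n_steps, max_steps)),
                 step_frames = res$cps, step_sizes = -res$drops,
                 category = category, reject_reason = reject_reason,
                 censored = is_censored, sigma = sigma),
            class = "step_call")
}

# Iteratively remove segmentation changepoints that are upward or smaller
# than min_drop, recomputing segment means after each merge.
prune_steps <- function(y, cps, min_drop) {
  repeat {
    bounds <- c(0L, cps, length(y))
    means <- vapply(seq_len(length(bounds) - 1L),
                    function(i) mean(y[(bounds[i] + 1L):bounds[i + 1L]]),
                    numeric(1))
    if (length(cps) == 0L) return(list(cps = cps, means = means, drops = numeric(0)))
    drops <- diff(means)  # negative = downward step
    bad <- which(drops > -min_drop)
    if (length(bad) == 0L) return(list(cps = cps, means = means, drops = drops))
    worst <- bad[which.max(drops[bad])]  # least-downward violator first
    cps <- cps[-worst]
  }
}

#' @export
print.step_call <- function(x, ...) {
  cat(sprintf("Step call: %d step(s), category %s%s\n", x$n_steps, x$category,
              if (isTRUE(x$censored)) " [censored]" else ""))
  invisible(x)
}

#' Build a step-category histogram from step calls
#'
#' Tallies one-step / two-step / multistep fractions over non-rejected
#' spots, with 95% Wilson score intervals per category; rejected spots are
#' counted separately and never enter the fractions.
#'
#' @param calls list of `step_call` objects (or a data.frame with a
#'   `category` column).
#' @return An object of class `step_histogram`: list with `counts`,
#'   `fractions`, `ci` (2 x 3 matrix), `n_analyzed`, `n_rejected`.
#' @examples
#' h <- step_histogram_from_counts(c(one_step = 94, two_step = 6, multistep = 0))
#' h$fractions
#' @export
build_histogram <- function(calls) {
  cat_of <- function(cl) cl$category
  cats <- if (is.data.frame(calls)) as.character(calls$category) else
    vapply(calls, cat_of, character(1))
  keep <- cats %in% c("one_step", "two_step", "multistep")
  if (!any(keep)) stop("all spots rejected: nothing to histogram", call. = FALSE)
  counts <- c(one_step = sum(cats == "one_step"),
              two_step = sum(cats == "two_step"),
              multistep = sum(cats == "multistep"))
  step_histogram_from_counts(counts, n_rejected = sum(!keep))
}

#' @rdname build_histogram
#' @param counts named vector of category counts (`one_step`, `two_step`,
#'   `multistep`).
#' @param n_rejected number of rejected spots, tallied separately.
#' @export
step_histogram_from_counts <- function(counts, n_rejected = 0L) {
  counts <- counts[c("one_step", "two_step", "multistep")]
  counts[is.na(counts)] <- 0
  names(counts) <- c("one_step", "two_step", "multistep")
  n <- sum(counts)
  if (n < 1) stop("need at least one analyzed spot", call. = FALSE)
  fractions <- counts / n
  ci <- vapply(fractions, function(p) wilson_ci(p, n), numeric(2))
  rownames(ci) <- c("lower", "upper")
  structure(list(counts = counts, fractions = fractions, ci = ci,
                 n_analyzed = n, n_rejected = as.integer(n_rejected)),
            class = "step_histogram")
}

wilson_ci <- function(p, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

#' @export
print.step_histogram <- function(x, ...) {
  cat(sprintf("Step histogram: %d spots analyzed, %d rejected\n",
              x$n_analyzed, x$n_rejected))
  tab <- rbind(count = x$counts, fraction = round(x$fractions, 4),
               round(x$ci, 4))
  print(tab)
  invisible(x)
}

#' Convert step calls to a data.frame
#'
#' @param calls list of `step_call` objects.
#' @return data.frame with one row per spot: `spot_id`, `n_steps`,
#'   `category`, `reject_reason`, `censored`.
#' @export
step_calls_table <- function(calls) {
  data.frame(
    spot_id = seq_along(calls),
    n_steps = vapply(calls, function(x) x$n_steps, integer(1)),
    category = vapply(calls, function(x) x$category, character(1)),
    reject_reason = vapply(calls, function(x)
      if (is.na(x$reject_reason)) NA_character_ else x$reject_reason, character(1)),
    censored = vapply(calls, function(x) isTRUE(x$censored), logical(1)))
}
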