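#' Visible-step-count distribution for an n-mer
#'
#' Probability mass function of the number of *visible* fluorophores k in an
#' assembly of n subunits, when each fluorophore is independently dark with
#' probability `p_dark`, conditioned on the spot being visible at all:
#' \deqn{P(k \mid n) = \binom{n}{k} (1-p)^k p^{n-k} / (1 - p^n), \quad k = 1..n.}
#' Under ideal step counting k equals the observed step count, which is why
#' a tetramer with a 30% dark fraction most often shows only three or fewer
#' steps.
#'
#' @param n subunit count (>= 1).
#' @param p_dark per-fluorophore dark probability in `[0, 1)`.
#' @return A list of class `step_distribution`: `k` (1..n), `pmf`, and
#'   `categories` (probabilities of one, two, and three-or-more visible
#'   fluorophores).
#' @examples
#' step_count_pmf(2, 0.3)$pmf  # 0.4615 0.5385
#' @export
step_count_pmf <- function(n, p_dark = 0.30) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (p_dark >= 1) stop("p_dark = 1: nothing is visible", call. = FALSE)
  stopifnot_scalar_prob(p_dark, "p_dark")
  k <- seq_len(n)
  pmf <- dbinom(k, n, 1 - p_dark) / (1 - p_dark^n)
  structure(list(k = k, pmf = pmf,
                 categories = c(one = pmf[1],
                                two = if (n >= 2) pmf[2] else 0,
                                multi = if (n >= 3) sum(pmf[-(1:2)]) else 0)),
            class = "step_distribution")
}

#' Expected step-category fractions for an oligomer mixture
#'
#' Forward model for the analyzed step-category histogram. Marginalizes the
#' visible-step pmf over the mixture weights, adds the
#' random-colocalization contribution (pairs of independent molecules in
#' one unresolvable spot, at rate `coloc_two_step` relative to the mixture
#' spots), and renormalizes over the three categories.
#'
#' `detect_prob` extends the model to finite recordings: it is the
#' probability that a visible fluorophore's bleaching step actually occurs
#' within the movie, \eqn{q = 1 - (1 - h)^{n_{frames}}} for per-frame
#' hazard h (see [detect_prob_from_acq()]). Fluorophores that survive the
#' whole movie contribute intensity but no step, so observed step counts
#' follow a binomial with success probability \eqn{s = (1-p_{dark})\,q};
#' spots showing zero steps are rejected by the detector and drop out of
#' the histogram. With `detect_prob = 1` this reduces to the ideal-counting
#' model. Mixture weights refer to the composition of visible spots, so
#' the n-mer weight among *analyzed* spots is additionally proportional to
#' the probability that a visible n-mer shows at least one step.
#'
#' @param mixture an [oligomer_mixture()].
#' @param coloc_two_step colocalization rate (e.g. the ~0.03 measured with
#'   a monomeric control protein); must be in `[0, 0.2]`.
#' @param detect_prob probability a visible fluorophore bleaches within the
#'   recording, in `(0, 1]`.
#' @return Named numeric vector `(one, two, multi)` summing to 1.
#' @examples
#' predict_categories(oligomer_mixture(c(`1` = 0.97, `2` = 0.03), 0.3), 0.03)
#' @export
predict_categories <- function(mixture, coloc_two_step = 0, detect_prob = 1) {
  stopifnot(inherits(mixture, "oligomer_mixture"))
  if (coloc_two_step < 0 || coloc_two_step > 0.2)
    stop("`coloc_two_step` must lie in [0, 0.2]", call. = FALSE)
  if (detect_prob <= 0 || detect_prob > 1)
    stop("`detect_prob` must lie in (0, 1]", call. = FALSE)
  p_dark <- mixture$p_dark
  q <- detect_prob
  s <- (1 - p_dark) * q
  # per-n: category probabilities of the observed step count k ~ Binom(n, s),
  # conditioned on the spot being visible (>=1 visible fluorophore); spots
  # with k = 0 are carried explicitly and dropped via the normalization
  per_n <- vapply(mixture$n, function(n) {
    vis <- 1 - p_dark^n
    c(one = dbinom(1, n, s) / vis,
      two = dbinom(2, n, s) / vis,
      multi = (1 - sum(dbinom(0:2, n, s))) / vis)
  }, numeric(3))
  cat_mix <- as.numeric(per_n %*% mixture$weights)
  # colocalized pairs: exactly two visible monomers, steps ~ Binom(2, q)
  cat_col <- coloc_two_step * c(2 * q * (1 - q), q^2, 0)
  p <- cat_mix + cat_col
  p <- p / sum(p)
  names(p) <- c("one", "two", "multi")
  p
}

#' Step-detection probability implied by acquisition settings
#'
#' Probability that a fluorophore bleaches — and therefore produces a
#' countable step — within the recorded movie: `1 - (1 - bleach_rate)^n_frames`.
#'
#' @param acq an [acq_params()].
#' @return Probability in (0, 1).
#' @export
detect_prob_from_acq <- function(acq) {
  1 - (1 - acq$bleach_rate)^acq$n_frames
}

#' Subtract the monomer-control colocalization baseline
#'
#' Reduces the two-step fraction by the baseline measured with a monomeric
#' control protein at comparable density, reassigning the removed mass to
#' the one-step category (those spots were really two monomers). Clipped at
#' zero with a warning when the baseline exceeds the observed two-step
#' fraction. The corrected fractions are re-expressed over the same number
#' of analyzed spots.
#'
#' @param hist a `step_histogram`.
#' @param baseline_two_step baseline two-step fraction in `[0, 1)`.
#' @return A corrected `step_histogram`; the correction is recorded in the
#'   `correction` element.
#' @examples
#' h <- step_histogram_from_counts(c(one_step = 94, two_step = 6, multistep = 0))
#' subtract_baseline(h, 0.03)$fractions
#' @export
subtract_baseline <- function(hist, baseline_two_step = 0.03) {
  stopifnot(inherits(hist, "step_histogram"))
  if (baseline_two_step < 0 || baseline_two_step >= 1)
    stop("`baseline_two_step` must lie in [0, 1)", call. = FALSE)
  f <- hist$fractions
  removed <- min(f[["two_step"]], baseline_two_step)
  if (baseline_two_step > f[["two_step"]])
    warning("baseline exceeds observed two-step fraction; clipping at 0")
  f2 <- c(one_step = f[["one_step"]] + removed,
          two_step = f[["two_step"]] - removed,
          multistep = f[["multistep"]])
  out <- hist
  out$fractions <- f2
  out$counts <- round(f2 * hist$n_analyzed)
  out$ci <- vapply(f2, function(p) wilson_ci(p, hist$n_analyzed), numeric(2))
  rownames(out$ci) <- c("lower", "upper")
  out$correction <- list(baseline_two_step = baseline_two_step,
                         removed = removed, mode = "fraction_shift")
  out
}

#' Fit an oligomer mixture to a step-category histogram
#'
#' Maximum-likelihood inversion of the binomial dark-fraction forward model:
#' finds mixture weights on the simplex over `support` that maximize the
#' multinomial likelihood of the observed (one, two, multi) counts under
#' [predict_categories()] (colocalization included in the forward model).
#' Optimization is a deterministic fixed multi-start Nelder-Mead search in
#' softmax coordinates seeded from the simplex vertices and centre, so
#' identical inputs give identical fits. With only three observed
#' categories, supports larger than three sizes are not fully identifiable;
#' the fit then reports the ridge through a `flat_likelihood` flag (weights
#' differing by less than 2 log-likelihood units from the optimum over a
#' simplex grid span a wide range). A sensitivity sweep over the dark
#' probability is attached to every fit.
#'
#' @param hist a `step_histogram` (raw, uncorrected fractions), or a named
#'   numeric vector of category fractions/counts
#'   `(one_step, two_step, multistep)`.
#' @param p_dark per-fluorophore dark probability (known input, not
#'   estimated; EGFP-like tags run ~0.25--0.35).
#' @param support integer vector of candidate subunit counts.
#' @param coloc_two_step colocalization two-step fraction in the forward
#'   model.
#' @param detect_prob probability a visible fluorophore bleaches within the
#'   recording (see [detect_prob_from_acq()]); 1 for ideal counting.
#' @param n_spots effective number of spots when `hist` is given as bare
#'   fractions.
#' @param p_dark_sensitivity values of `p_dark` at which the fit is repeated
#'   for the attached sensitivity table.
#' @return An object of class `mixture_fit`; see [coef.mixture_fit()],
#'   [predict.mixture_fit()], [simulate.mixture_fit()].
#' @examples
#' h <- step_histogram_from_counts(c(one_step = 940, two_step = 60, multistep = 0))
#' fit <- fit_mixture(h, p_dark = 0.3, support = c(1, 2))
#' coef(fit)
#' @export
fit_mixture <- function(hist, p_dark = 0.30, support = c(1, 2, 4, 6),
                        coloc_two_step = 0.03, detect_prob = 1,
                        n_spots = NULL,
                        p_dark_sensitivity = c(0.25, 0.35)) {
  if (inherits(hist, "step_histogram")) {
    counts <- hist$counts
    if (hist$n_analyzed < 50)
      stop("need at least 50 analyzed spots to fit a mixture", call. = FALSE)
  } else {
    counts <- hist[c("one_step", "two_step", "multistep")]
    if (sum(counts) <= 1.5) {  # fractions: scale to effective spot count
      counts <- counts * (n_spots %||% 1000)
    }
  }
  support <- sort(unique(as.integer(support)))
  if (length(support) == 0L) stop("`support` must be non-empty", call. = FALSE)
  obs <- as.numeric(counts)

  fit1 <- fit_mixture_core(obs, p_dark, support, coloc_two_step, detect_prob)
  sens <- lapply(p_dark_sensitivity, function(p)
    fit_mixture_core(obs, p, support, coloc_two_step, detect_prob)$weights)
  names(sens) <- paste0("p_dark=", p_dark_sensitivity)

  structure(c(fit1,
              list(counts = setNames(obs, c("one_step", "two_step", "multistep")),
                   p_dark = p_dark, support = support,
                   coloc_two_step = coloc_two_step,
                   detect_prob = detect_prob,
                   sensitivity = sens)),
            class = "mixture_fit")
}

# multinomial ML on the simplex; deterministic multi-start Nelder-Mead in
# softmax coordinates
fit_mixture_core <- function(obs, p_dark, support, coloc_two_step,
                             detect_prob = 1) {
  K <- length(support)
  predict_w <- function(w) {
    mix <- oligomer_mixture(setNames(w, support), p_dark)
    predict_categories(mix, coloc_two_step, detect_prob)
  }
  nll <- function(theta) {
    w <- softmax(c(0, theta))
    p <- pmax(predict_w(w), 1e-12)
    -sum(obs * log(p))
  }
  if (K == 1L) {
    w <- 1
  } else if (K == 2L) {
    o <- stats::optimize(function(t) nll(t), interval = c(-14, 14),
                         tol = 1e-12)
    w <- softmax(c(0, o$minimum))
  } else {
    starts <- rbind(matrix(0, 1, K - 1), diag(4, K - 1), -diag(4, K - 1))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      o <- optim(starts[i, ], nll, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
      if (is.null(best) || o$value < best$value) best <- o
    }
    w <- softmax(c(0, best$par))
  }
  pred <- predict_w(w)
  ll <- sum(obs * log(pmax(pred, 1e-12)))
  flat <- mixture_ridge_flat(obs, p_dark, support, coloc_two_step, ll,
                             detect_prob = detect_prob)
  list(weights = setNames(w, support), predicted = pred, logLik = ll,
       converged = TRUE, flat_likelihood = flat)
}

softmax <- function(z) { e <- exp(z - max(z)); e / sum(e) }

# crude identifiability probe: scan a simplex grid; if weights within 2 LL
# units of the optimum span a range > 0.2 for any component, the likelihood
# is flat along a ridge (expected for supports larger than the 3 categories)
mixture_ridge_flat <- function(obs, p_dark, support, coloc_two_step, ll_max,
                               step = 0.1, detect_prob = 1) {
  K <- length(support)
  if (K <= 2L) return(FALSE)
  grid <- simplex_grid(K, step)
  lls <- apply(grid, 1, function(w) {
    mix <- oligomer_mixture(setNames(w, support), p_dark)
    p <- pmax(predict_categories(mix, coloc_two_step, detect_prob), 1e-12)
    sum(obs * log(p))
  })
  near <- grid[lls >= ll_max - 2, , drop = FALSE]
  if (nrow(near) < 2L) return(FALSE)
  any(apply(near, 2, function(col) diff(range(col))) > 0.2)
}

simplex_grid <- function(K, step = 0.1) {
  m <- round(1 / step)
  combos <- expand.grid(rep(list(0:m), K - 1))
  combos <- combos[rowSums(combos) <= m, , drop = FALSE]
  w <- cbind(combos, m - rowSums(combos)) / m
  as.matrix(unname(w))
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Oligomer mixture fit (binomial dark-fraction model)\n")
  cat(sprintf("  p_dark = %.2f, colocalization two-step = %.3f\n",
              x$p_dark, x$coloc_two_step))
  cat("  weights:\n")
  print(round(x$weights, 4))
  cat(sprintf("  log-likelihood: %.2f%s\n", x$logLik,
              if (isTRUE(x$flat_likelihood)) "  (flat ridge: support not fully identifiable from 3 categories)" else ""))
  invisible(x)
}

#' @export
#' @rdname fit_mixture
#' @param object,x a `mixture_fit`.
#' @param ... unused.
coef.mixture_fit <- function(object, ...) object$weights

#' @export
summary.mixture_fit <- function(object, ...) {
  obs <- object$counts / sum(object$counts)
  out <- list(weights = object$weights, predicted = object$predicted,
              observed = setNames(as.numeric(obs), c("one", "two", "multi")),
              logLik = object$logLik, p_dark = object$p_dark,
              sensitivity = object$sensitivity,
              flat_likelihood = object$flat_likelihood)
  class(out) <- "summary.mixture_fit"
  out
}

#' @export
print.summary.mixture_fit <- function(x, ...) {
  cat("Mixture fit summary\n  weights:\n"); print(round(x$weights, 4))
  cat("  observed vs predicted category fractions:\n")
  print(round(rbind(observed = x$observed, predicted = x$predicted), 4))
  cat("  p_dark sensitivity:\n")
  for (nm in names(x$sensitivity)) {
    cat("   ", nm, ": ", paste(round(x$sensitivity[[nm]], 3), collapse = " "), "\n")
  }
  invisible(x)
}

#' Predict step-category fractions from a fitted mixture
#'
#' @param object a `mixture_fit`.
#' @param coloc_two_step override the colocalization fraction used at fit
#'   time (default: same).
#' @param ... unused.
#' @return Named `(one, two, multi)` fractions.
#' @export
predict.mixture_fit <- function(object, coloc_two_step = NULL,
                                detect_prob = NULL, ...) {
  mix <- oligomer_mixture(setNames(object$weights, object$support),
                          object$p_dark)
  predict_categories(mix, coloc_two_step %||% object$coloc_two_step,
                     detect_prob %||% (object$detect_prob %||% 1))
}

#' Forward-simulate spots from a fitted mixture
#'
#' Draws spot assemblies from the fitted weights (with colocalized
#' two-monomer spots injected at the fitted rate), applies the dark
#' fraction, and optionally pushes every spot through the full
#' trace-simulation + change-point detection pipeline. This is the
#' round-trip used to validate that the detector reproduces the category
#' fractions the mixture was fitted to.
#'
#' @param object a `mixture_fit`.
#' @param nsim number of visible spots to simulate.
#' @param seed optional integer seed.
#' @param acq an [acq_params()] for trace simulation (`pipeline = TRUE`).
#' @param pipeline if `TRUE` (default) simulate noisy traces and count steps
#'   with [count_steps()]; if `FALSE` use ideal counting (observed steps =
#'   visible fluorophores).
#' @param ... passed to [count_steps()].
#' @return A `step_histogram` with attribute `"calls"` (the per-spot calls
#'   when `pipeline = TRUE`).
#' @export
simulate.mixture_fit <- function(object, nsim = 5000, seed = NULL,
                                 acq = acq_params(shot = FALSE, read_sd = 20),
                                 pipeline = TRUE, ...) {
  with_seed(seed, {
    c_rate <- object$coloc_two_step
    n_coloc <- rbinom(1, nsim, c_rate / (1 + c_rate))
    n_mix <- nsim - n_coloc
    sizes <- if (length(object$support) == 1L) rep(object$support, n_mix) else
      sample(object$support, n_mix, replace = TRUE, prob = object$weights)
    vis <- rbinom(n_mix, sizes, 1 - object$p_dark)
    # condition on visibility (dark spots are never seen)
    while (any(vis == 0L)) {
      redo <- which(vis == 0L)
      vis[redo] <- rbinom(length(redo), sizes[redo], 1 - object$p_dark)
    }
    n_visible <- c(vis, rep(2L, n_coloc))  # colocalized pairs: two visible monomers
    if (!pipeline) {
      counts <- c(one_step = sum(n_visible == 1L),
                  two_step = sum(n_visible == 2L),
                  multistep = sum(n_visible >= 3L))
      return(step_histogram_from_counts(counts))
    }
    calls <- lapply(n_visible, function(nv)
      count_steps(simulate_trace(nv, acq), ...))
    h <- build_histogram(calls)
    attr(h, "calls") <- calls
    h
  })
}

#' Bootstrap confidence intervals for step histograms and mixture weights
#'
#' Nonparametric bootstrap over spots: resamples the per-spot category
#' calls, recomputes category fractions (and, optionally, the mixture fit)
#' per resample, and returns percentile intervals. Seeded and reproducible.
#'
#' @param calls list of `step_call` objects, or a `step_histogram` (counts
#'   are expanded into per-spot categories).
#' @param B number of resamples (>= 200).
#' @param seed optional integer seed.
#' @param fit optional function applied to each resampled `step_histogram`
#'   returning a numeric vector (e.g. mixture weights); intervals for it are
#'   returned alongside the per-category ones.
#' @param conf confidence level.
#' @return A list with `category_ci` (2 x 3 matrix) and, when `fit` is
#'   given, `fit_ci`.
#' @export
bootstrap_histogram <- function(calls, B = 500, seed = NULL, fit = NULL,
                                conf = 0.95) {
  if (B < 200) stop("`B` must be at least 200", call. = FALSE)
  cats <- if (inherits(calls, "step_histogram"))
    rep(names(calls$counts), calls$counts)
  else vapply(calls, function(x) x$category, character(1))
  cats <- cats[cats %in% c("one_step", "two_step", "multistep")]
  n <- length(cats)
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  with_seed(seed, {
    fr <- matrix(0, B, 3, dimnames = list(NULL, c("one_step", "two_step", "multistep")))
    fitvals <- NULL
    for (b in seq_len(B)) {
      res <- cats[sample.int(n, n, replace = TRUE)]
      cnt <- c(one_step = sum(res == "one_step"),
               two_step = sum(res == "two_step"),
               multistep = sum(res == "multistep"))
      fr[b, ] <- cnt / n
      if (!is.null(fit)) {
        v <- fit(step_histogram_from_counts(cnt))
        if (is.null(fitvals)) fitvals <- matrix(NA_real_, B, length(v),
                                                dimnames = list(NULL, names(v)))
        fitvals[b, ] <- v
      }
    }
    out <- list(category_ci = apply(fr, 2, quantile, probs = probs))
    if (!is.null(fitvals)) out$fit_ci <- apply(fitvals, 2, quantile, probs = probs)
    out
  })
}
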