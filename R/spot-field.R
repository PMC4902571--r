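#' Sample a ground-truthed field of diffraction-limited spots
#'
#' Places molecules by a homogeneous spatial Poisson process at the density
#' given by `coloc`, draws each molecule's assembly size from the oligomer
#' mixture, merges any chain of assemblies pairwise closer than the merge
#' radius into a single unresolvable spot (origin `"colocalized"`), and
#' switches each fluorophore off independently with probability `p_dark`.
#' Spots with zero visible fluorophores are dropped: they would never be
#' picked up by a detector.
#'
#' @param mixture an [oligomer_mixture()].
#' @param coloc a [coloc_model()].
#' @param field_size length-1 or length-2 numeric, field of view in micron.
#' @param seed optional integer seed.
#' @param drop_invisible drop spots whose fluorophores are all dark
#'   (default `TRUE`). Set `FALSE` to keep the full ground truth.
#' @return A data.frame with one row per spot: `x`, `y` (micron), `n_total`
#'   (fluorophores present), `n_visible` (non-dark fluorophores), `origin`
#'   (`"true_oligomer"` or `"colocalized"`).
#' @examples
#' fld <- sample_spot_field(oligomer_mixture(c(`1` = 1), p_dark = 0.3),
#'                          coloc_model(density = 4), field_size = 50,
#'                          seed = 1)
#' mean(fld$n_visible == 2)
#' @export
sample_spot_field <- function(mixture, coloc, field_size = c(13, 13),
                              seed = NULL, drop_invisible = TRUE) {
  stopifnot(inherits(mixture, "oligomer_mixture"), inherits(coloc, "coloc_model"))
  if (length(field_size) == 1L) field_size <- rep(field_size, 2L)
  if (any(field_size <= 0)) stop("`field_size` must be positive", call. = FALSE)
  with_seed(seed, {
    area <- prod(field_size)
    n_mol <- rpois(1L, coloc$density * area)
    if (n_mol == 0L) {
      return(data.frame(x = numeric(0), y = numeric(0), n_total = integer(0),
                        n_visible = integer(0), origin = character(0)))
    }
    x <- runif(n_mol, 0, field_size[1])
    y <- runif(n_mol, 0, field_size[2])
    sizes <- if (length(mixture$n) == 1L) rep(mixture$n, n_mol) else
      sample(mixture$n, n_mol, replace = TRUE, prob = mixture$weights)
    cl <- .oc_merge_points(x, y, coloc$merge_radius)
    members <- tabulate(cl)
    n_total <- as.integer(rowsum(as.numeric(sizes), cl))
    sx <- as.numeric(rowsum(x, cl)) / members
    sy <- as.numeric(rowsum(y, cl)) / members
    n_visible <- rbinom(length(n_total), n_total, 1 - mixture$p_dark)
    origin <- ifelse(members > 1L, "colocalized", "true_oligomer")
    out <- data.frame(x = sx, y = sy, n_total = n_total,
                      n_visible = n_visible, origin = origin)
    if (drop_invisible) out <- out[out$n_visible > 0L, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "seed") <- seed
    out
  })
}

#' Expected two-step fraction from random colocalization
#'
#' Small-density closed form for the fraction of diffraction-limited spots
#' that show exactly two visible fluorophores purely because two
#' non-interacting molecules landed within one unresolvable spot:
#' \deqn{(\lambda \pi r^2 / 2)\,(1 - p_{dark})^2,}
#' where \eqn{\lambda} is the surface density and \eqn{r} the merge radius.
#' The derivation counts both-visible pairs per molecule, so it is the
#' fraction relative to all spots in the field; conditioning the denominator
#' on spots being visible raises the value by a factor of roughly
#' \eqn{1/(1-p_{dark})} (see the package vignette). Valid only while
#' \eqn{\lambda \pi r^2 \ll 1}; the function refuses when
#' \eqn{\lambda \pi r^2 > 0.5}.
#'
#' @param density molecules per square micron.
#' @param radius merge radius, micron.
#' @param p_dark per-fluorophore dark probability.
#' @return Expected two-step spot fraction (unitless).
#' @examples
#' expected_pair_fraction(4, 0.1, 0.3)  # ~0.031
#' @export
expected_pair_fraction <- function(density, radius, p_dark = 0.30) {
  if (density <= 0 || radius <= 0)
    stop("`density` and `radius` must be > 0", call. = FALSE)
  stopifnot_scalar_prob(p_dark, "p_dark")
  crowding <- density * pi * radius^2
  if (crowding > 0.5)
    stop(sprintf(
      "density * pi * radius^2 = %.3f > 0.5: small-density approximation invalid",
      crowding), call. = FALSE)
  (crowding / 2) * (1 - p_dark)^2
}

#' Monte-Carlo colocalization two-step fraction
#'
#' Simulates a purely monomeric spot field and measures the two-step fraction
#' arising from random colocalization under ideal step counting (every
#' visible fluorophore yields one step). Both normalizations are returned:
#' `per_spot` divides two-visible spots by all spots (the convention of
#' [expected_pair_fraction()]), `per_visible_spot` divides by spots with at
#' least one visible fluorophore (what an experiment tallies).
#'
#' @inheritParams expected_pair_fraction
#' @param field_size simulated field side, micron (area = side^2).
#' @param seed optional integer seed.
#' @return A list with `per_spot`, `per_visible_spot`, `n_spots`,
#'   `n_visible_spots`, `n_two_visible`, and the matching `analytic` value.
#' @export
coloc_two_step_mc <- function(density, radius, p_dark = 0.30,
                              field_size = 1000, seed = NULL) {
  mix <- oligomer_mixture(c(`1` = 1), p_dark = p_dark)
  fld <- sample_spot_field(mix, coloc_model(density, radius),
                           field_size = field_size, seed = seed,
                           drop_invisible = FALSE)
  n_two <- sum(fld$n_visible == 2L)
  n_vis <- sum(fld$n_visible > 0L)
  list(per_spot = n_two / nrow(fld),
       per_visible_spot = n_two / n_vis,
       n_spots = nrow(fld), n_visible_spots = n_vis, n_two_visible = n_two,
       analytic = expected_pair_fraction(density, radius, p_dark))
}
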