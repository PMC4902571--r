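#' Oligomer mixture
#'
#' The distribution of assembly sizes (monomer, dimer, tetramer, ...) in a
#' receptor population, together with the probability that any one
#' fluorescent-protein tag is dark (never matured to a fluorescent state).
#' Dark fluorophores are the reason observed photobleaching step counts
#' underestimate true subunit counts; for EGFP roughly 25--35% of molecules
#' are dark, and 0.30 is used as the default throughout.
#'
#' @param weights named numeric vector; names are subunit counts (positive
#'   integers), values are population fractions summing to 1.
#' @param p_dark probability a single fluorophore is dark, in `[0, 1]`.
#' @return An object of class `oligomer_mixture` with elements `n` (integer
#'   subunit sizes), `weights`, and `p_dark`.
#' @examples
#' oligomer_mixture(c(`1` = 0.97, `2` = 0.03), p_dark = 0.3)
#' @export
oligomer_mixture <- function(weights, p_dark = 0.30) {
  if (is.null(names(weights)) || any(names(weights) == ""))
    stop("`weights` must be a named vector (names = subunit counts)", call. = FALSE)
  n <- as.integer(names(weights))
  if (any(is.na(n)) || any(n < 1L))
    stop("subunit counts must be positive integers", call. = FALSE)
  w <- as.numeric(weights)
  if (any(w < 0)) stop("mixture weights must be non-negative", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-9)
    stop("mixture weights must sum to 1 (within 1e-9)", call. = FALSE)
  stopifnot_scalar_prob(p_dark, "p_dark")
  structure(list(n = n, weights = w, p_dark = p_dark),
            class = "oligomer_mixture")
}

#' @export
print.oligomer_mixture <- function(x, ...) {
  cat("Oligomer mixture (p_dark =", format(x$p_dark), ")\n")
  print(setNames(round(x$weights, 4), paste0("n=", x$n)))
  invisible(x)
}

#' Random-colocalization model
#'
#' Describes how often non-interacting molecules fall within one
#' diffraction-limited spot: molecules are placed by a homogeneous Poisson
#' process at `density` and any two emitters closer than `merge_radius` are
#' unresolvable and appear as one spot.
#'
#' @param density molecules per square micron (typical single-molecule TIRF
#'   experiments run at ~1--5).
#' @param merge_radius micron; default 0.1 (diffraction-limited co-occupancy).
#' @return An object of class `coloc_model`.
#' @export
coloc_model <- function(density, merge_radius = 0.1) {
  if (!is.numeric(density) || density <= 0) stop("`density` must be > 0", call. = FALSE)
  if (!is.numeric(merge_radius) || merge_radius <= 0)
    stop("`merge_radius` must be > 0", call. = FALSE)
  structure(list(density = density, merge_radius = merge_radius),
            class = "coloc_model")
}

#' TIRF acquisition parameters
#'
#' Camera/illumination settings for simulated photobleaching movies and
#' traces. Defaults follow the typical single-molecule oocyte protocol:
#' 20 Hz frame rate, 500 frames, a 13 x 13 micron field and EMCCD-like noise
#' (Poisson shot noise plus Gaussian read noise).
#'
#' @param frame_rate frames per second.
#' @param n_frames number of frames (expected range 500--800 for full
#'   photobleaching movies; at least 50 for detection-only stacks — step
#'   analysis itself requires 100-frame traces).
#' @param field_size length-2 numeric, field of view in micron.
#' @param pixel_size micron per pixel.
#' @param psf_sigma Gaussian PSF sigma in micron.
#' @param unit_brightness expected counts per fluorophore per frame.
#' @param read_sd Gaussian read-noise SD in counts (0 disables).
#' @param shot logical; add Poisson shot noise on the signal.
#' @param bleach_rate per-frame bleaching hazard per fluorophore, in (0, 1).
#' @param blink_prob per-frame probability that a live fluorophore is
#'   transiently dark (reversible blinking); 0 by default — step counting
#'   assumes clean irreversible bleaching, and this flag exists for
#'   robustness testing only.
#' @param baseline camera offset in counts.
#' @return An object of class `acq_params`.
#' @export
acq_params <- function(frame_rate = 20, n_frames = 500,
                       field_size = c(13, 13), pixel_size = 0.1,
                       psf_sigma = 0.125, unit_brightness = 100,
                       read_sd = 0, shot = TRUE,
                       bleach_rate = 0.005, blink_prob = 0, baseline = 0) {
  if (frame_rate <= 0) stop("`frame_rate` must be > 0", call. = FALSE)
  if (n_frames < 50) stop("`n_frames` must be at least 50", call. = FALSE)
  if (bleach_rate <= 0 || bleach_rate >= 1)
    stop("`bleach_rate` must lie in (0, 1)", call. = FALSE)
  stopifnot_scalar_prob(blink_prob, "blink_prob")
  if (length(field_size) == 1L) field_size <- rep(field_size, 2L)
  structure(list(frame_rate = frame_rate, n_frames = as.integer(n_frames),
                 field_size = field_size, pixel_size = pixel_size,
                 psf_sigma = psf_sigma, unit_brightness = unit_brightness,
                 read_sd = read_sd, shot = isTRUE(shot),
                 bleach_rate = bleach_rate, blink_prob = blink_prob,
                 baseline = baseline),
            class = "acq_params")
}

#' Pulsed-interleaved excitation timing
#'
#' Two pulsed lasers alternate with a fixed nanosecond offset so each
#' photon's originating laser is identifiable from its microtime. With the
#' default 50 ns interleave delay and a 50 ns gate, red-detector photons that
#' follow a 488 nm pulse within the gate are rejected, removing green-to-red
#' bleed-through, FRET and direct red-fluorophore excitation by the blue
#' laser.
#'
#' @param pulse_period laser repetition period, ns.
#' @param interleave_delay green-to-red pulse offset, ns.
#' @param gate_window rejection window after the "wrong" pulse, ns; must not
#'   exceed `interleave_delay`.
#' @return An object of class `pie_config`.
#' @export
pie_config <- function(pulse_period = 100, interleave_delay = 50,
                       gate_window = 50) {
  if (interleave_delay <= 0) stop("`interleave_delay` must be > 0", call. = FALSE)
  if (gate_window > interleave_delay)
    stop("`gate_window` must not exceed `interleave_delay`", call. = FALSE)
  if (pulse_period < 2 * interleave_delay)
    stop("`pulse_period` must accommodate both pulses", call. = FALSE)
  structure(list(pulse_period = pulse_period,
                 interleave_delay = interleave_delay,
                 gate_window = gate_window),
            class = "pie_config")
}

#' Dual-color membrane diffusion simulation settings
#'
#' Conditions for the two-color photon-stream generator used to exercise the
#' PIE-FCCS pipeline: particles diffuse in a periodic 2D box through a
#' Gaussian detection profile. `co_diffusing_fraction` is the fraction of
#' each color's labelled particles that carry *both* labels (the quantity the
#' fraction-correlated estimator targets); the remainder is split into
#' green-only and red-only populations of equal size.
#'
#' @param diffusion_coeff micron^2/s (one value, or per class as a named list
#'   with entries `dual`, `green`, `red`).
#' @param co_diffusing_fraction fraction of labelled particles carrying both
#'   colors, in `[0, 1]`.
#' @param n_in_focus mean number of labelled particles of each color inside
#'   the effective detection area (pi * waist^2); sets particle numbers.
#' @param box_size periodic box side, micron. The box must be large
#'   relative to the beam waist: with a conserved particle number the
#'   discrete diffusion modes of a small periodic box measurably shorten
#'   the apparent correlation decay (about 9% on D at 2.5 um, under 3% at
#'   the 5 um default).
#' @param beam_waist 1/e^2 Gaussian beam waist, micron (both colors).
#' @param duration total acquisition, s (the standard protocol is five 15 s
#'   segments, i.e. 75 s).
#' @param brightness peak molecular brightness, photons/s at beam center.
#' @param background_rate uncorrelated background, photons/s per channel.
#' @param crosstalk fraction of green emission also detected in the red
#'   channel (removable by PIE gating).
#' @param bin_width internal simulation/binning resolution, s.
#' @return An object of class `membrane_sim_config`.
#' @export
membrane_sim_config <- function(diffusion_coeff = 0.4,
                                co_diffusing_fraction = 0,
                                n_in_focus = 5,
                                box_size = 5,
                                beam_waist = 0.25,
                                duration = 75,
                                brightness = 8e3,
                                background_rate = 0,
                                crosstalk = 0,
                                bin_width = 1e-4) {
  stopifnot_scalar_prob(co_diffusing_fraction, "co_diffusing_fraction")
  stopifnot_scalar_prob(crosstalk, "crosstalk")
  if (duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  if (is.list(diffusion_coeff)) {
    D <- list(dual = diffusion_coeff$dual %||% diffusion_coeff[[1]],
              green = diffusion_coeff$green %||% diffusion_coeff[[1]],
              red = diffusion_coeff$red %||% diffusion_coeff[[1]])
  } else {
    D <- list(dual = diffusion_coeff, green = diffusion_coeff,
              red = diffusion_coeff)
  }
  if (any(unlist(D) <= 0)) stop("diffusion coefficients must be > 0", call. = FALSE)
  structure(list(D = D, co_diffusing_fraction = co_diffusing_fraction,
                 n_in_focus = n_in_focus, box_size = box_size,
                 beam_waist = beam_waist, duration = duration,
                 brightness = brightness, background_rate = background_rate,
                 crosstalk = crosstalk, bin_width = bin_width),
            class = "membrane_sim_config")
}
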