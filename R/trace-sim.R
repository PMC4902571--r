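#' Simulate a photobleaching intensity trace
#'
#' Each visible fluorophore bleaches irreversibly at a geometric per-frame
#' hazard (`acq$bleach_rate`); the frame intensity is `unit_brightness`
#' times the number of not-yet-bleached fluorophores plus the camera
#' baseline, with optional Poisson shot noise on the signal and Gaussian
#' read noise. The true step frames are carried along as ground truth.
#'
#' @param n_visible number of visible fluorophores (>= 1).
#' @param acq an [acq_params()].
#' @param seed optional integer seed.
#' @return An object of class `fluor_trace`: list with `intensity` (counts
#'   per frame), `frame_rate`, `truth` (list with `n_visible`,
#'   `bleach_frames` — frame index at which each fluorophore's contribution
#'   disappears, possibly beyond the last frame if censored).
#' @examples
#' tr <- simulate_trace(2, acq_params(read_sd = 0, shot = FALSE), seed = 1)
#' @export
simulate_trace <- function(n_visible, acq = acq_params(), seed = NULL) {
  if (is.data.frame(n_visible)) n_visible <- n_visible$n_visible
  n_visible <- as.integer(n_visible)
  if (length(n_visible) != 1L || is.na(n_visible) || n_visible < 1L)
    stop("`n_visible` must be a single integer >= 1 (spot must be visible)",
         call. = FALSE)
  with_seed(seed, {
    nf <- acq$n_frames
    bleach <- rgeom(n_visible, acq$bleach_rate) + 1L  # frame of disappearance
    # level[f]: fluorophores alive during frame f (bleach happens entering frame)
    level <- alive_per_frame(bleach, nf)
    if (acq$blink_prob > 0)
      level <- level - rbinom(nf, level, acq$blink_prob)
    signal <- acq$unit_brightness * level
    if (acq$shot) signal <- rpois(nf, signal)
    intensity <- signal + acq$baseline
    if (acq$read_sd > 0) intensity <- intensity + rnorm(nf, 0, acq$read_sd)
    structure(list(intensity = as.numeric(intensity),
                   frame_rate = acq$frame_rate,
                   truth = list(n_visible = n_visible,
                                bleach_frames = sort(bleach))),
              class = "fluor_trace")
  })
}

# number of fluorophores still emitting during each frame, given the frame
# at which each one's contribution disappears
alive_per_frame <- function(bleach, nf) {
  gone <- cumsum(tabulate(pmin(bleach, nf + 1L), nbins = nf + 1L))
  length(bleach) - c(0L, gone[seq_len(nf - 1L)])
}

#' Simulate a batch of photobleaching traces
#'
#' Convenience wrapper drawing many spots' traces under shared acquisition
#' settings, e.g. directly from the `n_visible` column of
#' [sample_spot_field()] output.
#'
#' @param n_visible integer vector of visible-fluorophore counts (one spot
#'   each; zeros are not allowed).
#' @param acq an [acq_params()].
#' @param seed optional integer seed.
#' @return A list of `fluor_trace` objects.
#' @export
simulate_trace_set <- function(n_visible, acq = acq_params(), seed = NULL) {
  if (is.data.frame(n_visible)) n_visible <- n_visible$n_visible
  n_visible <- as.integer(n_visible)
  if (any(n_visible < 1L)) stop("all spots must have >= 1 visible fluorophore",
                                call. = FALSE)
  with_seed(seed, lapply(n_visible, simulate_trace, acq = acq))
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("Fluorescence trace: %d frames at %g Hz (%d visible fluorophores)\n",
              length(x$intensity), x$frame_rate, x$truth$n_visible))
  invisible(x)
}

#' Render a TIRF movie from a spot field
#'
#' Sums, frame by frame, the Gaussian point-spread functions of all
#' not-yet-bleached fluorophores on a pixel grid, then applies the
#' EMCCD-like noise model (Poisson shot noise plus Gaussian read noise).
#' Each spot's PSF patch integrates to `unit_brightness` counts per
#' fluorophore per frame.
#'
#' @param field data.frame from [sample_spot_field()] (columns `x`, `y`,
#'   `n_visible`), or `NULL`/empty for a pure-noise stack.
#' @param acq an [acq_params()]; `field_size`, `pixel_size` and `psf_sigma`
#'   set the geometry.
#' @param seed optional integer seed.
#' @return An object of class `image_stack`: list with `frames` (array
#'   H x W x n_frames), `pixel_size`, `frame_rate`, and `truth` (per-spot
#'   positions and bleach times).
#' @export
render_movie <- function(field, acq = acq_params(), seed = NULL) {
  H <- round(acq$field_size[2] / acq$pixel_size)
  W <- round(acq$field_size[1] / acq$pixel_size)
  if (H < 4 || W < 4) stop("field/pixel size mismatch: image too small", call. = FALSE)
  nf <- acq$n_frames
  with_seed(seed, {
    frames <- array(0, dim = c(H, W, nf))
    truth <- NULL
    if (!is.null(field) && nrow(field) > 0L) {
      if (any(field$x < 0 | field$x > acq$field_size[1] |
              field$y < 0 | field$y > acq$field_size[2]))
        stop("assemblies must lie inside the field", call. = FALSE)
      sig_px <- acq$psf_sigma / acq$pixel_size
      half <- max(3L, ceiling(4 * sig_px))
      truth <- vector("list", nrow(field))
      for (i in seq_len(nrow(field))) {
        nv <- field$n_visible[i]
        if (nv < 1L) next
        cx <- field$x[i] / acq$pixel_size + 0.5  # pixel-centre coordinates
        cy <- field$y[i] / acq$pixel_size + 0.5
        px <- round(cx); py <- round(cy)
        cols <- max(1L, px - half):min(W, px + half)
        rows <- max(1L, py - half):min(H, py + half)
        patch <- outer(exp(-(rows - cy)^2 / (2 * sig_px^2)),
                       exp(-(cols - cx)^2 / (2 * sig_px^2)))
        patch <- patch / sum(patch) * acq$unit_brightness
        bleach <- rgeom(nv, acq$bleach_rate) + 1L
        level <- alive_per_frame(bleach, nf)
        contrib <- outer(as.vector(patch), level)
        dim(contrib) <- c(length(rows), length(cols), nf)
        frames[rows, cols, ] <- frames[rows, cols, ] + contrib
        truth[[i]] <- list(x = field$x[i], y = field$y[i],
                           n_visible = nv, bleach_frames = sort(bleach))
      }
    }
    if (acq$shot) frames[] <- rpois(length(frames), frames)
    frames <- frames + acq$baseline
    if (acq$read_sd > 0) frames <- frames + rnorm(length(frames), 0, acq$read_sd)
    structure(list(frames = frames, pixel_size = acq$pixel_size,
                   frame_rate = acq$frame_rate, truth = truth),
              class = "image_stack")
  })
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Image stack: %d x %d px, %d frames at %g Hz (%.3g um/px)\n",
              d[1], d[2], d[3], x$frame_rate, x$pixel_size))
  invisible(x)
}

#' Write / read a movie as multi-page TIFF
#'
#' Frames are stored as 32-bit float pages after scaling to `[0, 1]` by the
#' stack maximum; the scale factor is returned and must be supplied to
#' [read_movie_tiff()] to recover counts.
#'
#' @param stack an `image_stack`.
#' @param path file path.
#' @return `write_movie_tiff` invisibly returns the scale factor;
#'   `read_movie_tiff` returns an `image_stack`.
#' @export
write_movie_tiff <- function(stack, path) {
  frames <- stack$frames
  scale <- max(frames, 1e-12)
  pages <- lapply(seq_len(dim(frames)[3]), function(f) frames[, , f] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(scale)
}

#' @rdname write_movie_tiff
#' @param scale counts-per-unit scale factor returned by [write_movie_tiff()].
#' @param pixel_size,frame_rate metadata not carried by plain TIFF.
#' @export
read_movie_tiff <- function(path, scale = 1, pixel_size = 0.1, frame_rate = 20) {
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) frames[, , f] <- pages[[f]] * scale
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_rate = frame_rate, truth = NULL),
            class = "image_stack")
}
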