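#' Detect diffraction-limited spots in a TIRF movie
#'
#' Works on the temporal-mean image: candidate spots are local maxima
#' exceeding the robust background by `threshold_sd` robust standard
#' deviations (median / MAD of the mean image), refined to sub-pixel
#' positions by intensity-weighted centroiding in a window of ~4 PSF sigma.
#' Each candidate carries its fitted width (second-moment radius) and
#' background-subtracted peak intensity, which downstream filtering uses.
#'
#' @param stack an `image_stack` (from [render_movie()] or
#'   [read_movie_tiff()]); at least 50 frames.
#' @param psf_sigma expected PSF sigma, micron.
#' @param threshold_sd detection threshold in robust SDs above background.
#' @return A data.frame of candidates: `x`, `y` (micron), `peak`
#'   (background-subtracted mean-image peak), `width` (micron), `px`, `py`
#'   (integer pixel of the maximum).
#' @export
detect_spots <- function(stack, psf_sigma = 0.125, threshold_sd = 5) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  if (length(d) != 3L || d[3] < 50L)
    stop("stack must contain at least 50 frames", call. = FALSE)
  if (max(stack$frames) >= 65535)
    warning("stack contains saturated (16-bit full-scale) pixels")
  img <- rowMeans(stack$frames, dims = 2)
  bg <- median(img)
  noise <- mad(img)
  if (noise == 0) noise <- max(sd(img), .Machine$double.eps)
  thr <- bg + threshold_sd * noise
  H <- d[1]; W <- d[2]
  # strict local maxima over the 8-neighborhood, away from a 1 px border
  core <- img[2:(H - 1), 2:(W - 1)]
  is_max <- core > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- img[(2 + dy):(H - 1 + dy), (2 + dx):(W - 1 + dx)]
    is_max <- is_max & (core >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), peak = numeric(0),
                      width = numeric(0), px = integer(0), py = integer(0)))
  py <- idx[, 1] + 1L; px <- idx[, 2] + 1L
  sig_px <- psf_sigma / stack$pixel_size
  half <- max(2L, ceiling(2.5 * sig_px))
  out <- data.frame(x = NA_real_, y = NA_real_, peak = img[cbind(py, px)] - bg,
                    width = NA_real_, px = px, py = py)[order(-img[cbind(py, px)]), ]
  for (i in seq_len(nrow(out))) {
    rows <- max(1L, out$py[i] - half):min(H, out$py[i] + half)
    cols <- max(1L, out$px[i] - half):min(W, out$px[i] + half)
    w <- pmax(img[rows, cols] - bg, 0)
    s <- sum(w)
    if (s <= 0) next
    cy <- sum(outer(rows, rep(1, length(cols))) * w) / s
    cx <- sum(outer(rep(1, length(rows)), cols) * w) / s
    vy <- sum(outer((rows - cy)^2, rep(1, length(cols))) * w) / s
    vx <- sum(outer(rep(1, length(rows)), (cols - cx)^2) * w) / s
    out$x[i] <- (cx - 0.5) * stack$pixel_size
    out$y[i] <- (cy - 0.5) * stack$pixel_size
    out$width[i] <- sqrt((vx + vy) / 2) * stack$pixel_size
  }
  out <- out[complete.cases(out), , drop = FALSE]
  # collapse duplicate maxima refined to (nearly) the same centre
  if (nrow(out) > 1L) {
    keep <- rep(TRUE, nrow(out))
    for (i in 2:nrow(out)) {
      dmin <- min(sqrt((out$x[i] - out$x[1:(i - 1)])^2 +
                       (out$y[i] - out$y[1:(i - 1)])^2)[keep[1:(i - 1)]])
      if (dmin < 2 * psf_sigma) keep[i] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Filter spot candidates before trace extraction
#'
#' Applies the exclusions used in single-molecule step counting: spots with
#' a neighbor closer than `min_separation` are removed in pairs
#' (overlapping traces cannot be attributed), and unusually bright or wide
#' spots — aggregates and other irregular objects that appear after ligand
#' addition — are removed when their peak brightness exceeds
#' `brightness_cap` robust z-scores or their fitted width exceeds
#' `width_cap` times the PSF sigma.
#'
#' @param candidates data.frame from [detect_spots()].
#' @param psf_sigma PSF sigma, micron.
#' @param min_separation micron; default 0.5.
#' @param brightness_cap robust z-score cap on peak brightness; default 5.
#' @param width_cap width cap as a multiple of `psf_sigma`; default 1.5.
#' @return A list with `accepted` (data.frame) and `rejections` (data.frame
#'   with `x`, `y`, `reason` in `overlapping` / `bright_irregular`).
#' @export
filter_spots <- function(candidates, psf_sigma = 0.125, min_separation = 0.5,
                         brightness_cap = 5, width_cap = 1.5) {
  n <- nrow(candidates)
  reason <- rep(NA_character_, n)
  if (n > 1L) {
    dmat <- as.matrix(dist(candidates[, c("x", "y")]))
    diag(dmat) <- Inf
    reason[apply(dmat < min_separation, 1, any)] <- "overlapping"
  }
  if (n > 0L) {
    med <- median(candidates$peak)
    s <- mad(candidates$peak)
    if (s == 0) s <- max(sd(candidates$peak), .Machine$double.eps)
    z <- (candidates$peak - med) / s
    bad <- is.na(reason) & (z > brightness_cap | candidates$width > width_cap * psf_sigma)
    reason[bad] <- "bright_irregular"
  }
  list(accepted = candidates[is.na(reason), , drop = FALSE],
       rejections = cbind(candidates[!is.na(reason), c("x", "y"), drop = FALSE],
                          reason = reason[!is.na(reason)]))
}

#' Extract per-spot intensity traces from a movie
#'
#' For each accepted spot, sums pixels inside a fixed circular aperture of
#' radius `3 * psf_sigma` centred on the (immobile) spot position, and
#' subtracts a local background estimated frame-by-frame as the median of an
#' annulus between 4 and 6 PSF sigma, scaled to the aperture area. Spots
#' whose aperture would cross the image edge are skipped with a log entry.
#'
#' @param stack an `image_stack`.
#' @param spots data.frame with `x`, `y` in micron ([filter_spots()] output
#'   `accepted`).
#' @param psf_sigma PSF sigma, micron.
#' @return A list with `traces` (list of `fluor_trace`) and `skipped`
#'   (data.frame of spots at the edge).
#' @export
extract_traces <- function(stack, spots, psf_sigma = 0.125) {
  d <- dim(stack$frames)
  H <- d[1]; W <- d[2]; nf <- d[3]
  px_ap <- 3 * psf_sigma / stack$pixel_size
  px_out <- 6 * psf_sigma / stack$pixel_size
  half <- ceiling(px_out)
  traces <- list(); skipped <- list()
  flat <- matrix(stack$frames, nrow = H * W, ncol = nf)
  for (i in seq_len(nrow(spots))) {
    cx <- spots$x[i] / stack$pixel_size + 0.5
    cy <- spots$y[i] / stack$pixel_size + 0.5
    if (cx - px_ap < 1 || cx + px_ap > W || cy - px_ap < 1 || cy + px_ap > H) {
      skipped[[length(skipped) + 1L]] <- spots[i, c("x", "y")]
      next
    }
    rows <- max(1L, round(cy) - half):min(H, round(cy) + half)
    cols <- max(1L, round(cx) - half):min(W, round(cx) + half)
    rr2 <- outer((rows - cy)^2, (cols - cx)^2, `+`)
    ap <- rr2 <= px_ap^2
    ann <- rr2 >= (4 * psf_sigma / stack$pixel_size)^2 & rr2 <= px_out^2
    lin <- as.vector(outer(rows, (cols - 1L) * H, `+`))
    sub <- flat[lin, , drop = FALSE]
    ap_sum <- colSums(sub[as.vector(ap), , drop = FALSE])
    bg <- if (any(ann)) apply(sub[as.vector(ann), , drop = FALSE], 2, median) else 0
    traces[[length(traces) + 1L]] <- structure(
      list(intensity = ap_sum - bg * sum(ap), frame_rate = stack$frame_rate,
           position = c(spots$x[i], spots$y[i]), truth = NULL),
      class = "fluor_trace")
  }
  list(traces = traces,
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(x = numeric(0), y = numeric(0)))
}
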