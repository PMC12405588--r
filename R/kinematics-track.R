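#' Construct an 11-point midline track
#'
#' Container for one larva's tracked midline: sample times (possibly at the
#' tracker's irregular framerate) and, per sample, 11 ordered (x, y) spine
#' points with point 1 the head and point 11 the tail.
#'
#' @param larva_id Identifier (coerced to character).
#' @param times Sample times (s), strictly increasing.
#' @param x,y T x 11 numeric matrices of spine coordinates (mm).
#' @param stimulus_onset Stimulus onset time (s); the air puff is delivered
#'   at the 60th second by convention.
#' @param stimulus_duration Stimulus duration (s); 30 s by convention.
#' @return Object of class \code{spine_track}.
#' @export
spine_track <- function(larva_id, times, x, y,
                        stimulus_onset = 60, stimulus_duration = 30) {
  x <- as.matrix(x); y <- as.matrix(y)
  times <- as.numeric(times)
  if (ncol(x) != 11L || ncol(y) != 11L) stop("x and y must have 11 columns")
  if (nrow(x) != length(times) || nrow(y) != length(times))
    stop("times, x, y must have matching sample counts")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite coordinates in track ", larva_id)
  structure(list(larva_id = as.character(larva_id), times = times,
                 x = unname(x), y = unname(y),
                 stimulus_onset = stimulus_onset,
                 stimulus_duration = stimulus_duration,
                 preprocessed = FALSE),
            class = "spine_track")
}

#' @export
print.spine_track <- function(x, ...) {
  cat("spine_track '", x$larva_id, "': ", length(x$times), " samples over [",
      round(min(x$times), 2), ", ", round(max(x$times), 2), "] s",
      if (x$preprocessed) " (preprocessed, 10 Hz)" else "", "\n", sep = "")
  invisible(x)
}

#' Orient a track head-first
#'
#' Tracking software does not always emit the spine head-first. The head
#' travels farther than the tail over a recording (lateral head sweeps and
#' bends add path on top of the common translation), so when the putative
#' tail point accumulates clearly more path than the putative head point,
#' the point order is reversed. The margin keeps tracks without
#' head-dominated movements (pure straight crawling, where the two ends
#' travel equally) in their original orientation rather than flipping on
#' noise.
#'
#' @param track A [spine_track()].
#' @param margin Relative excess of tail over head path required to flip.
#' @return The track, with point 1 the head.
#' @export
orient_head_first <- function(track, margin = 0.05) {
  path_of <- function(j) {
    sum(sqrt(diff(track$x[, j])^2 + diff(track$y[, j])^2))
  }
  if (path_of(11) > (1 + margin) * path_of(1)) {
    track$x <- track$x[, 11:1, drop = FALSE]
    track$y <- track$y[, 11:1, drop = FALSE]
  }
  track
}

#' Resample a track to 10 Hz and low-pass filter it
#'
#' Coordinates are linearly interpolated onto a regular 0.1 s grid covering
#' the original time span, then smoothed with a zero-phase Butterworth
#' low-pass filter with a 2 Hz cut-off -- high enough not to alter the
#' crawling-related dynamics around the dominant ~1.4 Hz peristaltic
#' frequency while rejecting tracking jitter.
#'
#' @param track A [spine_track()].
#' @param dt Target timestep (s).
#' @param cutoff_hz Low-pass cut-off frequency (Hz).
#' @param order Butterworth order (applied forward and backward).
#' @param orient Apply the [orient_head_first()] check first?
#' @return A preprocessed \code{spine_track} on the regular grid.
#' @export
preprocess_track <- function(track, dt = 0.1, cutoff_hz = 2, order = 6,
                             orient = TRUE) {
  stopifnot(inherits(track, "spine_track"))
  if (orient) track <- orient_head_first(track)
  span <- diff(range(track$times))
  if (length(track$times) < 2 || span < 1)
    stop("track span too short for preprocessing: ", signif(span, 3), " s")
  t0 <- track$times[1]
  grid <- seq(t0, track$times[length(track$times)], by = dt)
  interp <- function(col, src) stats::approx(track$times, src[, col], xout = grid)$y
  xi <- vapply(1:11, interp, numeric(length(grid)), src = track$x)
  yi <- vapply(1:11, interp, numeric(length(grid)), src = track$y)
  # zero-phase filtering: no phase distortion of event (stride, stimulus) times;
  # odd-reflection padding suppresses the start/end transients of filtfilt
  bf <- signal::butter(order, cutoff_hz / (1 / dt / 2), type = "low")
  npad <- min(length(grid) - 1, 50)
  smooth <- function(v) {
    if (stats::sd(v) < .Machine$double.eps) return(v)  # constant channels pass through
    head_pad <- 2 * v[1] - v[(npad + 1):2]
    tail_pad <- 2 * v[length(v)] - v[(length(v) - 1):(length(v) - npad)]
    f <- as.numeric(signal::filtfilt(bf, c(head_pad, v, tail_pad)))
    f[(npad + 1):(npad + length(v))]
  }
  out <- track
  out$times <- grid
  out$x <- apply(xi, 2, smooth)
  out$y <- apply(yi, 2, smooth)
  out$preprocessed <- TRUE
  out
}

#' Median body length of a larva
#'
#' The instantaneous body length fluctuates during crawling through
#' successive stretching and contraction, so the individual's length is the
#' median over time of the midline polyline length through all 11 points.
#'
#' @param track A preprocessed [spine_track()].
#' @return Scalar length (mm).
#' @export
body_length <- function(track) {
  stats::median(midline_length(track))
}

#' Instantaneous midline length
#'
#' @param track A [spine_track()].
#' @return Numeric vector, one polyline length (mm) per sample.
#' @export
midline_length <- function(track) {
  dx <- track$x[, -1, drop = FALSE] - track$x[, -11, drop = FALSE]
  dy <- track$y[, -1, drop = FALSE] - track$y[, -11, drop = FALSE]
  rowSums(sqrt(dx^2 + dy^2))
}

# centroid G = mean of the 11 midline points (proxy for the tracker's
# centre-of-mass output); isolated here so the definition lives in one place
.centroid <- function(track) {
  cbind(rowMeans(track$x), rowMeans(track$y))
}

# central-difference velocity of an T x 2 position series (mm/s)
.velocity <- function(pos, times) {
  n <- nrow(pos)
  if (n < 2) stop("need at least 2 samples for a velocity")
  v <- matrix(0, n, 2)
  v[1, ] <- (pos[2, ] - pos[1, ]) / (times[2] - times[1])
  v[n, ] <- (pos[n, ] - pos[n - 1, ]) / (times[n] - times[n - 1])
  if (n > 2) {
    idx <- 2:(n - 1)
    v[idx, ] <- (pos[idx + 1, ] - pos[idx - 1, ]) / (times[idx + 1] - times[idx - 1])
  }
  v
}
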