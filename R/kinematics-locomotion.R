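#' Path length and dispersal of a trajectory
#'
#' Both metrics use the 9th midline point as the larva's position: a
#' relatively stable rear point unaffected by lateral head sweeps and
#' peristaltic jitter. Path length is the cumulative displacement; dispersal
#' is the instantaneous straight-line distance from the initial position.
#'
#' @param track A preprocessed [spine_track()].
#' @param scale_bl Divide both series by the median body length?
#' @return Data frame with columns \code{t}, \code{pathlength},
#'   \code{dispersal} (mm, or BL when scaled).
#' @export
path_metrics <- function(track, scale_bl = FALSE) {
  px <- track$x[, 9]; py <- track$y[, 9]
  step <- c(0, sqrt(diff(px)^2 + diff(py)^2))
  pathlength <- cumsum(step)
  dispersal <- sqrt((px - px[1])^2 + (py - py[1])^2)
  if (scale_bl) {
    bl <- body_length(track)
    pathlength <- pathlength / bl
    dispersal <- dispersal / bl
  }
  data.frame(t = track$times, pathlength = pathlength, dispersal = dispersal)
}

#' Straightness index of a trajectory
#'
#' A fixed time window is advanced along the track; at each point the ratio
#' of the dispersal accrued within the trailing window to the distance
#' actually travelled in it is reported. The index runs from 0 (no
#' movement, by convention) to 1 (straight-line movement) and captures the
#' tortuosity of the path at the scale set by the window.
#'
#' @param track A preprocessed [spine_track()].
#' @param window Window length (s).
#' @return Data frame with columns \code{t} and \code{si}; \code{si} is NA
#'   before the first full window.
#' @export
straightness_index <- function(track, window = 20) {
  span <- diff(range(track$times))
  if (span < window) stop("track span (", signif(span, 4),
                          " s) shorter than the ", window, " s window")
  pm <- path_metrics(track)
  n <- nrow(pm)
  dt <- stats::median(diff(pm$t))
  wsteps <- round(window / dt)
  si <- rep(NA_real_, n)
  px <- track$x[, 9]; py <- track$y[, 9]
  for (i in (wsteps + 1):n) {
    j <- i - wsteps
    travelled <- pm$pathlength[i] - pm$pathlength[j]
    disp <- sqrt((px[i] - px[j])^2 + (py[i] - py[j])^2)
    si[i] <- if (travelled < 1e-9) 0 else min(disp / travelled, 1)
  }
  data.frame(t = pm$t, si = si)
}

#' Dominant crawl frequency of a track
#'
#' Fourier analysis of the scaled crawling (centroid) speed: the frequency
#' of the spectral peak within a physiological band is taken as the
#' dominant peristaltic frequency, and its inverse as the expected duration
#' of one crawling cycle.
#'
#' @param track A preprocessed [spine_track()].
#' @param band Frequency band searched (Hz); crawling sits near 1.4 Hz.
#' @return List with \code{frequency} (Hz) and \code{cycle} (s).
#' @export
crawl_frequency <- function(track, band = c(0.5, 2.5)) {
  sp <- scaled_speeds(track)$centroid
  if (length(sp) < 100) stop("need at least 10 s of signal for a spectrum")
  v <- sp - mean(sp)
  # flat relative to the mean level: resampling residue is not a rhythm
  if (stats::sd(v) < 1e-4 * max(abs(mean(sp)), 1e-8))
    stop("flat speed signal: no dominant frequency")
  pg <- stats::spec.pgram(stats::ts(v, frequency = 1 / stats::median(diff(track$times))),
                          taper = 0, plot = FALSE, detrend = TRUE)
  inband <- pg$freq >= band[1] & pg$freq <= band[2]
  if (!any(inband)) stop("no spectral estimate inside the band [",
                         band[1], ", ", band[2], "] Hz")
  if (max(pg$spec[inband]) < 1e-12) stop("flat spectrum in the crawl band")
  f <- pg$freq[inband][which.max(pg$spec[inband])]
  list(frequency = f, cycle = 1 / f)
}

# strict local minima/maxima with plateaus broken at the leftmost sample
.local_extrema <- function(v, minima = TRUE) {
  s <- if (minima) -v else v
  n <- length(s)
  if (n < 3) return(integer(0))
  d <- diff(s)
  d[d == 0] <- .Machine$double.eps  # leftmost point of a plateau wins
  which(d[-1] < 0 & d[-(n - 1)] > 0) + 1L
}

#' Detect peristaltic strides
#'
#' A stride is the epoch between two consecutive local minima of the scaled
#' crawling speed that contains a local maximum of at least
#' \code{speed_threshold} and lasts between 0.7 and 1.5 times the expected
#' cycle duration (the inverse of the dominant crawl frequency).
#'
#' @param track A preprocessed [spine_track()].
#' @param cycle Expected cycle duration (s); computed from
#'   [crawl_frequency()] when NULL.
#' @param speed_threshold Minimum contained peak speed (BL/s).
#' @param duration_range Acceptable stride duration as multiples of the
#'   cycle.
#' @return Data frame of stride intervals: \code{start}, \code{end} (s),
#'   \code{peak_speed} (BL/s). Zero rows when no stride qualifies.
#' @export
detect_strides <- function(track, cycle = NULL, speed_threshold = 0.3,
                           duration_range = c(0.7, 1.5)) {
  if (is.null(cycle)) cycle <- crawl_frequency(track)$cycle
  sp <- scaled_speeds(track)$centroid
  minima <- .local_extrema(sp, minima = TRUE)
  out <- list()
  for (k in seq_len(length(minima) - 1)) {
    i <- minima[k]; j <- minima[k + 1]
    dur <- track$times[j] - track$times[i]
    if (dur < duration_range[1] * cycle || dur > duration_range[2] * cycle) next
    pk <- max(sp[i:j])
    if (pk < speed_threshold) next
    out[[length(out) + 1]] <- data.frame(start = track$times[i],
                                         end = track$times[j],
                                         peak_speed = pk)
  }
  if (!length(out)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      peak_speed = numeric(0)))
  }
  do.call(rbind, out)
}

#' Annotate runs and pauses from detected strides
#'
#' A run is an uninterrupted sequence of consecutive strides (gap of at most
#' one timestep between one stride's end and the next one's start); a
#' crawl-pause is a maximal stride-free epoch during which the scaled speed
#' stays below the stride threshold throughout.
#'
#' @param track A preprocessed [spine_track()].
#' @param strides Data frame from [detect_strides()].
#' @param speed_threshold Pause speed ceiling (BL/s).
#' @param min_pause Minimum pause duration (s); sub-threshold fragments
#'   shorter than a peristaltic cycle carry no behavioural meaning.
#' @return List of class \code{epoch_annotation}: \code{strides},
#'   \code{runs}, \code{pauses} (interval data frames), \code{cycle}.
#' @export
annotate_runs_pauses <- function(track, strides = NULL, speed_threshold = 0.3,
                                 min_pause = 0.5) {
  cf <- tryCatch(crawl_frequency(track), error = function(e) NULL)
  if (is.null(strides)) {
    strides <- if (is.null(cf)) {
      data.frame(start = numeric(0), end = numeric(0), peak_speed = numeric(0))
    } else detect_strides(track, cycle = cf$cycle,
                          speed_threshold = speed_threshold)
  }
  dt <- stats::median(diff(track$times))
  runs <- data.frame(start = numeric(0), end = numeric(0), n_strides = integer(0))
  if (nrow(strides)) {
    gap <- c(Inf, strides$start[-1] - strides$end[-nrow(strides)])
    grp <- cumsum(gap > dt + 1e-9)
    runs <- do.call(rbind, lapply(split(strides, grp), function(g) {
      data.frame(start = min(g$start), end = max(g$end), n_strides = nrow(g))
    }))
    rownames(runs) <- NULL
  }
  # stride-free samples below threshold, merged into maximal epochs
  sp <- scaled_speeds(track)$centroid
  in_stride <- rep(FALSE, length(sp))
  for (k in seq_len(nrow(strides))) {
    in_stride[track$times >= strides$start[k] - 1e-9 &
              track$times <= strides$end[k] + 1e-9] <- TRUE
  }
  quiet <- !in_stride & sp < speed_threshold
  pauses <- .bool_intervals(quiet, track$times)
  pauses <- pauses[pauses$end - pauses$start >= min_pause, , drop = FALSE]
  rownames(pauses) <- NULL
  structure(list(strides = strides, runs = runs, pauses = pauses,
                 cycle = if (is.null(cf)) NA_real_ else cf$cycle),
            class = "epoch_annotation")
}

# maximal TRUE runs of a logical vector as [start, end] time intervals
.bool_intervals <- function(flag, times) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(start = times[starts[keep]], end = times[ends[keep]])
}

#' @export
print.epoch_annotation <- function(x, ...) {
  cat("epoch_annotation:", nrow(x$strides), "strides,", nrow(x$runs),
      "runs,", nrow(x$pauses), "pauses; cycle =", signif(x$cycle, 3), "s\n")
  invisible(x)
}
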