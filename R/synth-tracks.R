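#' Configuration of the synthetic-track generator
#'
#' Collects every knob of the generator: cohort size, recording protocol
#' (95 s tracks with the stimulus delivered at the 60th second for 30 s),
#' body-size distribution, crawl kinematics (dominant peristaltic frequency
#' 1.4 Hz), per-action kinematic templates, the pre/post-stimulus action
#' tables, and the tracking noise (frame-rate jitter around the raw ~10 Hz
#' acquisition and coordinate noise). Action amplitudes are parameterised
#' caricatures chosen so the classification thresholds (0.3 BL/s stride
#' threshold, 0.3--0.6 Hunch length change) are meaningfully straddled; see
#' the methods vignette.
#'
#' @param seed Mandatory integer seed.
#' @param n_larvae Cohort size.
#' @param duration Track length (s).
#' @param stimulus_onset,stimulus_duration Stimulus timing (s).
#' @param body_length_mean,body_length_sd Body length distribution (mm).
#' @param crawl_freq Peristaltic frequency (Hz).
#' @param crawl_speed_peak Peak scaled crawl speed (BL/s).
#' @param cast_freq,cast_angle Head-cast sweep frequency (Hz) and maximum
#'   bend angle (rad).
#' @param bend_angle,bend_ramp Static-bend final angle (rad) and ramp (s).
#' @param hunch_contraction Fractional body-length contraction of a Hunch.
#' @param backup_speed Backward speed during a back-up (BL/s).
#' @param response_probs Named probabilities of the initial post-stimulus
#'   action (must sum to 1).
#' @param pre_probs Named probabilities of baseline actions (sum to 1).
#' @param action_durations Named mean action durations (s).
#' @param frame_rate_range Raw acquisition rate range (Hz) for timestamp
#'   jitter.
#' @param coord_noise Coordinate noise SD (mm).
#' @return List of class \code{generation_config}.
#' @export
generation_config <- function(seed,
                              n_larvae = 30,
                              duration = 95,
                              stimulus_onset = 60,
                              stimulus_duration = 30,
                              body_length_mean = 4,
                              body_length_sd = 0.3,
                              crawl_freq = 1.4,
                              crawl_speed_peak = 0.5,
                              cast_freq = 0.4,
                              cast_angle = 1.2,
                              bend_angle = 0.9,
                              bend_ramp = 1,
                              hunch_contraction = 0.4,
                              backup_speed = 0.15,
                              response_probs = c(hunch = 0.4, head_cast = 0.3,
                                                 stop = 0.2, back_up = 0.1),
                              pre_probs = c(crawl = 0.8, head_cast = 0.1,
                                            stop = 0.1),
                              action_durations = c(crawl = 4, head_cast = 1.5,
                                                   static_bend = 2.5,
                                                   hunch = 1, stop = 1.5,
                                                   back_up = 1.5),
                              frame_rate_range = c(8, 12),
                              coord_noise = 0.01) {
  if (missing(seed)) stop("seed is mandatory")
  for (p in list(response_probs, pre_probs)) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("action probability tables must be nonnegative and sum to 1")
    if (!all(names(p) %in% action_levels()))
      stop("unknown action in a probability table")
  }
  structure(as.list(environment()), class = "generation_config")
}

# fractional bend angle applied cumulatively over the 4 head segments
.synth_pose <- function(bl, len, beta, head_scale, anchor, heading) {
  u <- c(cos(heading), sin(heading))
  seg0 <- len / 10
  lens <- rep(seg0, 10)
  if (head_scale < 1) {
    lens[1:4] <- seg0 * head_scale           # head segments contract
    lens[5:10] <- (len - sum(lens[1:4])) / 6  # rest keeps the total length
  }
  dirs <- matrix(rep(u, each = 10), 10, 2)
  for (j in 1:4) {  # segments 1..4 curve progressively toward the head
    a <- beta * (5 - j) / 4
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    dirs[j, ] <- as.vector(R %*% u)
  }
  pts <- matrix(0, 11, 2)
  pts[11, ] <- anchor
  for (j in 10:1) pts[j, ] <- pts[j + 1, ] + dirs[j, ] * lens[j]
  pts
}

#' Generate one synthetic larva track from a timed action script
#'
#' Animates an 11-point midline according to per-action kinematic
#' templates: peristaltic speed and length oscillation at the configured
#' frequency during crawling, a lateral head sweep for Head Casts, a slow
#' head ramp into a held curved posture for Static Bends, a fast head-ward
#' length contraction for Hunches, immobility for Stops and slow backward
#' motion for Back-ups. Timestamps are jittered within the configured raw
#' frame-rate range and Gaussian coordinate noise is added; the ground
#' truth is returned as an [action_seq()] aligned to the canonical 10 Hz
#' grid.
#'
#' @param config A [generation_config()].
#' @param script Data frame with columns \code{action}, \code{start},
#'   \code{end} covering \code{[0, duration]} without overlaps.
#' @param larva_id Identifier for the track.
#' @return List with \code{track} (raw [spine_track()]), \code{truth}
#'   (ground-truth [action_seq()] on the 10 Hz grid), \code{script}.
#' @export
gen_track <- function(config, script, larva_id = "synthetic-1") {
  stopifnot(inherits(config, "generation_config"))
  script <- script[order(script$start), , drop = FALSE]
  if (nrow(script) > 1 &&
      any(script$start[-1] < script$end[-nrow(script)] - 1e-9))
    stop("overlapping script entries")
  if (script$start[1] > 1e-9 || script$end[nrow(script)] < config$duration - 1e-9)
    stop("script must cover the full duration")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(config$seed + .id_hash(larva_id))

  bl <- max(1, stats::rnorm(1, config$body_length_mean, config$body_length_sd))
  heading <- stats::runif(1, 0, 2 * pi)
  origin <- stats::runif(2, 40, 80)

  # raw irregular timestamps spanning exactly [0, duration]
  tt <- 0
  while (utils::tail(tt, 1) < config$duration) {
    tt <- c(tt, utils::tail(tt, 1) +
              1 / stats::runif(1, config$frame_rate_range[1],
                               config$frame_rate_range[2]))
  }
  tt[length(tt)] <- config$duration

  entry_at <- function(t) {
    k <- findInterval(t, script$start)
    as.integer(max(1, min(k, nrow(script))))
  }
  phase <- stats::runif(1, 0, 2 * pi)
  n <- length(tt)
  len <- numeric(n); beta <- numeric(n); hscale <- rep(1, n); v <- numeric(n)
  for (i in seq_len(n)) {
    k <- entry_at(tt[i])
    a <- script$action[k]
    tl <- tt[i] - script$start[k]
    dur <- script$end[k] - script$start[k]
    len[i] <- bl
    if (a == "crawl") {
      # mild in-phase length modulation: its centroid-velocity contribution
      # partially offsets the anchor speed, so keep it small to preserve the
      # stride-defining speed oscillation
      len[i] <- bl * (1 + 0.02 * sin(2 * pi * config$crawl_freq * tt[i] + phase))
      v[i] <- bl * config$crawl_speed_peak / 2 *
        (1 - cos(2 * pi * config$crawl_freq * tt[i] + phase))
    } else if (a == "head_cast") {
      beta[i] <- config$cast_angle * sin(2 * pi * config$cast_freq * tl)
    } else if (a == "static_bend") {
      beta[i] <- config$bend_angle * min(1, tl / config$bend_ramp)
    } else if (a == "hunch") {
      g <- sin(pi * min(tl, dur) / dur)
      len[i] <- bl * (1 - config$hunch_contraction * g)
      hscale[i] <- 1 - 1.8 * config$hunch_contraction * g
    } else if (a == "back_up") {
      v[i] <- -config$backup_speed * bl
    }
  }
  disp <- c(0, cumsum(diff(tt) * (v[-1] + v[-n]) / 2))
  x <- matrix(0, n, 11); y <- matrix(0, n, 11)
  u <- c(cos(heading), sin(heading))
  for (i in seq_len(n)) {
    anchor <- origin + u * disp[i]
    pts <- .synth_pose(bl, len[i], beta[i], hscale[i], anchor, heading)
    x[i, ] <- pts[, 1]; y[i, ] <- pts[, 2]
  }
  if (config$coord_noise > 0) {
    x <- x + stats::rnorm(length(x), 0, config$coord_noise)
    y <- y + stats::rnorm(length(y), 0, config$coord_noise)
  }
  track <- spine_track(larva_id, tt, x, y,
                       stimulus_onset = config$stimulus_onset,
                       stimulus_duration = config$stimulus_duration)
  grid <- seq(0, config$duration, by = 0.1)
  truth <- action_seq(grid,
                      script$action[vapply(grid, entry_at, 1L)],
                      stimulus_onset = config$stimulus_onset)
  list(track = track, truth = truth, script = script)
}

.id_hash <- function(id) {
  sum(utf8ToInt(as.character(id)) * seq_along(utf8ToInt(as.character(id)))) %% 10000L
}

# semi-Markov action script: i.i.d. categorical actions with exponential
# durations, switching tables at stimulus onset; the Hunch appears only as
# the initial post-stimulus response (it initiates at stimulation)
.gen_script <- function(config) {
  draw_dur <- function(a) {
    m <- config$action_durations[[a]]
    min(max(stats::rexp(1, 1 / m), 0.6), 3 * m)
  }
  rows <- list()
  t <- 0
  while (t < config$stimulus_onset) {
    a <- sample(names(config$pre_probs), 1, prob = config$pre_probs)
    d <- draw_dur(a)
    end <- min(t + d, config$stimulus_onset)
    rows[[length(rows) + 1]] <- data.frame(action = a, start = t, end = end)
    t <- end
  }
  a <- sample(names(config$response_probs), 1, prob = config$response_probs)
  d <- draw_dur(a)
  end <- min(t + d, config$duration)
  rows[[length(rows) + 1]] <- data.frame(action = a, start = t, end = end)
  t <- end
  post <- config$pre_probs  # baseline repertoire resumes after the response
  while (t < config$duration) {
    a <- sample(names(post), 1, prob = post)
    d <- draw_dur(a)
    end <- min(t + d, config$duration)
    rows[[length(rows) + 1]] <- data.frame(action = a, start = t, end = end)
    t <- end
  }
  do.call(rbind, rows)
}

#' Generate a synthetic cohort with ground-truth action labels
#'
#' Draws one timed action script per larva -- baseline actions from the
#' pre-stimulus table, an initial response action from the response table
#' at stimulus onset (the only point where a Hunch can start), then
#' baseline actions again -- and animates each script with [gen_track()].
#' Byte-reproducible given the config seed.
#'
#' @param config A [generation_config()].
#' @param make_tracks Animate the scripts into midline tracks? Setting
#'   \code{FALSE} returns scripts and ground-truth sequences only, which is
#'   cheap for purely statistical uses.
#' @return List of class \code{synthetic_cohort}: \code{tracks} (NULL when
#'   \code{make_tracks = FALSE}), \code{truths}, \code{scripts},
#'   \code{config}.
#' @export
gen_cohort <- function(config, make_tracks = TRUE) {
  stopifnot(inherits(config, "generation_config"))
  old <- .save_seed(); on.exit(.restore_seed(old))
  scripts <- vector("list", config$n_larvae)
  for (i in seq_len(config$n_larvae)) {
    set.seed(config$seed * 131L %% 100000L + i)
    scripts[[i]] <- .gen_script(config)
  }
  grid <- seq(0, config$duration, by = 0.1)
  truth_of <- function(script) {
    k <- pmin(pmax(findInterval(grid, script$start), 1L), nrow(script))
    action_seq(grid, script$action[k], stimulus_onset = config$stimulus_onset)
  }
  if (make_tracks) {
    out <- lapply(seq_len(config$n_larvae), function(i) {
      gen_track(config, scripts[[i]], larva_id = sprintf("larva-%03d", i))
    })
    tracks <- lapply(out, `[[`, "track")
    truths <- lapply(out, `[[`, "truth")
  } else {
    tracks <- NULL
    truths <- lapply(scripts, truth_of)
  }
  structure(list(tracks = tracks, truths = truths,
                 scripts = scripts, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", length(x$tracks), "larvae,",
      x$config$duration, "s, seed", x$config$seed, "\n")
  invisible(x)
}
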