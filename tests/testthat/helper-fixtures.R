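# Geometric track fixtures built in code. Coordinates in mm, times in s.

# straight larva along +x, head at the +x end (point 1), tail at the origin
straight_points <- function(length_mm = 4) {
  x <- seq(length_mm, 0, length.out = 11)
  cbind(x, rep(0, 11))
}

# track of a rigid shape following a displacement profile disp(t) along +x
rigid_track <- function(times, disp, points = straight_points(),
                        id = "rigid", onset = 60, dur = 30) {
  x <- outer(disp, points[, 1], `+`)
  y <- matrix(rep(points[, 2], each = length(times)), ncol = 11)
  spine_track(id, times, x, y, stimulus_onset = onset, stimulus_duration = dur)
}

static_track <- function(times = seq(0, 30, by = 0.1), points = straight_points(),
                         id = "static") {
  rigid_track(times, rep(0, length(times)), points, id = id,
              onset = 15, dur = 5)
}

# track whose centroid speed follows a prescribed profile (rigid motion)
speed_track <- function(times, speed_mm_s, ...) {
  dt <- diff(times)
  disp <- c(0, cumsum(dt * (utils::head(speed_mm_s, -1) +
                              utils::tail(speed_mm_s, -1)) / 2))
  rigid_track(times, disp, ...)
}

# balanced multi-action script exercising every class for classifier training
balanced_script <- function() {
  acts <- c("crawl", "head_cast", "crawl", "static_bend", "crawl", "stop",
            "back_up", "crawl", "hunch", "crawl", "head_cast", "stop", "crawl")
  lens <- c(6, 3, 4, 3, 4, 2.5, 2.5, 5, 1.2, 6, 3, 2.5, 17.3)
  s <- cumsum(c(0, utils::head(lens, -1)))
  data.frame(action = acts, start = s, end = s + lens)
}

# features + windows + aligned truth labels for one scripted larva
scripted_windows <- function(config, script, id) {
  g <- gen_track(config, script, id)
  tp <- preprocess_track(g$track)
  W <- feature_window(frame_features(tp))
  n <- min(nrow(W), length(g$truth$labels))
  list(windows = W[seq_len(n), , drop = FALSE],
       labels = g$truth$labels[seq_len(n)],
       times = tp$times[seq_len(n)], track = tp, raw = g)
}

# small trained bundle shared across classifier tests (built once per run)
shared_bundle_env <- new.env()
get_shared_bundle <- function() {
  if (is.null(shared_bundle_env$bundle)) {
    cfg <- generation_config(seed = 11, duration = 60, stimulus_onset = 55,
                             stimulus_duration = 5, n_larvae = 4)
    parts <- lapply(1:4, function(i)
      scripted_windows(cfg, balanced_script(), paste0("train-", i)))
    X <- do.call(rbind, lapply(parts, `[[`, "windows"))
    y <- unlist(lapply(parts, `[[`, "labels"))
    shared_bundle_env$bundle <- train_frame_classifier(X, y, seed = 5)
    shared_bundle_env$config <- cfg
  }
  shared_bundle_env
}
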