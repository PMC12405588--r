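test_that("preprocessing preserves statics and the crawl band, rejects jitter", {
  # static larva at jittered 8-12 Hz: identical coordinates on the 10 Hz grid
  set.seed(1)
  tt <- cumsum(runif(200, 1 / 12, 1 / 8))
  tr <- rigid_track(tt, rep(0, length(tt)))
  tp <- preprocess_track(tr)
  expect_equal(median(diff(tp$times)), 0.1, tolerance = 1e-12)
  expect_lt(max(abs(sweep(tp$x, 2, straight_points()[, 1]))), 1e-9)
  # pure oscillations in midline length: 1.4 Hz passes (< 5% loss), 5 Hz dies
  osc_track <- function(f) {
    t2 <- seq(0, 20, by = 1 / 30)
    base <- straight_points()[, 1]
    x <- outer(1 + 0.1 * sin(2 * pi * f * t2), base)
    spine_track("osc", t2, x, matrix(0, length(t2), 11), 15, 1)
  }
  amp_ratio <- function(f) {
    tp <- preprocess_track(osc_track(f))
    ml <- midline_length(tp)
    mid <- tp$times > 2 & tp$times < 18
    (max(ml[mid]) - min(ml[mid])) / 2 / 0.4
  }
  expect_gt(amp_ratio(1.4), 0.95)
  expect_lt(amp_ratio(5), 0.5)
  expect_error(preprocess_track(static_track(times = c(0, 0.5))), "span")
})

test_that("tail-first tracks are flipped head-first before analysis", {
  cfg <- generation_config(seed = 13, duration = 20, stimulus_onset = 15,
                           stimulus_duration = 5)
  g <- gen_track(cfg, data.frame(action = c("crawl", "head_cast"),
                                 start = c(0, 10), end = c(10, 20)), "flip")
  tr <- g$track
  rev_tr <- tr
  rev_tr$x <- tr$x[, 11:1]
  rev_tr$y <- tr$y[, 11:1]
  fixed <- orient_head_first(rev_tr)
  expect_identical(fixed$x, tr$x)
  # an already head-first track is untouched
  expect_identical(orient_head_first(tr)$x, tr$x)
  # the preprocessed features agree regardless of the input orientation
  expect_equal(frame_features(preprocess_track(rev_tr)),
               frame_features(preprocess_track(tr)))
})

test_that("body length is the median midline length", {
  # 11 collinear points spaced 0.4 mm
  tr <- static_track()
  expect_equal(body_length(tr), 4)
  # alternating 3.8 / 4.2 mm over equal numbers of frames
  t2 <- seq(0.1, 10, by = 0.1)
  scale <- rep(c(3.8, 4.2) / 4, length.out = length(t2))
  x <- outer(scale, straight_points()[, 1])
  tr2 <- spine_track("alt", t2, x, matrix(0, length(t2), 11), 5, 1)
  expect_equal(body_length(tr2), 4)
})

test_that("scaled speeds are rigid-motion consistent", {
  t2 <- seq(0, 10, by = 0.1)
  tr <- rigid_track(t2, t2 * 1.0)  # 1 mm/s, body length 4 mm
  sp <- scaled_speeds(tr)
  mid <- 5:95
  expect_equal(sp$head[mid], rep(0.25, length(mid)), tolerance = 1e-9)
  expect_equal(sp$centroid[mid], rep(0.25, length(mid)), tolerance = 1e-9)
  expect_equal(sp$tail[mid], rep(0.25, length(mid)), tolerance = 1e-9)
  expect_true(all(scaled_speeds(static_track()) == 0))
})

test_that("nematic order hits its geometric anchors", {
  expect_equal(nematic_order(static_track()), rep(1, 301))
  # degenerate fold: every segment (nearly) perpendicular to the body axis
  zig <- cbind(rep(c(1, 0), length.out = 11), (0:10) * 1e-7)
  trz <- static_track(points = zig)
  expect_equal(nematic_order(trz)[1], -0.5, tolerance = 1e-6)
  # C-shaped semicircular spine: against direct summation over the arc
  th <- seq(0, pi, length.out = 11)
  arc <- cbind(cos(th), sin(th))
  tra <- static_track(points = arc)
  ax <- arc[1, ] - arc[11, ]
  segs <- diff(arc)
  cosq <- ((segs %*% ax) / (sqrt(rowSums(segs^2)) * sqrt(sum(ax^2))))^2
  expect_equal(nematic_order(tra)[5], (3 * mean(cosq) - 1) / 2,
               tolerance = 1e-12)
})

test_that("shape factor separates straight, circular and elliptic spines", {
  expect_equal(shape_factor(static_track()), rep(1, 301))
  th <- 2 * pi * (0:10) / 11
  circ <- static_track(points = cbind(cos(th), sin(th)))
  expect_equal(shape_factor(circ), rep(0, 301), tolerance = 1e-12)
  ell <- static_track(points = cbind(2 * cos(th), sin(th)))
  expect_equal(shape_factor(ell), rep(0.6, 301), tolerance = 1e-12)
})

test_that("axis ratio is 1 for symmetric larvae and guarded when degenerate", {
  expect_equal(axis_ratio(static_track()), rep(1, 301))
  # tail coincident with the centroid: x = 5.5 equals the mean of all 11
  xs <- c(10:1, 5.5)
  tr <- static_track(points = cbind(xs, rep(0, 11)))
  expect_true(all(is.na(axis_ratio(tr))))
})

test_that("velocity projections and cosines follow the geometry", {
  t2 <- seq(0, 10, by = 0.1)
  along <- rigid_track(t2, t2)  # head moves along the +x spine axis
  va <- velocity_alignment(along)
  mid <- 5:95
  expect_equal(va$head_cos[mid], rep(1, length(mid)), tolerance = 1e-9)
  expect_equal(va$head_proj[mid], rep(0.25, length(mid)), tolerance = 1e-9)
  # perpendicular motion: spine along x, displacement along y
  x <- matrix(rep(straight_points()[, 1], each = length(t2)), ncol = 11)
  y <- matrix(rep(t2, 11), ncol = 11)
  perp <- spine_track("perp", t2, x, y, 5, 1)
  vp <- velocity_alignment(perp)
  expect_equal(vp$head_cos[mid], rep(0, length(mid)), tolerance = 1e-9)
  expect_equal(vp$head_proj[mid], rep(0, length(mid)), tolerance = 1e-9)
  # 45 degrees
  diag45 <- spine_track("diag", t2, x + t2, y, 5, 1)
  vd <- velocity_alignment(diag45)
  expect_equal(vd$head_cos[mid], rep(sqrt(2) / 2, length(mid)),
               tolerance = 1e-9)
  sp45 <- scaled_speeds(diag45)$head
  expect_equal(vd$head_proj[mid], sp45[mid] * sqrt(2) / 2, tolerance = 1e-9)
})

test_that("feature windows stack 7 steps with edge replication", {
  F1 <- matrix(rep(1:12, each = 20), nrow = 20)
  colnames(F1) <- paste0("f", 1:12)
  W <- feature_window(F1)
  expect_equal(dim(W), c(20, 84))
  expect_true(all(W[10, ] == rep(1:12, 7)))
  expect_error(feature_window(F1[1:6, ]), "short")
})

test_that("path metrics and straightness behave on canonical paths", {
  t2 <- seq(0, 40, by = 0.1)
  tr <- rigid_track(t2, t2 * 0.25)  # straight 10 mm run
  pm <- path_metrics(tr)
  expect_equal(pm$pathlength[length(t2)], 10, tolerance = 1e-9)
  expect_equal(pm$dispersal[length(t2)], 10, tolerance = 1e-9)
  si <- straightness_index(tr)
  expect_equal(si$si[!is.na(si$si)],
               rep(1, sum(!is.na(si$si))), tolerance = 1e-9)
  # out-and-back: zero final dispersal, positive pathlength, SI near 0
  disp <- 2 * pmin(t2, 40 - t2) * 0.25
  tr2 <- rigid_track(t2, disp)
  pm2 <- path_metrics(tr2)
  expect_lt(pm2$dispersal[length(t2)], 1e-9)
  expect_gt(pm2$pathlength[length(t2)], 19)
  # stationary: SI = 0 by convention
  si0 <- straightness_index(static_track(times = seq(0, 30, by = 0.1)))
  expect_true(all(si0$si[!is.na(si0$si)] == 0))
  expect_error(straightness_index(rigid_track(seq(0, 10, 0.1),
                                              seq(0, 10, 0.1))), "window")
  # property: dispersal never exceeds pathlength on wiggly tracks
  set.seed(4)
  for (k in 1:5) {
    wig <- rigid_track(t2, cumsum(rnorm(length(t2), 0.01, 0.05)))
    pmw <- path_metrics(wig)
    expect_true(all(pmw$dispersal <= pmw$pathlength + 1e-9))
  }
})

test_that("dominant crawl frequency is recovered from speed spectra", {
  t2 <- seq(0, 30, by = 0.05)
  mk <- function(freq, noise = 0) {
    v <- 1 + sin(2 * pi * freq * t2) + rnorm(length(t2), 0, noise)
    speed_track(t2, v)
  }
  set.seed(2)
  f14 <- crawl_frequency(preprocess_track(mk(1.4)))
  expect_equal(f14$frequency, 1.4, tolerance = 0.05)
  f10 <- crawl_frequency(preprocess_track(mk(1.0, noise = 1 / 3)))
  expect_equal(f10$frequency, 1.0, tolerance = 0.05)
  expect_error(crawl_frequency(preprocess_track(speed_track(
    t2, rep(1, length(t2))))), "flat")
})

test_that("stride detection applies the speed and duration rules", {
  t2 <- seq(0, 10.5, by = 0.05)
  cyc <- 1 / 1.4
  mk <- function(amp) {  # speed oscillating 0..amp BL/s at 1.4 Hz, BL = 4 mm
    speed_track(t2, 4 * amp / 2 * (1 - cos(2 * pi * 1.4 * t2)))
  }
  st <- detect_strides(preprocess_track(mk(0.5)), cycle = cyc)
  expect_gte(nrow(st), 13)
  expect_lte(nrow(st), 15)
  expect_true(all(st$peak_speed >= 0.3))
  # below the 0.3 BL/s bar: no strides
  expect_equal(nrow(detect_strides(preprocess_track(mk(0.2)), cycle = cyc)), 0)
  # epochs lasting twice the cycle are rejected by the duration rule
  st2 <- detect_strides(preprocess_track(mk(0.5)), cycle = cyc / 2)
  expect_equal(nrow(st2), 0)
})

test_that("runs and pauses partition the track consistently", {
  cfg <- generation_config(seed = 3, duration = 30, stimulus_onset = 25,
                           stimulus_duration = 5, coord_noise = 0.005)
  script <- data.frame(action = c("crawl", "stop", "crawl"),
                       start = c(0, 10, 18), end = c(10, 18, 30))
  g <- gen_track(cfg, script, "cfc")
  tp <- preprocess_track(g$track)
  ann <- annotate_runs_pauses(tp)
  expect_equal(nrow(ann$runs), 2)
  expect_equal(nrow(ann$pauses), 1)
  expect_equal(ann$pauses$start[1], 10, tolerance = 0.5)
  expect_equal(ann$pauses$end[1], 18, tolerance = 0.5)
  # no stride overlaps a pause
  for (k in seq_len(nrow(ann$strides))) {
    overlaps <- ann$pauses$start < ann$strides$end[k] &
      ann$pauses$end > ann$strides$start[k]
    expect_false(any(overlaps))
  }
})

test_that("features are invariant to rigid translation and rotation", {
  cfg <- generation_config(seed = 9, duration = 12, stimulus_onset = 10,
                           stimulus_duration = 2, coord_noise = 0)
  g <- gen_track(cfg, data.frame(action = c("crawl", "head_cast"),
                                 start = c(0, 8), end = c(8, 12)), "inv")
  tp <- preprocess_track(g$track)
  shift <- tp; shift$x <- tp$x + 12.3; shift$y <- tp$y - 4.5
  expect_equal(nematic_order(shift), nematic_order(tp))
  expect_equal(shape_factor(shift), shape_factor(tp))
  expect_equal(axis_ratio(shift), axis_ratio(tp))
  a <- 0.7; R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  rot <- tp
  rot$x <- tp$x * R[1, 1] + tp$y * R[1, 2]
  rot$y <- tp$x * R[2, 1] + tp$y * R[2, 2]
  expect_equal(nematic_order(rot), nematic_order(tp), tolerance = 1e-9)
  expect_equal(shape_factor(rot), shape_factor(tp), tolerance = 1e-9)
  expect_equal(scaled_speeds(rot), scaled_speeds(tp), tolerance = 1e-9)
  # determinism: identical input gives identical output
  expect_identical(frame_features(tp), frame_features(tp))
})
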