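test_that("generators are seed-deterministic", {
  cfg <- generation_config(seed = 17, duration = 20, stimulus_onset = 15,
                           stimulus_duration = 5)
  s <- data.frame(action = "crawl", start = 0, end = 20)
  g1 <- gen_track(cfg, s, "a")
  g2 <- gen_track(cfg, s, "a")
  expect_identical(g1$track$x, g2$track$x)
  expect_identical(g1$track$times, g2$track$times)
  co1 <- gen_cohort(generation_config(seed = 5, n_larvae = 3, duration = 20,
                                      stimulus_onset = 15,
                                      stimulus_duration = 5))
  co2 <- gen_cohort(generation_config(seed = 5, n_larvae = 3, duration = 20,
                                      stimulus_onset = 15,
                                      stimulus_duration = 5))
  expect_identical(co1$tracks[[2]]$x, co2$tracks[[2]]$x)
  expect_identical(co1$scripts, co2$scripts)
  pc1 <- gen_point_clouds(5, 10, 0.3, seed = 2)
  pc2 <- gen_point_clouds(5, 10, 0.3, seed = 2)
  expect_identical(pc1, pc2)
  expect_error(generation_config(), "seed")
})

test_that("action templates carry their kinematic signatures", {
  cfg <- generation_config(seed = 33, duration = 70)
  sh <- data.frame(action = c("crawl", "hunch", "crawl"),
                   start = c(0, 60, 61), end = c(60, 61, 70))
  g <- gen_track(cfg, sh, "hunch-sig")
  tp <- preprocess_track(g$track)
  ml <- midline_length(tp)
  ar <- axis_ratio(tp)
  pre <- tp$times < 60
  during <- tp$times >= 60.2 & tp$times <= 60.8
  # length dips by at least the configured contraction (minus filter loss)
  dip <- 1 - min(ml[during]) / median(ml[pre])
  expect_gt(dip, 0.3)
  expect_lt(min(ar[during]), 0.8)  # head pulled toward the centroid
  # head-only sweep: head much faster than tail
  gc <- gen_track(cfg, data.frame(action = c("stop", "head_cast", "stop"),
                                  start = c(0, 30, 33), end = c(30, 33, 70)),
                  "cast-sig")
  tpc <- preprocess_track(gc$track)
  spc <- scaled_speeds(tpc)
  cast <- tpc$times >= 30.5 & tpc$times <= 32.5
  expect_gt(mean(spc$head[cast]) / mean(spc$tail[cast]), 3)
  # zero-noise static script: features constant
  cfg0 <- generation_config(seed = 1, duration = 20, stimulus_onset = 15,
                            stimulus_duration = 5, coord_noise = 0)
  gs <- gen_track(cfg0, data.frame(action = "stop", start = 0, end = 20), "st")
  tps <- preprocess_track(gs$track)
  ff <- frame_features(tps)
  expect_lt(max(apply(ff, 2, stats::sd)), 1e-9)
  expect_error(gen_track(cfg0, data.frame(action = c("stop", "crawl"),
                                          start = c(0, 5), end = c(10, 20)),
                         "bad"), "overlap")
})

test_that("scripted ground truth matches the configured response table", {
  cfg <- generation_config(seed = 77, n_larvae = 200)
  co <- gen_cohort(cfg, make_tracks = FALSE)
  hunch <- vapply(co$truths, function(s)
    any(s$labels[s$times >= 60 & s$times < 65] == "hunch"), TRUE)
  phat <- mean(hunch)
  margin <- 1.96 * sqrt(0.4 * 0.6 / 200)
  expect_lt(abs(phat - 0.4), margin + 1e-9)
  # at most one hunch per larva by construction, starting at onset
  n_hunch <- vapply(co$truths, function(s) {
    iv <- as_intervals(s)
    sum(iv$label == "hunch")
  }, 0L)
  expect_true(all(n_hunch <= 1))
  # degenerate table: crawl-only cohort
  cfg1 <- generation_config(seed = 3, n_larvae = 5,
                            response_probs = c(crawl = 1),
                            pre_probs = c(crawl = 1))
  co1 <- gen_cohort(cfg1, make_tracks = FALSE)
  expect_true(all(vapply(co1$truths, function(s)
    all(s$labels == "crawl"), TRUE)))
  expect_error(generation_config(seed = 1, pre_probs = c(crawl = 0.5)),
               "sum to 1")
})

test_that("group-count and point-cloud generators match their parameters", {
  g <- gen_group_counts(c(0.4, 0.1), c(0.4, 0.1), N = c(500, 500), seed = 12)
  expect_equal(g$test$N_post, 500)
  expect_lt(abs(g$test$n_post / 500 - 0.4), 0.06)
  expect_error(gen_group_counts(c(0.4, 0.1), c(0.4, 0.1), N = c(0, 10)),
               "positive")
  expect_error(gen_group_counts(c(1.4, 0.1), c(0.4, 0.1)), "rates")
  pc <- gen_point_clouds(d = 25, n = 400, shift = 1, seed = 6)
  d_means <- colMeans(pc$Y) - colMeans(pc$X)
  expect_equal(sqrt(sum(d_means^2)), 1, tolerance = 0.3)
  pc0 <- gen_point_clouds(d = 25, n = 400, shift = 0, seed = 6)
  expect_lt(mmd_statistic(pc0$X, pc0$Y), 0.005)
})

test_that("fluorescence trials straddle the failure rule as configured", {
  sim <- gen_fluorescence_traces(n_trials = 300, failure_fraction = 0.4,
                                 seed = 9)
  fr <- failure_rate(sim$traces)
  expect_identical(fr$n_failed, sum(sim$failed_truth))
  margin <- 1.96 * sqrt(0.4 * 0.6 / 300)
  expect_lt(abs(fr$failure_rate - 0.4), margin + 1e-9)
  # amplitude zero: every trial fails
  all0 <- gen_fluorescence_traces(n_trials = 20, amplitude_mean = 0,
                                  failure_fraction = 1, seed = 2)
  expect_equal(failure_rate(all0$traces)$failure_rate, 1)
  expect_identical(gen_fluorescence_traces(5, seed = 4),
                   gen_fluorescence_traces(5, seed = 4))
})
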