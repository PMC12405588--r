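const_seq <- function(labels, t0 = 0, onset = 60, dt = 0.1) {
  action_seq(seq(t0, by = dt, length.out = length(labels)), labels,
             stimulus_onset = onset)
}

test_that("cumulative action probabilities count qualifying larvae only", {
  # 10 larvae tracked through [60, 65): 4 hunch within the window
  seqs <- lapply(1:10, function(i) {
    labs <- rep("crawl", 400)  # 40 s from t = 30
    if (i <= 4) labs[c(305:315)] <- "hunch"  # ~60.5 s
    const_seq(labs, t0 = 30)
  })
  ap <- action_probabilities(seqs, "hunch", mode = "cumulative")
  expect_equal(ap$probability, 0.4)
  expect_equal(ap$N, 10)
  # a larva lost mid-window drops out of the denominator
  seqs_lost <- c(seqs, list(const_seq(rep("hunch", 100), t0 = 55)))  # ends 65-
  ap2 <- action_probabilities(seqs_lost, "hunch", mode = "cumulative")
  expect_equal(ap2$N, 10)
  expect_error(action_probabilities(list(const_seq(rep("crawl", 10))),
                                    "hunch"), "window")
})

test_that("corrected-mean probability subtracts the baseline occupancy", {
  # identical pre- and post-stimulus head-cast occupancy cancels to zero
  labs <- rep(c(rep("head_cast", 5), rep("crawl", 5)), 100)
  s <- const_seq(labs, t0 = 0)
  ap <- action_probabilities(list(s), "head_cast", mode = "corrected_mean")
  expect_equal(ap$probability, 0, tolerance = 1e-12)
})

test_that("chi and Theta follow their closed forms and symmetries", {
  g1 <- group_window_counts(50, 100, 20, 100)   # chi = 0.3
  g2 <- group_window_counts(10, 100, 0, 100)    # chi = 0.1
  expect_equal(chi_estimator(g1), 0.3)
  expect_equal(theta_statistic(g1, g2), 0.2)
  expect_equal(theta_statistic(g2, g1), -0.2)   # antisymmetry
  expect_equal(theta_statistic(g1, g1), 0)
  gmin <- group_window_counts(0, 50, 50, 50)
  expect_equal(chi_estimator(gmin), -1)
  expect_error(group_window_counts(5, 4, 0, 10), "exceed")
  expect_error(group_window_counts(-1, 4, 0, 10), "nonnegative")
})

test_that("the Theta resampling test is seed-deterministic and sane", {
  g1 <- group_window_counts(40, 100, 10, 100)
  r1 <- theta_test(g1, g1, n_sim = 500, seed = 11)
  expect_equal(r1$theta, 0)
  expect_equal(r1$p_value, 1)  # every |Theta*| >= 0
  g2 <- group_window_counts(12, 100, 10, 100)
  a <- theta_test(g1, g2, n_sim = 500, seed = 4)
  b <- theta_test(g1, g2, n_sim = 500, seed = 4)
  expect_identical(a$p_value, b$p_value)
  expect_identical(a$null_sample, b$null_sample)
  expect_lt(a$p_value, 0.05)  # a 0.28 effect at N = 100 is detectable
  expect_error(theta_test(g1, g2, n_sim = 50), "100")
  # the literal single-draw scheme stays available for comparison
  lit <- theta_test(g1, g2, n_sim = 500, seed = 4, scheme = "literal")
  expect_true(all(lit$null_sample %in% seq(-2, 2, by = 1)))
})

test_that("transition counts respect the window and its fallback", {
  s <- const_seq(c(rep("crawl", 605), rep("hunch", 5), rep("head_cast", 10),
                   rep("crawl", 330)))
  tm <- transition_matrix(list(s), window = 2, min_transitions = 2)
  expect_equal(tm$counts["crawl", "hunch"], 1L)
  expect_equal(tm$counts["hunch", "head_cast"], 1L)
  expect_equal(tm$total, 2L)
  expect_false(tm$fallback_engaged)
  # constant-label cohort: nothing to count, fallback engaged
  tm0 <- transition_matrix(list(const_seq(rep("crawl", 900))))
  expect_equal(sum(tm0$counts), 0)
  expect_true(tm0$fallback_engaged)
  expect_equal(tm0$window_used, 10)
})

test_that("GLR z matches the direct log-likelihood evaluation", {
  eq <- glr_transition_test(10, 20, 10, 20)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)
  # frozen value from the independent dbinom-based oracle
  r <- glr_transition_test(15, 20, 5, 20)
  expect_equal(r$z, 10.464962875291, tolerance = 1e-12)
  expect_equal(r$p_value, 0.00121659992338, tolerance = 1e-9)
  # symmetric under swapping the groups
  expect_equal(glr_transition_test(5, 20, 15, 20)$z, r$z)
  # boundary counts stay finite
  expect_gte(glr_transition_test(0, 10, 10, 10)$z, 0)
  expect_error(glr_transition_test(1, 0, 1, 5), "trials")
})

test_that("GLR agrees with the oracle across random tables", {
  set.seed(8)
  for (k in 1:200) {
    N1 <- sample(5:200, 1); N2 <- sample(5:200, 1)
    n1 <- rbinom(1, N1, runif(1)); n2 <- rbinom(1, N2, runif(1))
    pp <- (n1 + n2) / (N1 + N2)
    zo <- -2 * (dbinom(n1, N1, pp, log = TRUE) + dbinom(n2, N2, pp, log = TRUE) -
                  dbinom(n1, N1, n1 / N1, log = TRUE) -
                  dbinom(n2, N2, n2 / N2, log = TRUE))
    expect_equal(glr_transition_test(n1, N1, n2, N2)$z, max(zo, 0),
                 tolerance = 1e-10)
  }
})

test_that("segment vectors have 200 elements and honour coverage", {
  cfg <- generation_config(seed = 2, duration = 70, coord_noise = 0)
  g <- gen_track(cfg, data.frame(action = "crawl", start = 0, end = 70), "seg")
  tp <- preprocess_track(g$track)
  V <- segment_window_vectors(tp)
  expect_equal(dim(V), c(5, 200))
  # a static larva yields five identical vectors
  stat <- static_track(times = seq(0, 70, by = 0.1))
  Vs <- segment_window_vectors(stat)
  expect_equal(max(abs(sweep(Vs, 2, Vs[1, ]))), 0)
  # a track ending early covers fewer centres
  short <- static_track(times = seq(0, 65.8, by = 0.1))
  expect_warning(V2 <- segment_window_vectors(short), "skipped")
  expect_equal(nrow(V2), 4)
  shorter <- static_track(times = seq(0, 64, by = 0.1))
  V3 <- suppressWarnings(segment_window_vectors(shorter))
  expect_equal(nrow(V3), 3)
})

test_that("MMD matches its closed forms and brute-force value", {
  set.seed(5)
  X <- matrix(rnorm(40), 20, 2)
  expect_lte(mmd_statistic(X, X), 1e-12)  # U-statistic on identical samples
  # frozen brute-force double-loop value for two 3-point 1-D sets
  A <- matrix(c(0, 1, 2), 3, 1)
  B <- matrix(c(0.5, 1.5, 3), 3, 1)
  expect_equal(mmd_statistic(A, B), -0.111166816599646, tolerance = 1e-12)
  expect_error(mmd_statistic(X, matrix(0, 5, 3)), "dimension")
  # estimate grows with the mean shift (fixed draws, increasing offsets)
  base <- gen_point_clouds(d = 5, n = 200, shift = 0, seed = 9)
  vals <- vapply(c(0, 1, 2, 3), function(s)
    mmd_statistic(base$X, sweep(base$Y, 2, rep(s / sqrt(5), 5), `+`)),
    numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("the MMD permutation test is deterministic and Bonferroni-aware", {
  pc <- gen_point_clouds(d = 10, n = 40, shift = 2, seed = 3)
  a <- mmd_permutation_test(pc$X, pc$Y, B = 150, seed = 6, bonferroni_m = 45)
  b <- mmd_permutation_test(pc$X, pc$Y, B = 150, seed = 6, bonferroni_m = 45)
  expect_identical(a$p_value, b$p_value)
  expect_equal(a$p_adjusted, min(1, 45 * a$p_value))
  expect_lt(a$p_value, 0.05)  # a 2-sigma shift at n = 40 is obvious
  expect_error(mmd_permutation_test(pc$X, pc$Y, B = 50), "100")
})

test_that("fluorescence responses and the failure rule behave", {
  tt <- seq(0, 15, by = 0.2)
  flat <- fluorescence_trace(tt, rep(2, length(tt)))
  m <- dff_metrics(flat)
  expect_equal(m$stimulus_mean, 0)
  expect_true(m$failed)
  up <- fluorescence_trace(tt, ifelse(tt >= 5 & tt <= 10, 2.5, 2),
                           baseline_window = c(0, 4.8))
  m2 <- dff_metrics(up)
  expect_equal(m2$stimulus_mean, 0.25)
  expect_false(m2$failed)
  expect_error(dff_metrics(fluorescence_trace(tt, rep(0, length(tt)))),
               "positive")
  # cohort of 5 trials with means {0.05, 0.2, 0.3, 0.08, 0.5}: 2/5 failed
  mk <- function(a) fluorescence_trace(tt, 1 + a * (tt >= 5 & tt <= 10))
  fr <- failure_rate(lapply(c(0.05, 0.2, 0.3, 0.08, 0.5), mk))
  expect_equal(fr$failure_rate, 2 / 5)
})

test_that("the preference index follows its definition and bounds", {
  expect_equal(preference_index(20, 0, 20), 1)
  expect_equal(preference_index(7, 7, 20), 0)
  expect_equal(preference_index(6, 10, 20), -0.2)
  expect_error(preference_index(15, 10, 20), "exceed")
  expect_error(preference_index(0, 0, 0), "positive")
})
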