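#' Simulate responder counts for two groups
#'
#' Binomial draws of per-window responder counts for a test and a control
#' group, given true response rates: the calibration substrate for
#' [theta_test()] and [glr_transition_test()].
#'
#' @param rate_test,rate_control Two-element vectors \code{c(post, pre)} of
#'   true response probabilities.
#' @param N Two-element vector \code{c(test, control)} of group sizes
#'   (strictly positive).
#' @param seed Integer seed.
#' @return List with \code{test} and \code{control}
#'   ([group_window_counts()]).
#' @export
gen_group_counts <- function(rate_test, rate_control, N = c(100, 100), seed = 1) {
  rates <- c(rate_test, rate_control)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (any(N <= 0)) stop("group sizes must be positive")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  draw <- function(rate, n) {
    group_window_counts(n_post = stats::rbinom(1, n, rate[1]), N_post = n,
                        n_pre = stats::rbinom(1, n, rate[2]), N_pre = n)
  }
  list(test = draw(rate_test, N[1]), control = draw(rate_control, N[2]))
}

#' Simulate a pair of Gaussian point clouds
#'
#' Isotropic unit-variance Gaussians in d dimensions; the second cloud's
#' mean is displaced by a vector of Euclidean norm \code{shift} (spread
#' equally over all coordinates). Stands in for embedding-space samples in
#' MMD calibration studies.
#'
#' @param d Dimension (default 25).
#' @param n Points per cloud.
#' @param shift Euclidean norm of the mean displacement.
#' @param seed Integer seed.
#' @return List with matrices \code{X} and \code{Y} (n x d).
#' @export
gen_point_clouds <- function(d = 25, n = 100, shift = 0, seed = 1) {
  if (d < 1 || n < 1) stop("d and n must be at least 1")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  X <- matrix(stats::rnorm(n * d), n, d)
  Y <- matrix(stats::rnorm(n * d), n, d)
  Y <- sweep(Y, 2, rep(shift / sqrt(d), d), `+`)
  list(X = X, Y = Y)
}

#' Simulate calcium-imaging trials with a known failure fraction
#'
#' Traces follow the standard trial structure (5 s baseline, 5 s
#' stimulation, 5 s recovery) around a baseline fluorescence of 1. A
#' configured fraction of trials is failed (stimulus-averaged response
#' drawn at or below 8\%); the rest respond with amplitudes safely above
#' the 10\% failure rule.
#'
#' @param n_trials Number of trials.
#' @param amplitude_mean Mean response amplitude of successful trials
#'   (fraction of baseline).
#' @param failure_fraction True probability of a failed trial.
#' @param seed Integer seed.
#' @param fs Sampling rate (Hz).
#' @param noise_sd Additive noise SD (a.u.).
#' @return List with \code{traces} (list of [fluorescence_trace()]) and
#'   \code{failed_truth} (logical ground truth).
#' @export
gen_fluorescence_traces <- function(n_trials = 5, amplitude_mean = 0.3,
                                    failure_fraction = 0, seed = 1,
                                    fs = 5, noise_sd = 0.005) {
  if (failure_fraction < 0 || failure_fraction > 1)
    stop("failure_fraction must lie in [0, 1]")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  times <- seq(0, 15, by = 1 / fs)
  stim <- times >= 5 & times <= 10
  traces <- vector("list", n_trials)
  failed <- stats::runif(n_trials) < failure_fraction
  for (i in seq_len(n_trials)) {
    amp <- if (failed[i]) stats::runif(1, 0, 0.08)
    else max(0.15, stats::rnorm(1, amplitude_mean, amplitude_mean / 4))
    # half-sine envelope scaled so its stimulus-window mean is ~amp
    env <- ifelse(stim, pmax(sin(pi * (times - 5) / 5), 0)^0.5, 0)
    f <- 1 + amp * env * 1.27 + stats::rnorm(length(times), 0, noise_sd)
    traces[[i]] <- fluorescence_trace(times, f,
                                      baseline_window = c(0, 5),
                                      stimulus_window = c(5, 10))
  }
  list(traces = traces, failed_truth = failed)
}
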