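#' Construct a fluorescence trace
#'
#' One trial of a calcium-imaging recording: raw fluorescence over time
#' with a baseline (pre-stimulation) window defining F0 and a stimulus
#' window over which the response is averaged. A typical trial is 5 s of
#' baseline, 5 s of stimulation, 5 s of recovery.
#'
#' @param times Sample times (s).
#' @param f Raw fluorescence (a.u.).
#' @param baseline_window,stimulus_window Two-element (start, end) vectors
#'   (s) inside the trace span.
#' @return Object of class \code{fluorescence_trace}.
#' @export
fluorescence_trace <- function(times, f, baseline_window = c(0, 5),
                               stimulus_window = c(5, 10)) {
  if (length(times) != length(f)) stop("times and f must align")
  rng <- range(times)
  for (w in list(baseline_window, stimulus_window)) {
    if (w[1] < rng[1] - 1e-9 || w[2] > rng[2] + 1e-9)
      stop("window [", w[1], ", ", w[2], "] outside the trace span")
  }
  structure(list(times = as.numeric(times), f = as.numeric(f),
                 baseline_window = baseline_window,
                 stimulus_window = stimulus_window),
            class = "fluorescence_trace")
}

#' Baseline-normalised fluorescence response of one trial
#'
#' F0 is the mean fluorescence during the baseline window;
#' \eqn{\Delta F/F_0 = (F(t) - F_0)/F_0}. The trial's response is the mean
#' \eqn{\Delta F/F_0} over the stimulus window, and the trial is failed
#' when that mean does not exceed 10\%.
#'
#' @param trace A [fluorescence_trace()].
#' @param failure_threshold Response floor below or at which a trial counts
#'   as failed.
#' @return List: \code{dff} (series), \code{f0}, \code{stimulus_mean},
#'   \code{failed}.
#' @export
dff_metrics <- function(trace, failure_threshold = 0.10) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  bw <- trace$baseline_window
  f0 <- mean(trace$f[trace$times >= bw[1] & trace$times <= bw[2]])
  if (!is.finite(f0) || f0 <= 0) stop("F0 must be positive; got ", f0)
  dff <- (trace$f - f0) / f0
  sw <- trace$stimulus_window
  stim_mean <- mean(dff[trace$times >= sw[1] & trace$times <= sw[2]])
  list(dff = dff, f0 = f0, stimulus_mean = stim_mean,
       failed = stim_mean <= failure_threshold)
}

#' Failure rate over repeated stimulation trials
#'
#' Fraction of trials whose stimulus-averaged \eqn{\Delta F/F_0} does not
#' exceed the failure threshold; the stimulation is typically repeated 5
#' times with 60 s resting intervals to estimate a response frequency.
#'
#' @param traces List of [fluorescence_trace()] objects.
#' @param failure_threshold Passed to [dff_metrics()].
#' @return List: \code{failure_rate}, \code{n_failed}, \code{n_trials},
#'   \code{stimulus_means}.
#' @export
failure_rate <- function(traces, failure_threshold = 0.10) {
  res <- lapply(traces, dff_metrics, failure_threshold = failure_threshold)
  failed <- vapply(res, function(x) x$failed, TRUE)
  list(failure_rate = mean(failed), n_failed = sum(failed),
       n_trials = length(res),
       stimulus_means = vapply(res, function(x) x$stimulus_mean, 0))
}

#' Sucrose place-preference index
#'
#' \eqn{PI = (N_s - N_a)/N_{tot}} with \eqn{N_s} larvae on the sucrose
#' side, \eqn{N_a} larvae on the agar side, and \eqn{N_{tot}} the total;
#' larvae touching the boundary between the two media are excluded from
#' both sides but still count in \eqn{N_{tot}}.
#'
#' @param n_sucrose,n_agar,n_total Counts.
#' @return Scalar PI in [-1, 1].
#' @export
preference_index <- function(n_sucrose, n_agar, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_sucrose + n_agar > n_total)
    stop("side counts exceed the total (boundary larvae are excluded)")
  (n_sucrose - n_agar) / n_total
}
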