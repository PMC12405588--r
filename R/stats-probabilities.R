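#' Responder counts for one group over the post- and pre-stimulus windows
#'
#' The substrate of the chi and Theta estimators: per group, the number of
#' larvae tracked through the post-stimulus window (\code{N_post}) and how
#' many of them performed the action in it (\code{n_post}), plus the same
#' pair for the 30--50 s pre-stimulus baseline window.
#'
#' @param n_post,N_post Post-window responders and total tracked.
#' @param n_pre,N_pre Baseline-window responders and total tracked.
#' @return Object of class \code{group_window_counts}.
#' @export
group_window_counts <- function(n_post, N_post, n_pre, N_pre) {
  v <- c(n_post = n_post, N_post = N_post, n_pre = n_pre, N_pre = N_pre)
  if (any(v < 0) || any(v != round(v))) stop("counts must be nonnegative integers")
  if (n_post > N_post || n_pre > N_pre) stop("n cannot exceed N in a window")
  structure(as.list(v), class = "group_window_counts")
}

#' Action probability of a cohort
#'
#' Cumulative mode: the fraction of qualifying larvae (tracked through the
#' entire post-stimulus window) that perform the action at least once within
#' it. Corrected-mean mode (for actions frequent during baseline
#' locomotion, Crawl and Head Cast): the mean instantaneous fraction of
#' larvae in the action over the post window, minus the same mean over the
#' 30--50 s pre-stimulus baseline.
#'
#' @param sequences List of [action_seq()], one per larva, sharing the
#'   stimulus onset.
#' @param action Action label to score.
#' @param mode \code{"cumulative"} or \code{"corrected_mean"}.
#' @param window Post-stimulus window (s relative to onset), default
#'   \code{c(0, 5)}; the optogenetic Hunch window is \code{c(0, 2)} and the
#'   late bend window \code{c(1, 4)}.
#' @param baseline Baseline window (s relative to onset), default
#'   \code{c(-30, -10)}.
#' @return List: \code{probability}, \code{n} (responders, cumulative mode),
#'   \code{N} (qualifying larvae), \code{mode}, \code{window}.
#' @export
action_probabilities <- function(sequences, action,
                                 mode = c("cumulative", "corrected_mean"),
                                 window = c(0, 5), baseline = c(-30, -10)) {
  mode <- match.arg(mode)
  onset <- sequences[[1]]$stimulus_onset
  post <- onset + window
  base <- onset + baseline
  covers <- function(s, win) {
    min(s$times) <= win[1] + 1e-9 && max(s$times) >= win[2] - 1e-9
  }
  need <- if (mode == "cumulative") post else c(base[1], post[2])
  qualify <- Filter(function(s) covers(s, need), sequences)
  if (!length(qualify))
    stop("no larva tracked through the entire window [",
         need[1], ", ", need[2], "] s")
  if (mode == "cumulative") {
    hits <- vapply(qualify, function(s) {
      any(s$labels[s$times >= post[1] & s$times < post[2]] == action)
    }, TRUE)
    list(probability = mean(hits), n = sum(hits), N = length(qualify),
         mode = mode, window = post)
  } else {
    occupancy <- function(s, win) {
      idx <- s$times >= win[1] & s$times < win[2]
      mean(s$labels[idx] == action)
    }
    post_occ <- mean(vapply(qualify, occupancy, 0, win = post))
    base_occ <- mean(vapply(qualify, occupancy, 0, win = base))
    list(probability = post_occ - base_occ, n = NA_integer_,
         N = length(qualify), mode = mode, window = post)
  }
}

#' Stimulus-induced change in action probability
#'
#' \eqn{\chi = p_A - p_B}: the difference between the post-stimulus action
#' probability \eqn{p_A} and the pre-stimulus baseline probability
#' \eqn{p_B}, each computed as responders over larvae tracked through the
#' respective window.
#'
#' @param counts A [group_window_counts()].
#' @return Scalar in [-1, 1].
#' @export
chi_estimator <- function(counts) {
  stopifnot(inherits(counts, "group_window_counts"))
  if (counts$N_post == 0 || counts$N_pre == 0)
    stop("zero denominator in a window")
  counts$n_post / counts$N_post - counts$n_pre / counts$N_pre
}

#' Theta estimator comparing a test group to its control
#'
#' \eqn{\Theta(p, q) = \chi(p) - \chi(q)}: the difference between the test
#' and control groups of the stimulus-induced change in action probability.
#' Takes values in [-1, 1]; zero under the null of no group difference;
#' antisymmetric under swapping the groups. By accumulating events over a
#' time window it detects behaviours whose onset is widely distributed
#' across the population.
#'
#' @param test,control [group_window_counts()] for the two groups.
#' @return Scalar Theta.
#' @export
theta_statistic <- function(test, control) {
  chi_estimator(test) - chi_estimator(control)
}

#' Resampling test for the Theta estimator
#'
#' Simulates the null of no group difference by resampling the four counts:
#' per window, the pooled responders are redistributed between test and
#' control by a hypergeometric draw (conditioning on the pooled total, so
#' both groups share the window's response rate). Theta is recomputed for
#' each replicate and the two-sided add-one p-value
#' \eqn{(1 + \#\{|\Theta^*| \ge |\Theta_{obs}|\})/(1 + n_{sim})} is
#' returned. The degenerate single-draw scheme is retained behind
#' \code{scheme = "literal"} for comparison.
#'
#' @param test,control [group_window_counts()].
#' @param n_sim Number of null replicates (at least 100).
#' @param seed Integer seed; the test is deterministic given it.
#' @param scheme \code{"pooled"} (default) or \code{"literal"}.
#' @return List: \code{theta}, \code{p_value}, \code{null_sample},
#'   \code{n_sim}, \code{seed}, \code{scheme}.
#' @export
theta_test <- function(test, control, n_sim = 1000, seed = 1,
                       scheme = c("pooled", "literal")) {
  scheme <- match.arg(scheme)
  if (n_sim < 100) stop("n_sim must be at least 100")
  obs <- theta_statistic(test, control)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  draw_window <- function(n_t, N_t, n_c, N_c) {
    m <- n_t + n_c
    nt_star <- stats::rhyper(n_sim, m, N_t + N_c - m, N_t)
    cbind(nt_star / N_t, (m - nt_star) / N_c)
  }
  if (scheme == "pooled") {
    post <- draw_window(test$n_post, test$N_post, control$n_post, control$N_post)
    pre <- draw_window(test$n_pre, test$N_pre, control$n_pre, control$N_pre)
    null_sample <- (post[, 1] - pre[, 1]) - (post[, 2] - pre[, 2])
  } else {
    # literal single-draw scheme: one Hypergeometric(N_all, N, 1) draw per
    # group and window, i.e. a Bernoulli with the group's own rate
    p1 <- function(n, N) stats::rhyper(n_sim, n, N - n, 1)
    null_sample <- (p1(test$n_post, test$N_post) - p1(test$n_pre, test$N_pre)) -
      (p1(control$n_post, control$N_post) - p1(control$n_pre, control$N_pre))
  }
  p <- (1 + sum(abs(null_sample) >= abs(obs))) / (1 + n_sim)
  list(theta = obs, p_value = p, null_sample = null_sample,
       n_sim = n_sim, seed = seed, scheme = scheme)
}
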