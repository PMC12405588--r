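#' Action-to-action transition counts after stimulus onset
#'
#' Counts ordered label changes within a short window after stimulus onset.
#' The default 2 s window targets the transitions that happen immediately
#' upon stimulation; when the total number of transitions is low (< 100)
#' the count is recomputed over the first 10 s for robustness, and the
#' window actually used is recorded.
#'
#' @param sequences List of [action_seq()] (regularised).
#' @param window Window length (s) after onset.
#' @param fallback_window Fallback length (s) engaged when the total is
#'   below \code{min_transitions}.
#' @param min_transitions Robustness floor on the transition total.
#' @return Object of class \code{transition_counts}: \code{counts}
#'   (action x action matrix, from in rows), \code{window_used},
#'   \code{fallback_engaged}, \code{total}.
#' @export
transition_matrix <- function(sequences, window = 2, fallback_window = 10,
                              min_transitions = 100) {
  count_in <- function(win) {
    acts <- action_levels()
    M <- matrix(0L, length(acts), length(acts), dimnames = list(acts, acts))
    for (s in sequences) {
      lo <- s$stimulus_onset
      idx <- which(s$times >= lo & s$times < lo + win)
      if (length(idx) < 2) next
      lab <- s$labels[idx]
      ch <- which(lab[-1] != lab[-length(lab)])
      for (k in ch) M[lab[k], lab[k + 1]] <- M[lab[k], lab[k + 1]] + 1L
    }
    M
  }
  M <- count_in(window)
  used <- window
  fallback <- FALSE
  if (sum(M) < min_transitions) {
    M <- count_in(fallback_window)
    used <- fallback_window
    fallback <- TRUE
  }
  structure(list(counts = M, window_used = used, fallback_engaged = fallback,
                 total = sum(M)),
            class = "transition_counts")
}

#' @export
print.transition_counts <- function(x, ...) {
  cat("transition_counts:", x$total, "transitions in a", x$window_used,
      "s window", if (x$fallback_engaged) "(fallback engaged)" else "", "\n")
  keep <- rowSums(x$counts) > 0 | colSums(x$counts) > 0
  print(x$counts[keep, keep, drop = FALSE])
  invisible(x)
}

#' Generalized likelihood-ratio test on two binomial proportions
#'
#' Compares the frequency of a transition (or any binary outcome) between a
#' manipulated group (\code{n_m} of \code{N_m}) and a control group
#' (\code{n_0} of \code{N_0}). The statistic is
#' \deqn{z = -2 \log \frac{B(\pi, N_m, n_m)\, B(\pi, N_0, n_0)}
#'                       {B(\pi_m, N_m, n_m)\, B(\pi_0, N_0, n_0)}}
#' with \eqn{\pi = (n_m + n_0)/(N_m + N_0)} the pooled proportion and
#' \eqn{\pi_m, \pi_0} the per-group proportions; the p-value comes from the
#' chi-square distribution with one degree of freedom. Computed in
#' log-space with the 0 log 0 = 0 convention, so z is exactly 0 when the
#' two proportions are equal and nonnegative always.
#'
#' @param n_m,N_m Successes and trials in the manipulated group.
#' @param n_0,N_0 Successes and trials in the control group.
#' @return List with \code{z}, \code{p_value}, \code{pi_pooled},
#'   \code{pi_m}, \code{pi_0}.
#' @export
glr_transition_test <- function(n_m, N_m, n_0, N_0) {
  if (N_m <= 0 || N_0 <= 0) stop("both groups must contain trials")
  if (n_m < 0 || n_0 < 0 || n_m > N_m || n_0 > N_0)
    stop("counts must satisfy 0 <= n <= N")
  xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))
  loglik <- function(pi, N, n) xlogy(n, pi) + xlogy(N - n, 1 - pi)
  pi_m <- n_m / N_m
  pi_0 <- n_0 / N_0
  pi_pool <- (n_m + n_0) / (N_m + N_0)
  z <- -2 * (loglik(pi_pool, N_m, n_m) + loglik(pi_pool, N_0, n_0) -
               loglik(pi_m, N_m, n_m) - loglik(pi_0, N_0, n_0))
  z <- max(z, 0)  # clip numerical negatives at the boundary
  list(z = z, p_value = stats::pchisq(z, df = 1, lower.tail = FALSE),
       pi_pooled = pi_pool, pi_m = pi_m, pi_0 = pi_0)
}
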