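#' Right-hand side of the circuit rate equations
#'
#' Evaluates the rate derivative
#' \deqn{\tau \dot r = -V_0 - r + s + i + \mathrm{recurrent}(r)}
#' where the recurrent term depends on the coupling form of the spec
#' (see [circuit_spec()]). The stimulus \code{s} enters only at the MCh
#' population and only while the stimulus is on. To enforce positivity of
#' the rates, derivative entries are clamped to be nonnegative wherever the
#' corresponding rate is below 1e-9; silenced populations get derivative 0.
#'
#' @param spec A [circuit_spec].
#' @param r Rate vector of length 7, elementwise nonnegative.
#' @param stimulus_on Logical; apply the MCh stimulus input?
#' @param silenced Character vector of population names clamped at zero.
#' @return Numeric vector of length 7 (a.u. rate per a.u. time).
#' @export
rate_derivative <- function(spec, r, stimulus_on = TRUE, silenced = character(0)) {
  if (length(r) != 7L) stop("rate vector must have length 7, got ", length(r))
  sil <- .silenced_index(spec, silenced)
  r <- pmax(as.numeric(r), 0)
  r[sil] <- 0
  stim <- numeric(7)
  if (isTRUE(stimulus_on)) stim[1] <- spec$stimulus_amplitude
  ex <- as.vector(spec$A_ex %*% r)
  inh <- as.vector(spec$A_in %*% r)
  rec <- switch(spec$coupling,
    shunting_exc = spec$k_ex * (spec$rmax - r) * ex - inh,
    shunting_all = spec$k_ex * (spec$rmax - r) * (ex - inh),
    literal      = spec$k_ex * (r - spec$rmax) * (ex - inh)
  )
  dr <- (-spec$V0 - r + stim + spec$tonic_input + rec) / spec$tau
  dr[r < 1e-9 & dr < 0] <- 0
  dr[sil] <- 0
  stats::setNames(as.numeric(dr), spec$population_order)
}

.silenced_index <- function(spec, silenced) {
  if (length(silenced) == 0) return(integer(0))
  idx <- match(silenced, spec$population_order)
  if (anyNA(idx)) stop("unknown population name(s): ",
                       paste(silenced[is.na(idx)], collapse = ", "))
  idx
}

#' Integrate the circuit rate model
#'
#' Adaptive stiff-capable integration (LSODA via \pkg{deSolve}) at relative
#' and absolute tolerance 1e-3. The state is clamped nonnegative and
#' derivative components are clamped nonnegative whenever the corresponding
#' state component falls below 1e-9, so the solution stays positive.
#' Silenced populations are removed from the dynamics by holding both their
#' rate and derivative at zero.
#'
#' @inheritParams rate_derivative
#' @param duration Integration time (a.u.), strictly positive.
#' @param r0 Initial rates, length 7, nonnegative; default all zero.
#' @param dt_out Output sampling step (a.u.).
#' @return An object of class \code{rate_trajectory}: list with \code{times},
#'   \code{rates} (7 x T matrix, populations in rows), \code{spec},
#'   \code{silenced}.
#' @export
integrate_circuit <- function(spec, duration, r0 = numeric(7),
                              silenced = character(0), stimulus_on = TRUE,
                              dt_out = 0.5) {
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  if (length(r0) != 7L || any(r0 < 0)) stop("r0 must be length 7 and nonnegative")
  sil <- .silenced_index(spec, silenced)
  r0 <- as.numeric(r0)
  r0[sil] <- 0
  func <- function(t, r, parms) {
    list(rate_derivative(spec, r, stimulus_on = stimulus_on, silenced = silenced))
  }
  times <- unique(c(seq(0, duration, by = dt_out), duration))
  out <- suppressWarnings(
    deSolve::ode(y = r0, times = times, func = func, parms = NULL,
                 method = "lsoda", rtol = 1e-3, atol = 1e-3, maxsteps = 50000)
  )
  if (nrow(out) < length(times)) {
    stop("solver failure at t = ", out[nrow(out), 1], "; last state: ",
         paste(signif(out[nrow(out), -1], 4), collapse = ", "))
  }
  rates <- t(pmax(unname(out[, -1, drop = FALSE]), 0))
  rates[sil, ] <- 0
  rownames(rates) <- spec$population_order
  structure(list(times = out[, 1], rates = rates, spec = spec,
                 silenced = silenced),
            class = "rate_trajectory")
}

#' @export
print.rate_trajectory <- function(x, ...) {
  cat("rate_trajectory:", length(x$times), "samples over [0, ",
      max(x$times), "] a.u.\n", sep = "")
  if (length(x$silenced)) cat("  silenced:", paste(x$silenced, collapse = ", "), "\n")
  cat("  final rates:", paste(sprintf("%s=%.2f", rownames(x$rates),
                                      x$rates[, ncol(x$rates)]), collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.rate_trajectory <- function(x, populations = rownames(x$rates), ...) {
  idx <- match(populations, rownames(x$rates))
  graphics::matplot(x$times, t(x$rates[idx, , drop = FALSE]), type = "l",
                    lty = 1, xlab = "time (a.u.)", ylab = "rate (a.u.)", ...)
  graphics::legend("topright", legend = populations, col = seq_along(idx),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Classify a (B1, B2) steady state by the scalar rate ratio
#'
#' The two attractors of the stimulated circuit are a coactive state (B1 and
#' B2 both high; behavioural readout Head Cast) and a monoactive state (B1
#' high, B2 near zero; readout Hunch). The scalar rate(B2)/rate(B1)
#' separates them: large for coactive, small for monoactive.
#'
#' @param b1,b2 Steady rates of B1 and B2 (a.u.).
#' @param ratio_threshold Label is monoactive when b2/b1 falls below this.
#' @param activity_floor B1 rates below this leave the ratio unguarded and
#'   the label \code{"undetermined"}.
#' @return List with \code{ratio} (NA when guarded) and \code{label}.
#' @export
ratio_label <- function(b1, b2, ratio_threshold = 0.1, activity_floor = 1e-3) {
  if (!is.finite(b1) || b1 < activity_floor) {
    return(list(ratio = NA_real_, label = "undetermined"))
  }
  ratio <- b2 / b1
  list(ratio = ratio,
       label = if (ratio < ratio_threshold) "monoactive" else "coactive")
}

#' Steady state of the stimulated circuit
#'
#' Integrates from all-zero initial rates with the stimulus held on, in
#' chunks, until max |dr/dt| drops below \code{tol} or the time cap is
#' reached. The behavioural label comes from the rate(B2)/rate(B1) ratio
#' rule (see [ratio_label()]).
#'
#' @inheritParams rate_derivative
#' @param tol Convergence tolerance on max |dr/dt|.
#' @param t_cap Time cap (a.u.); default 50 x max(tau).
#' @param chunk Integration chunk length between convergence checks (a.u.).
#' @return An object of class \code{steady_state_result}: \code{rates}
#'   (length 7), \code{converged}, \code{b2_b1_ratio}, \code{label}
#'   (\code{"coactive"}, \code{"monoactive"} or \code{"undetermined"}),
#'   \code{time}.
#' @export
steady_state <- function(spec, silenced = character(0), tol = 1e-6,
                         t_cap = 50 * max(spec$tau), chunk = 250) {
  r <- numeric(7)
  t_now <- 0
  converged <- FALSE
  while (t_now < t_cap) {
    step <- min(chunk, t_cap - t_now)
    tr <- tryCatch(
      integrate_circuit(spec, step, r0 = r, silenced = silenced,
                        stimulus_on = TRUE, dt_out = step / 4),
      error = function(e) NULL)
    if (is.null(tr)) break  # boundary chatter: report as non-converged
    r <- tr$rates[, ncol(tr$rates)]
    t_now <- t_now + step
    dr <- rate_derivative(spec, r, stimulus_on = TRUE, silenced = silenced)
    if (max(abs(dr)) < tol) { converged <- TRUE; break }
  }
  names(r) <- spec$population_order
  rl <- ratio_label(r["B1"], r["B2"])
  if (!converged) rl$label <- "undetermined"
  structure(list(rates = r, converged = converged,
                 b2_b1_ratio = rl$ratio, label = rl$label, time = t_now,
                 spec = spec, silenced = silenced),
            class = "steady_state_result")
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat("steady state (", if (x$converged) "converged" else "NOT converged",
      " at t=", x$time, "): label=", x$label,
      ", B2/B1=", signif(x$b2_b1_ratio, 4), "\n", sep = "")
  print(round(x$rates, 3))
  invisible(x)
}
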