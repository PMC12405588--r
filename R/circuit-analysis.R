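#' Steady-state scan over the MCh to iLNa weight
#'
#' Convenience wrapper running [steady_state()] for each value of the
#' stimulus-affinity weight w_iLNa, emulating the ensemble of stimuli the
#' larva encounters.
#'
#' @param base A [circuit_spec] whose other parameters are held fixed.
#' @param w_grid Ascending numeric vector of w_iLNa values.
#' @return List with \code{results} (list of [steady_state()] outputs) and
#'   \code{table} (data frame: w_iLNa, B1, B2, ratio, label, converged).
#' @export
scan_weights <- function(base, w_grid = seq(0.5, 1.5, by = 0.05)) {
  results <- lapply(w_grid, function(w) {
    sp <- base
    sp$w_iLNa <- w
    sp$A_ex["iLNa", "MCh"] <- w
    steady_state(sp)
  })
  table <- data.frame(
    w_iLNa = w_grid,
    B1 = vapply(results, function(x) unname(x$rates["B1"]), 0),
    B2 = vapply(results, function(x) unname(x$rates["B2"]), 0),
    ratio = vapply(results, function(x) if (is.na(x$b2_b1_ratio)) NA_real_
                   else x$b2_b1_ratio, 0),
    label = vapply(results, function(x) x$label, ""),
    converged = vapply(results, function(x) x$converged, TRUE)
  )
  list(results = results, table = table)
}

#' Cluster an ensemble of steady states into coactive/monoactive
#'
#' k-means with k = 2 on the (B1, B2) steady rates of an ensemble of
#' simulations; the cluster with the larger mean B2 is named
#' \code{"coactive"} (Head Cast) and the other \code{"monoactive"} (Hunch).
#' The scalar-ratio alternative labels (see [ratio_label()]) are returned
#' alongside for comparison.
#'
#' @param ensemble List of [steady_state()] results (at least 2, converged).
#' @param nstart Number of k-means restarts (ties broken by inertia, as in
#'   \code{stats::kmeans}).
#' @param seed Integer seed making the restarts reproducible.
#' @return List with \code{labels} (character, per item), \code{centers}
#'   (2 x 2 matrix, rows named coactive/monoactive), \code{ratio_labels},
#'   \code{agreement} (fraction of items on which the two labelers agree),
#'   and the underlying \code{kmeans} fit.
#' @export
label_outcomes <- function(ensemble, nstart = 10, seed = 1) {
  if (length(ensemble) < 2) stop("ensemble must contain at least 2 results")
  pts <- t(vapply(ensemble, function(x) unname(x$rates[c("B1", "B2")]),
                  numeric(2)))
  colnames(pts) <- c("B1", "B2")
  if (all(abs(sweep(pts, 2, pts[1, ])) < 1e-12)) {
    stop("degenerate ensemble: all (B1, B2) points are identical")
  }
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(seed)
  km <- stats::kmeans(pts, centers = 2, nstart = nstart)
  co_cluster <- which.max(km$centers[, "B2"])
  labels <- ifelse(km$cluster == co_cluster, "coactive", "monoactive")
  centers <- km$centers[order(-km$centers[, "B2"]), , drop = FALSE]
  rownames(centers) <- c("coactive", "monoactive")
  ratio_labels <- vapply(ensemble, function(x) x$label, "")
  list(labels = labels, centers = centers, ratio_labels = ratio_labels,
       agreement = mean(labels == ratio_labels), kmeans = km)
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Phase diagram over stimulus affinity and a neuromodulation parameter
#'
#' Solves the steady state for every combination of the MCh to iLNa weight
#' (w_iLNa) and one modulation parameter -- the iLNa maximum rate or the
#' tonic input current to Hb -- and extracts, per modulation value, the
#' transition threshold in w_iLNa at which the outcome flips from coactive
#' (Head Cast) to monoactive (Hunch).
#'
#' The threshold is the midpoint of the grid interval bracketing the first
#' monoactive label in ascending w; \code{NA} marks a modulation value with
#' no flip inside the grid. Non-converged cells are flagged, excluded from
#' threshold extraction, and reported with a warning.
#'
#' @param base A [circuit_spec]; its w_iLNa and the chosen modulation
#'   parameter are overridden cell by cell.
#' @param w_grid Ascending values of w_iLNa.
#' @param mod_param \code{"rmax_iLNa"} or \code{"i_Hb"}.
#' @param mod_grid Ascending values of the modulation parameter.
#' @return Object of class \code{phase_diagram}: \code{w_grid},
#'   \code{mod_param}, \code{mod_grid}, \code{ratio} and \code{label}
#'   matrices (w in rows, modulation values in columns), \code{converged}
#'   matrix, \code{threshold} (per modulation value).
#' @export
phase_diagram <- function(base, w_grid = seq(0.5, 1.5, by = 0.05),
                          mod_param = c("rmax_iLNa", "i_Hb"),
                          mod_grid) {
  mod_param <- match.arg(mod_param)
  if (length(w_grid) == 0 || is.unsorted(w_grid, strictly = TRUE))
    stop("w_grid must be nonempty and strictly ascending")
  if (length(mod_grid) == 0 || is.unsorted(mod_grid, strictly = TRUE))
    stop("mod_grid must be nonempty and strictly ascending")
  nw <- length(w_grid); nm <- length(mod_grid)
  ratio <- matrix(NA_real_, nw, nm, dimnames = list(w_grid, mod_grid))
  label <- matrix(NA_character_, nw, nm, dimnames = list(w_grid, mod_grid))
  conv <- matrix(FALSE, nw, nm, dimnames = list(w_grid, mod_grid))
  for (j in seq_len(nm)) {
    sp <- base
    if (mod_param == "rmax_iLNa") sp$rmax["iLNa"] <- mod_grid[j]
    else sp$tonic_input["Hb"] <- mod_grid[j]
    for (i in seq_len(nw)) {
      sp$w_iLNa <- w_grid[i]
      sp$A_ex["iLNa", "MCh"] <- w_grid[i]
      st <- steady_state(sp)
      ratio[i, j] <- if (is.na(st$b2_b1_ratio)) NA_real_ else st$b2_b1_ratio
      label[i, j] <- st$label
      conv[i, j] <- st$converged
    }
  }
  if (!all(conv)) {
    warning(sum(!conv), " phase-diagram cell(s) did not converge; ",
            "thresholds use converged cells only")
  }
  threshold <- vapply(seq_len(nm), function(j) {
    ok <- conv[, j]
    lab <- label[ok, j]
    wv <- w_grid[ok]
    i1 <- which(lab == "monoactive")[1]
    if (is.na(i1) || i1 == 1) {
      if (identical(i1, 1L)) return(wv[1])  # flips at/below the grid start
      return(NA_real_)
    }
    (wv[i1] + wv[i1 - 1]) / 2
  }, numeric(1))
  structure(list(w_grid = w_grid, mod_param = mod_param, mod_grid = mod_grid,
                 ratio = ratio, label = label, converged = conv,
                 threshold = stats::setNames(threshold, mod_grid),
                 base = base),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat("phase_diagram over w_iLNa [", min(x$w_grid), ", ", max(x$w_grid),
      "] x ", x$mod_param, " [", min(x$mod_grid), ", ", max(x$mod_grid),
      "]\n", sep = "")
  cat("thresholds (w_iLNa at coactive -> monoactive flip):\n")
  print(round(x$threshold, 4))
  invisible(x)
}

#' @export
as.data.frame.phase_diagram <- function(x, ...) {
  grid <- expand.grid(w_iLNa = x$w_grid, mod_value = x$mod_grid)
  grid$mod_param <- x$mod_param
  grid$ratio <- as.vector(x$ratio)
  grid$label <- as.vector(x$label)
  grid$converged <- as.vector(x$converged)
  grid
}

#' @export
plot.phase_diagram <- function(x, ...) {
  z <- matrix(as.numeric(factor(x$label, levels = c("monoactive", "coactive",
                                                    "undetermined"))),
              nrow = length(x$w_grid))
  graphics::image(x$w_grid, x$mod_grid, z, col = c("#d95f02", "#1b9e77", "grey"),
                  xlab = "w_iLNa", ylab = x$mod_param, ...)
  ok <- !is.na(x$threshold)
  if (any(ok)) graphics::lines(x$threshold[ok], x$mod_grid[ok], lwd = 2)
  invisible(x)
}

#' Effect of silencing one population on another's activity
#'
#' Runs the stimulated circuit twice -- with and without the target
#' population clamped at zero -- and reports the readout population's time
#' course and its time integral in both conditions, emulating the model
#' predictions for genetic silencing experiments (e.g. silencing Hb
#' increases iLNa activity; silencing iLNa strongly increases Hb activity).
#'
#' @inheritParams rate_derivative
#' @param target Population to clamp at zero.
#' @param readout Population whose activity is reported; must differ from
#'   \code{target}.
#' @param duration Length of the stimulated epoch to integrate over (a.u.).
#' @return List with \code{trajectory} and \code{trajectory_silenced}
#'   ([integrate_circuit()] outputs), \code{readout}, \code{target}, and
#'   \code{summary}: readout integrals with/without silencing plus their
#'   difference (\code{excess}).
#' @export
silencing_effect <- function(spec, target, readout, duration = 350) {
  if (identical(target, readout)) stop("target and readout must differ")
  .silenced_index(spec, c(target, readout))  # validates names
  base <- integrate_circuit(spec, duration, stimulus_on = TRUE)
  sil <- integrate_circuit(spec, duration, silenced = target, stimulus_on = TRUE)
  int_base <- .trapz(base$times, base$rates[readout, ])
  int_sil <- .trapz(sil$times, sil$rates[readout, ])
  list(trajectory = base, trajectory_silenced = sil,
       target = target, readout = readout,
       summary = c(integral = int_base, integral_silenced = int_sil,
                   excess = int_sil - int_base))
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
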