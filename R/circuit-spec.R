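#' Population names of the Hunch/Head-Cast decision circuit
#'
#' Fixed ordering used by every matrix and vector in a [circuit_spec]:
#' chordotonal mechanosensory input (MCh), the two Basin projection neurons
#' (B1, B2), the reciprocally connected feedforward inhibitory interneurons
#' (iLNb, iLNa), and the feedback inhibitory interneurons Handle-a/b (Ha, Hb).
#'
#' @return Character vector of length 7.
#' @export
circuit_populations <- function() {
  c("MCh", "B1", "B2", "iLNb", "iLNa", "Ha", "Hb")
}

# Connectome-derived coupling matrices, rows = postsynaptic population.
# The MCh->iLNa entry is symbolic (w_iLNa) and filled in by circuit_spec();
# the MCh->iLNb weight is fixed at 2.
.A_ex_template <- function() {
  p <- circuit_populations()
  A <- matrix(0, 7, 7, dimnames = list(p, p))
  A["B1",   "MCh"] <- 1.5
  A["B2",   "MCh"] <- 0.75
  A["iLNb", "MCh"] <- 2
  A["Ha",   "B1"]  <- 0.2
  A["Ha",   "B2"]  <- 0.2
  A["Hb",   "MCh"] <- 0.4
  A["Hb",   "B2"]  <- 0.5
  A
}

.A_in_template <- function() {
  p <- circuit_populations()
  A <- matrix(0, 7, 7, dimnames = list(p, p))
  A["B1",   c("iLNb", "iLNa")]       <- c(1.7648, 1.3841)
  A["B2",   c("iLNb", "iLNa")]       <- c(1, 5.9167)
  A["iLNb", c("iLNa", "Ha", "Hb")]   <- c(3.3744, 1.6659, 2.191)
  A["iLNa", c("iLNb", "Ha", "Hb")]   <- c(2.7133, 1.1010, 3.3031)
  A["Ha",   c("iLNb", "iLNa")]       <- c(1.8411, 1.1158)
  A["Hb",   c("iLNb", "iLNa")]       <- c(1.7331, 2.2145)
  A
}

#' Construct a parameterisation of the decision-circuit rate model
#'
#' Low-level constructor; most users should call [build_circuit()] with a
#' named variant instead.
#'
#' @param w_iLNa MCh to iLNa excitatory weight, the scanned stimulus-affinity
#'   parameter (dimensionless synaptic weight).
#' @param rmax_iLNa Maximum rate of the iLNa population (a.u.); 20 in the fed
#'   state, 18 in the sucrose state.
#' @param i_Hb Tonic input current to Hb from other brain regions (a.u.);
#'   0 in the fed state, 10 in the sucrose state.
#' @param stimulus_amplitude Constant stimulus input \code{s} applied to MCh
#'   while the stimulus is on (a.u.). Default 1.5; see the methods vignette
#'   for the calibration rationale.
#' @param w_iLNb MCh to iLNb excitatory weight; fixed at 2 in the reference
#'   parameterisation, exposed for the clustering-ensemble scan.
#' @param k_ex Input-sensitivity factor (dimensionless).
#' @param tau Per-population time constants (a.u. time), length 7.
#' @param V0 Per-population activation thresholds (a.u. rate), length 7.
#' @param coupling Functional form of the recurrent term:
#'   \code{"shunting_exc"} (default) applies the gain
#'   \code{k_ex (rmax - r)} to the excitatory drive only, with subtractive
#'   inhibition; \code{"shunting_all"} applies it to the net drive
#'   \code{(A_ex - A_in) r}; \code{"literal"} uses the sign-inverted gain
#'   \code{k_ex (r - rmax)}, kept for comparison. See the methods vignette.
#' @return An object of class \code{circuit_spec}.
#' @seealso [build_circuit()], [rate_derivative()], [integrate_circuit()]
#' @export
circuit_spec <- function(w_iLNa = 1, rmax_iLNa = 20, i_Hb = 0,
                         stimulus_amplitude = 1.5, w_iLNb = 2, k_ex = 2.5,
                         tau = c(1, rep(35, 6)), V0 = c(0, rep(20, 6)),
                         coupling = c("shunting_exc", "shunting_all", "literal")) {
  coupling <- match.arg(coupling)
  p <- circuit_populations()
  stopifnot(length(tau) == 7, length(V0) == 7)
  if (any(tau <= 0)) stop("tau must be strictly positive")
  if (w_iLNa < 0) stop("w_iLNa must be nonnegative")
  A_ex <- .A_ex_template()
  A_ex["iLNa", "MCh"] <- w_iLNa
  A_ex["iLNb", "MCh"] <- w_iLNb
  rmax <- rep(20, 7)
  rmax[p == "iLNa"] <- rmax_iLNa
  tonic <- rep(0, 7)
  tonic[p == "Hb"] <- i_Hb
  spec <- structure(list(
    population_order = p,
    tau = stats::setNames(as.numeric(tau), p),
    V0 = stats::setNames(as.numeric(V0), p),
    rmax = stats::setNames(rmax, p),
    tonic_input = stats::setNames(tonic, p),
    k_ex = k_ex,
    A_ex = A_ex,
    A_in = .A_in_template(),
    w_iLNa = w_iLNa,
    stimulus_amplitude = stimulus_amplitude,
    coupling = coupling
  ), class = "circuit_spec")
  validate_circuit(spec)
  spec
}

#' Validate the structural invariants of a circuit parameterisation
#'
#' Checks matrix nonnegativity and zero diagonals, vector lengths, strictly
#' positive time constants and a nonnegative MCh to iLNa weight.
#'
#' @param spec A [circuit_spec] object.
#' @return \code{spec}, invisibly; errors on violation.
#' @export
validate_circuit <- function(spec) {
  stopifnot(inherits(spec, "circuit_spec"))
  for (nm in c("tau", "V0", "rmax", "tonic_input")) {
    if (length(spec[[nm]]) != 7L) stop("field '", nm, "' must have length 7")
  }
  for (nm in c("A_ex", "A_in")) {
    A <- spec[[nm]]
    if (!all(dim(A) == c(7L, 7L))) stop(nm, " must be 7x7")
    if (any(A < 0)) stop(nm, " must be nonnegative")
    if (any(diag(A) != 0)) stop(nm, " must have a zero diagonal")
  }
  if (any(spec$tau <= 0)) stop("tau must be strictly positive")
  if (spec$w_iLNa < 0) stop("w_iLNa must be nonnegative")
  invisible(spec)
}

#' Build a named variant of the decision circuit
#'
#' Returns the reference parameterisation of the seven-population rate model
#' under one of the feeding-state hypotheses: \code{"fed"} (rmax_iLNa = 20,
#' i_Hb = 0), \code{"sucrose_model1"} (extra tonic input current of 10 a.u.
#' to Hb), \code{"sucrose_model2"} (iLNa maximum rate lowered to 18 a.u.,
#' modelling a saturated response), or \code{"sucrose_combined"} (both).
#'
#' @param variant One of \code{"fed"}, \code{"sucrose_model1"},
#'   \code{"sucrose_model2"}, \code{"sucrose_combined"}.
#' @param overrides Named list overriding individual parameters; allowed
#'   names are the arguments of [circuit_spec()]. Unknown names are an error.
#' @return A [circuit_spec] object.
#' @examples
#' fed <- build_circuit("fed")
#' fed$A_in["B2", "iLNa"]  # 5.9167, extracted from synaptic counts
#' suc <- build_circuit("sucrose_combined", overrides = list(w_iLNa = 1.2))
#' @export
build_circuit <- function(variant = c("fed", "sucrose_model1", "sucrose_model2",
                                      "sucrose_combined"),
                          overrides = list()) {
  if (!is.character(variant) || !variant[1] %in%
      c("fed", "sucrose_model1", "sucrose_model2", "sucrose_combined")) {
    stop("unknown circuit variant: ", deparse(variant[1]))
  }
  variant <- variant[1]
  args <- list(
    rmax_iLNa = if (variant %in% c("sucrose_model2", "sucrose_combined")) 18 else 20,
    i_Hb = if (variant %in% c("sucrose_model1", "sucrose_combined")) 10 else 0
  )
  if (length(overrides)) {
    known <- names(formals(circuit_spec))
    bad <- setdiff(names(overrides), known)
    if (length(bad)) stop("unknown override name(s): ", paste(bad, collapse = ", "))
    args[names(overrides)] <- overrides
  }
  spec <- do.call(circuit_spec, args)
  spec$variant <- variant
  spec
}

#' @export
print.circuit_spec <- function(x, ...) {
  cat("Decision-circuit rate model (7 populations)\n")
  if (!is.null(x$variant)) cat("  variant:  ", x$variant, "\n")
  cat("  coupling: ", x$coupling, "\n")
  cat("  w_iLNa =", x$w_iLNa,
      " rmax_iLNa =", x$rmax["iLNa"],
      " i_Hb =", x$tonic_input["Hb"],
      " s =", x$stimulus_amplitude,
      " k_ex =", x$k_ex, "\n")
  invisible(x)
}
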