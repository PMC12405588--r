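#' Vectorise short posture segments around stimulus onset
#'
#' For each of 5 evenly spaced time points in the 60--65 s window a 2 s
#' window is centred on the point; the coordinates of the reduced 5-point
#' spine are collected within it at 10 Hz and concatenated into a
#' 200-element vector (5 points x 2 coordinates x 20 frames). These raw
#' segment vectors are the inputs of continuous (embedding-based)
#' behavioural comparisons. Centres whose window is not fully covered by
#' the track are skipped with a warning.
#'
#' @param track A preprocessed [spine_track()].
#' @param centers Window centres (s); default 5 evenly spaced in [60, 65].
#' @param spine_points Indices of the reduced spine (default
#'   \code{c(1, 3, 6, 9, 11)}).
#' @param half_window Half window length (s).
#' @return Matrix with one 200-element row per usable centre; row names
#'   give the centre times.
#' @export
segment_window_vectors <- function(track, centers = seq(60, 65, length.out = 5),
                                   spine_points = c(1, 3, 6, 9, 11),
                                   half_window = 1) {
  stopifnot(inherits(track, "spine_track"))
  dt <- stats::median(diff(track$times))
  n_frames <- round(2 * half_window / dt)
  rows <- list()
  for (cc in centers) {
    idx <- which(track$times >= cc - half_window - 1e-9 &
                 track$times < cc + half_window - 1e-9)
    if (length(idx) < n_frames) {
      warning("window centred at ", cc, " s not covered by track '",
              track$larva_id, "'; skipped")
      next
    }
    idx <- idx[seq_len(n_frames)]
    seg <- cbind(track$x[idx, spine_points, drop = FALSE],
                 track$y[idx, spine_points, drop = FALSE])
    rows[[as.character(cc)]] <- as.vector(t(seg))
  }
  if (!length(rows)) return(matrix(numeric(0), 0, 2 * length(spine_points) * n_frames))
  do.call(rbind, rows)
}

.gauss_kernel_cross <- function(X, Y, sigma, denom) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  exp(-d2 / denom)
}

.mmd_denom <- function(sigma, width_is_denominator) {
  if (width_is_denominator) sigma else 2 * sigma^2
}

#' Maximum mean discrepancy between two point clouds
#'
#' Unbiased (U-statistic) estimate of the squared MMD with a Gaussian
#' kernel \eqn{k(x, y) = \exp(-\|x - y\|^2 / (2\sigma^2))} of width
#' \eqn{\sigma} = 2 by default. The unbiased form excludes the diagonal
#' terms, so the estimate can be slightly negative when the samples come
#' from the same distribution.
#'
#' @param X,Y Numeric matrices (rows = points) of equal dimension.
#' @param sigma Kernel width.
#' @param width_is_denominator Alternative reading of "width": use
#'   \eqn{\exp(-\|x-y\|^2/\sigma)} instead.
#' @return Scalar squared-MMD estimate.
#' @export
mmd_statistic <- function(X, Y, sigma = 2, width_is_denominator = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("X and Y must share their dimension")
  n <- nrow(X); m <- nrow(Y)
  if (n < 2 || m < 2) stop("need at least 2 points per sample")
  denom <- .mmd_denom(sigma, width_is_denominator)
  Kxx <- .gauss_kernel_cross(X, X, sigma, denom)
  Kyy <- .gauss_kernel_cross(Y, Y, sigma, denom)
  Kxy <- .gauss_kernel_cross(X, Y, sigma, denom)
  (sum(Kxx) - sum(diag(Kxx))) / (n * (n - 1)) +
    (sum(Kyy) - sum(diag(Kyy))) / (m * (m - 1)) -
    2 * mean(Kxy)
}

#' Permutation test on the MMD statistic
#'
#' Pools the two samples, relabels them B times, and compares the observed
#' MMD against the surrogate distribution; the add-one p-value
#' \eqn{(1 + \#\{MMD^* \ge MMD_{obs}\})/(1 + B)} is returned, optionally
#' Bonferroni-adjusted for the actual number of pairwise comparisons
#' performed in a screen.
#'
#' @inheritParams mmd_statistic
#' @param B Number of permutations (at least 100).
#' @param seed Integer seed; deterministic given it.
#' @param bonferroni_m Number of comparisons for the adjustment.
#' @return List: \code{mmd}, \code{p_value}, \code{p_adjusted}, \code{B},
#'   \code{seed}, \code{sigma}, \code{null_sample}.
#' @export
mmd_permutation_test <- function(X, Y, sigma = 2, B = 200, seed = 1,
                                 bonferroni_m = 1,
                                 width_is_denominator = FALSE) {
  if (B < 100) stop("B must be at least 100")
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("X and Y must share their dimension")
  n <- nrow(X); m <- nrow(Y)
  denom <- .mmd_denom(sigma, width_is_denominator)
  P <- rbind(X, Y)
  K <- .gauss_kernel_cross(P, P, sigma, denom)
  stat_for <- function(ix) {
    iy <- setdiff(seq_len(n + m), ix)
    Kxx <- K[ix, ix]; Kyy <- K[iy, iy]; Kxy <- K[ix, iy]
    (sum(Kxx) - sum(diag(Kxx))) / (n * (n - 1)) +
      (sum(Kyy) - sum(diag(Kyy))) / (m * (m - 1)) -
      2 * mean(Kxy)
  }
  obs <- stat_for(seq_len(n))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  null_sample <- vapply(seq_len(B), function(b)
    stat_for(sample(n + m, n)), numeric(1))
  p <- (1 + sum(null_sample >= obs)) / (1 + B)
  list(mmd = obs, p_value = p, p_adjusted = min(1, bonferroni_m * p),
       B = B, seed = seed, sigma = sigma, null_sample = null_sample)
}
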