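#' Scaled head, centroid and tail speeds
#'
#' Finite-difference speeds of the head (spine point 1), the midline
#' centroid G, and the tail (point 11), each normalised by the larva's
#' median body length so values are in body-lengths per second and
#' comparable across larval sizes.
#'
#' @param track A preprocessed [spine_track()].
#' @return Data frame with columns \code{head}, \code{centroid}, \code{tail}
#'   (BL/s), one row per timestep.
#' @export
scaled_speeds <- function(track) {
  bl <- body_length(track)
  sp <- function(pos) sqrt(rowSums(.velocity(pos, track$times)^2)) / bl
  data.frame(head = sp(cbind(track$x[, 1], track$y[, 1])),
             centroid = sp(.centroid(track)),
             tail = sp(cbind(track$x[, 11], track$y[, 11])))
}

#' Nematic order parameter of the spine
#'
#' \eqn{S = (3 \langle \cos^2\theta \rangle - 1) / 2}, where \eqn{\theta} is
#' the angle between each of the 10 spine segments and the body axis (the
#' unit vector from tail to head) and the average runs over segments. S is 1
#' for a straight larva and -0.5 when every segment lies perpendicular to
#' the body axis.
#'
#' @param track A preprocessed [spine_track()].
#' @return Numeric vector in [-0.5, 1], one value per timestep.
#' @export
nematic_order <- function(track) {
  ax <- cbind(track$x[, 1] - track$x[, 11], track$y[, 1] - track$y[, 11])
  axn <- sqrt(rowSums(ax^2))
  n <- length(track$times)
  S <- numeric(n)
  for (t in seq_len(n)) {
    sx <- diff(track$x[t, ]); sy <- diff(track$y[t, ])
    seglen <- sqrt(sx^2 + sy^2)
    keep <- seglen > .Machine$double.eps & axn[t] > .Machine$double.eps
    if (!any(keep)) { S[t] <- NA_real_; next }
    cosq <- ((sx[keep] * ax[t, 1] + sy[keep] * ax[t, 2]) /
               (seglen[keep] * axn[t]))^2
    S[t] <- (3 * mean(cosq) - 1) / 2
  }
  S
}

#' Shape factor of the midline point cloud
#'
#' \eqn{\lambda = (\lambda_1 - \lambda_2) / (\lambda_1 + \lambda_2)} with
#' \eqn{\lambda_1 \ge \lambda_2} the eigenvalues of the 2x2 covariance of
#' the 11 midline points, averaged over a +/- 3-timestep window. 1 for a
#' perfectly straight (rank-1) spine, 0 for an isotropic configuration such
#' as points on a circle.
#'
#' @param track A preprocessed [spine_track()].
#' @param half_window Timesteps averaged on each side.
#' @return Numeric vector in [0, 1]; NA where the covariance has zero trace.
#' @export
shape_factor <- function(track, half_window = 3) {
  n <- length(track$times)
  covs <- lapply(seq_len(n), function(t) {
    stats::cov(cbind(track$x[t, ], track$y[t, ]))
  })
  vapply(seq_len(n), function(t) {
    idx <- max(1, t - half_window):min(n, t + half_window)
    M <- Reduce(`+`, covs[idx]) / length(idx)
    ev <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
    if (sum(ev) < .Machine$double.eps) return(NA_real_)
    (ev[1] - ev[2]) / (ev[1] + ev[2])
  }, numeric(1))
}

#' Head-to-tail axis ratio
#'
#' Ratio of the head-to-centroid and tail-to-centroid distances,
#' \eqn{\|HG\| / \|TG\|}. Below 1 when the head is pulled toward the body
#' centre, as during a Hunch.
#'
#' @param track A preprocessed [spine_track()].
#' @param eps Guard: timesteps with \eqn{\|TG\|} below this yield NA rather
#'   than an infinite ratio.
#' @return Numeric vector, one ratio per timestep.
#' @export
axis_ratio <- function(track, eps = 1e-9) {
  G <- .centroid(track)
  hg <- sqrt((track$x[, 1] - G[, 1])^2 + (track$y[, 1] - G[, 2])^2)
  tg <- sqrt((track$x[, 11] - G[, 1])^2 + (track$y[, 11] - G[, 2])^2)
  ifelse(tg < eps, NA_real_, hg / tg)
}

#' Head/tail velocity projections and alignment cosines
#'
#' The scalar projection of the head (tail) velocity onto the unit vector of
#' the first (last) spine segment, normalised by body length (BL/s), and the
#' cosine of the angle between the same vector pairs. The first segment
#' points from spine point 2 out through the head; the last from point 10
#' out through the tail. Zero-velocity frames yield NA cosines.
#'
#' @param track A preprocessed [spine_track()].
#' @return Data frame: \code{head_proj}, \code{tail_proj} (BL/s),
#'   \code{head_cos}, \code{tail_cos} (in [-1, 1] or NA).
#' @export
velocity_alignment <- function(track) {
  bl <- body_length(track)
  vh <- .velocity(cbind(track$x[, 1], track$y[, 1]), track$times)
  vt <- .velocity(cbind(track$x[, 11], track$y[, 11]), track$times)
  s1 <- cbind(track$x[, 1] - track$x[, 2], track$y[, 1] - track$y[, 2])
  s10 <- cbind(track$x[, 11] - track$x[, 10], track$y[, 11] - track$y[, 10])
  proj_cos <- function(v, seg) {
    segn <- sqrt(rowSums(seg^2))
    vn <- sqrt(rowSums(v^2))
    dot <- rowSums(v * seg)
    proj <- ifelse(segn > .Machine$double.eps, dot / segn, NA_real_) / bl
    cosv <- ifelse(segn > .Machine$double.eps & vn > .Machine$double.eps,
                   dot / (segn * vn), NA_real_)
    list(proj = proj, cos = pmin(pmax(cosv, -1), 1))
  }
  h <- proj_cos(vh, s1); tl <- proj_cos(vt, s10)
  data.frame(head_proj = h$proj, tail_proj = tl$proj,
             head_cos = h$cos, tail_cos = tl$cos)
}

#' Per-timestep feature table for action classification
#'
#' Assembles the per-frame features used by the frame classifier: the three
#' scaled speeds, nematic order S, shape factor, head/tail axis ratio,
#' velocity projections and alignment cosines, and the scaled instantaneous
#' midline length. NA cosines (zero-velocity frames) are encoded as 0
#' (no preferred direction).
#'
#' @param track A preprocessed [spine_track()].
#' @return Data frame with 11 feature columns, one row per timestep.
#' @export
frame_features <- function(track) {
  sp <- scaled_speeds(track)
  va <- velocity_alignment(track)
  va$head_cos[is.na(va$head_cos)] <- 0
  va$tail_cos[is.na(va$tail_cos)] <- 0
  ar <- axis_ratio(track)
  ar[is.na(ar)] <- 1
  bl <- body_length(track)
  data.frame(speed_head = sp$head, speed_centroid = sp$centroid,
             speed_tail = sp$tail, nematic_S = nematic_order(track),
             shape_lambda = shape_factor(track), axis_ratio = ar,
             head_proj = va$head_proj, tail_proj = va$tail_proj,
             head_cos = va$head_cos, tail_cos = va$tail_cos,
             scaled_length = midline_length(track) / bl)
}

#' Stack features over a 7-step window
#'
#' Concatenates every feature over the examined timestep and the three
#' timesteps before and after it, yielding one vector per timestep. At the
#' track edges the boundary timestep is replicated so every timestep has a
#' full window.
#'
#' @param features Data frame or matrix of per-timestep features on a
#'   regular grid (rows = timesteps).
#' @param half_window Steps on each side (default 3, i.e. a 7-step window).
#' @return Matrix with \code{nrow(features)} rows and
#'   \code{ncol(features) * (2 * half_window + 1)} columns.
#' @export
feature_window <- function(features, half_window = 3) {
  X <- as.matrix(features)
  n <- nrow(X)
  win <- 2 * half_window + 1
  if (n < win) stop("track too short for windowing: ", n, " < ", win, " steps")
  offs <- (-half_window):half_window
  blocks <- lapply(offs, function(o) {
    idx <- pmin(pmax(seq_len(n) + o, 1), n)  # edge replication
    X[idx, , drop = FALSE]
  })
  out <- do.call(cbind, blocks)
  colnames(out) <- as.vector(vapply(offs, function(o) {
    paste0(colnames(X), "_t", ifelse(o >= 0, "+", ""), o)
  }, character(ncol(X))))
  out
}
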