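# tie-break priority for ensemble votes: rarer classes win ties, in the
# spirit of the balanced-weight training
.vote_priority <- c("hunch", "back_up", "stop", "static_bend", "head_cast",
                    "small", "crawl")

#' Train the frame-level action classifier ensemble
#'
#' Trains ten random forests, each on a bootstrap resample of the training
#' split, with class weights inversely proportional to class frequency
#' (balanced weights). A stratified held-out split measures per-class
#' accuracy of the majority vote; the published acceptance bar is at least
#' 80\% per class. Deterministic given the seed.
#'
#' @param windows Matrix of windowed feature vectors (see
#'   [feature_window()]), one row per timestep.
#' @param labels Action label per row.
#' @param seed Integer seed.
#' @param n_members Ensemble size.
#' @param holdout_frac Fraction of rows held out for accuracy estimation.
#' @param num_trees Trees per forest member.
#' @return Object of class \code{classifier_bundle}: \code{members} (ranger
#'   fits), \code{classes}, \code{feature_names}, \code{class_accuracy}
#'   (held-out, per class), \code{seed}, \code{fingerprint} of the training
#'   fixture.
#' @export
train_frame_classifier <- function(windows, labels, seed = 1, n_members = 10,
                                   holdout_frac = 0.3, num_trees = 100) {
  X <- as.matrix(windows)
  labels <- as.character(labels)
  if (nrow(X) != length(labels)) stop("windows and labels must align")
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("training data must contain at least 2 classes")
  dup <- duplicated(X) | duplicated(X, fromLast = TRUE)
  if (any(dup)) {
    key <- apply(X[dup, , drop = FALSE], 1, paste, collapse = "\r")
    conflicting <- tapply(labels[dup], key, function(l) length(unique(l)) > 1)
    if (any(conflicting))
      warning("degenerate training data: identical feature rows carry ",
              "different labels")
  }
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  # stratified holdout
  hold <- unlist(lapply(classes, function(cl) {
    idx <- which(labels == cl)
    sample(idx, max(1, round(length(idx) * holdout_frac)))
  }))
  train_idx <- setdiff(seq_len(nrow(X)), hold)
  freq <- table(factor(labels[train_idx], levels = classes))
  if (any(freq == 0)) stop("a class vanished from the training split; ",
                           "provide more rows per class")
  wts <- as.numeric(1 / freq); names(wts) <- classes
  df_train <- data.frame(.label = factor(labels[train_idx], levels = classes),
                         X[train_idx, , drop = FALSE], check.names = FALSE)
  members <- lapply(seq_len(n_members), function(m) {
    boot <- sample(nrow(df_train), nrow(df_train), replace = TRUE)
    ranger::ranger(dependent.variable.name = ".label",
                   data = df_train[boot, , drop = FALSE],
                   num.trees = num_trees, class.weights = wts,
                   seed = seed * 1000L + m, num.threads = 1)
  })
  bundle <- structure(list(members = members, classes = classes,
                           feature_names = colnames(X),
                           seed = seed, n_members = n_members,
                           fingerprint = sprintf("%dx%d|%.6g",
                                                 nrow(X), ncol(X), sum(X))),
                      class = "classifier_bundle")
  pred <- .vote(bundle, X[hold, , drop = FALSE])
  truth <- labels[hold]
  bundle$class_accuracy <- vapply(classes, function(cl)
    mean(pred[truth == cl] == cl), numeric(1))
  bundle
}

.vote <- function(bundle, X) {
  df <- data.frame(X, check.names = FALSE)
  votes <- vapply(bundle$members, function(m)
    as.character(stats::predict(m, data = df, num.threads = 1)$predictions),
    character(nrow(X)))
  if (nrow(X) == 1) votes <- matrix(votes, nrow = 1)
  apply(votes, 1, function(v) {
    tab <- table(v)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1) top
    else top[order(match(top, .vote_priority))][1]
  })
}

#' @export
print.classifier_bundle <- function(x, ...) {
  cat("classifier_bundle:", x$n_members, "forests,",
      length(x$feature_names), "features, classes:",
      paste(x$classes, collapse = ", "), "\n")
  if (!is.null(x$class_accuracy)) {
    cat("held-out per-class accuracy:\n")
    print(round(x$class_accuracy, 3))
  }
  invisible(x)
}

#' Classify frames with a trained ensemble
#'
#' Per-timestep majority vote across the ensemble members; ties are broken
#' by a fixed class priority in which rarer classes win (hunch > back_up >
#' stop > static_bend > head_cast > small > crawl).
#'
#' @param bundle A [train_frame_classifier()] bundle.
#' @param windows Feature-window matrix with the same layout the bundle was
#'   trained on.
#' @param times Timestamps aligned with the rows of \code{windows}.
#' @param stimulus_onset Stimulus onset (s) recorded in the output sequence.
#' @return A raw [action_seq()].
#' @export
classify_frames <- function(bundle, windows, times, stimulus_onset = 60) {
  X <- as.matrix(windows)
  if (!identical(colnames(X), bundle$feature_names))
    stop("feature layout mismatch: windows do not match the training layout")
  if (nrow(X) != length(times)) stop("times must align with windows")
  action_seq(times, .vote(bundle, X), stimulus_onset)
}
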