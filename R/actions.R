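#' Action vocabulary
#'
#' Mutually exclusive actions a larva can perform at each timestep, plus the
#' \code{"small"} catch-all for movements too weak to qualify.
#'
#' @return Character vector of the 7 action labels.
#' @export
action_levels <- function() {
  c("crawl", "head_cast", "static_bend", "hunch", "stop", "back_up", "small")
}

#' Construct a per-timestep action sequence
#'
#' @param times Regular (10 Hz) timestamps (s).
#' @param labels Character vector of actions, one per timestep, drawn from
#'   [action_levels()].
#' @param stimulus_onset Stimulus onset time (s).
#' @param provenance Per-timestep provenance, \code{"raw"},
#'   \code{"reassigned"} or \code{"expanded"}.
#' @return Object of class \code{action_seq}.
#' @export
action_seq <- function(times, labels, stimulus_onset = 60,
                       provenance = rep("raw", length(labels))) {
  labels <- as.character(labels)
  if (length(times) != length(labels))
    stop("times and labels must have equal length")
  bad <- setdiff(unique(labels), action_levels())
  if (length(bad)) stop("unknown action label(s): ", paste(bad, collapse = ", "))
  structure(list(times = as.numeric(times), labels = labels,
                 stimulus_onset = stimulus_onset, provenance = provenance),
            class = "action_seq")
}

#' Intervals of an action sequence
#'
#' Run-length encodes the per-timestep labels into a (label, start, end)
#' interval table; each interval's provenance is that of its first timestep.
#'
#' @param seq An [action_seq()].
#' @return Data frame: \code{label}, \code{start}, \code{end} (s),
#'   \code{n_steps}, \code{provenance}.
#' @export
as_intervals <- function(seq) {
  r <- rle(seq$labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(label = r$values,
             start = seq$times[starts], end = seq$times[ends],
             n_steps = r$lengths,
             provenance = seq$provenance[starts])
}

#' @export
print.action_seq <- function(x, ...) {
  tab <- table(factor(x$labels, levels = action_levels()))
  cat("action_seq:", length(x$labels), "timesteps;",
      paste(sprintf("%s=%d", names(tab)[tab > 0], tab[tab > 0]), collapse = " "),
      "\n")
  invisible(x)
}

#' Regularise biologically unrealistic short actions
#'
#' Actions lasting fewer than 3 timesteps (0.3 s at 10 Hz) are unrealistic.
#' Two-step intervals are treated preventively: the behaviour is expanded by
#' five timesteps before and after, overwriting its neighbours. Remaining
#' intervals shorter than 3 steps are reassigned to a flanking behaviour
#' using the surrounding context (intervals N-2 and N+2): if both flanking
#' behaviours agree the short interval adopts their label, otherwise it
#' joins the longer neighbour. The result is idempotent: regularising an
#' already regular sequence leaves it unchanged.
#'
#' @param seq An [action_seq()] on the regular 10 Hz grid.
#' @param expand_steps Steps added on each side of a two-step behaviour.
#' @param min_steps Minimum realistic interval length (timesteps).
#' @return A regularised [action_seq()] with provenance flags.
#' @export
regularize_actions <- function(seq, expand_steps = 5, min_steps = 3) {
  labels <- seq$labels
  prov <- seq$provenance
  n <- length(labels)

  # pass 1: expand exactly-two-step behaviours
  iv <- .rle_intervals(labels)
  for (k in seq_len(nrow(iv))) {
    if (iv$len[k] == 2L) {
      lo <- max(1L, iv$from[k] - expand_steps)
      hi <- min(n, iv$to[k] + expand_steps)
      labels[lo:hi] <- iv$label[k]
      prov[lo:hi] <- "expanded"
    }
  }

  # pass 2: absorb remaining short intervals into their context
  repeat {
    iv <- .rle_intervals(labels)
    expanded <- vapply(seq_len(nrow(iv)), function(k)
      any(prov[iv$from[k]:iv$to[k]] == "expanded"), TRUE)
    short <- which(iv$len < min_steps & !expanded)
    if (!length(short)) break
    k <- short[which.min(iv$len[short])]
    before <- if (k > 1) iv$label[k - 1] else NA_character_
    after <- if (k < nrow(iv)) iv$label[k + 1] else NA_character_
    target <- if (!is.na(before) && !is.na(after)) {
      if (before == after) before
      else if (iv$len[k - 1] >= iv$len[k + 1]) before else after
    } else if (!is.na(before)) before else if (!is.na(after)) after
    else break  # single-interval sequence: nothing to absorb into
    idx <- iv$from[k]:iv$to[k]
    labels[idx] <- target
    prov[idx] <- "reassigned"
  }
  action_seq(seq$times, labels, seq$stimulus_onset, prov)
}

.rle_intervals <- function(labels) {
  r <- rle(labels)
  to <- cumsum(r$lengths)
  data.frame(label = r$values, from = to - r$lengths + 1L, to = to,
             len = r$lengths)
}

#' Post-stimulus Hunch rules
#'
#' Larvae typically produce at most one Hunch, at stimulus onset. Any Hunch
#' after the first one post-stimulus is reclassified as a Head Cast. A Hunch
#' must also show a sufficient effective length change -- the drop of the
#' minimum midline length during the interval below the pre-stimulus median
#' length, as a fraction of that median -- or the interval is assigned to
#' the \code{"small"} behaviour. The threshold is line-specific, between
#' 0.3 and 0.6.
#'
#' @param seq An [action_seq()].
#' @param length_series Instantaneous midline length (mm), aligned with
#'   \code{seq$times} (see [midline_length()]).
#' @param line_threshold Effective length-change threshold; values outside
#'   [0.3, 0.6] are allowed but trigger a warning.
#' @return An [action_seq()] with the Hunch rules applied.
#' @export
apply_hunch_rules <- function(seq, length_series, line_threshold = 0.3) {
  if (length(length_series) != length(seq$labels))
    stop("length_series must align with the action sequence")
  if (line_threshold < 0.3 || line_threshold > 0.6)
    warning("line_threshold ", line_threshold,
            " outside the documented [0.3, 0.6] range")
  labels <- seq$labels
  prov <- seq$provenance
  pre <- seq$times < seq$stimulus_onset
  if (!any(pre)) stop("no pre-stimulus samples to compute a baseline length")
  baseline <- stats::median(length_series[pre])
  iv <- .rle_intervals(labels)
  hunches <- which(iv$label == "hunch" & seq$times[iv$from] >= seq$stimulus_onset)
  if (length(hunches) > 1) {
    for (k in hunches[-1]) {  # only the first post-stimulus Hunch survives
      idx <- iv$from[k]:iv$to[k]
      labels[idx] <- "head_cast"
      prov[idx] <- "reassigned"
    }
    iv <- .rle_intervals(labels)
    hunches <- which(iv$label == "hunch" & seq$times[iv$from] >= seq$stimulus_onset)
  }
  for (k in which(iv$label == "hunch")) {
    idx <- iv$from[k]:iv$to[k]
    eff_change <- (baseline - min(length_series[idx])) / baseline
    if (eff_change < line_threshold) {
      labels[idx] <- "small"
      prov[idx] <- "reassigned"
    }
  }
  action_seq(seq$times, labels, seq$stimulus_onset, prov)
}

#' Split bends into Static Bends and Head Casts
#'
#' A bend interval spanning n timesteps is a Static Bend when the scaled
#' motion (centroid) speed stays, for at least a fraction P of those
#' timesteps (boundary inclusive), below p times the larva's mean head
#' speed before stimulation; otherwise it is a Head Cast. P and p are
#' line-specific thresholds.
#'
#' @param seq An [action_seq()] whose bend intervals carry the labels
#'   \code{"head_cast"} or \code{"static_bend"}.
#' @param head_speeds,motion_speeds Scaled head and centroid speeds (BL/s)
#'   aligned with \code{seq$times}.
#' @param P Fraction of qualifying timesteps required (default 0.75).
#' @param p Multiplier on the pre-stimulus mean head speed (default 0.5).
#' @return An [action_seq()] with every bend relabelled.
#' @export
split_bend_types <- function(seq, head_speeds, motion_speeds, P = 0.75, p = 0.5) {
  if (length(head_speeds) != length(seq$labels) ||
      length(motion_speeds) != length(seq$labels))
    stop("speed series must align with the action sequence")
  pre <- seq$times < seq$stimulus_onset
  if (!any(pre)) stop("no pre-stimulus samples to compute the baseline head speed")
  baseline_head <- mean(head_speeds[pre])
  labels <- seq$labels
  prov <- seq$provenance
  iv <- .rle_intervals(labels)
  for (k in which(iv$label %in% c("head_cast", "static_bend"))) {
    idx <- iv$from[k]:iv$to[k]
    frac_slow <- mean(motion_speeds[idx] < p * baseline_head)
    new <- if (frac_slow >= P) "static_bend" else "head_cast"
    if (new != iv$label[k]) prov[idx] <- "reassigned"
    labels[idx] <- new
  }
  action_seq(seq$times, labels, seq$stimulus_onset, prov)
}
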