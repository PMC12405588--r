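#' Write tracks to the delimited track-table format
#'
#' Long-form tab-separated text, one row per raw sample, columns
#' \code{larva_id, t, x1..x11, y1..y11} (units s and mm), with a JSON
#' sidecar (same path plus \code{.json}) holding the stimulus onset and
#' duration.
#'
#' @param tracks List of [spine_track()] objects.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    df <- data.frame(larva_id = tr$larva_id, t = tr$times)
    for (j in 1:11) df[[paste0("x", j)]] <- tr$x[, j]
    for (j in 1:11) df[[paste0("y", j)]] <- tr$y[, j]
    df
  })
  tab <- do.call(rbind, rows)
  utils::write.table(format(tab, digits = 12, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(stimulus_onset = tracks[[1]]$stimulus_onset,
               stimulus_duration = tracks[[1]]$stimulus_duration)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read tracks from the delimited track-table format
#'
#' Parses the format written by [write_tracks()]. Malformed rows are
#' rejected with their line numbers; times must be strictly increasing
#' within each larva.
#'
#' @param path Input file path; an accompanying \code{<path>.json} sidecar,
#'   when present, supplies the stimulus metadata.
#' @return List of [spine_track()] objects (possibly empty, with a
#'   warning).
#' @export
read_tracks <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  needed <- c("larva_id", "t", paste0("x", 1:11), paste0("y", 1:11))
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(tab) == 0) {
    warning("empty track table: ", path)
    return(list())
  }
  meta_path <- paste0(path, ".json")
  onset <- 60; dur <- 30
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    if (!is.null(meta$stimulus_onset)) onset <- meta$stimulus_onset
    if (!is.null(meta$stimulus_duration)) dur <- meta$stimulus_duration
  }
  num <- tab[, setdiff(needed, "larva_id")]
  bad <- which(!stats::complete.cases(num) |
                 apply(num, 1, function(r) any(!is.finite(r))))
  if (length(bad))
    stop("malformed row(s) at line(s): ",
         paste(utils::head(bad + 1, 10), collapse = ", "))
  lapply(split(seq_len(nrow(tab)), tab$larva_id), function(idx) {
    sub <- tab[idx, ]
    if (any(diff(sub$t) <= 0)) {
      off <- which(diff(sub$t) <= 0)[1]
      stop("non-monotone times for larva '", sub$larva_id[1],
           "' at line ", idx[off + 1] + 1)
    }
    spine_track(sub$larva_id[1], sub$t,
                as.matrix(sub[, paste0("x", 1:11)]),
                as.matrix(sub[, paste0("y", 1:11)]),
                stimulus_onset = onset, stimulus_duration = dur)
  })
}

#' Write tidy result tables plus a JSON summary
#'
#' Each named data frame becomes \code{<name>.csv} under the output
#' directory; the summary list (thresholds, p-values, and the seed of every
#' stochastic stage) is written as \code{summary.json}.
#'
#' @param tables Named list of data frames.
#' @param path Output directory (created if needed).
#' @param summary Named list of scalar results and seeds.
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(tables, path, summary = list()) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(path, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  if (length(summary)) {
    f <- file.path(path, "summary.json")
    jsonlite::write_json(summary, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, f)
  }
  invisible(files)
}

#' Read or write a run configuration
#'
#' Run configurations are plain YAML: stage parameters, windows,
#' thresholds, grids, and an explicit seed for every stochastic stage, so
#' a run can be reproduced from its emitted config.
#'
#' @param path YAML file path.
#' @param config Named list to write; omit to read.
#' @return The configuration list.
#' @export
run_config <- function(path, config = NULL) {
  if (is.null(config)) {
    yaml::read_yaml(path)
  } else {
    yaml::write_yaml(config, path)
    invisible(config)
  }
}
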