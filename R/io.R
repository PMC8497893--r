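# Plain-text persistence: recordings as CSV with a JSON sidecar, feature
# tables as CSV with canonical names, reports as JSON.

#' Write a recording to CSV + JSON sidecar
#'
#' The CSV holds `time_s`, `ecg`, `ppg`, `resp`; the sidecar
#' (`<path>.json`) holds the configuration, seed and ground-truth
#' annotations.
#'
#' @param recording A `ppg_recording`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  n <- length(recording$ppg)
  df <- data.frame(time_s = (seq_len(n) - 1) / recording$fs,
                   ecg = recording$ecg, ppg = recording$ppg,
                   resp = recording$resp)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(fs = recording$fs, duration_s = recording$duration_s,
               seed = recording$seed,
               config = unclass(recording$config),
               truth = if (!is.null(recording$truth)) list(
                 state = recording$truth$state,
                 r_times = recording$truth$r_times,
                 onset_times = recording$truth$onset_times,
                 fiducials = recording$truth$fiducials))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path CSV file path (sidecar expected at `<path>.json`).
#' @return A `ppg_recording` (configuration restored; truth restored when
#'   present in the sidecar).
#' @export
read_recording <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- side$config
  cfg$beat_shape <- lapply(cfg$beat_shape, as.numeric)
  config <- do.call(sim_config, cfg)
  truth <- if (!is.null(side$truth)) {
    list(state = side$truth$state, r_times = side$truth$r_times,
         onset_times = side$truth$onset_times,
         fiducials = as.data.frame(side$truth$fiducials))
  }
  structure(list(ecg = df$ecg, ppg = df$ppg, resp = df$resp,
                 fs = side$fs, duration_s = side$duration_s,
                 config = config, seed = side$seed, truth = truth),
            class = "ppg_recording")
}

#' Write a cohort feature table to CSV
#'
#' One row per recording: `subject_id`, `state`, then `f001` ... `f110`.
#' A comment header maps the positional codes to the canonical feature
#' names, so the file round-trips losslessly through
#' [read_feature_table()].
#'
#' @param table Data frame with `subject_id`, `state` and the 110 feature
#'   columns (canonical names).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  nm <- ppg_feature_names()
  stopifnot(all(nm %in% names(table)))
  codes <- sprintf("f%03d", seq_along(nm))
  out <- table[, c("subject_id", "state", nm)]
  names(out) <- c("subject_id", "state", codes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", codes, " = ", nm), con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return Data frame with `subject_id`, `state` and canonical feature
#'   columns.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  codes <- sprintf("f%03d", seq_along(ppg_feature_names()))
  stopifnot(all(codes %in% names(df)))
  names(df)[match(codes, names(df))] <- ppg_feature_names()
  df
}
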