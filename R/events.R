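#' Event list: scored or detected arousal events
#'
#' A plain data frame with one row per event and columns `onset_s`,
#' `duration_s`, `rater_id`, `emg_associated` (logical, may be `NA` for human
#' scores that do not carry the flag). Onsets and durations are in seconds,
#' 0-based, half-open intervals `[onset, onset + duration)`. Detector output
#' additionally carries `bands` (comma-joined triggering bands) and `stage`.
#'
#' @param onset_s numeric onsets (s), >= 0.
#' @param duration_s numeric durations (s), > 0.
#' @param rater_id character rater identifier (recycled).
#' @param emg_associated logical flag (recycled; default `NA`).
#' @param ... further columns (e.g. `bands`, `stage`), recycled.
#' @return a `data.frame` of class `event_list`, sorted by onset.
#' @export
#' @examples
#' event_list(c(10, 100), c(5, 3), rater_id = "HR1")
event_list <- function(onset_s = numeric(), duration_s = numeric(),
                       rater_id = "unknown", emg_associated = NA, ...) {
  n <- length(onset_s)
  df <- data.frame(onset_s = as.numeric(onset_s),
                   duration_s = as.numeric(duration_s),
                   rater_id = rep_len(as.character(rater_id), n),
                   emg_associated = rep_len(as.logical(emg_associated), n),
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
  if (nrow(df)) {
    if (any(df$onset_s < 0)) stop("event onsets must be >= 0")
    if (any(df$duration_s <= 0)) stop("event durations must be > 0")
    df <- df[order(df$onset_s), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("event_list", "data.frame")
  df
}

#' Write an event list to CSV
#'
#' Column order is fixed (`onset_s,duration_s,rater_id,emg_associated`, then
#' any extra columns) so files round-trip identically through
#' [read_events()].
#'
#' @param events an [event_list()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  core <- c("onset_s", "duration_s", "rater_id", "emg_associated")
  stopifnot(all(core %in% names(events)))
  df <- as.data.frame(events)[, c(core, setdiff(names(events), core)),
                              drop = FALSE]
  # character fields are quoted: the detector's `bands` column can hold
  # comma-joined band sets
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an event list from CSV
#'
#' @param path CSV written by [write_events()] (or any CSV with the same
#'   header).
#' @return an [event_list()].
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset_s", "duration_s", "rater_id", "emg_associated")
  if (!all(need %in% names(df)))
    stop("event CSV needs columns ", paste(need, collapse = ","))
  df$emg_associated <- as.logical(df$emg_associated)
  extra <- df[, setdiff(names(df), need), drop = FALSE]
  do.call(event_list, c(as.list(df[, need, drop = FALSE]), as.list(extra)))
}
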