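#' Multichannel polysomnography recording
#'
#' The in-memory signal container used throughout the pipeline: a samples x
#' channels numeric matrix in microvolts, one common sampling rate, and a role
#' (EEG / EOG / EMG) per channel. EMG is carried as the two referenced
#' channels of the bipolar submental pair; the composite EMG trace is derived
#' later by [build_composite_emg()].
#'
#' @param signals numeric matrix, samples in rows, channels in columns, µV.
#' @param fs sampling rate in Hz (positive; integer-valued for EDF export).
#' @param labels character channel names, unique, one per column.
#' @param roles character, one of `"EEG"`, `"EOG"`, `"EMG"` per channel.
#' @param reference free-text montage note (e.g. "linked mastoids").
#' @return an object of class `psg_recording`.
#' @export
#' @examples
#' x <- matrix(rnorm(128 * 60 * 2), ncol = 2)
#' rec <- recording(x, fs = 128, labels = c("C3", "C4"),
#'                  roles = c("EEG", "EEG"))
#' n_seconds(rec)
recording <- function(signals, fs, labels, roles, reference = "linked mastoids") {
  signals <- as.matrix(signals)
  storage.mode(signals) <- "double"
  if (length(fs) != 1 || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  if (ncol(signals) != length(labels) || length(labels) != length(roles))
    stop("labels and roles must have one entry per signal column")
  if (anyDuplicated(labels))
    stop("channel labels must be unique")
  roles <- match.arg(roles, c("EEG", "EOG", "EMG"), several.ok = TRUE)
  if (sum(roles == "EEG") < 1)
    stop("at least one EEG channel is required")
  n_emg <- sum(roles == "EMG")
  if (!n_emg %in% c(0L, 2L))
    stop("EMG must be absent or a bipolar pair (2 referenced channels), got ",
         n_emg)
  colnames(signals) <- labels
  structure(
    list(signals = signals, fs = fs, labels = as.character(labels),
         roles = roles, reference = reference),
    class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  cat(sprintf("<psg_recording> %d channels, fs = %g Hz, %.1f s (%s)\n",
              ncol(x$signals), x$fs, nrow(x$signals) / x$fs, x$reference))
  cat(paste0("  ", x$labels, " [", x$roles, "]", collapse = "\n"), "\n")
  invisible(x)
}

#' Duration of a recording in whole seconds
#' @param rec a `psg_recording`.
#' @return integer count of whole seconds (`floor(samples / fs)`).
#' @export
n_seconds <- function(rec) as.integer(floor(nrow(rec$signals) / rec$fs))

#' Channel indices for a role
#' @param rec a `psg_recording`.
#' @param role `"EEG"`, `"EOG"` or `"EMG"`.
#' @return integer column indices.
#' @export
channels_of <- function(rec, role) which(rec$roles == role)
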