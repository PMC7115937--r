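#' Band-pass filter a recording by channel role
#'
#' Each modality gets its own order-3 Butterworth band-pass: EEG 0.5–30 Hz,
#' EOG 0.1–5 Hz, EMG 10–100 Hz by default. Filtering is zero-phase
#' (forward–backward) so event onsets are not delayed; the effective roll-off
#' is then twice the single-pass slope. A low-pass edge at or above Nyquist
#' (e.g. the EMG 100 Hz edge on 128 Hz data) is clipped to `0.9 * fs/2` with
#' a warning.
#'
#' @param rec a [recording()].
#' @param cfg an [arousal_config()]; uses `filter_order`, `filter_edges`,
#'   `zero_phase`.
#' @return the filtered recording.
#' @export
apply_filters <- function(rec, cfg = arousal_config()) {
  stopifnot(inherits(rec, "psg_recording"))
  fs <- rec$fs
  nyq <- fs / 2
  n <- nrow(rec$signals)
  out <- rec$signals
  for (role in unique(rec$roles)) {
    edges <- cfg$filter_edges[[role]]
    if (is.null(edges)) stop("no filter edges configured for role ", role)
    if (edges[1] >= nyq)
      stop("high-pass edge ", edges[1], " Hz not below Nyquist (", nyq, " Hz)")
    if (edges[2] >= nyq) {
      warning(sprintf("%s low-pass edge %g Hz >= Nyquist; clipped to %g Hz",
                      role, edges[2], 0.9 * nyq))
      edges[2] <- 0.9 * nyq
    }
    if (edges[1] >= edges[2]) stop("degenerate band for role ", role)
    # three time-constants of the slowest (high-pass) corner must fit
    if (n < 3 * fs / edges[1])
      stop("recording too short for the ", role, " high-pass corner to settle")
    bt <- signal::butter(cfg$filter_order, edges / nyq, type = "pass")
    for (ch in which(rec$roles == role)) {
      out[, ch] <- if (isTRUE(cfg$zero_phase)) {
        signal::filtfilt(bt, rec$signals[, ch])
      } else {
        as.numeric(signal::filter(bt, rec$signals[, ch]))
      }
    }
  }
  rec$signals <- out
  rec
}

#' Build the 30 s scoring-window / 1 s epoch grid
#'
#' The grid is the universal time coordinate of the detector: the recording
#' is cut into whole 1 s epochs (remainder samples beyond the last whole
#' second are excluded), grouped into 30 s scoring windows. A final partial
#' window (< 30 epochs) is retained and flagged.
#'
#' @param rec a [recording()].
#' @return an `epoch_grid` with fields `fs`, `n_epochs`, `n_windows`,
#'   `epochs_per_window` (30), `window_of` (1-based window index per epoch),
#'   `partial_last` (logical).
#' @export
build_grid <- function(rec) {
  n_sec <- n_seconds(rec)
  if (n_sec < 30) stop("recording must be at least 30 s long")
  n_win <- ceiling(n_sec / 30)
  structure(list(
    fs = rec$fs,
    n_epochs = n_sec,
    n_windows = n_win,
    epochs_per_window = 30L,
    window_of = (seq_len(n_sec) - 1L) %/% 30L + 1L,
    partial_last = (n_sec %% 30L) != 0L
  ), class = "epoch_grid")
}

#' @export
print.epoch_grid <- function(x, ...) {
  cat(sprintf("<epoch_grid> %d x 1 s epochs in %d x 30 s windows%s, fs = %g Hz\n",
              x$n_epochs, x$n_windows,
              if (x$partial_last) " (last partial)" else "", x$fs))
  invisible(x)
}

#' Epochs belonging to a scoring window
#' @param grid an `epoch_grid`.
#' @param w 1-based window index.
#' @return integer vector of 1-based epoch indices.
#' @export
window_epochs <- function(grid, w) {
  stopifnot(w >= 1, w <= grid$n_windows)
  which(grid$window_of == w)
}

#' Sample range of a 1 s epoch
#' @param grid an `epoch_grid`.
#' @param epoch 1-based epoch index (second `epoch - 1`).
#' @return integer vector of sample indices `[ (epoch-1)*fs + 1, epoch*fs ]`.
#' @export
epoch_samples <- function(grid, epoch) {
  stopifnot(epoch >= 1, epoch <= grid$n_epochs)
  ((epoch - 1L) * grid$fs + 1L):(epoch * grid$fs)
}

#' Remove each channel's whole-recording mean
#'
#' @param rec a [recording()].
#' @return the mean-corrected recording (each channel has mean 0).
#' @export
mean_correct <- function(rec) {
  stopifnot(inherits(rec, "psg_recording"))
  rec$signals <- sweep(rec$signals, 2, colMeans(rec$signals))
  rec
}
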