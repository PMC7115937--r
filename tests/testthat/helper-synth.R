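# Shared fixtures, all built in code at test time.

quiet_detect <- function(...) suppressWarnings(suppressMessages(detect(...)))

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# a minimal recording: named channels filled with given columns
make_rec <- function(..., fs = 128, roles = NULL) {
  cols <- list(...)
  sig <- do.call(cbind, cols)
  if (is.null(roles)) roles <- rep("EEG", ncol(sig))
  recording(sig, fs = fs, labels = names(cols), roles = roles)
}

# composite-EMG stand-in built directly from a signal
make_emg <- function(signal, grid, provenance = NULL) {
  if (is.null(provenance)) provenance <- rep("both", grid$n_windows)
  structure(list(signal = signal[seq_len(grid$n_epochs * grid$fs)],
                 provenance = provenance,
                 epoch_usable = provenance[grid$window_of] != "none"),
            class = "composite_emg")
}

# band-power table built from an aggregated epoch x band matrix
make_bp <- function(power) {
  structure(list(power = power,
                 per_channel = array(power, c(dim(power), 1),
                                     dimnames = list(NULL, colnames(power),
                                                     "CH1")),
                 bands = arousal_config()$bands),
            class = "band_power_table")
}

# all-good bad-channel mask for a recording/grid
good_mask <- function(rec, grid) {
  eeg <- which(rec$roles == "EEG")
  structure(list(global_bad = character(),
                 window_bad = matrix(FALSE, length(eeg), grid$n_windows,
                                     dimnames = list(rec$labels[eeg], NULL))),
            class = "bad_channel_mask")
}
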