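# Bad-channel screening and composite EMG reconstruction.

window_sample_idx <- function(grid, w) {
  ep <- window_epochs(grid, w)
  ((ep[1] - 1L) * grid$fs + 1L):(ep[length(ep)] * grid$fs)
}

#' Globally bad EEG channels
#'
#' Flat or saturated channels are flagged over the whole recording: an EEG
#' channel whose signal standard deviation is below 1 µV (flat) or above
#' 6e3 µV (noisy) is excluded from all further processing.
#'
#' @param rec a filtered [recording()].
#' @param cfg an [arousal_config()] (`sd_flat`, `sd_noisy`).
#' @return character vector of bad EEG channel labels.
#' @export
detect_bad_eeg_global <- function(rec, cfg = arousal_config()) {
  eeg <- channels_of(rec, "EEG")
  sds <- apply(rec$signals[, eeg, drop = FALSE], 2, stats::sd)
  bad <- rec$labels[eeg][sds < cfg$sd_flat | sds > cfg$sd_noisy]
  if (length(bad) == length(eeg))
    stop("all EEG channels are globally bad; detection cannot proceed")
  bad
}

#' Per-window bad EEG channels
#'
#' Over each 30 s scoring window, each (globally good) EEG channel's SD is
#' compared to the median SD of the other good channels; a deviating ratio
#' above `bad_ratio` (default 5) — or below its reciprocal when the
#' two-sided rule is on — marks the channel bad in that window. With a
#' single good channel left no per-window test is possible and none is
#' flagged.
#'
#' @param rec a filtered [recording()].
#' @param grid the [build_grid()] of `rec`.
#' @param global_bad labels from [detect_bad_eeg_global()].
#' @param cfg an [arousal_config()].
#' @return a `bad_channel_mask`: list with `global_bad` (labels) and
#'   `window_bad`, a logical matrix (EEG channel x window; globally bad
#'   channels are bad in every window).
#' @export
detect_bad_eeg_windows <- function(rec, grid, global_bad = character(),
                                   cfg = arousal_config()) {
  eeg <- channels_of(rec, "EEG")
  labs <- rec$labels[eeg]
  wb <- matrix(FALSE, length(eeg), grid$n_windows,
               dimnames = list(labs, NULL))
  wb[labs %in% global_bad, ] <- TRUE
  good <- which(!labs %in% global_bad)
  if (length(good) >= 2) {
    for (w in seq_len(grid$n_windows)) {
      smp <- window_sample_idx(grid, w)
      sds <- apply(rec$signals[smp, eeg[good], drop = FALSE], 2, stats::sd)
      for (i in seq_along(good)) {
        centre <- stats::median(sds[-i])
        if (centre == 0) next
        ratio <- sds[i] / centre
        if (ratio > cfg$bad_ratio ||
            (isTRUE(cfg$bad_ratio_two_sided) && ratio < 1 / cfg$bad_ratio))
          wb[good[i], w] <- TRUE
      }
    }
  } else {
    message("only one good EEG channel; per-window SD-ratio test skipped")
  }
  structure(list(global_bad = global_bad, window_bad = wb),
            class = "bad_channel_mask")
}

#' Reconstruct a composite submental EMG channel
#'
#' The bipolar EMG pair is screened per 30 s scoring window: (a) a referenced
#' channel whose median absolute amplitude is below 0.1 µV is flat; (b) if
#' neither is flat, a channel whose window median absolute amplitude is at
#' least twice the other's is candidate noisy; (c) a candidate is confirmed
#' window-noisy when the per-1 s-epoch ratio of the two channels' mean
#' absolute amplitudes exceeds 2 in more than half of the window's epochs
#' (> 15 of 30). The composite is the bipolar difference where both channels
#' are clean, the single surviving referenced channel where one is excluded,
#' and masked (`NA`) where neither is usable.
#'
#' @param rec a filtered [recording()] with an EMG pair.
#' @param grid the [build_grid()] of `rec`.
#' @param cfg an [arousal_config()].
#' @return a `composite_emg`: list with `signal` (µV, `grid$n_epochs * fs`
#'   samples, `NA` where unusable), `provenance` (per window: `"both"`,
#'   `"emg1-only"`, `"emg2-only"`, `"none"`) and `epoch_usable` (logical per
#'   1 s epoch).
#' @export
build_composite_emg <- function(rec, grid, cfg = arousal_config()) {
  emg <- channels_of(rec, "EMG")
  if (length(emg) != 2)
    stop("composite EMG needs exactly 2 referenced EMG channels, got ",
         length(emg))
  e1 <- rec$signals[, emg[1]]
  e2 <- rec$signals[, emg[2]]
  n_smp <- grid$n_epochs * grid$fs
  sig <- rep(NA_real_, n_smp)
  prov <- character(grid$n_windows)

  for (w in seq_len(grid$n_windows)) {
    smp <- window_sample_idx(grid, w)
    ep <- window_epochs(grid, w)
    m1 <- stats::median(abs(e1[smp]))
    m2 <- stats::median(abs(e2[smp]))
    flat1 <- m1 < cfg$emg_flat_median
    flat2 <- m2 < cfg$emg_flat_median
    use <- if (flat1 && flat2) {
      "none"
    } else if (flat1) {
      "emg2-only"
    } else if (flat2) {
      "emg1-only"
    } else {
      cand <- if (m1 >= cfg$emg_noisy_ratio * m2) 1L
              else if (m2 >= cfg$emg_noisy_ratio * m1) 2L else 0L
      if (cand == 0L) {
        "both"
      } else {
        a1 <- vapply(ep, function(e) mean(abs(e1[epoch_samples(grid, e)])), 0)
        a2 <- vapply(ep, function(e) mean(abs(e2[epoch_samples(grid, e)])), 0)
        ratio <- if (cand == 1L) a1 / a2 else a2 / a1
        n_noisy <- sum(ratio > cfg$emg_noisy_ratio, na.rm = TRUE)
        quota <- cfg$emg_noisy_quota * length(ep) / 30
        if (n_noisy > quota) {
          if (cand == 1L) "emg2-only" else "emg1-only"
        } else {
          "both"
        }
      }
    }
    prov[w] <- use
    sig[smp] <- switch(use,
                       both = e1[smp] - e2[smp],
                       `emg1-only` = e1[smp],
                       `emg2-only` = e2[smp],
                       none = NA_real_)
  }
  if (any(prov == "none"))
    message(sum(prov == "none"),
            " window(s) without usable EMG; EMG features masked there")
  structure(list(signal = sig, provenance = prov,
                 epoch_usable = prov[grid$window_of] != "none"),
            class = "composite_emg")
}
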