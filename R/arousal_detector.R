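# Assembly of per-epoch shift masks into arousal events, and the end-to-end
# detection pipeline.

runs_of <- function(x) {
  # maximal runs of TRUE: data.frame(start, length), 1-based epoch indices
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[keep], length = r$lengths[keep])
}

#' Assemble shift masks into arousal events
#'
#' The per-epoch trigger is any theta/alpha/beta EEG shift that is not a
#' spindle (sigma) epoch; maximal runs of at least `min_duration_s` (3)
#' consecutive triggered epochs become candidate events. Spindle exclusion is
#' applied before run-finding, so a sigma epoch inside a run can split it. An
#' event is EMG-associated when an EMG shift overlaps it or falls within
#' `emg_concomitance_s` (1 s) of its boundaries. Events whose onset lies in a
#' REM-staged window are retained only when EMG-associated; events with onset
#' in wake are dropped.
#'
#' @param masks a `shift_masks` object.
#' @param hyp a [hypnogram()] (shorter hypnograms: unstaged tail counts as
#'   wake).
#' @param grid the epoch grid the masks were computed on.
#' @param cfg an [arousal_config()].
#' @return an [event_list()] with `rater_id = "AD"` and extra columns
#'   `bands` (comma-joined triggering bands) and `stage`.
#' @export
assemble_events <- function(masks, hyp, grid, cfg = arousal_config()) {
  n <- grid$n_epochs
  if (length(masks$spindle) != n || nrow(masks$eeg_shift) != n)
    stop("shift masks and epoch grid have different lengths")
  eeg_any <- masks$eeg_shift[, "theta"] | masks$eeg_shift[, "alpha"] |
    masks$eeg_shift[, "beta"]

  if (isTRUE(cfg$same_band_runs)) {
    ev <- NULL
    for (b in c("theta", "alpha", "beta")) {
      trig <- masks$eeg_shift[, b] & !masks$spindle
      r <- runs_of(trig)
      r <- r[r$length >= cfg$min_duration_s, , drop = FALSE]
      ev <- rbind(ev, r)
    }
    # merge overlapping per-band runs into maximal events
    if (!is.null(ev) && nrow(ev)) {
      cover <- rep(FALSE, n)
      for (i in seq_len(nrow(ev)))
        cover[ev$start[i]:(ev$start[i] + ev$length[i] - 1L)] <- TRUE
      runs <- runs_of(cover)
    } else {
      runs <- data.frame(start = integer(), length = integer())
    }
  } else {
    trig <- eeg_any & !masks$spindle
    runs <- runs_of(trig)
    runs <- runs[runs$length >= cfg$min_duration_s, , drop = FALSE]
  }
  if (!nrow(runs))
    return(event_list(rater_id = character(), bands = character(),
                      stage = character()))

  slack <- cfg$emg_concomitance_s
  onset <- runs$start - 1L                    # 0-based seconds
  dur <- runs$length
  emg_assoc <- logical(nrow(runs))
  band_lab <- character(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    ep <- runs$start[i]:(runs$start[i] + dur[i] - 1L)
    near <- max(1L, runs$start[i] - slack):min(n, runs$start[i] + dur[i] - 1L + slack)
    emg_assoc[i] <- any(masks$emg_shift[near])
    bset <- c("theta", "alpha", "beta")[
      vapply(c("theta", "alpha", "beta"),
             function(b) any(masks$eeg_shift[ep, b]), TRUE)]
    band_lab[i] <- paste(bset, collapse = ",")
  }
  stage <- stage_at(hyp, onset)
  keep <- stage != "W" & !(stage == "REM" & !emg_assoc)
  ev <- event_list(onset_s = onset[keep], duration_s = dur[keep],
                   rater_id = "AD", emg_associated = emg_assoc[keep],
                   bands = band_lab[keep], stage = stage[keep])

  if (cfg$merge_gap_s > 0 && nrow(ev) > 1) {
    i <- 1
    while (i < nrow(ev)) {
      gap <- ev$onset_s[i + 1] - (ev$onset_s[i] + ev$duration_s[i])
      if (gap <= cfg$merge_gap_s) {
        ev$duration_s[i] <- ev$onset_s[i + 1] + ev$duration_s[i + 1] - ev$onset_s[i]
        ev$emg_associated[i] <- ev$emg_associated[i] || ev$emg_associated[i + 1]
        ev$bands[i] <- paste(unique(unlist(strsplit(
          c(ev$bands[i], ev$bands[i + 1]), ","))), collapse = ",")
        ev <- ev[-(i + 1), , drop = FALSE]
      } else i <- i + 1
    }
    rownames(ev) <- NULL
  }
  ev
}

#' Run the full arousal detection pipeline
#'
#' Filters the recording per modality, mean-corrects it, builds the 30 s /
#' 1 s epoch grid, screens bad EEG channels (globally and per window),
#' reconstructs the composite EMG, extracts per-epoch EMG/EEG/sigma shift
#' masks with recording-adapted thresholds, and assembles arousal events.
#' Deterministic: identical inputs give identical output.
#'
#' @param rec a raw [recording()] (µV).
#' @param hyp a [hypnogram()].
#' @param cfg an [arousal_config()].
#' @param emg_only if `TRUE`, return only EMG-associated events (the
#'   EMG-restricted detection variant).
#' @return an [event_list()] of detected arousals.
#' @export
#' @examples
#' \donttest{
#' syn <- synth_psg(synth_spec(duration_s = 600, seed = 1))
#' ev <- detect(syn$recording, syn$hypnogram)
#' }
detect <- function(rec, hyp, cfg = arousal_config(), emg_only = FALSE) {
  rec <- apply_filters(rec, cfg)
  rec <- mean_correct(rec)
  grid <- build_grid(rec)
  gb <- detect_bad_eeg_global(rec, cfg)
  mask <- detect_bad_eeg_windows(rec, grid, gb, cfg)
  emg <- if (length(channels_of(rec, "EMG")) == 2)
    build_composite_emg(rec, grid, cfg) else NULL
  masks <- shift_masks(rec, grid, mask, emg, cfg)
  ev <- assemble_events(masks, hyp, grid, cfg)
  if (emg_only) {
    ev <- ev[which(ev$emg_associated), , drop = FALSE]
    rownames(ev) <- NULL
  }
  ev
}
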