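# Per-1 s-epoch features: band power, EMG tone shifts, EEG frequency shifts,
# spindle (sigma) epochs. All thresholds are medians/ratios of the recording
# itself, so every mask is invariant to global amplitude scaling.

band_bins <- function(band, n_bins) {
  # half-open [lo, hi) on the 1 Hz periodogram grid of a 1 s epoch
  k <- seq_len(n_bins)
  k[k >= band[1] & k < band[2]]
}

#' Per-epoch band power
#'
#' For every 1 s epoch the one-sided periodogram (rectangular window) is
#' integrated over the theta (3–7 Hz), alpha (7–13 Hz), sigma (11–16 Hz) and
#' beta (16–30 Hz) bands; a 1 s epoch at an integer sampling rate gives an
#' exact 1 Hz bin grid, and bands are half-open `[lo, hi)` so shared printed
#' edges (alpha/sigma) never double-count a bin. The scaling is such that a
#' pure sinusoid of amplitude A at an in-band bin frequency contributes
#' A^2/2 (µV^2). Channel fusion is the median over EEG channels that are
#' good in the epoch's window; epochs whose window has no good channel are
#' `NA`, never 0.
#'
#' @param rec a filtered, mean-corrected [recording()].
#' @param grid the [build_grid()] of `rec`.
#' @param mask a `bad_channel_mask` from [detect_bad_eeg_windows()].
#' @param cfg an [arousal_config()].
#' @return a `band_power_table`: list with `power` (epoch x band matrix,
#'   aggregated), `per_channel` (epoch x band x channel array) and `bands`.
#' @export
band_power <- function(rec, grid, mask = NULL, cfg = arousal_config()) {
  fs <- grid$fs
  if (fs != round(fs)) stop("band power needs an integer sampling rate")
  eeg <- channels_of(rec, "EEG")
  labs <- rec$labels[eeg]
  bands <- cfg$bands
  n_ep <- grid$n_epochs
  n_bins <- floor(fs / 2) - 1L
  bins <- lapply(bands, band_bins, n_bins = n_bins)
  if (any(lengths(bins) == 0)) stop("a band contains no periodogram bin")

  pc <- array(NA_real_, c(n_ep, length(bands), length(eeg)),
              dimnames = list(NULL, names(bands), labs))
  for (j in seq_along(eeg)) {
    x <- matrix(rec$signals[seq_len(n_ep * fs), eeg[j]], nrow = fs)
    sp <- stats::mvfft(x)
    pow <- 2 * (Mod(sp)^2) / fs^2          # one-sided, bins 1..fs/2-1
    for (b in seq_along(bands))
      pc[, b, j] <- colSums(pow[bins[[b]] + 1L, , drop = FALSE])
  }
  # mask epochs where the channel is bad in that window
  if (!is.null(mask)) {
    for (j in seq_along(labs)) {
      badw <- mask$window_bad[labs[j], , drop = TRUE]
      if (any(badw)) pc[badw[grid$window_of], , j] <- NA_real_
    }
  }
  agg <- apply(pc, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else stats::median(v)
  })
  structure(list(power = agg, per_channel = pc, bands = bands),
            class = "band_power_table")
}

per_epoch_tone <- function(emg, grid) {
  m <- colMeans(matrix(abs(emg$signal), nrow = grid$fs))
  m[!emg$epoch_usable] <- NA_real_
  m
}

window_median_filter <- function(m, grid, span = 1L) {
  # per-epoch local background tone: the median of the per-epoch tone over a
  # symmetric centred 3-scoring-window span (window +/- `span`); a 3-epoch
  # median would sit on the burst itself for any >=3 s tone increase and
  # could never flag it
  med_w <- rep(NA_real_, grid$n_windows)
  for (w in seq_len(grid$n_windows)) {
    ep <- which(grid$window_of >= w - span & grid$window_of <= w + span)
    v <- m[ep]
    v <- v[!is.na(v)]
    if (length(v)) med_w[w] <- stats::median(v)
  }
  med_w[grid$window_of]
}

#' Detect EMG tone shifts
#'
#' Three cascaded tests on the per-1 s-epoch mean absolute amplitude of the
#' composite EMG: (1) global — epochs exceeding the baseline maximum tone of
#' the first 240 s are candidate peaks; (2) local — epochs exceeding
#' `emg_local_factor` times a median filter of the tone series over a
#' symmetric centred 3-scoring-window (90 s) span are candidate peaks;
#' (3) validation — a candidate is confirmed when
#' its tone exceeds `emg_valid_factor` times the median tone of the nearest
#' 10 candidate-free epochs on each side (clipped at the recording edges).
#' Contiguous confirmed epochs form one shift. Epochs without usable EMG are
#' never flagged.
#'
#' @param emg a `composite_emg` from [build_composite_emg()].
#' @param grid the epoch grid.
#' @param cfg an [arousal_config()].
#' @return logical vector, one flag per 1 s epoch.
#' @export
detect_emg_shifts <- function(emg, grid, cfg = arousal_config()) {
  m <- per_epoch_tone(emg, grid)
  n <- length(m)
  base_ep <- seq_len(min(cfg$baseline_s, n))
  baseline <- suppressWarnings(max(m[base_ep], na.rm = TRUE))
  cand1 <- if (is.finite(baseline)) !is.na(m) & m > baseline else rep(FALSE, n)
  med_loc <- window_median_filter(m, grid)
  cand2 <- !is.na(m) & !is.na(med_loc) & m > cfg$emg_local_factor * med_loc
  cand <- cand1 | cand2

  clean <- which(!cand & !is.na(m))
  confirmed <- rep(FALSE, n)
  for (i in which(cand)) {
    pos <- findInterval(i, clean)             # clean epochs at or before i
    left <- clean[seq_len(pos)]
    left <- utils::tail(left[left < i], 10)
    right <- clean[clean > i]
    right <- utils::head(right, 10)
    ref <- c(m[left], m[right])
    if (!length(ref)) next
    if (m[i] > cfg$emg_valid_factor * stats::median(ref)) confirmed[i] <- TRUE
  }
  confirmed
}

neighbour_free_epochs <- function(free, w_first, w_last, k) {
  # nearest k EMG-shift-free epochs strictly outside [w_first, w_last]
  left <- utils::tail(free[free < w_first], k)
  right <- utils::head(free[free > w_last], k)
  c(left, right)
}

#' Detect EEG frequency shifts per band
#'
#' Two data-derived thresholds per band (theta, alpha, beta). Fixed: the
#' median band power over the whole recording. Adaptive: per 30 s scoring
#' window, `adaptive_factor` (2) times the median band power over the
#' window's EMG-shift-free epochs plus the nearest `neighbour_epochs` (10)
#' EMG-shift-free epochs on each side. An epoch is flagged when its power
#' exceeds both. A window whose selection set is empty falls back to the
#' fixed threshold (logged).
#'
#' With `cfg$aggregate = "any"` the same test runs per channel on the
#' per-channel powers and a band flag is the OR across channels.
#'
#' @param bp a `band_power_table`.
#' @param emg_shift logical per-epoch EMG shift mask.
#' @param grid the epoch grid.
#' @param cfg an [arousal_config()].
#' @return logical matrix, epoch x band (theta, alpha, beta).
#' @export
detect_eeg_shifts <- function(bp, emg_shift, grid, cfg = arousal_config()) {
  bands <- intersect(c("theta", "alpha", "beta"), colnames(bp$power))
  shift_one <- function(powmat) {
    out <- matrix(FALSE, nrow(powmat), length(bands),
                  dimnames = list(NULL, bands))
    free <- which(!emg_shift & !is.na(powmat[, bands[1]]))
    for (b in bands) {
      p <- powmat[, b]
      t_fixed <- stats::median(p, na.rm = TRUE)
      if (is.na(t_fixed)) next
      a_win <- numeric(grid$n_windows)
      for (w in seq_len(grid$n_windows)) {
        ep <- window_epochs(grid, w)
        inside <- ep[!emg_shift[ep] & !is.na(p[ep])]
        sel <- c(inside,
                 neighbour_free_epochs(free, ep[1], ep[length(ep)],
                                       cfg$neighbour_epochs))
        a_win[w] <- if (length(sel)) {
          cfg$adaptive_factor * stats::median(p[sel])
        } else {
          cfg$adaptive_factor * t_fixed
        }
      }
      out[, b] <- !is.na(p) & p > t_fixed & p > a_win[grid$window_of]
    }
    out
  }
  if (identical(cfg$aggregate, "any")) {
    acc <- NULL
    for (j in seq_len(dim(bp$per_channel)[3])) {
      f <- shift_one(bp$per_channel[, , j])
      acc <- if (is.null(acc)) f else acc | f
    }
    acc
  } else {
    shift_one(bp$power)
  }
}

#' Detect spindle (sigma) epochs
#'
#' The relative sigma power of an epoch is its sigma band power divided by
#' the sum of its alpha, sigma and beta band powers. Epochs whose relative
#' sigma power exceeds `sigma_quantile` (85%) of the recording-wide maximum
#' are marked as spindle epochs and later excluded from arousal triggering.
#' Epochs with an all-zero denominator are skipped (never flagged).
#'
#' @param bp a `band_power_table` including the sigma band.
#' @param cfg an [arousal_config()].
#' @return logical vector, one flag per 1 s epoch.
#' @export
detect_spindle_epochs <- function(bp, cfg = arousal_config()) {
  p <- bp$power
  denom <- p[, "alpha"] + p[, "sigma"] + p[, "beta"]
  rel <- ifelse(!is.na(denom) & denom > 0, p[, "sigma"] / denom, NA_real_)
  if (all(is.na(rel))) return(rep(FALSE, nrow(p)))
  !is.na(rel) & rel > cfg$sigma_quantile * max(rel, na.rm = TRUE)
}

#' Compute all per-epoch shift masks
#'
#' Convenience wrapper running [band_power()], [detect_emg_shifts()],
#' [detect_eeg_shifts()] and [detect_spindle_epochs()].
#'
#' @param rec filtered, mean-corrected recording.
#' @param grid epoch grid.
#' @param mask bad-channel mask.
#' @param emg composite EMG (or `NULL` when the recording has no EMG pair;
#'   EMG shifts are then all-false).
#' @param cfg an [arousal_config()].
#' @return a `shift_masks` list: `emg_shift`, `eeg_shift` (epoch x band),
#'   `spindle`, `emg_available` (logical per epoch).
#' @export
shift_masks <- function(rec, grid, mask, emg, cfg = arousal_config()) {
  bp <- band_power(rec, grid, mask, cfg)
  if (is.null(emg)) {
    emg_shift <- rep(FALSE, grid$n_epochs)
    emg_avail <- rep(FALSE, grid$n_epochs)
  } else {
    emg_shift <- detect_emg_shifts(emg, grid, cfg)
    emg_avail <- emg$epoch_usable
  }
  structure(list(
    emg_shift = emg_shift,
    eeg_shift = detect_eeg_shifts(bp, emg_shift, grid, cfg),
    spindle = detect_spindle_epochs(bp, cfg),
    emg_available = emg_avail
  ), class = "shift_masks")
}
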