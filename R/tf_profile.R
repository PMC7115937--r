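# Morlet time-frequency characterisation of detected events.

#' Morlet wavelet power
#'
#' Complex Morlet continuous wavelet transform via FFT convolution. Wavelets
#' are L2-normalised, so stationary white noise has (in expectation) the same
#' power in every frequency bin.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param freqs centre frequencies (Hz).
#' @param cycles wavelet width in cycles (constant across frequencies).
#' @return power matrix, `length(x)` x `length(freqs)`.
#' @export
morlet_power <- function(x, fs, freqs, cycles = 7) {
  n <- length(x)
  nfft <- stats::nextn(2L * n, 2)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  out <- matrix(0, n, length(freqs))
  t_half <- (nfft %/% 2)
  tt <- c(0:(t_half - 1), -(nfft - t_half):-1) / fs
  for (k in seq_along(freqs)) {
    f <- freqs[k]
    sigma_t <- cycles / (2 * pi * f)
    w <- exp(-tt^2 / (2 * sigma_t^2)) * exp(2i * pi * f * tt)
    w <- w / sqrt(sum(Mod(w)^2))             # unit energy
    W <- stats::fft(X * Conj(stats::fft(w)), inverse = TRUE) / nfft
    out[, k] <- Mod(W[seq_len(n)])^2
  }
  out
}

aggregate_eeg <- function(rec, mask = NULL, grid = NULL) {
  eeg <- channels_of(rec, "EEG")
  labs <- rec$labels[eeg]
  sig <- rec$signals[, eeg, drop = FALSE]
  if (!is.null(mask) && length(mask$global_bad)) {
    keep <- !(labs %in% mask$global_bad)
    if (!any(keep)) stop("no good EEG channel to aggregate")
    sig <- sig[, keep, drop = FALSE]
  }
  if (ncol(sig) == 1) as.numeric(sig) else apply(sig, 1, stats::median)
}

#' Morlet time-frequency profile of an arousal event
#'
#' The first 3 s of the event (events last at least 3 s by definition) are
#' transformed on the channel-aggregated EEG with 1 Hz Morlet bins centred at
#' 0.5, 1.5, ..., 29.5 Hz. Each bin is baseline-corrected by subtracting its
#' mean power over a 500 ms baseline — the event's own first 500 ms by
#' default (`tf_baseline = "within"`), or the 500 ms preceding the onset
#' (`"pre"`) — with negative residuals clipped at zero. Bin powers are then
#' summed over the 3 s and normalised so all bins sum to 1; band sums
#' aggregate theta (4.5–7.5 Hz), alpha (8.5–11.5 Hz) and beta
#' (16.5–29.5 Hz), band edges inclusive on the bin-centre grid so no bin is
#' counted twice.
#'
#' @param rec a [recording()] (filtered or raw; the profile is relative).
#' @param event one event: a list/row with `onset_s` (and `duration_s >= 3`).
#' @param cfg an [arousal_config()] (`morlet_cycles`, `tf_baseline`).
#' @param mask optional `bad_channel_mask` used for channel aggregation.
#' @return a `tf_profile`: list with `freqs`, `rel_power` (sums to 1) and
#'   `band_sums` (theta, alpha, beta).
#' @export
event_tf_profile <- function(rec, event, cfg = arousal_config(), mask = NULL) {
  fs <- rec$fs
  onset <- event$onset_s
  if (!is.null(event$duration_s) && event$duration_s < 3)
    stop("events shorter than 3 s have no 3 s profile")
  n <- nrow(rec$signals)
  if ((onset + 3) * fs > n) stop("event too close to the recording end")
  pre_s <- if (identical(cfg$tf_baseline, "pre")) 0.5 else 0
  if (onset - pre_s < 0) stop("no pre-event baseline available before onset")

  pad <- 1                                   # s of context against edge bias
  a <- max(0, onset - pre_s - pad)
  b <- min(n / fs, onset + 3 + pad)
  x <- aggregate_eeg(rec, mask)[(floor(a * fs) + 1):floor(b * fs)]
  freqs <- seq(0.5, 29.5, by = 1)
  pow <- morlet_power(x, fs, freqs, cfg$morlet_cycles)

  off <- floor((onset - a) * fs)             # sample offset of the onset
  ev_idx <- (off + 1):(off + 3 * fs)
  base_idx <- if (pre_s > 0) (off - round(0.5 * fs) + 1):off
              else (off + 1):(off + round(0.5 * fs))
  base <- colMeans(pow[base_idx, , drop = FALSE])
  resid <- sweep(pow[ev_idx, , drop = FALSE], 2, base)
  resid[resid < 0] <- 0
  bin_sums <- colSums(resid)
  tot <- sum(bin_sums)
  if (tot <= 0) stop("event has no power above baseline in any bin")
  rel <- bin_sums / tot
  band <- function(lo, hi) sum(rel[freqs >= lo & freqs <= hi])
  structure(list(
    freqs = freqs, rel_power = rel,
    band_sums = c(theta = band(4.5, 7.5), alpha = band(8.5, 11.5),
                  beta = band(16.5, 29.5))
  ), class = "tf_profile")
}

#' Compare two groups of event time-frequency profiles
#'
#' Descriptive comparison of relative band power (theta/alpha/beta band
#' sums) between two groups of events, e.g. events only found automatically
#' versus events also found by a human rater.
#'
#' @param only_ad,shared non-empty lists of `tf_profile`s.
#' @return data.frame with per-band group means, SDs and the mean difference
#'   (`only_ad - shared`).
#' @export
compare_profiles <- function(only_ad, shared) {
  if (!length(only_ad) || !length(shared)) stop("both groups must be non-empty")
  bs <- function(group)
    t(vapply(group, function(p) p$band_sums, numeric(3)))
  a <- bs(only_ad); b <- bs(shared)
  data.frame(
    band = c("theta", "alpha", "beta"),
    mean_only_ad = colMeans(a), sd_only_ad = apply(a, 2, stats::sd),
    mean_shared = colMeans(b), sd_shared = apply(b, 2, stats::sd),
    mean_diff = colMeans(a) - colMeans(b),
    row.names = NULL
  )
}
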