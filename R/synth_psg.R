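# Ground-truth-labelled synthetic polysomnography. The generator emulates
# the statistical features the detector keys on: stage-dependent 1/f-like
# background EEG, transient narrowband theta/alpha/beta accelerations
# (arousals), sigma bursts (spindles), submental EMG tone increases, and
# channel faults -- all deterministic given one integer seed.

#' Specification for a synthetic polysomnography recording
#'
#' @param duration_s recording length in seconds (default 28800 = 8 h).
#' @param fs sampling rate in Hz (default 128, a typical storage rate).
#' @param n_eeg number of EEG channels (default 3).
#' @param n_emg 0 or 2 referenced EMG channels (default 2).
#' @param stages optional explicit stage sequence (one label per 30 s epoch);
#'   by default repeating ~90 min sleep cycles
#'   (W/N1/N2/N3/N2/REM) fill the night.
#' @param background per-stage background model: named list
#'   `stage = c(exponent, amplitude_uV)`; the EEG background is `1/f^exponent`
#'   coloured noise scaled to the stated SD. Defaults span wake (flat, low
#'   amplitude) to N3 (steep, high amplitude).
#' @param emg_sd per-stage SD (µV) of the referenced EMG background noise
#'   (REM lowest: atonia).
#' @param events event plan, a data.frame with columns `onset_s`,
#'   `duration_s`, `band` (`theta`/`alpha`/`beta`/`sigma`), `gain` (target
#'   ratio of injected band power to the local background band power) and
#'   `with_emg` (logical). Use [plan_events()] to draw one. Overlapping
#'   events are an error.
#' @param artifacts optional channel-fault plan: list with data.frames
#'   `flat` and `noisy`, columns `channel` (label), `start_s`, `end_s`
#'   (and `factor` for noisy).
#' @param burst_type `"noise"` (band-pass filtered Gaussian noise, default:
#'   band-power statistics resemble real EEG) or `"sine"` (pure tone at the
#'   band centre, for analytic unit tests).
#' @param seed integer; fully determines the output.
#' @return a `synth_spec` list.
#' @export
synth_spec <- function(duration_s = 28800, fs = 128, n_eeg = 3, n_emg = 2,
                       stages = NULL,
                       background = list(W = c(1.0, 15), N1 = c(1.2, 20),
                                         N2 = c(1.3, 30), N3 = c(1.5, 50),
                                         REM = c(1.1, 20)),
                       emg_sd = c(W = 8, N1 = 5, N2 = 5, N3 = 5, REM = 3),
                       events = NULL,
                       artifacts = NULL,
                       burst_type = c("noise", "sine"),
                       seed = 1) {
  burst_type <- match.arg(burst_type)
  if (!n_emg %in% c(0, 2)) stop("n_emg must be 0 or 2")
  n_win <- floor(duration_s / 30)
  if (is.null(stages)) {
    cycle <- c(rep("W", 6), rep("N1", 4), rep("N2", 50), rep("N3", 40),
               rep("N2", 30), rep("REM", 50))                # 90 min
    stages <- rep(cycle, length.out = n_win)
  } else {
    stages <- normalise_stages(stages)
    if (length(stages) < n_win) stop("stage plan shorter than the recording")
    stages <- stages[seq_len(n_win)]
  }
  if (is.null(events))
    events <- data.frame(onset_s = numeric(), duration_s = numeric(),
                         band = character(), gain = numeric(),
                         with_emg = logical())
  if (nrow(events)) {
    ev <- events[order(events$onset_s), ]
    if (any(ev$onset_s + ev$duration_s > duration_s))
      stop("an injected event extends past the recording end")
    if (nrow(ev) > 1 &&
        any(ev$onset_s[-1] < (ev$onset_s + ev$duration_s)[-nrow(ev)]))
      stop("injected events overlap")
    events <- ev
  }
  structure(list(duration_s = duration_s, fs = fs, n_eeg = n_eeg,
                 n_emg = n_emg, stages = stages, background = background,
                 emg_sd = emg_sd, events = events, artifacts = artifacts,
                 burst_type = burst_type, seed = seed),
            class = "synth_spec")
}

#' Draw a ground-truth event plan over a stage sequence
#'
#' Places non-overlapping events of the requested bands in staged sleep
#' (never wake), separated by at least 10 s, avoiding the final 30 s of the
#' recording.
#'
#' @param stages stage label per 30 s epoch.
#' @param n number of events.
#' @param duration_s event duration(s), recycled.
#' @param bands bands to sample from (recycled in order).
#' @param gain injected band-power gain relative to background.
#' @param with_emg logical, recycled; whether an EMG burst accompanies each.
#' @param stage_in restrict event onsets to these stages (default all sleep).
#' @param seed integer seed.
#' @return event plan data.frame for [synth_spec()].
#' @export
plan_events <- function(stages, n, duration_s = 4,
                        bands = c("theta", "alpha", "beta"),
                        gain = 4, with_emg = FALSE,
                        stage_in = c("N1", "N2", "N3", "REM", "NREM"),
                        seed = 1) {
  set.seed(seed)
  dur <- rep_len(duration_s, n)
  band <- rep_len(bands, n)
  emg <- rep_len(with_emg, n)
  g <- rep_len(gain, n)
  ok_win <- which(stages %in% stage_in)
  total_s <- length(stages) * 30
  cand_s <- unlist(lapply(ok_win, function(w) ((w - 1) * 30):((w * 30) - 1)))
  cand_s <- cand_s[cand_s + max(dur) <= total_s - 30]
  onset <- numeric(0)
  taken <- logical(total_s)
  for (i in seq_len(n)) {
    free <- cand_s[!vapply(cand_s, function(s) {
      any(taken[max(1, s - 10 + 1):min(total_s, s + dur[i] + 10)])
    }, TRUE)]
    # keep the whole event inside one stage-consistent region: onset window
    # stage governs the event's truth stage
    if (!length(free)) stop("could not place ", n, " non-overlapping events")
    s <- sample(free, 1)
    onset <- c(onset, s)
    taken[(s + 1):min(total_s, s + dur[i] + 1)] <- TRUE
  }
  ord <- order(onset)
  data.frame(onset_s = onset[ord], duration_s = dur[ord], band = band[ord],
             gain = g[ord], with_emg = emg[ord])
}

coloured_noise <- function(n, exponent, fs = 128, f_lo = 0.5) {
  # FFT-shaped 1/f^exponent Gaussian noise, unit SD. Components below `f_lo`
  # are suppressed so the stated amplitude is the EEG-band (>= 0.5 Hz)
  # amplitude: real amplitude conventions refer to what survives the
  # acquisition high-pass, and an unbounded 1/f tail would concentrate the
  # variance in unobservable infra-slow drift.
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))                # guard DC
  f <- pmin(f, n - f + 1)                  # two-sided frequency index
  hz <- f * fs / n
  W <- W * pmax(hz, f_lo)^(-exponent / 2) * (hz >= f_lo)
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x / stats::sd(x)
}

band_burst <- function(n_smp, fs, band_edges, type, taper_s = 0.25) {
  x <- if (type == "sine") {
    sin(2 * pi * mean(band_edges) * seq_len(n_smp) / fs)
  } else {
    bt <- signal::butter(4, band_edges / (fs / 2), type = "pass")
    as.numeric(signal::filtfilt(bt, stats::rnorm(n_smp + 2 * fs)))[
      (fs + 1):(fs + n_smp)]
  }
  ramp <- round(taper_s * fs)
  if (ramp > 0 && n_smp > 2 * ramp) {
    up <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
    x[seq_len(ramp)] <- x[seq_len(ramp)] * up
    x[(n_smp - ramp + 1):n_smp] <- x[(n_smp - ramp + 1):n_smp] * rev(up)
  }
  x
}

epoch_band_power_of <- function(x, fs, band_edges) {
  n_ep <- floor(length(x) / fs)
  m <- matrix(x[seq_len(n_ep * fs)], nrow = fs)
  pow <- 2 * Mod(stats::mvfft(m))^2 / fs^2
  bins <- band_bins(band_edges, floor(fs / 2) - 1L)
  colSums(pow[bins + 1L, , drop = FALSE])
}

#' Generate a synthetic polysomnography recording
#'
#' Builds stage-dependent coloured-noise EEG background, injects the planned
#' narrowband bursts (scaled so the epoch band power in the target band is
#' `gain` times the local background's), adds EMG background and tone bursts
#' on the referenced EMG pair, applies channel faults last, and returns the
#' recording together with its hypnogram and the exact ground-truth ledger.
#'
#' @param spec a [synth_spec()].
#' @return list with `recording` ([recording()]), `hypnogram`
#'   ([hypnogram()]), `ledger` (an [event_list()] with `rater_id = "truth"`,
#'   extra columns `band`, `gain`) and `spec`.
#' @export
synth_psg <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  fs <- spec$fs
  n_smp <- spec$duration_s * fs
  stages <- spec$stages
  n_ch <- spec$n_eeg + spec$n_emg
  labels <- c(paste0("EEG", seq_len(spec$n_eeg)),
              if (spec$n_emg) c("EMG1", "EMG2"))
  roles <- c(rep("EEG", spec$n_eeg), rep("EMG", spec$n_emg))
  sig <- matrix(0, n_smp, n_ch)

  # background, one contiguous segment per run of identical stage
  seg <- rle(stages)
  w0 <- 0L
  for (k in seq_along(seg$lengths)) {
    st <- seg$values[k]
    smp <- (w0 * 30L * fs + 1L):min(n_smp, (w0 + seg$lengths[k]) * 30L * fs)
    par <- spec$background[[st]]
    if (is.null(par)) par <- spec$background[["N2"]]
    for (j in seq_len(spec$n_eeg))
      sig[smp, j] <- coloured_noise(length(smp), par[1], fs) * par[2]
    if (spec$n_emg) {
      esd <- spec$emg_sd[[st]]
      for (j in spec$n_eeg + 1:2)
        sig[smp, j] <- stats::rnorm(length(smp)) * esd
    }
    w0 <- w0 + seg$lengths[k]
  }

  band_edges_of <- function(b)
    switch(b, theta = c(3, 7), alpha = c(7, 13), sigma = c(11.5, 15.5),
           beta = c(16, 30), stop("unknown band ", b))

  ev <- spec$events
  for (i in seq_len(nrow(ev))) {
    smp <- (ev$onset_s[i] * fs + 1):((ev$onset_s[i] + ev$duration_s[i]) * fs)
    edges <- band_edges_of(ev$band[i])
    burst <- band_burst(length(smp), fs, edges, spec$burst_type)
    meas_band <- if (ev$band[i] == "sigma") c(11, 16) else edges
    bg_p <- mean(epoch_band_power_of(sig[smp, 1], fs, meas_band))
    b_p <- mean(epoch_band_power_of(burst, fs, meas_band))
    if (b_p > 0 && bg_p > 0)
      burst <- burst * sqrt(ev$gain[i] * bg_p / b_p)
    for (j in seq_len(spec$n_eeg)) sig[smp, j] <- sig[smp, j] + burst
    if (isTRUE(ev$with_emg[i]) && spec$n_emg) {
      esd <- spec$emg_sd[[stages[ev$onset_s[i] %/% 30 + 1]]]
      tone <- stats::rnorm(length(smp)) * 8 * esd
      ramp <- round(0.25 * fs)
      up <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
      tone[seq_len(ramp)] <- tone[seq_len(ramp)] * up
      tone[(length(tone) - ramp + 1):length(tone)] <-
        tone[(length(tone) - ramp + 1):length(tone)] * rev(up)
      sig[smp, spec$n_eeg + 1] <- sig[smp, spec$n_eeg + 1] + tone
    }
  }

  # channel faults last
  art <- spec$artifacts
  if (!is.null(art)) {
    apply_fault <- function(df, fun) {
      for (i in seq_len(NROW(df))) {
        ch <- match(df$channel[i], labels)
        if (is.na(ch)) stop("unknown fault channel ", df$channel[i])
        smp <- (df$start_s[i] * fs + 1):(df$end_s[i] * fs)
        sig[smp, ch] <<- fun(sig[smp, ch], df[i, ])
      }
    }
    if (!is.null(art$flat)) apply_fault(art$flat, function(x, r) x * 0)
    if (!is.null(art$noisy))
      apply_fault(art$noisy, function(x, r)
        x * if (!is.null(r$factor)) r$factor else 10)
  }

  rec <- recording(sig, fs = fs, labels = labels, roles = roles,
                   reference = "synthetic linked mastoids")
  led <- if (nrow(ev)) {
    event_list(onset_s = ev$onset_s, duration_s = ev$duration_s,
               rater_id = "truth", emg_associated = ev$with_emg,
               band = ev$band, gain = ev$gain)
  } else {
    event_list(rater_id = character(), band = character(), gain = numeric())
  }
  list(recording = rec, hypnogram = hypnogram(stages), ledger = led,
       spec = spec)
}

#' Simulate a human rater from a ground-truth ledger
#'
#' Copies the ledger events, drops each independently with probability
#' `miss_rate`, and jitters onsets and durations by a uniform amount in
#' `[-jitter_s, jitter_s]` (durations are kept >= 1 s, onsets >= 0).
#'
#' @param ledger an [event_list()] (the generator's ground truth).
#' @param miss_rate per-event miss probability in `[0, 1]`.
#' @param jitter_s maximum absolute onset/duration jitter in seconds.
#' @param seed integer seed (deterministic output).
#' @param rater_id id written on the simulated events.
#' @return an [event_list()].
#' @export
make_rater <- function(ledger, miss_rate = 0, jitter_s = 0, seed = 1,
                       rater_id = "HRsim") {
  stopifnot(miss_rate >= 0, miss_rate <= 1)
  set.seed(seed)
  keep <- stats::runif(nrow(ledger)) >= miss_rate
  ev <- ledger[keep, , drop = FALSE]
  if (!nrow(ev))
    return(event_list(rater_id = character()))
  onset <- pmax(0, ev$onset_s + stats::runif(nrow(ev), -jitter_s, jitter_s))
  dur <- pmax(1, ev$duration_s + stats::runif(nrow(ev), -jitter_s, jitter_s))
  event_list(onset_s = onset, duration_s = dur, rater_id = rater_id,
             emg_associated = ev$emg_associated)
}
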