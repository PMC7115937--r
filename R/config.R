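#' Default detection configuration
#'
#' Builds the configuration object consumed by [detect()] and the lower-level
#' stages. Every threshold of the detection pipeline is collected here; the
#' defaults reproduce the published, self-calibrating behaviour of the
#' algorithm and a run with an unmodified config is the reference run.
#'
#' @param ... named overrides of any default listed below. Unknown keys are an
#'   error so that a typo in a config file cannot silently fall back to a
#'   default.
#'
#' @details Defaults (units in parentheses):
#' \describe{
#'   \item{filter_order}{3 — Butterworth order per modality.}
#'   \item{filter_edges}{band edges (Hz) per role: EEG 0.5–30, EOG 0.1–5,
#'     EMG 10–100. Low-pass edges at or above Nyquist are clipped to
#'     0.9 * fs/2 with a warning.}
#'   \item{zero_phase}{TRUE — forward–backward filtering so event onsets are
#'     not lagged by the filter's group delay.}
#'   \item{sd_flat, sd_noisy}{1 and 6e3 (µV) — whole-recording SD bounds
#'     flagging flat/noisy EEG channels.}
#'   \item{bad_ratio}{5 — per-window SD ratio beyond which an EEG channel is
#'     bad; \code{bad_ratio_two_sided} (TRUE) also flags ratios < 1/5.}
#'   \item{emg_flat_median}{0.1 (µV) — per-window median absolute amplitude
#'     below which a referenced EMG channel is flat.}
#'   \item{emg_noisy_ratio}{2 — median (window) and mean (epoch) absolute
#'     amplitude ratio declaring one EMG channel noisy relative to the other.}
#'   \item{emg_noisy_quota}{15 — epochs (out of 30) that must be noisy before
#'     the whole scoring window is dropped for that EMG channel.}
#'   \item{baseline_s}{240 (s) — initial stretch providing the global EMG
#'     baseline (its maximum per-epoch tone).}
#'   \item{emg_local_factor, emg_valid_factor}{2 and 2 — multipliers for the
#'     3-epoch median-filter test and the 10-epoch-neighbourhood validation
#'     test of the EMG shift cascade.}
#'   \item{bands}{band edges (Hz): theta 3–7, alpha 7–13, sigma 11–16,
#'     beta 16–30; half-open \code{[lo, hi)} when mapped to periodogram bins.}
#'   \item{adaptive_factor}{2 — the per-window adaptive EEG threshold is twice
#'     the median band power of the EMG-shift-free selection.}
#'   \item{neighbour_epochs}{10 — EMG-shift-free epochs taken on each side of
#'     a scoring window for the adaptive selection.}
#'   \item{sigma_quantile}{0.85 — spindle epochs have relative sigma power
#'     above this fraction of its recording-wide maximum.}
#'   \item{min_duration_s}{3 (s) — minimum arousal duration.}
#'   \item{aggregate}{"median" — across-channel fusion of band power
#'     ("median" over good EEG channels, or "any": flag if any channel
#'     shifts).}
#'   \item{estimator}{"periodogram" — per-epoch band power estimator.}
#'   \item{emg_concomitance_s}{1 (s) — slack around an event within which an
#'     EMG shift counts as concomitant; 0 gives strict overlap.}
#'   \item{merge_gap_s}{0 (s) — optional post-hoc merging of events separated
#'     by at most this many seconds (off by default).}
#'   \item{same_band_runs}{FALSE — if TRUE the >=3 consecutive epochs must be
#'     triggered by one and the same band (no theta→alpha hand-over).}
#'   \item{morlet_cycles}{7 — Morlet width (cycles) for event profiling.}
#'   \item{tf_baseline}{"within" — 500 ms baseline window for time-frequency
#'     profiles: "within" (event's first 500 ms) or "pre" (500 ms before
#'     onset).}
#' }
#'
#' @return a named list of class `arousal_config`.
#' @seealso [read_config()], [write_config()]
#' @export
#' @examples
#' cfg <- arousal_config(min_duration_s = 5)
#' cfg$min_duration_s
arousal_config <- function(...) {
  cfg <- list(
    filter_order = 3,
    filter_edges = list(EEG = c(0.5, 30), EOG = c(0.1, 5), EMG = c(10, 100)),
    zero_phase = TRUE,
    sd_flat = 1,
    sd_noisy = 6e3,
    bad_ratio = 5,
    bad_ratio_two_sided = TRUE,
    emg_flat_median = 0.1,
    emg_noisy_ratio = 2,
    emg_noisy_quota = 15,
    baseline_s = 240,
    emg_local_factor = 2,
    emg_valid_factor = 2,
    bands = list(theta = c(3, 7), alpha = c(7, 13),
                 sigma = c(11, 16), beta = c(16, 30)),
    adaptive_factor = 2,
    neighbour_epochs = 10,
    sigma_quantile = 0.85,
    min_duration_s = 3,
    aggregate = "median",
    estimator = "periodogram",
    emg_concomitance_s = 1,
    merge_gap_s = 0,
    same_band_runs = FALSE,
    morlet_cycles = 7,
    tf_baseline = "within"
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("config overrides must be named")
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "arousal_config")
}

#' Read a detection configuration from YAML
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path YAML file.
#' @return an `arousal_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  # nested band / edge lists come back as plain lists of length-2 vectors
  if (!is.null(raw$filter_edges))
    raw$filter_edges <- lapply(raw$filter_edges, as.numeric)
  if (!is.null(raw$bands))
    raw$bands <- lapply(raw$bands, as.numeric)
  do.call(arousal_config, raw)
}

#' Write a detection configuration to YAML
#'
#' @param cfg an `arousal_config`.
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "arousal_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.arousal_config <- function(x, ...) {
  cat("<arousal_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    if (is.list(v)) {
      cat("  ", k, ":\n", sep = "")
      for (b in names(v))
        cat("    ", b, ": ", paste(v[[b]], collapse = "-"), "\n", sep = "")
    } else {
      cat("  ", k, ": ", paste(v, collapse = ", "), "\n", sep = "")
    }
  }
  invisible(x)
}
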