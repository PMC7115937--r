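# Minimal EDF/EDF+ I/O in base R: 16-bit little-endian data records, ASCII
# headers, 1 s record duration on write. Continuous signals only; the EDF+
# annotations track is out of scope.

edf_pad <- function(x, n) {
  x <- as.character(x)
  if (nchar(x) > n) x <- substr(x, 1, n)
  formatC(x, width = -n, flag = " ")
}

edf_num <- function(x, n) {
  # ASCII numeric field; EDF allows 8 chars for physical min/max
  s <- formatC(x, format = "g", digits = n - 2, width = 1)
  if (nchar(s) > n) s <- substr(s, 1, n)
  edf_pad(s, n)
}

#' Write a recording to an EDF file
#'
#' Signals are quantised to 16-bit integers over a symmetric physical range
#' covering each channel (quantisation error <= range / 2^16). The record
#' duration is 1 s, so `fs` must be integer-valued.
#'
#' @param rec a [recording()].
#' @param path output file.
#' @param physical_dim physical dimension string written per channel,
#'   `"uV"` by default (`"mV"` and `"V"` are understood on read-back).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, physical_dim = "uV") {
  stopifnot(inherits(rec, "psg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF export requires an integer sampling rate")
  scale_out <- switch(physical_dim, uV = 1, mV = 1e-3, V = 1e-6,
                      stop("unsupported physical dimension: ", physical_dim))
  ns <- ncol(rec$signals)
  n_rec <- floor(nrow(rec$signals) / fs)
  if (n_rec < 1) stop("recording shorter than one 1 s data record")
  sig <- rec$signals[seq_len(n_rec * fs), , drop = FALSE] * scale_out

  pmax_ <- apply(abs(sig), 2, max)
  pmax_[pmax_ == 0] <- 1
  pmax_ <- pmax_ * 1.0001              # keep extremes strictly inside range
  dmax <- 32767; dmin <- -32768

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad(1, 8),
    edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(f, n) writeChar(paste0(vapply(f, edf_pad, "", n),
                                           collapse = ""), con, eos = NULL)
  field(rec$labels, 16)
  field(rep("", ns), 80)
  field(rep(physical_dim, ns), 8)
  writeChar(paste0(vapply(-pmax_, edf_num, "", 8), collapse = ""), con, eos = NULL)
  writeChar(paste0(vapply(pmax_, edf_num, "", 8), collapse = ""), con, eos = NULL)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)
  field(rep(fs, ns), 8)
  field(rep("", ns), 32)

  # re-read the physical ranges exactly as a reader will parse them, so the
  # digital scaling below matches the truncated ASCII header fields
  pmin_hdr <- as.numeric(vapply(-pmax_, edf_num, "", 8))
  pmax_hdr <- as.numeric(vapply(pmax_, edf_num, "", 8))

  gain <- (pmax_hdr - pmin_hdr) / (dmax - dmin)
  dig <- sweep(sig, 2, pmin_hdr)
  dig <- sweep(dig, 2, gain, "/") + dmin
  dig <- round(pmin(pmax(dig, dmin), dmax))
  storage.mode(dig) <- "integer"

  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(dig[rows, ]), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("unreadable EDF: bad signal count")
  fields <- function(n) vapply(seq_len(ns), function(i) rd(n), "")
  labels <- trimws(fields(16))
  fields(80)                              # transducer
  phys_dim <- trimws(fields(8))
  pmin_ <- as.numeric(fields(8))
  pmax_ <- as.numeric(fields(8))
  dmin <- as.numeric(fields(8))
  dmax <- as.numeric(fields(8))
  fields(80)                              # prefiltering
  spr <- as.integer(fields(8))
  fields(32)
  if (anyNA(c(pmin_, pmax_, dmin, dmax, spr, n_rec, rec_dur)))
    stop("unreadable EDF: malformed header numerics")

  total <- spr * n_rec
  sig <- matrix(0, max(total), ns)
  idx <- rep(1L, ns)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[s], size = 2, endian = "little",
                   signed = TRUE)
      if (length(v) < spr[s]) stop("unreadable EDF: truncated data records")
      sig[idx[s]:(idx[s] + spr[s] - 1L), s] <- v
      idx[s] <- idx[s] + spr[s]
    }
  }
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (s in seq_len(ns))
    sig[, s] <- (sig[, s] - dmin[s]) * gain[s] + pmin_[s]
  list(signals = sig, labels = labels, phys_dim = phys_dim,
       fs = spr / rec_dur, n_samples = total)
}

#' Read a polysomnography recording from EDF
#'
#' Channels are selected and assigned roles through `role_map`; channels the
#' map does not mention are dropped with a warning. Physical units are
#' converted to microvolts from the per-channel physical-dimension header
#' field (`uV`, `mV`, `V`; anything else is assumed to already be µV and
#' warned about).
#'
#' @param path EDF/EDF+ file.
#' @param role_map named character vector, `label = role` with role in
#'   `EEG`, `EOG`, `EMG`.
#' @param reference montage note stored on the returned recording.
#' @return a [recording()].
#' @export
read_recording <- function(path, role_map, reference = "linked mastoids") {
  raw <- read_edf_raw(path)
  keep <- which(raw$labels %in% names(role_map))
  dropped <- setdiff(raw$labels, names(role_map))
  if (length(dropped))
    warning("dropping channels not in role_map: ",
            paste(dropped, collapse = ", "))
  if (!length(keep)) stop("no channels left after applying role_map")
  fs <- unique(raw$fs[keep])
  if (length(fs) != 1)
    stop("retained channels have mismatched sampling rates: ",
         paste(raw$fs[keep], collapse = ", "))
  to_uv <- vapply(raw$phys_dim[keep], function(d) {
    switch(d, uV = 1, mV = 1e3, V = 1e6, {
      warning("unknown physical dimension '", d, "'; assuming uV")
      1
    })
  }, 0)
  sig <- raw$signals[seq_len(min(raw$n_samples[keep])), keep, drop = FALSE]
  sig <- sweep(sig, 2, to_uv, "*")
  recording(sig, fs = fs, labels = raw$labels[keep],
            roles = unname(role_map[raw$labels[keep]]), reference = reference)
}
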