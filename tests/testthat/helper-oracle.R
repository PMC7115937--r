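# Independent brute-force oracle for epoch- and event-level agreement:
# everything is done by explicit enumeration of seconds and event pairs,
# deliberately sharing no code with the package's confusion().

oracle_events <- function(track) {
  ev <- list()
  i <- 1
  n <- length(track)
  while (i <= n) {
    if (track[i]) {
      j <- i
      while (j < n && track[j + 1]) j <- j + 1
      ev[[length(ev) + 1]] <- c(start = i - 1L, end = j)   # 0-based [start,end)
      i <- j + 1
    } else i <- i + 1
  }
  ev
}

oracle_confusion <- function(test, gold) {
  tp <- fp <- tn <- fn <- 0L
  for (s in seq_along(test)) {
    if (test[s] && gold[s]) tp <- tp + 1L
    else if (test[s] && !gold[s]) fp <- fp + 1L
    else if (!test[s] && gold[s]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  et <- oracle_events(test)
  eg <- oracle_events(gold)
  used <- rep(FALSE, length(et))
  tpe <- 0L
  overlaps <- numeric(0)
  lens <- numeric(0)
  for (g in eg) {
    found <- FALSE
    for (j in seq_along(et)) {
      if (used[j]) next
      ov <- 0L
      for (s in g["start"]:(g["end"] - 1L))
        if (s >= et[[j]]["start"] && s < et[[j]]["end"]) ov <- ov + 1L
      if (ov >= 1L) {
        used[j] <- TRUE
        tpe <- tpe + 1L
        overlaps <- c(overlaps, ov)
        lens <- c(lens, g["end"] - g["start"])
        found <- TRUE
        break
      }
    }
  }
  list(TPs = tp, FPs = fp, TNs = tn, FNs = fn,
       TPe = tpe, FNe = length(eg) - tpe, FPe = sum(!used),
       C = if (length(lens)) mean(overlaps / lens) else NA_real_)
}

int_to_track <- function(i, n_bits) {
  as.logical(bitwAnd(i, 2^(seq_len(n_bits) - 1)) > 0)
}

as_track <- function(x) structure(as.logical(x), class = "detection_track")
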