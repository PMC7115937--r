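# Scorer-agreement framework: 1 s-epoch tracks, confusion counts at epoch
# and event level, and the five agreement coefficients (S, kappa, Se, C, FDR).

#' Convert an event list to a 1 s detection track
#'
#' Each 1 s epoch is labelled as arousal when events cover strictly more than
#' 0.5 s of it: a 1 s event starting at 10.6 s covers 0.4 s of epoch 10 (not
#' labelled) and 0.6 s of epoch 11 (labelled); an onset at exactly 10.5 s
#' covers exactly 0.5 s of each and labels neither (the rule is strict).
#'
#' @param events an [event_list()].
#' @param n_seconds track length in seconds.
#' @return a `detection_track`: logical vector of length `n_seconds`.
#' @export
to_track <- function(events, n_seconds) {
  n_seconds <- as.integer(n_seconds)
  cover <- numeric(n_seconds)
  if (nrow(events)) {
    if (any(events$onset_s + events$duration_s > n_seconds))
      stop("an event extends past the end of the track")
    for (i in seq_len(nrow(events))) {
      a <- events$onset_s[i]
      b <- a + events$duration_s[i]
      e0 <- floor(a); e1 <- min(ceiling(b) - 1, n_seconds - 1)
      for (e in e0:e1)
        cover[e + 1] <- cover[e + 1] + max(0, min(b, e + 1) - max(a, e))
    }
  }
  structure(cover > 0.5, class = "detection_track")
}

track_events <- function(track) {
  r <- rle(as.logical(track))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[keep] - 1L, length = r$lengths[keep])  # 0-based s
}

intervals_to_track <- function(iv, n) {
  x <- rep(FALSE, n)
  if (nrow(iv)) for (i in seq_len(nrow(iv)))
    x[(iv$start[i] + 1L):(iv$start[i] + iv$length[i])] <- TRUE
  structure(x, class = "detection_track")
}

overlap_len <- function(a0, a1, b0, b1) max(0L, min(a1, b1) - max(a0, b0))

#' Fuse two raters' tracks into a composite gold standard
#'
#' `"inclusive"` keeps every arousal found by either rater (epochwise OR).
#' `"conservative"` keeps only arousals identified by both: pairs of events
#' (maximal true runs) sharing at least 1 s are retained and each pair
#' contributes its union interval (`granularity = "intersection"` keeps only
#' the common seconds instead).
#'
#' @param a,b `detection_track`s of equal length.
#' @param mode `"inclusive"` or `"conservative"`.
#' @param granularity interval written for a conservative pair, `"union"`
#'   (default) or `"intersection"`.
#' @return a `detection_track`.
#' @export
fuse_raters <- function(a, b, mode = c("inclusive", "conservative"),
                        granularity = c("union", "intersection")) {
  mode <- match.arg(mode)
  granularity <- match.arg(granularity)
  if (length(a) != length(b)) stop("tracks have different lengths")
  if (mode == "inclusive")
    return(structure(as.logical(a) | as.logical(b), class = "detection_track"))
  ea <- track_events(a); eb <- track_events(b)
  iv <- data.frame(start = integer(), length = integer())
  for (i in seq_len(nrow(ea))) for (j in seq_len(nrow(eb))) {
    a0 <- ea$start[i]; a1 <- a0 + ea$length[i]
    b0 <- eb$start[j]; b1 <- b0 + eb$length[j]
    if (overlap_len(a0, a1, b0, b1) >= 1) {
      iv <- rbind(iv, if (granularity == "union") {
        data.frame(start = min(a0, b0), length = max(a1, b1) - min(a0, b0))
      } else {
        data.frame(start = max(a0, b0), length = min(a1, b1) - max(a0, b0))
      })
    }
  }
  intervals_to_track(iv, length(a))
}

#' Epoch- and event-level confusion counts
#'
#' Epoch counts compare the tracks pointwise. Event counts match maximal
#' true runs requiring at least 1 s (one epoch) of overlap; matching is
#' one-to-one greedy in onset order by default, so a gold event overlapped by
#' two test events yields one true positive and one false positive
#' (`match_mode = "many-to-one"` lets several test events share one gold).
#'
#' @param test,gold `detection_track`s of equal length (gold = the rater
#'   taken as reference).
#' @param match_mode `"one-to-one"` or `"many-to-one"`.
#' @return a `confusion_counts` list: `TPs`, `FPs`, `TNs`, `FNs`, `TPe`,
#'   `FPe`, `FNe`, `n`, and `matched` (per matched gold event: its length and
#'   the overlapping seconds, feeding the mean-overlap coefficient C).
#' @export
confusion <- function(test, gold, match_mode = c("one-to-one", "many-to-one")) {
  match_mode <- match.arg(match_mode)
  if (length(test) != length(gold)) stop("tracks have different lengths")
  t <- as.logical(test); g <- as.logical(gold)
  TPs <- sum(t & g); FPs <- sum(t & !g); TNs <- sum(!t & !g); FNs <- sum(!t & g)

  et <- track_events(test); eg <- track_events(gold)
  used_t <- rep(FALSE, nrow(et))
  matched_g <- rep(FALSE, nrow(eg))
  m_len <- integer(); m_ov <- integer()
  for (i in seq_len(nrow(eg))) {
    g0 <- eg$start[i]; g1 <- g0 + eg$length[i]
    best <- 0L
    for (j in seq_len(nrow(et))) {
      if (match_mode == "one-to-one" && used_t[j]) next
      ov <- overlap_len(g0, g1, et$start[j], et$start[j] + et$length[j])
      if (ov >= 1) {
        if (match_mode == "one-to-one") {
          used_t[j] <- TRUE
          matched_g[i] <- TRUE
          best <- ov
          break                       # greedy: first unmatched overlapping
        } else {
          used_t[j] <- TRUE
          matched_g[i] <- TRUE
          best <- best + ov
        }
      }
    }
    if (matched_g[i]) { m_len <- c(m_len, eg$length[i]); m_ov <- c(m_ov, best) }
  }
  structure(list(
    TPs = TPs, FPs = FPs, TNs = TNs, FNs = FNs,
    TPe = sum(matched_g), FNe = sum(!matched_g), FPe = sum(!used_t),
    n = length(t),
    matched = data.frame(gold_len = m_len, overlap = m_ov)
  ), class = "confusion_counts")
}

#' Agreement coefficients from confusion counts
#'
#' Computes the five coefficients: Bennett's inter-rater agreement
#' `S = 2 * P0 - 1` with `P0` the 1 s-epoch accuracy; Cohen's kappa
#' `(P0 - Pe) / (1 - Pe)`; event sensitivity `Se = TPe / (TPe + FNe)`; mean
#' event overlap `C` (mean, over gold events matched by the test, of the
#' overlapping seconds divided by the gold event's duration); and the false
#' discovery ratio `FDR = FPe / (TPe + FPe)`.
#'
#' Two chance terms are available for kappa: `"standard"` uses Cohen's
#' marginal expected agreement
#' `Pe = [(TPs+FPs)(TPs+FNs) + (TNs+FNs)(TNs+FPs)] / n^2`;
#' `"paper-literal"` uses `Pr = (TPs+TNs)(TPs+FPs) / n^2`, an alternative
#' chance term found in print in the sleep-scoring literature. Undefined
#' ratios (0/0) are reported as `NA` with a reason, never silently.
#'
#' @param counts a `confusion_counts`.
#' @param kappa_variant `"standard"` or `"paper-literal"`.
#' @return an `agreement_report` list: `S`, `kappa`, `Se`, `C`, `FDR`, `P0`,
#'   `counts`, `kappa_variant`, `interpretation` (Landis–Koch label for
#'   kappa), `notes` (reasons for any `NA`).
#' @export
coefficients <- function(counts, kappa_variant = c("standard", "paper-literal")) {
  kappa_variant <- match.arg(kappa_variant)
  n <- counts$n
  if (n <= 0) stop("empty track")
  notes <- character()
  P0 <- (counts$TPs + counts$TNs) / n
  S <- 2 * P0 - 1
  Pe <- if (kappa_variant == "standard") {
    ((counts$TPs + counts$FPs) * (counts$TPs + counts$FNs) +
       (counts$TNs + counts$FNs) * (counts$TNs + counts$FPs)) / n^2
  } else {
    (counts$TPs + counts$TNs) * (counts$TPs + counts$FPs) / n^2
  }
  kappa <- if (Pe == 1) {
    notes <- c(notes, "kappa undefined: chance agreement is 1")
    NA_real_
  } else (P0 - Pe) / (1 - Pe)
  Se <- if (counts$TPe + counts$FNe == 0) {
    notes <- c(notes, "Se undefined: gold standard has no events")
    NA_real_
  } else counts$TPe / (counts$TPe + counts$FNe)
  FDR <- if (counts$TPe + counts$FPe == 0) {
    notes <- c(notes, "FDR undefined: test has no events")
    NA_real_
  } else counts$FPe / (counts$TPe + counts$FPe)
  C <- if (nrow(counts$matched) == 0) {
    notes <- c(notes, "C undefined: no matched events")
    NA_real_
  } else mean(counts$matched$overlap / counts$matched$gold_len)
  structure(list(
    S = S, kappa = kappa, Se = Se, C = C, FDR = FDR, P0 = P0,
    counts = counts, kappa_variant = kappa_variant,
    interpretation = if (is.na(kappa)) NA_character_
                     else kappa_interpretation(kappa),
    notes = notes
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n")
  cat(sprintf("  S = %.3f  kappa(%s) = %s (%s)\n", x$S, x$kappa_variant,
              ifelse(is.na(x$kappa), "NA", sprintf("%.3f", x$kappa)),
              ifelse(is.na(x$interpretation), "-", x$interpretation)))
  cat(sprintf("  Se = %s  C = %s  FDR = %s\n",
              format(x$Se, digits = 3), format(x$C, digits = 3),
              format(x$FDR, digits = 3)))
  cat(sprintf("  epochs: TP %d FP %d TN %d FN %d | events: TP %d FP %d FN %d\n",
              x$counts$TPs, x$counts$FPs, x$counts$TNs, x$counts$FNs,
              x$counts$TPe, x$counts$FPe, x$counts$FNe))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Landis–Koch interpretation of a kappa value
#'
#' @param kappa a kappa value (<= 1).
#' @return one of `"Poor"` (< 0), `"Slight"` (0–0.20), `"Fair"`
#'   (0.21–0.40), `"Moderate"` (0.41–0.60), `"Substantial"` (0.61–0.80),
#'   `"Almost perfect"` (0.81–1.00).
#' @export
kappa_interpretation <- function(kappa) {
  stopifnot(kappa <= 1)
  if (kappa < 0) "Poor"
  else if (kappa <= 0.20) "Slight"
  else if (kappa <= 0.40) "Fair"
  else if (kappa <= 0.60) "Moderate"
  else if (kappa <= 0.80) "Substantial"
  else "Almost perfect"
}

#' Per-sleep-stage epoch-level agreement
#'
#' Restricts the two tracks to the seconds of each sleep stage and reports
#' the 1 s-epoch coefficients (S and kappa) per stage; event-level
#' coefficients are not meaningful within a stage stratum because events
#' straddle stage boundaries.
#'
#' @param test,gold `detection_track`s.
#' @param hyp a [hypnogram()] covering the tracks.
#' @param kappa_variant passed to [coefficients()].
#' @return data.frame with columns `stage`, `n`, `S`, `kappa`.
#' @export
stage_agreement <- function(test, gold, hyp,
                            kappa_variant = c("standard", "paper-literal")) {
  kappa_variant <- match.arg(kappa_variant)
  st <- stage_at(hyp, seq_along(test) - 1)
  out <- NULL
  for (s in unique(st)) {
    idx <- st == s
    cc <- confusion(structure(as.logical(test)[idx], class = "detection_track"),
                    structure(as.logical(gold)[idx], class = "detection_track"))
    co <- coefficients(cc, kappa_variant)
    out <- rbind(out, data.frame(stage = s, n = sum(idx),
                                 S = co$S, kappa = co$kappa))
  }
  out
}
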