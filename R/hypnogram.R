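#' Hypnogram of 30 s sleep-stage labels
#'
#' @param stages character vector of stage labels, one per 30 s epoch, from
#'   the full set `W, N1, N2, N3, REM` or the reduced set `W, NREM, REM`.
#' @return an object of class `hypnogram`.
#' @export
hypnogram <- function(stages) {
  stages <- normalise_stages(stages)
  structure(list(stages = stages, epoch_len = 30), class = "hypnogram")
}

STAGE_SET <- c("W", "N1", "N2", "N3", "REM", "NREM")

normalise_stages <- function(stages) {
  s <- toupper(trimws(as.character(stages)))
  s[s %in% c("WAKE", "W")] <- "W"
  s[s == "R"] <- "REM"
  bad <- setdiff(unique(s), STAGE_SET)
  if (length(bad))
    stop("unknown sleep stage token(s): ", paste(bad, collapse = ", "))
  s
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d x 30 s epochs (%.1f h)\n",
              length(x$stages), length(x$stages) / 120))
  print(table(factor(x$stages, levels = STAGE_SET)))
  invisible(x)
}

#' Read a hypnogram
#'
#' Two dialects: `"lines"` — one stage token per line (or whitespace
#' separated), each token one 30 s epoch; `"csv"` — columns `onset_s,stage`
#' with strictly contiguous 30 s rows.
#'
#' @param path input file.
#' @param dialect `"lines"` or `"csv"`.
#' @return a [hypnogram()].
#' @export
read_hypnogram <- function(path, dialect = c("lines", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "lines") {
    toks <- scan(path, what = "", quiet = TRUE)
    return(hypnogram(toks))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("onset_s", "stage") %in% names(df)))
    stop("csv hypnogram needs columns onset_s,stage")
  expect <- seq(0, by = 30, length.out = nrow(df))
  if (!isTRUE(all.equal(as.numeric(df$onset_s), expect)))
    stop("csv hypnogram epochs are not contiguous 30 s rows")
  hypnogram(df$stage)
}

#' Write a hypnogram
#'
#' @param hyp a [hypnogram()].
#' @param path output file.
#' @param dialect `"lines"` or `"csv"` (see [read_hypnogram()]).
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path, dialect = c("lines", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "lines") {
    writeLines(hyp$stages, path)
  } else {
    utils::write.csv(
      data.frame(onset_s = seq(0, by = 30, length.out = length(hyp$stages)),
                 stage = hyp$stages),
      path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Stage label covering a given second
#'
#' Seconds past the end of the hypnogram are treated as wake (arousals are
#' not scored in wake, so an unstaged tail is conservatively masked out); the
#' first such query warns.
#'
#' @param hyp a [hypnogram()].
#' @param second 0-based second index (vectorised).
#' @return character stage per second.
#' @export
stage_at <- function(hyp, second) {
  idx <- floor(second / 30) + 1
  out <- rep("W", length(idx))
  inside <- idx <= length(hyp$stages)
  if (any(!inside))
    warning("seconds beyond the staged range treated as W")
  out[inside] <- hyp$stages[idx[inside]]
  out
}
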