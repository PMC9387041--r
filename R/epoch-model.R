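# Canonical AASM stage vocabulary, in the order used throughout the package.
STAGE_LEVELS <- c("W", "N1", "N2", "N3", "R")

# Priority used to break frequency ties among non-W stages when a 2-min
# epoch is sub-classified (R outranks N1 outranks N2 outranks N3).
STAGE_PRIORITY <- c("R", "N1", "N2", "N3")

EPOCH30_SEC <- 30
EPOCH2_SEC <- 120

#' Stage vocabulary
#'
#' The five AASM sleep stages accepted by the package, in canonical order:
#' \code{W}, \code{N1}, \code{N2}, \code{N3}, \code{R}.  Legacy labels such as
#' \code{"Stage 3+4"} or \code{"Stage REM"} are accepted by the file readers
#' (see [read_hypnogram()]) and mapped onto this vocabulary.
#'
#' @return Character vector of the five stage labels.
#' @export
stage_levels <- function() STAGE_LEVELS

parse_iso8601 <- function(x, what = "timestamp") {
  if (inherits(x, "POSIXct")) return(x)
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (is.na(out))
    stop(sprintf("cannot parse %s '%s' as ISO-8601 (YYYY-MM-DDTHH:MM:SS)",
                 what, as.character(x)), call. = FALSE)
  out
}

format_iso8601 <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

check_stages <- function(stages) {
  stages <- as.character(stages)
  bad <- which(!(stages %in% STAGE_LEVELS))
  if (length(bad))
    stop(sprintf("unknown stage label '%s' at position %d (expected one of %s)",
                 stages[bad[1]], bad[1],
                 paste(STAGE_LEVELS, collapse = ", ")), call. = FALSE)
  stages
}

#' 30-second hypnogram
#'
#' Container for a night of visually staged polysomnography: one AASM stage
#' (\code{W}, \code{N1}, \code{N2}, \code{N3}, \code{R}) per 30-s epoch,
#' anchored at lights-off.  The lights-on time must equal lights-off plus
#' 30 s times the number of stages; when \code{lights_on} is omitted it is
#' derived from the length.
#'
#' @param stages Character vector of stage labels, one per 30-s epoch
#'   (length at least 4).
#' @param lights_off Lights-off time, \code{POSIXct} or ISO-8601 string.
#' @param lights_on Optional lights-on time; derived from \code{stages} when
#'   missing, validated against it when supplied.
#' @return An object of class \code{"hypnogram30"}: a list with elements
#'   \code{stages}, \code{lights_off}, \code{lights_on}.
#' @seealso [collapse_hypnogram()], [read_hypnogram()]
#' @export
hypnogram <- function(stages, lights_off, lights_on = NULL) {
  stages <- check_stages(stages)
  if (length(stages) < 4L)
    stop("a hypnogram needs at least 4 30-s epochs (one 2-min epoch)",
         call. = FALSE)
  lights_off <- parse_iso8601(lights_off, "lights_off")
  expected_on <- lights_off + EPOCH30_SEC * length(stages)
  if (is.null(lights_on)) {
    lights_on <- expected_on
  } else {
    lights_on <- parse_iso8601(lights_on, "lights_on")
    if (abs(as.numeric(difftime(lights_on, expected_on, units = "secs"))) > 1e-6)
      stop(sprintf(
        "lights_on inconsistent with %d stages of 30 s after lights_off (expected %s, got %s)",
        length(stages), format_iso8601(expected_on), format_iso8601(lights_on)),
        call. = FALSE)
  }
  structure(list(stages = stages, lights_off = lights_off,
                 lights_on = lights_on),
            class = "hypnogram30")
}

#' @export
print.hypnogram30 <- function(x, ...) {
  cat(sprintf("30-s hypnogram: %d epochs (%.1f min in bed), lights off %s\n",
              length(x$stages), length(x$stages) * 0.5,
              format_iso8601(x$lights_off)))
  tab <- table(factor(x$stages, levels = STAGE_LEVELS))
  print(tab)
  invisible(x)
}

#' 2-minute activity-count series
#'
#' Container for the actigraph's stored record: one integer activity
#' intensity in 0--31 per 2-min epoch (the device counts threshold crossings
#' of a 3-axis accelerometer every 0.125 s, sums them over 2 min, and stores
#' the sum on a 32-level scale).  The series is anchored at lights-off so it
#' can be aligned epoch-for-epoch with a collapsed hypnogram.
#'
#' @param counts Integer vector of activity intensities, each in 0--31.
#' @param start Start time of the first epoch (the lights-off anchor),
#'   \code{POSIXct} or ISO-8601 string.
#' @return An object of class \code{"activity_series"}.
#' @seealso [score_series()], [read_activity()]
#' @export
activity_series <- function(counts, start) {
  if (length(counts) < 1L) stop("empty activity series", call. = FALSE)
  if (any(!is.finite(counts)))
    stop("activity counts must be finite", call. = FALSE)
  if (any(counts != round(counts)))
    stop(sprintf("non-integer activity count %s at epoch %d",
                 format(counts[which(counts != round(counts))[1]]),
                 which(counts != round(counts))[1] - 1L), call. = FALSE)
  counts <- as.integer(round(counts))
  bad <- which(counts < 0L | counts > 31L)
  if (length(bad))
    stop(sprintf("activity count %d at epoch %d outside the 32-level range [0, 31]",
                 counts[bad[1]], bad[1] - 1L), call. = FALSE)
  structure(list(counts = counts, start = parse_iso8601(start, "start")),
            class = "activity_series")
}

#' @export
print.activity_series <- function(x, ...) {
  cat(sprintf("activity series: %d 2-min epochs from %s (mean count %.2f)\n",
              length(x$counts), format_iso8601(x$start), mean(x$counts)))
  invisible(x)
}

#' Collapse four 30-s stages to one 2-min sleep/wake epoch
#'
#' Implements the 2-min re-classification rule: a window of four consecutive
#' 30-s stages is wake (\code{W}) when it contains two or more \code{W}
#' scores; otherwise it is sleep (\code{S}), sub-classified as the most
#' frequent non-W stage in the window, with frequency ties broken by the
#' priority R > N1 > N2 > N3.
#'
#' @param stages Exactly four stage labels.
#' @return A list with elements \code{sw} (\code{"S"} or \code{"W"}) and
#'   \code{substage} (one of \code{N1}, \code{N2}, \code{N3}, \code{R}, or
#'   \code{NA} for wake epochs).
#' @examples
#' collapse_window(c("W", "W", "N1", "N1"))  # wake: two W in the window
#' collapse_window(c("N1", "N1", "R", "R"))  # sleep, substage R (tie priority)
#' @export
collapse_window <- function(stages) {
  stages <- check_stages(stages)
  if (length(stages) != 4L)
    stop(sprintf("collapse window must hold exactly 4 stages, got %d",
                 length(stages)), call. = FALSE)
  if (sum(stages == "W") >= 2L)
    return(list(sw = "W", substage = NA_character_))
  counts <- tabulate(factor(stages[stages != "W"], levels = STAGE_PRIORITY),
                     nbins = length(STAGE_PRIORITY))
  # STAGE_PRIORITY is ordered R, N1, N2, N3, so the first maximum is the
  # highest-priority stage among the tied most-frequent ones.
  list(sw = "S", substage = STAGE_PRIORITY[which.max(counts)])
}

#' Collapse a 30-s hypnogram to 2-min sleep/wake epochs
#'
#' Partitions the hypnogram into consecutive non-overlapping windows of four
#' 30-s stages starting at lights-off and maps each window through
#' [collapse_window()].  Nights longer than \code{tib_cap_min} are truncated
#' to their first \code{tib_cap_min} minutes before collapsing (the analysis
#' convention of using only the first 7 h of long nights); shorter nights are
#' used whole.
#'
#' @param h A [hypnogram()] object.
#' @param trailing Policy for trailing stages that do not fill a 4-window:
#'   \code{"drop"} (default) discards them, \code{"error"} refuses.
#' @param tib_cap_min Time-in-bed cap in minutes (default 420 = 7 h); use
#'   \code{Inf} to disable.
#' @return An object of class \code{"collapsed_hypnogram"}: a list with
#'   character vectors \code{sw} (\code{"S"}/\code{"W"}) and \code{substage}
#'   (\code{NA} for wake epochs), plus \code{lights_off} and \code{lights_on}
#'   spanning the consumed epochs.
#' @export
collapse_hypnogram <- function(h, trailing = c("drop", "error"),
                               tib_cap_min = 420) {
  stopifnot(inherits(h, "hypnogram30"))
  trailing <- match.arg(trailing)
  stages <- h$stages
  cap_epochs <- if (is.finite(tib_cap_min)) as.integer(tib_cap_min * 2) else
    length(stages)
  if (length(stages) > cap_epochs) stages <- stages[seq_len(cap_epochs)]
  n_win <- length(stages) %/% 4L
  if (n_win < 1L) stop("hypnogram too short to form a 2-min epoch",
                       call. = FALSE)
  if (length(stages) %% 4L != 0L && trailing == "error")
    stop(sprintf("hypnogram length %d is not a multiple of 4 30-s epochs",
                 length(stages)), call. = FALSE)
  sw <- character(n_win)
  substage <- character(n_win)
  for (i in seq_len(n_win)) {
    e <- collapse_window(stages[(4L * (i - 1L) + 1L):(4L * i)])
    sw[i] <- e$sw
    substage[i] <- e$substage
  }
  structure(list(sw = sw, substage = substage,
                 lights_off = h$lights_off,
                 lights_on = h$lights_off + EPOCH2_SEC * n_win),
            class = "collapsed_hypnogram")
}

#' @export
print.collapsed_hypnogram <- function(x, ...) {
  cat(sprintf("collapsed hypnogram: %d 2-min epochs (%d sleep, %d wake)\n",
              length(x$sw), sum(x$sw == "S"), sum(x$sw == "W")))
  invisible(x)
}

#' Align a collapsed hypnogram with an activity series
#'
#' Pairs PSG-collapsed 2-min epochs with the activity counts recorded over
#' the same intervals.  Both series must share the lights-off anchor.  When
#' the lengths differ the pairing is truncated to the shorter series with a
#' warning; a difference beyond \code{tolerance} epochs is treated as a
#' recording fault and raises an error.
#'
#' @param ch A [collapse_hypnogram()] result.
#' @param act An [activity_series()].
#' @param tolerance Maximum tolerated length difference in epochs (default 2).
#' @return A data frame with one row per aligned epoch: \code{epoch_index}
#'   (0-based), \code{sw} (PSG sleep/wake), \code{substage}, \code{count}.
#' @export
align_series <- function(ch, act, tolerance = 2L) {
  stopifnot(inherits(ch, "collapsed_hypnogram"),
            inherits(act, "activity_series"))
  if (abs(as.numeric(difftime(ch$lights_off, act$start, units = "secs"))) > 1e-6)
    stop(sprintf("alignment anchors differ: PSG lights-off %s vs activity start %s",
                 format_iso8601(ch$lights_off), format_iso8601(act$start)),
         call. = FALSE)
  n_psg <- length(ch$sw)
  n_act <- length(act$counts)
  d <- abs(n_psg - n_act)
  if (d > tolerance)
    stop(sprintf("PSG (%d epochs) and activity (%d epochs) lengths differ by %d (> tolerance %d)",
                 n_psg, n_act, d, tolerance), call. = FALSE)
  if (d > 0L)
    warning(sprintf("PSG (%d) and activity (%d) epoch counts differ; truncating to %d pairs",
                    n_psg, n_act, min(n_psg, n_act)), call. = FALSE)
  n <- min(n_psg, n_act)
  data.frame(epoch_index = seq_len(n) - 1L,
             sw = ch$sw[seq_len(n)],
             substage = ch$substage[seq_len(n)],
             count = act$counts[seq_len(n)],
             stringsAsFactors = FALSE)
}
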