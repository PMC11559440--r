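#' Consolidate a posture recording into one of five posture groups
#'
#' Every raw recording — a single code or a permutation of codes — maps to
#' exactly one of five groups by the following precedence:
#' \enumerate{
#'   \item any token with an \code{"S-"} prefix (a self-report) →
#'     \code{UserDefined};
#'   \item any \code{UNK} token, or a blank recording → \code{Unknown};
#'   \item all tokens among the lying codes \code{LSP,LPR,LRS,LLS} →
#'     \code{Lying};
#'   \item any \code{U90} or \code{WLK} → \code{Upright};
#'   \item any \code{U45} → \code{Reclined};
#'   \item anything else (e.g. \code{FALL} alone, or an unrecognized token)
#'     → \code{Unknown}, counted in the \code{"n_unrecognized"} attribute.
#' }
#' Walking is folded into Upright because the device may label walking as
#' \code{U90}; self-reports are kept apart because their intent cannot be
#' verified.
#'
#' @param tokens character vector of upper-cased code tokens for one
#'   recording (as produced by [tokenize_recording()]).
#' @return A single group label, one of [posture_group_levels].
#' @examples
#' classify_recording(c("U45", "LSP", "WLK"))   # Upright
#' classify_recording(c("LSP", "LRS"))          # Lying
#' classify_recording(character(0))             # Unknown (blank recording)
#' @export
classify_recording <- function(tokens) {
  if (length(tokens) == 0L) return("Unknown")
  if (any(startsWith(tokens, "S-"))) return("UserDefined")
  if (any(tokens == "UNK")) return("Unknown")
  if (all(tokens %in% posture_codes$lying)) return("Lying")
  if (any(tokens %in% c("U90", "WLK"))) return("Upright")
  if (any(tokens == "U45")) return("Reclined")
  "Unknown"
}

#' Classify a vector of raw posture strings
#'
#' Vectorized consolidation: tokenizes and classifies each raw posture
#' string. Only unique strings are classified (raw recordings repeat
#' heavily), so this is fast on millions of rows. Strings that fall through
#' to Unknown by the catch-all rule (rule 6) are tallied in the
#' \code{"n_unrecognized"} attribute.
#'
#' @param posture_string character vector of raw posture strings.
#' @return character vector of group labels, same length as the input, with
#'   attribute \code{"n_unrecognized"}.
#' @export
classify_postures <- function(posture_string) {
  u <- unique(posture_string)
  toks <- lapply(strsplit(toupper(trimws(u)), "\\s+"), function(t) t[nzchar(t)])
  grp <- vapply(toks, classify_recording, character(1))
  # catch-all detection: Unknown without a UNK token and not blank
  fallthrough <- grp == "Unknown" &
    !vapply(toks, function(t) length(t) == 0L || any(t == "UNK"), logical(1))
  out <- grp[match(posture_string, u)]
  n_unrec <- sum(fallthrough[match(posture_string, u)])
  if (n_unrec > 0)
    warning(sprintf("%d recording(s) with unrecognized codes classified as Unknown",
                    n_unrec), call. = FALSE)
  structure(out, n_unrecognized = n_unrec)
}

#' Build per-patient posture group series from cleaned recordings
#'
#' Consolidates each cleaned recording into its posture group, producing one
#' ordered (timestamp, group) sequence per patient on the 15-second grid.
#' Requires cleaned input: one recording per (mrn, timestamp).
#'
#' @param recordings cleaned recordings table ([apply_exclusions()]).
#' @return A \code{data.table} with columns \code{mrn}, \code{timestamp},
#'   \code{group}, keyed and ordered by (mrn, timestamp).
#' @export
consolidate_recordings <- function(recordings) {
  dt <- data.table::as.data.table(recordings)
  if (anyDuplicated(dt[, .(mrn, timestamp)]))
    stop_config("consolidate_recordings expects cleaned input: duplicate (mrn, timestamp) found")
  out <- dt[, .(mrn, timestamp, group = as.character(suppressWarnings(classify_postures(posture))))]
  data.table::setorder(out, mrn, timestamp)
  out[]
}

# Core smoothing rule on one ordered run of group labels with grid-adjacency
# information. Single simultaneous pass over the INPUT values: position i is
# changed only when both neighbours are grid-adjacent (15 s away) and agree
# with each other but not with x[i]; ties (all three distinct) and
# boundaries are left unchanged.
smooth_values <- function(x, ts) {
  n <- length(x)
  if (n < 3L) return(x)
  dt_prev <- c(NA_real_, diff(as.numeric(ts)))
  i <- 2L:(n - 1L)
  adjacent <- dt_prev[i] == GRID_SECONDS & dt_prev[i + 1L] == GRID_SECONDS
  flip <- adjacent & x[i - 1L] == x[i + 1L] & x[i] != x[i - 1L]
  out <- x
  out[i][flip] <- x[i - 1L][flip]
  out
}

#' Majority-vote smoothing of a posture group series
#'
#' Removes single-timestamp noise: an isolated posture at one timestamp that
#' sits between two timestamps sharing a different posture. For each interior
#' timestamp whose neighbours are both exactly 15 seconds away, a majority
#' vote over the 3-window (the timestamp and its two neighbours) decides the
#' output; with no winner (all three different) the value is unchanged. The
#' vote reads the \emph{input} series throughout (a single simultaneous
#' pass — no iteration to a fixed point), analogous to a 3-point moving
#' window with the mode in place of the mean. Timestamps at the edge of a
#' contiguous run — including either side of a data gap — are never changed,
#' since voting across a gap would mix non-adjacent moments.
#'
#' @param series a group series (\code{mrn}, \code{timestamp}, \code{group}),
#'   e.g. from [consolidate_recordings()]; one or many patients.
#' @return The series with the same rows, timestamps and gap structure, and
#'   smoothed \code{group} values.
#' @examples
#' ts <- as.POSIXct("2019-03-01 08:00:00", tz = "UTC") + 15 * (0:2)
#' s <- data.frame(mrn = "P1", timestamp = ts,
#'                 group = c("Lying", "Reclined", "Lying"))
#' smooth_majority_vote(s)$group   # middle Reclined is noise -> Lying
#' @export
smooth_majority_vote <- function(series) {
  dt <- data.table::as.data.table(series)
  data.table::setorder(dt, mrn, timestamp)
  dt[, group := smooth_values(group, timestamp), by = mrn]
  dt[]
}
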