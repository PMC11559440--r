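#' Tokenize a raw posture string
#'
#' Splits a posture recording string into its code tokens. A recording may be
#' a single code, a space-separated permutation of several codes (the monitor
#' emits one when the posture changed within the 15-second slot), or blank.
#' Tokens are upper-cased; order is preserved; a blank string yields an empty
#' token vector. Unknown tokens pass through untouched — classification into
#' posture groups decides what to do with them.
#'
#' @param posture_string character vector of raw posture strings.
#' @return For a single string, a character vector of tokens; for a vector of
#'   strings, a list of token vectors.
#' @examples
#' tokenize_recording("U45 U90")
#' tokenize_recording("  s-u90 ")
#' tokenize_recording("")
#' @export
tokenize_recording <- function(posture_string) {
  toks <- lapply(strsplit(toupper(trimws(posture_string)), "\\s+"),
                 function(t) t[nzchar(t)])
  if (length(posture_string) == 1L) toks[[1]] else toks
}

recordings_columns <- c("mrn", "file_id", "device_serial", "timestamp", "posture")
admissions_columns <- c("mrn", "admit_time", "discharge_time", "age", "sex")

#' Read a posture recordings table
#'
#' Reads one or more CSV files in the canonical recordings dialect
#' (UTF-8, comma-separated, header \code{mrn,file_id,device_serial,timestamp,
#' posture}, ISO-8601 timestamps at 1-second resolution). Timestamps must lie
#' on the 15-second recording grid (seconds 0, 15, 30 or 45). Off-grid rows
#' are rejected and reported in strict mode (the default), or snapped to the
#' nearest grid point in lenient mode. Rows are ordered by patient then
#' timestamp; ties keep file order. No row is silently dropped: input rows =
#' parsed rows + reported rejected rows.
#'
#' @param path character vector of file paths (a patient's data may span
#'   several files; all are read and concatenated).
#' @param lenient logical; snap off-grid timestamps instead of rejecting.
#' @return A \code{data.table} with columns \code{mrn}, \code{file_id},
#'   \code{device_serial}, \code{timestamp} (POSIXct) and \code{posture}.
#'   The attribute \code{"rejected"} holds the rejected rows (with a
#'   \code{reason} column); \code{"n_snapped"} counts lenient-mode snaps.
#' @export
read_recordings <- function(path, lenient = FALSE) {
  stopifnot(length(path) >= 1L, all(file.exists(path)))
  parts <- lapply(path, function(p) {
    dt <- data.table::fread(p, colClasses = "character", na.strings = NULL)
    if (!identical(names(dt), recordings_columns))
      stop_config("schema error in %s: expected columns %s, got %s", p,
                  paste(recordings_columns, collapse = ","),
                  paste(names(dt), collapse = ","))
    dt[, src_row := seq_len(.N)]
    dt[, src_file := p]
    dt
  })
  dt <- data.table::rbindlist(parts)
  ts <- parse_timestamp(dt$timestamp)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))
    stop_config("parse error: malformed timestamp %s (file %s, row %d)",
                dt$timestamp[bad[1]], dt$src_file[bad[1]], dt$src_row[bad[1]])
  }
  blank <- !nzchar(dt$mrn) | !nzchar(dt$file_id) | !nzchar(dt$device_serial)
  if (any(blank))
    stop_config("schema error: blank mrn/file_id/device_serial at %s row %d",
                dt$src_file[which(blank)[1]], dt$src_row[which(blank)[1]])
  dt[, timestamp := ts]
  n_snapped <- 0L
  off <- !on_grid(dt$timestamp)
  rejected <- dt[0]
  if (any(off)) {
    if (lenient) {
      dt[off, timestamp := snap_to_grid(timestamp)]
      n_snapped <- sum(off)
      message(sprintf("read_recordings: snapped %d off-grid timestamp(s)", n_snapped))
    } else {
      rejected <- dt[off]
      message(sprintf("read_recordings: rejected %d off-grid row(s)", sum(off)))
      dt <- dt[!off]
    }
  }
  data.table::setorder(dt, mrn, timestamp, src_file, src_row)
  dt[, c("src_row", "src_file") := NULL]
  rejected[, reason := rep("off-grid timestamp", .N)]
  data.table::setattr(dt, "rejected", rejected[])
  data.table::setattr(dt, "n_snapped", n_snapped)
  dt[]
}

#' Read an admissions table
#'
#' Reads the canonical admissions CSV (\code{mrn,admit_time,discharge_time,
#' age,sex}). One row per patient; a duplicated MRN is a schema error, and a
#' row with admit time at or after discharge time is a validation error. Age
#' may be missing; sex is normalized to \code{male}/\code{female}/
#' \code{unknown}.
#'
#' @param path path to the admissions CSV.
#' @return A \code{data.table} with columns \code{mrn}, \code{admit_time},
#'   \code{discharge_time} (POSIXct), \code{age} (numeric, may be NA) and
#'   \code{sex}.
#' @export
read_admissions <- function(path) {
  stopifnot(file.exists(path))
  dt <- data.table::fread(path, colClasses = "character", na.strings = NULL)
  if (!identical(names(dt), admissions_columns))
    stop_config("schema error in %s: expected columns %s", path,
                paste(admissions_columns, collapse = ","))
  if (anyDuplicated(dt$mrn))
    stop_config("schema error: duplicate MRN %s", dt$mrn[duplicated(dt$mrn)][1])
  adm <- parse_timestamp(dt$admit_time)
  dis <- parse_timestamp(dt$discharge_time)
  if (anyNA(adm) || anyNA(dis))
    stop_config("parse error: malformed admit/discharge time in %s", path)
  if (any(adm >= dis))
    stop_config("validation error: admit_time >= discharge_time for MRN %s",
                dt$mrn[which(adm >= dis)[1]])
  sex <- tolower(trimws(dt$sex))
  sex[!sex %in% c("male", "female")] <- "unknown"
  out <- data.table::data.table(
    mrn = dt$mrn, admit_time = adm, discharge_time = dis,
    age = suppressWarnings(as.numeric(dt$age)), sex = sex)
  out[]
}

#' Write recordings / admissions tables
#'
#' Serialize tables in the canonical CSV dialects read back by
#' [read_recordings()] and [read_admissions()]; the write/read round trip is
#' the identity on all fields.
#'
#' @param recordings,admissions tables as returned by the readers.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_recordings <- function(recordings, path) {
  out <- data.table::as.data.table(recordings)[, .(
    mrn, file_id, device_serial,
    timestamp = format_timestamp(timestamp), posture)]
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_recordings
#' @export
write_admissions <- function(admissions, path) {
  out <- data.table::as.data.table(admissions)[, .(
    mrn, admit_time = format_timestamp(admit_time),
    discharge_time = format_timestamp(discharge_time), age, sex)]
  data.table::fwrite(out, path)
  invisible(path)
}
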