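#' Flag recordings outside the admission window
#'
#' A recording is time-inconsistent when its timestamp falls strictly before
#' the patient's admission time or strictly after the discharge time.
#' Boundary timestamps (exactly at admit or discharge) are kept: recorded
#' admit/discharge times are not exact, so the benign reading is inclusive.
#' Patients with no admission record cannot be checked at all; every one of
#' their recordings is flagged and their MRNs are reported in the
#' \code{"missing_admission_mrns"} attribute.
#'
#' @param recordings recordings table ([read_recordings()]).
#' @param admissions admissions table ([read_admissions()]).
#' @return logical vector, one flag per recording row (TRUE = inconsistent).
#' @export
flag_inconsistent <- function(recordings, admissions) {
  rec <- data.table::as.data.table(recordings)
  adm <- data.table::as.data.table(admissions)
  idx <- match(rec$mrn, adm$mrn)
  missing <- is.na(idx)
  flag <- rep(TRUE, nrow(rec))
  ok <- !missing
  flag[ok] <- rec$timestamp[ok] < adm$admit_time[idx[ok]] |
    rec$timestamp[ok] > adm$discharge_time[idx[ok]]
  missing_mrns <- sort(unique(rec$mrn[missing]))
  if (length(missing_mrns) > 0)
    message(sprintf("flag_inconsistent: %d patient(s) with no admission record excluded entirely",
                    length(missing_mrns)))
  structure(flag, missing_admission_mrns = missing_mrns)
}

#' Flag overlapping recordings
#'
#' The overlap problem: two or more recordings under one patient at the same
#' timestamp with different readings (typically different devices or files),
#' indicating data misassigned from another patient. There is no objective
#' way to tell which stream is correct, so \emph{all} recordings at a
#' collided (mrn, timestamp) are flagged for exclusion. Exact duplicate rows
#' (all five fields equal — e.g. a re-exported file) carry no ambiguity and
#' are marked \code{"duplicate"} instead: all copies beyond the first are
#' dropped, the surviving copy is not flagged.
#'
#' @param recordings recordings table.
#' @return character vector, one status per row: \code{"keep"},
#'   \code{"duplicate"} (redundant exact copy, to drop silently) or
#'   \code{"overlap"} (collision, to exclude and count).
#' @export
flag_overlap <- function(recordings) {
  rec <- data.table::as.data.table(recordings)
  status <- rep("keep", nrow(rec))
  dup <- duplicated(rec[, .(mrn, file_id, device_serial, timestamp, posture)])
  status[dup] <- "duplicate"
  # collisions among surviving rows
  key <- paste(rec$mrn, as.numeric(rec$timestamp))
  tab <- table(key[!dup])
  collided <- names(tab)[tab >= 2L]
  status[!dup & key %in% collided] <- "overlap"
  status
}

#' Apply the two-stage exclusion and account for every row
#'
#' Cleaning has two stages in fixed order: (1) exclusion of time-inconsistent
#' recordings (outside the admission window, plus whole patients lacking an
#' admission record), then (2) de-duplication of exact copies and exclusion
#' of overlap collisions. Patients left with zero recordings after a stage
#' are removed from the cohort. The report accounts for every input row:
#' recordings_in = recordings_out + excluded (+ deduplicated) at each stage.
#'
#' @param recordings recordings table.
#' @param admissions admissions table.
#' @return list with \code{recordings} (the cleaned table, unique per
#'   (mrn, timestamp), all within admission windows) and \code{report}
#'   (a \code{cleaning_report}: stage-wise patient/recording counts and the
#'   overall percentages excluded).
#' @export
apply_exclusions <- function(recordings, admissions) {
  rec <- data.table::as.data.table(recordings)
  patients_in <- data.table::uniqueN(rec$mrn)
  recordings_in <- nrow(rec)

  inc <- flag_inconsistent(rec, admissions)
  s1 <- rec[!inc]
  stage1 <- list(patients_in = patients_in, recordings_in = recordings_in,
                 patients_out = data.table::uniqueN(s1$mrn),
                 recordings_out = nrow(s1),
                 recordings_excluded = sum(inc))

  ov <- flag_overlap(s1)
  s2 <- s1[ov == "keep"]
  stage2 <- list(patients_in = stage1$patients_out,
                 recordings_in = stage1$recordings_out,
                 patients_out = data.table::uniqueN(s2$mrn),
                 recordings_out = nrow(s2),
                 recordings_deduplicated = sum(ov == "duplicate"),
                 recordings_excluded = sum(ov == "overlap"))

  report <- structure(list(
    inconsistency = stage1, overlap = stage2,
    patients_excluded = patients_in - stage2$patients_out,
    recordings_excluded = recordings_in - stage2$recordings_out,
    pct_patients_excluded =
      100 * (patients_in - stage2$patients_out) / max(patients_in, 1L),
    pct_recordings_excluded =
      100 * (recordings_in - stage2$recordings_out) / max(recordings_in, 1L)
  ), class = "cleaning_report")

  data.table::setorder(s2, mrn, timestamp)
  list(recordings = s2[], report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Data cleaning flow\n")
  cat(sprintf("  input:                %d patients, %d recordings\n",
              x$inconsistency$patients_in, x$inconsistency$recordings_in))
  cat(sprintf("  after inconsistency:  %d patients, %d recordings (%d excluded)\n",
              x$inconsistency$patients_out, x$inconsistency$recordings_out,
              x$inconsistency$recordings_excluded))
  cat(sprintf("  after overlap:        %d patients, %d recordings (%d excluded, %d deduplicated)\n",
              x$overlap$patients_out, x$overlap$recordings_out,
              x$overlap$recordings_excluded, x$overlap$recordings_deduplicated))
  cat(sprintf("  overall excluded:     %.1f%% of patients, %.1f%% of recordings\n",
              x$pct_patients_excluded, x$pct_recordings_excluded))
  invisible(x)
}
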