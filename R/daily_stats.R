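#' Split a posture group series into patient-days
#'
#' One patient-day per calendar date (local midnight boundary) with at least
#' one recording. "Hours of data" is recording-count based: n recordings
#' times 15 seconds, so a day qualifies as an analysis day — at least 22
#' hours of recordings — exactly when it has at least 5280 recordings.
#' Total days counts every date with any recording, however short; analysis
#' days are the only days used for duration and transition statistics.
#'
#' @param series group series (\code{mrn}, \code{timestamp}, \code{group}).
#' @param threshold_hours minimum hours of recordings for an analysis day
#'   (default 22).
#' @return \code{data.table}: \code{mrn}, \code{date}, \code{n_recordings},
#'   \code{hours_of_data}, \code{is_analysis_day}.
#' @export
split_days <- function(series, threshold_hours = 22) {
  dt <- data.table::as.data.table(series)
  if (nrow(dt) == 0L)
    return(data.table::data.table(mrn = character(), date = as.Date(character()),
                                  n_recordings = integer(), hours_of_data = numeric(),
                                  is_analysis_day = logical()))
  days <- dt[, .(n_recordings = .N), by = .(mrn, date = local_date(timestamp))]
  days[, hours_of_data := n_recordings * GRID_SECONDS / 3600]
  days[, is_analysis_day := hours_of_data >= threshold_hours]
  data.table::setorder(days, mrn, date)
  days[]
}

#' Count posture transitions in a series slice
#'
#' A transition is a change of posture group between two grid-adjacent
#' recordings (15 seconds apart), restricted to the three physical groups
#' Lying, Reclined and Upright (6 ordered transition types). Pairs involving
#' Unknown or UserDefined, and pairs spanning a data gap, are not counted —
#' whether a physical transition happened there is unknowable.
#'
#' @param group character vector of group labels, in time order.
#' @param timestamp POSIXct vector aligned with \code{group}.
#' @return integer transition count.
#' @export
transition_count <- function(group, timestamp) {
  n <- length(group)
  if (n < 2L) return(0L)
  i <- 1L:(n - 1L)
  phys <- c("Lying", "Reclined", "Upright")
  adjacent <- diff(as.numeric(timestamp)) == GRID_SECONDS
  sum(adjacent & group[i] %in% phys & group[i + 1L] %in% phys &
        group[i] != group[i + 1L])
}

# Per (patient, analysis day, window) building block: recordings per group,
# hours of data and transition count, for window in {WD, DT, NT}.
# A transition pair belongs to a day only if both endpoints share the date,
# and to DT/NT only if both endpoints fall in that window; pairs spanning
# midnight or the 07:00/19:00 boundaries are attributed to no window.
day_window_stats <- function(series, threshold_hours = 22) {
  dt <- data.table::as.data.table(series)
  data.table::setorder(dt, mrn, timestamp)
  dt[, date := local_date(timestamp)]
  dt[, is_dt := in_daytime(timestamp)]
  days <- split_days(dt, threshold_hours)
  dt <- dt[days[is_analysis_day == TRUE], on = c("mrn", "date"), nomatch = NULL]

  counts <- list(
    WD = dt[, .(n = .N), by = .(mrn, date, group)],
    DT = dt[is_dt == TRUE, .(n = .N), by = .(mrn, date, group)],
    NT = dt[is_dt == FALSE, .(n = .N), by = .(mrn, date, group)]
  )

  # adjacent-pair transitions
  phys <- c("Lying", "Reclined", "Upright")
  dt[, `:=`(nxt_ts = data.table::shift(timestamp, -1L),
            nxt_group = data.table::shift(group, -1L),
            nxt_date = data.table::shift(date, -1L),
            nxt_is_dt = data.table::shift(is_dt, -1L)), by = mrn]
  dt[, pair_valid := !is.na(nxt_ts) &
       as.numeric(nxt_ts) - as.numeric(timestamp) == GRID_SECONDS &
       date == nxt_date & group %in% phys & nxt_group %in% phys &
       group != nxt_group]
  trans <- list(
    WD = dt[pair_valid == TRUE, .(n_trans = .N), by = .(mrn, date)],
    DT = dt[pair_valid & is_dt & nxt_is_dt, .(n_trans = .N), by = .(mrn, date)],
    NT = dt[pair_valid & !is_dt & !nxt_is_dt, .(n_trans = .N), by = .(mrn, date)]
  )

  list(days = days, counts = counts, trans = trans)
}

window_scale <- c(WD = 24, DT = 12, NT = 12)

# average-then-scale duration rule for one window
window_durations <- function(counts_w, scale) {
  if (nrow(counts_w) == 0L)
    return(data.table::data.table(mrn = character(), group = character(),
                                  hours = numeric()))
  tot <- counts_w[, .(day_total = sum(n)), by = .(mrn, date)]
  # complete the group axis with zeros so every analysis day contributes a
  # proportion (possibly 0) to every group's average
  grid <- tot[, .(group = posture_group_levels), by = .(mrn, date, day_total)]
  full <- merge(grid, counts_w, by = c("mrn", "date", "group"), all.x = TRUE)
  full[is.na(n), n := 0L]
  full[, prop := n / day_total]
  full[, .(hours = scale * mean(prop)), by = .(mrn, group)]
}

#' Posture duration statistics
#'
#' For each patient with at least one analysis day, the average time per day
#' spent in each of the five posture groups, for one of three windows:
#' whole day (\code{WD}), daytime (\code{DT}, 07:00:00-18:59:45 local) or
#' nighttime (\code{NT}, the complementary 12 hours). On each analysis day
#' the proportion of the window's recordings in each group is computed;
#' proportions are averaged across the patient's analysis days and scaled by
#' 24 (WD) or 12 (DT/NT) hours. Analysis days with no recordings at all in
#' the requested window are omitted from that window's average.
#'
#' @param series group series.
#' @param window one of \code{"WD"}, \code{"DT"}, \code{"NT"}.
#' @param threshold_hours analysis-day threshold (hours, default 22).
#' @return \code{data.table}: \code{mrn}, \code{group}, \code{hours}.
#' @export
duration_stats <- function(series, window = c("WD", "DT", "NT"),
                           threshold_hours = 22) {
  window <- match.arg(window)
  parts <- day_window_stats(series, threshold_hours)
  window_durations(parts$counts[[window]], window_scale[[window]])
}

#' Frequency of posture transitions (FPT)
#'
#' Transitions per hour among Lying, Reclined and Upright, for one window.
#' On each analysis day the transition count in the window is divided by the
#' actual hours of data in that window (recordings x 15 s); the per-day
#' rates are averaged across the patient's analysis days. Days with zero
#' hours of data in the window are omitted from that window's average.
#'
#' @inheritParams duration_stats
#' @return \code{data.table}: \code{mrn}, \code{fpt} (transitions per hour).
#' @export
fpt_stats <- function(series, window = c("WD", "DT", "NT"),
                      threshold_hours = 22) {
  window <- match.arg(window)
  parts <- day_window_stats(series, threshold_hours)
  fpt_from_parts(parts, window)
}

fpt_from_parts <- function(parts, window) {
  hours <- parts$counts[[window]][, .(hours_data = sum(n) * GRID_SECONDS / 3600),
                                  by = .(mrn, date)]
  if (nrow(hours) == 0L)
    return(data.table::data.table(mrn = character(), fpt = numeric()))
  tr <- parts$trans[[window]]
  day_rates <- merge(hours, tr, by = c("mrn", "date"), all.x = TRUE)
  day_rates[is.na(n_trans), n_trans := 0L]
  day_rates[, .(fpt = mean(n_trans / hours_data)), by = mrn]
}

#' Per-patient summary statistics
#'
#' Assembles the full per-patient summary: the data-quantity measures
#' (\code{total_days}, \code{analysis_days}), the 15 posture duration
#' statistics (five groups x WD/DT/NT), the three transition-frequency
#' statistics (\code{FPT-WD}, \code{FPT-DT}, \code{FPT-NT}) and the derived
#' Rest quantities (\code{Rest-DT}, \code{Rest-NT}; Rest = Lying +
#' Reclined). Patients with no analysis day are excluded; their number is in
#' the \code{"n_excluded_no_analysis_days"} attribute.
#'
#' @inheritParams duration_stats
#' @return one row per retained patient; duration/FPT columns are named
#'   \code{Lying-WD}, ..., \code{FPT-NT} (backtick to access).
#' @export
patient_summaries <- function(series, threshold_hours = 22) {
  parts <- day_window_stats(series, threshold_hours)
  days <- parts$days
  quantity <- days[, .(total_days = .N, analysis_days = sum(is_analysis_day)),
                   by = mrn]
  retained <- quantity[analysis_days >= 1L]
  out <- retained
  for (w in c("WD", "DT", "NT")) {
    dur <- window_durations(parts$counts[[w]], window_scale[[w]])
    wide <- data.table::dcast(dur, mrn ~ group, value.var = "hours", fill = 0)
    miss <- setdiff(posture_group_levels, names(wide))
    for (m in miss) wide[, (m) := 0]
    data.table::setnames(wide, posture_group_levels,
                         paste0(posture_group_levels, "-", w))
    out <- merge(out, wide, by = "mrn", all.x = TRUE)
    fpt <- fpt_from_parts(parts, w)
    data.table::setnames(fpt, "fpt", paste0("FPT-", w))
    out <- merge(out, fpt, by = "mrn", all.x = TRUE)
  }
  out[, `Rest-DT` := `Lying-DT` + `Reclined-DT`]
  out[, `Rest-NT` := `Lying-NT` + `Reclined-NT`]
  data.table::setcolorder(out, c(
    "mrn", "total_days", "analysis_days",
    unlist(lapply(c("WD", "DT", "NT"),
                  function(w) paste0(c(posture_group_levels, "FPT"), "-", w))),
    "Rest-DT", "Rest-NT"))
  data.table::setorder(out, mrn)
  n_excl <- nrow(quantity) - nrow(retained)
  if (n_excl > 0)
    message(sprintf("patient_summaries: %d patient(s) with no analysis day excluded", n_excl))
  data.table::setattr(out, "n_excluded_no_analysis_days", n_excl)
  out[]
}

#' Regression of analysis days on total days
#'
#' Ordinary least squares fit of per-patient analysis days against total
#' days, plus the medians of both data-quantity measures.
#'
#' @param summaries output of [patient_summaries()] (needs
#'   \code{total_days}, \code{analysis_days}).
#' @return list: \code{intercept}, \code{slope}, \code{median_total_days},
#'   \code{median_analysis_days}, and the fitted \code{model}.
#' @export
quantity_regression <- function(summaries) {
  s <- data.table::as.data.table(summaries)
  if (nrow(s) < 2L || data.table::uniqueN(s$total_days) < 2L)
    stop_config("quantity_regression needs >= 2 patients with distinct total_days")
  fit <- lm(analysis_days ~ total_days, data = s)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       median_total_days = median(s$total_days),
       median_analysis_days = median(s$analysis_days),
       model = fit)
}
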