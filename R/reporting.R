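#' Histogram table for a summary statistic
#'
#' Fixed-width bins from 0; the bin counts always sum to the number of
#' patients. Default widths follow the reporting conventions of the
#' pipeline: 2-hour bins for whole-day durations, 1-hour for daytime /
#' nighttime durations, 1 transition-per-hour for FPT.
#'
#' @param x numeric vector.
#' @param binwidth bin width.
#' @param xmax upper edge of the last bin (default: cover the data).
#' @return \code{data.table}: \code{lo}, \code{hi}, \code{n}, \code{pct}.
#' @export
histogram_table <- function(x, binwidth = 2, xmax = NULL) {
  xmax <- xmax %||% (ceiling(max(x, 0) / binwidth) * binwidth)
  edges <- seq(0, max(xmax, binwidth), by = binwidth)
  if (max(x) >= edges[length(edges)]) edges <- c(edges, max(x) + binwidth)
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  n <- tabulate(idx, nbins = length(edges) - 1L)
  data.table::data.table(lo = edges[-length(edges)], hi = edges[-1],
                         n = n, pct = 100 * n / length(x))
}

#' Cohort-level report tables
#'
#' Builds the descriptive outputs of the pipeline: demographics (age
#' mean/SD and median/IQR; sex counts and percentages) before and after
#' exclusion, the median/IQR quartile table of every per-patient summary
#' statistic, histogram tables for the duration and FPT statistics, and the
#' daytime/nighttime scatter exports (Lying vs Reclined, Upright vs Rest)
#' with their 12-hour cap \code{Lying + Reclined <= 12}.
#'
#' @param summaries [patient_summaries()] output (the retained patients).
#' @param admissions full admissions table (the pre-exclusion cohort).
#' @return list: \code{demographics}, \code{quartiles}, \code{histograms},
#'   \code{scatter}.
#' @export
cohort_report <- function(summaries, admissions) {
  s <- data.table::as.data.table(summaries)
  adm <- data.table::as.data.table(admissions)
  demo <- function(a) {
    sex_n <- table(factor(a$sex, levels = c("male", "female", "unknown")))
    list(n = nrow(a),
         age_mean = mean(a$age, na.rm = TRUE), age_sd = sd(a$age, na.rm = TRUE),
         age_median = median(a$age, na.rm = TRUE),
         age_iqr = unname(quantile(a$age, c(.25, .75), na.rm = TRUE)),
         sex_n = as.integer(sex_n),
         sex_pct = round(100 * as.integer(sex_n) / max(nrow(a), 1L), 1))
  }
  demographics <- list(before = demo(adm),
                       after = demo(adm[mrn %in% s$mrn]))

  stat_cols <- setdiff(names(s), "mrn")
  quartiles <- data.table::rbindlist(lapply(stat_cols, function(col) {
    q <- quantile(s[[col]], c(.25, .5, .75), na.rm = TRUE)
    data.table::data.table(statistic = col, median = q[2], q1 = q[1], q3 = q[3])
  }))

  histograms <- list()
  for (g in c("Lying", "Reclined", "Upright", "Unknown")) {
    histograms[[paste0(g, "-WD")]] <- histogram_table(s[[paste0(g, "-WD")]], 2, 24)
    histograms[[paste0(g, "-DT")]] <- histogram_table(s[[paste0(g, "-DT")]], 1, 12)
    histograms[[paste0(g, "-NT")]] <- histogram_table(s[[paste0(g, "-NT")]], 1, 12)
  }
  for (w in c("WD", "DT", "NT"))
    histograms[[paste0("FPT-", w)]] <- histogram_table(s[[paste0("FPT-", w)]], 1)
  histograms[["total_days"]] <- histogram_table(as.numeric(s$total_days), 1)
  histograms[["analysis_days"]] <- histogram_table(as.numeric(s$analysis_days), 1)

  scatter <- list(
    dt = s[, .(mrn, lying = `Lying-DT`, reclined = `Reclined-DT`,
               upright = `Upright-DT`, rest = `Rest-DT`)],
    nt = s[, .(mrn, lying = `Lying-NT`, reclined = `Reclined-NT`,
               upright = `Upright-NT`, rest = `Rest-NT`)],
    cap_hours = 12)

  list(demographics = demographics, quartiles = quartiles,
       histograms = histograms, scatter = scatter)
}

#' Nurse-labor savings of continuous posture monitoring
#'
#' Direct observation requires a fixed number of nurse-hours per
#' patient-day (2 hours at a 30-minute observation frequency); continuous
#' monitoring makes those hours unnecessary. Hours saved = patient-days x
#' hours per patient-day; cost saved = hours x hourly wage, rounded to the
#' nearest currency unit.
#'
#' @param patient_days number of monitored patient-days.
#' @param hours_per_patient_day nurse-hours replaced per patient-day
#'   (default 2).
#' @param wage hourly wage (default 41.38, a median registered-nurse rate).
#' @return list: \code{hours_saved}, \code{cost_saved}.
#' @examples
#' labor_savings(4847, 2, 41.38)   # $401,138 over 9694 hours
#' @export
labor_savings <- function(patient_days, hours_per_patient_day = 2, wage = 41.38) {
  if (patient_days < 0 || hours_per_patient_day < 0 || wage < 0)
    stop_config("labor_savings inputs must be nonnegative")
  hours <- patient_days * hours_per_patient_day
  list(hours_saved = hours, cost_saved = round(hours * wage))
}

#' Run the full pipeline
#'
#' Ingest, clean, consolidate, smooth, summarize, cluster — in that order —
#' with per-stage counts collected along the way. Inputs can be in-memory
#' tables or file paths.
#'
#' @param recordings recordings table, or path(s) to recordings CSV(s).
#' @param admissions admissions table, or path to the admissions CSV.
#' @param threshold_hours analysis-day threshold (default 22).
#' @param cluster_sets feature sets to cluster (subset of
#'   \code{c("wd","dt","nt","combined")}); empty to skip clustering.
#' @param k_range,restarts,seed passed to [fit_kmeans_select()].
#' @param out_dir optional directory; when given, stage outputs are written
#'   as CSV/JSON.
#' @return list: \code{clean} (recordings), \code{report} (cleaning flow),
#'   \code{series} (smoothed group series), \code{summaries},
#'   \code{regression}, \code{clusters} (one \code{cluster_result} +
#'   table per set), \code{cohort_tables}, \code{counts}.
#' @export
run_pipeline <- function(recordings, admissions, threshold_hours = 22,
                         cluster_sets = c("wd", "dt", "nt", "combined"),
                         k_range = 2:10, restarts = 50, seed = 1L,
                         out_dir = NULL) {
  if (is.character(recordings)) recordings <- read_recordings(recordings)
  if (is.character(admissions)) admissions <- read_admissions(admissions)
  counts <- list(recordings_in = nrow(recordings),
                 patients_in = data.table::uniqueN(recordings$mrn))

  cleaned <- apply_exclusions(recordings, admissions)
  series <- smooth_majority_vote(consolidate_recordings(cleaned$recordings))
  summaries <- patient_summaries(series, threshold_hours)
  counts$patients_clean <- data.table::uniqueN(series$mrn)
  counts$recordings_clean <- nrow(series)
  counts$patients_retained <- nrow(summaries)

  regression <- if (nrow(summaries) >= 2L &&
                    data.table::uniqueN(summaries$total_days) >= 2L)
    quantity_regression(summaries) else NULL

  clusters <- list()
  for (set in cluster_sets) {
    fm <- feature_matrix(summaries, set)
    if (nrow(fm) > min(k_range)) {
      res <- fit_kmeans_select(fm, k_range = k_range, restarts = restarts,
                               seed = seed)
      clusters[[set]] <- list(result = res, table = cluster_table(res, fm))
    }
  }

  tables <- cohort_report(summaries, admissions)
  bundle <- list(clean = cleaned$recordings, report = cleaned$report,
                 series = series, summaries = summaries,
                 regression = regression, clusters = clusters,
                 cohort_tables = tables, counts = counts)
  if (!is.null(out_dir)) write_pipeline_outputs(bundle, out_dir)
  bundle
}

write_pipeline_outputs <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_recordings(bundle$clean, file.path(out_dir, "clean.csv"))
  g <- data.table::as.data.table(bundle$series)
  g[, timestamp := format_timestamp(timestamp)]
  data.table::fwrite(g, file.path(out_dir, "groups.csv"))
  data.table::fwrite(bundle$summaries, file.path(out_dir, "summaries.csv"))
  flow <- unclass(bundle$report)
  jsonlite::write_json(flow, file.path(out_dir, "flow.json"), auto_unbox = TRUE,
                       digits = NA)
  data.table::fwrite(bundle$cohort_tables$quartiles,
                     file.path(out_dir, "quartiles.csv"))
  for (set in names(bundle$clusters)) {
    res <- bundle$clusters[[set]]$result
    data.table::fwrite(data.table::data.table(mrn = names(res$assignment),
                                              cluster = res$assignment),
                       file.path(out_dir, sprintf("clusters_%s.csv", set)))
    tab <- bundle$clusters[[set]]$table
    data.table::fwrite(data.table::data.table(cluster = rownames(tab), tab),
                       file.path(out_dir, sprintf("cluster_table_%s.csv", set)))
  }
  invisible(out_dir)
}
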