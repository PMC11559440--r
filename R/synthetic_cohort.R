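#' Define a posture-habit archetype
#'
#' An archetype is a generative stand-in for one patient subtype: a pair of
#' posture-group weight vectors (daytime and nighttime, over Lying /
#' Reclined / Upright / Unknown), a mean bout length governing how long a
#' posture is held, and a noise rate for isolated single-timestamp flips.
#' Bouts are drawn independently — group from the window-appropriate weight
#' vector, length 1 + Geometric so the mean equals \code{mean_bout_len} —
#' which makes the stationary time share of each group equal its weight.
#'
#' @param name archetype label.
#' @param daytime_group_weights,nighttime_group_weights numeric length-4
#'   (Lying, Reclined, Upright, Unknown), nonnegative, summing to 1.
#' @param mean_bout_len expected consecutive recordings per bout (>= 1).
#' @param noise_rate per-interior-timestamp probability of an isolated flip
#'   to a uniformly random different group, in [0, 0.2].
#' @param perm_rate probability that a within-window bout boundary slot is
#'   emitted as a 2-code permutation string ("old new").
#' @param long_perm_rate per-slot probability of a 3+-code permutation that
#'   still classifies to the slot's group (tokenizer exercise).
#' @param selfreport_rate per-bout probability of a short (2-slot)
#'   self-reported posture episode ("S-" codes, the UserDefined group).
#' @return an \code{archetype_spec} list.
#' @export
archetype_spec <- function(name, daytime_group_weights, nighttime_group_weights,
                           mean_bout_len, noise_rate = 0,
                           perm_rate = 0.3, long_perm_rate = 0.002,
                           selfreport_rate = 0) {
  check_w <- function(w, nm) {
    if (length(w) != 4L || any(w < 0) || abs(sum(w) - 1) > 1e-8)
      stop_config("%s must be 4 nonnegative weights summing to 1", nm)
  }
  check_w(daytime_group_weights, "daytime_group_weights")
  check_w(nighttime_group_weights, "nighttime_group_weights")
  if (mean_bout_len < 1) stop_config("mean_bout_len must be >= 1")
  if (noise_rate < 0 || noise_rate > 0.2)
    stop_config("noise_rate must be in [0, 0.2]")
  structure(list(
    name = name,
    daytime_group_weights = setNames(as.numeric(daytime_group_weights),
                                     c("Lying", "Reclined", "Upright", "Unknown")),
    nighttime_group_weights = setNames(as.numeric(nighttime_group_weights),
                                       c("Lying", "Reclined", "Upright", "Unknown")),
    mean_bout_len = mean_bout_len, noise_rate = noise_rate,
    perm_rate = perm_rate, long_perm_rate = long_perm_rate,
    selfreport_rate = selfreport_rate
  ), class = "archetype_spec")
}

#' Default posture-habit archetypes
#'
#' Four archetypes emulating the subtypes the whole-day cluster analysis is
#' designed to find: two sedentary resting styles (one preferring Lying, one
#' Reclined), an active subtype with more Upright time and more frequent
#' transitions, and a small subtype dominated by Unknown readings. The
#' whole-day time shares and relative sizes are chosen to resemble a typical
#' inpatient cohort; diurnal tilt concentrates Lying at night.
#'
#' @param noise_rate shared isolated-flip rate (default 0.01).
#' @return named list of four \code{archetype_spec}s with attribute
#'   \code{"mix"} (the default cohort proportions).
#' @export
default_archetypes <- function(noise_rate = 0.01) {
  a <- list(
    lying_rester = archetype_spec(
      "lying_rester",
      daytime_group_weights   = c(0.50, 0.30, 0.14, 0.06),
      nighttime_group_weights = c(0.88, 0.06, 0.02, 0.04),
      mean_bout_len = 96, noise_rate = noise_rate, selfreport_rate = 0.01),
    reclined_rester = archetype_spec(
      "reclined_rester",
      daytime_group_weights   = c(0.12, 0.62, 0.20, 0.06),
      nighttime_group_weights = c(0.32, 0.58, 0.05, 0.05),
      mean_bout_len = 90, noise_rate = noise_rate, selfreport_rate = 0.01),
    active = archetype_spec(
      "active",
      daytime_group_weights   = c(0.14, 0.33, 0.48, 0.05),
      nighttime_group_weights = c(0.38, 0.42, 0.15, 0.05),
      mean_bout_len = 40, noise_rate = noise_rate, selfreport_rate = 0.01),
    unknown_dominant = archetype_spec(
      "unknown_dominant",
      daytime_group_weights   = c(0.14, 0.14, 0.10, 0.62),
      nighttime_group_weights = c(0.15, 0.10, 0.03, 0.72),
      mean_bout_len = 90, noise_rate = noise_rate, selfreport_rate = 0.01)
  )
  attr(a, "mix") <- c(lying_rester = 0.42, reclined_rester = 0.32,
                      active = 0.23, unknown_dominant = 0.03)
  a
}

# one representative code per (group, bout); lying bouts pick one of the
# four lying codes, upright bouts mostly U90 with occasional WLK
sample_group_code <- function(groups) {
  n <- length(groups)
  code <- character(n)
  code[groups == "Lying"] <- sample(posture_codes$lying,
                                    sum(groups == "Lying"), replace = TRUE)
  code[groups == "Reclined"] <- "U45"
  code[groups == "Upright"] <- sample(c("U90", "WLK"), sum(groups == "Upright"),
                                      replace = TRUE, prob = c(0.8, 0.2))
  code[groups == "Unknown"] <- "UNK"
  code[groups == "UserDefined"] <- sample(posture_codes$self_reported,
                                          sum(groups == "UserDefined"),
                                          replace = TRUE)
  code
}

# a 3+-code permutation string that still classifies to the given group
long_perm_string <- function(group) {
  switch(group,
         Lying = "LSP LRS LLS",
         Reclined = "U45 LSP LPR",
         Upright = "U90 U45 WLK",
         Unknown = "UNK LSP U90",
         UserDefined = "UNK U90 U45 LLS S-U90")
}

#' Generate one patient's posture recording stream
#'
#' Simulates the 15-second recording stream of a single hospital stay:
#' bouts drawn per window (daytime/nighttime) from the archetype's weight
#' vectors with geometric lengths; a new bout starts at each 07:00/19:00
#' window switch; device serials change daily (each device is charged
#' daily) and the stream is split across several files; bout-boundary slots
#' may be emitted as 2-code permutation strings; occasional longer
#' permutations and short self-reported episodes exercise the tokenizer;
#' isolated single-timestamp flips are injected at the archetype's noise
#' rate, only at run-interior slots and never adjacent to one another (so a
#' 3-point majority vote provably reverts each one).
#'
#' @param archetype an [archetype_spec()].
#' @param n_days stay length in days (>= 1).
#' @param admit admission time (POSIXct, on the 15-s grid); recordings span
#'   \code{[admit, admit + n_days days)}.
#' @param mrn patient identifier.
#' @param seed optional integer seed.
#' @return list: \code{recordings} (raw recording table), \code{admission}
#'   (one admissions row), \code{truth} (per-recording ground truth:
#'   realized post-consolidation group and an \code{is_noise_flip} flag).
#' @export
generate_patient_series <- function(archetype, n_days, admit, mrn = "P1",
                                    seed = NULL) {
  stopifnot(inherits(archetype, "archetype_spec"), n_days >= 1)
  if (!is.null(seed)) set.seed(seed)
  admit <- as.POSIXct(admit, tz = TZ)
  if (!on_grid(admit)) stop_config("admit time must lie on the 15-s grid")
  n <- as.integer(n_days * RECORDINGS_PER_DAY)
  ts <- admit + GRID_SECONDS * (seq_len(n) - 1L)
  is_dt <- in_daytime(ts)

  # window segments: maximal runs with constant daytime flag
  seg_id <- cumsum(c(TRUE, diff(is_dt) != 0))
  seg_len <- tabulate(seg_id)
  p_geom <- 1 / archetype$mean_bout_len

  group <- character(n)
  bout_id <- integer(n)
  n_bouts_total <- 0L
  pos <- 1L
  for (s in seq_along(seg_len)) {
    len <- seg_len[s]
    w <- if (is_dt[pos]) archetype$daytime_group_weights else archetype$nighttime_group_weights
    filled <- 0L
    while (filled < len) {
      m <- max(8L, ceiling(2 * (len - filled) * p_geom))
      lens <- 1L + rgeom(m, p_geom)
      gs <- sample(names(w), m, replace = TRUE, prob = w)
      keep <- cumsum(lens) - lens < (len - filled)
      lens <- lens[keep]; gs <- gs[keep]
      total <- min(sum(lens), len - filled)
      idx <- pos + filled + seq_len(total) - 1L
      group[idx] <- rep(gs, lens)[seq_len(total)]
      bout_id[idx] <- n_bouts_total + rep(seq_along(lens), lens)[seq_len(total)]
      n_bouts_total <- n_bouts_total + length(lens)
      filled <- filled + total
    }
    pos <- pos + len
  }

  # short self-reported episodes (2 slots so smoothing cannot erase them)
  n_ud <- rgeom_pois(archetype$selfreport_rate * n_bouts_total)
  if (n_ud > 0 && n > 4L) {
    starts <- sample.int(n - 1L, n_ud)
    for (st in starts) group[st:(st + 1L)] <- "UserDefined"
  }

  # one representative code per bout, constant within the bout
  chg <- c(TRUE, group[-1] != group[-n])
  run_id <- cumsum(chg)
  run_groups <- group[chg]
  run_codes <- sample_group_code(run_groups)
  code <- run_codes[run_id]
  posture <- code

  # 2-code permutations at bout boundaries interior to a window
  bnd <- which(chg[-1]) + 1L               # first slot of each new run
  bnd <- bnd[is_dt[bnd] == is_dt[bnd - 1L]]
  if (length(bnd) > 0 && archetype$perm_rate > 0) {
    sel <- bnd[runif(length(bnd)) < archetype$perm_rate]
    posture[sel] <- paste(code[sel - 1L], code[sel])
  }

  # longer permutations, classification-invariant
  if (archetype$long_perm_rate > 0) {
    sel <- which(runif(n) < archetype$long_perm_rate)
    posture[sel] <- vapply(group[sel], long_perm_string, character(1))
  }

  # realized consolidated group (permutation slots can change group)
  realized <- as.character(classify_postures(posture))

  # isolated noise flips: only where the realized series is locally constant,
  # never two flips within 2 slots of each other
  is_flip <- rep(FALSE, n)
  if (archetype$noise_rate > 0 && n >= 3L) {
    i <- 2L:(n - 1L)
    eligible <- i[realized[i - 1L] == realized[i] & realized[i] == realized[i + 1L]]
    cand <- eligible[runif(length(eligible)) < archetype$noise_rate]
    if (length(cand) > 1L) {
      keep <- c(TRUE, diff(cand) > 2L)
      # greedy: drop any candidate within 2 slots of the previously kept one
      last <- cand[1]
      for (j in seq_along(cand)[-1]) {
        if (cand[j] - last > 2L) { keep[j] <- TRUE; last <- cand[j] }
        else keep[j] <- FALSE
      }
      cand <- cand[keep]
    }
    if (length(cand) > 0) {
      others <- lapply(realized[cand], function(g) setdiff(posture_group_levels, g))
      newg <- vapply(others, function(o) sample(o, 1L), character(1))
      posture[cand] <- sample_group_code(newg)
      realized[cand] <- newg
      is_flip[cand] <- TRUE
    }
  }

  day_idx <- as.integer(floor(as.numeric(ts - admit, units = "days"))) + 1L
  device_serial <- sprintf("D%s-%02d", mrn, day_idx)
  file_idx <- (day_idx - 1L) %/% 2L + 1L
  file_id <- sprintf("F%s-%d", mrn, file_idx)

  recordings <- data.table::data.table(
    mrn = mrn, file_id = file_id, device_serial = device_serial,
    timestamp = ts, posture = posture)
  discharge <- admit + n_days * 86400
  admission <- data.table::data.table(
    mrn = mrn, admit_time = admit, discharge_time = discharge,
    age = round(runif(1, 20, 95)),
    sex = sample(c("male", "female"), 1L))
  truth <- data.table::data.table(
    mrn = mrn, file_id = file_id, device_serial = device_serial,
    timestamp = ts, true_group = realized, is_noise_flip = is_flip,
    is_overlap_injected = FALSE, is_out_of_window = FALSE)
  list(recordings = recordings, admission = admission, truth = truth)
}

# Poisson draw helper with guard for rate 0
rgeom_pois <- function(lambda) if (lambda <= 0) 0L else stats::rpois(1L, lambda)

#' Cohort simulation configuration
#'
#' @param n_patients number of patients.
#' @param days_per_patient integer scalar or length-2 range (days sampled
#'   uniformly from the range).
#' @param archetypes named list of [archetype_spec()]s.
#' @param archetype_mix named probabilities per archetype (sums to 1).
#' @param frac_overlap_patients proportion of patients receiving injected
#'   record overlap (misassigned data from another patient).
#' @param frac_inconsistent_patients proportion receiving recordings outside
#'   their admission window.
#' @param frac_incomplete_days proportion of patient-days degraded below the
#'   22-hour analysis-day threshold by deleting a contiguous block.
#' @param start_date first possible admission date (admissions are at
#'   midnight so that day boundaries align with stays).
#' @param seed integer seed; all draws flow from it.
#' @return a \code{cohort_config} list.
#' @export
cohort_config <- function(n_patients = 50,
                          days_per_patient = c(2, 6),
                          archetypes = default_archetypes(),
                          archetype_mix = attr(default_archetypes(), "mix"),
                          frac_overlap_patients = 0.1,
                          frac_inconsistent_patients = 0.1,
                          frac_incomplete_days = 0.3,
                          start_date = as.Date("2019-01-01"),
                          seed = 1L) {
  assert_proportion(frac_overlap_patients, "frac_overlap_patients")
  assert_proportion(frac_inconsistent_patients, "frac_inconsistent_patients")
  assert_proportion(frac_incomplete_days, "frac_incomplete_days")
  if (abs(sum(archetype_mix) - 1) > 1e-8 ||
      !setequal(names(archetype_mix), names(archetypes)))
    stop_config("archetype_mix must be named probabilities over `archetypes` summing to 1")
  structure(list(n_patients = as.integer(n_patients),
                 days_per_patient = days_per_patient,
                 archetypes = archetypes, archetype_mix = archetype_mix,
                 frac_overlap_patients = frac_overlap_patients,
                 frac_inconsistent_patients = frac_inconsistent_patients,
                 frac_incomplete_days = frac_incomplete_days,
                 start_date = as.Date(start_date), seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a multi-patient posture telemetry cohort
#'
#' Draws an archetype and stay length per patient, generates each patient's
#' recording stream with [generate_patient_series()], degrades the
#' configured fraction of patient-days below the analysis-day threshold,
#' then injects the two error types ([inject_overlap()],
#' [inject_inconsistency()]). Every injected error is flagged in the ground
#' truth.
#'
#' @param config a [cohort_config()].
#' @return a \code{posture_cohort}: list with \code{recordings},
#'   \code{admissions}, \code{truth} (list: \code{flags} per recording,
#'   \code{patients} with archetype label and true weight parameters) and
#'   the \code{config}.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  arch_names <- sample(names(config$archetype_mix), n, replace = TRUE,
                       prob = config$archetype_mix)
  dpp <- config$days_per_patient
  days <- if (length(dpp) == 1L) rep(as.integer(dpp), n) else
    sample(seq(dpp[1], dpp[2]), n, replace = TRUE)
  admits <- as.POSIXct(paste(config$start_date + sample.int(300, n, replace = TRUE),
                             "00:00:00"), tz = TZ)
  mrns <- sprintf("P%04d", seq_len(n))

  pats <- lapply(seq_len(n), function(i)
    generate_patient_series(config$archetypes[[arch_names[i]]], days[i],
                            admits[i], mrn = mrns[i]))
  recordings <- data.table::rbindlist(lapply(pats, `[[`, "recordings"))
  admissions <- data.table::rbindlist(lapply(pats, `[[`, "admission"))
  flags <- data.table::rbindlist(lapply(pats, `[[`, "truth"))

  # degrade a fraction of patient-days below the analysis threshold
  if (config$frac_incomplete_days > 0) {
    recordings[, date := local_date(timestamp)]
    pd <- unique(recordings[, .(mrn, date)])
    sel <- pd[runif(.N) < config$frac_incomplete_days]
    if (nrow(sel) > 0) {
      sel[, del_hours := runif(.N, 3, 20)]
      sel[, del_start := runif(.N, 0, 24 - del_hours)]
      rec2 <- merge(recordings, sel, by = c("mrn", "date"), all.x = TRUE)
      sod <- seconds_of_day(rec2$timestamp)
      drop <- !is.na(rec2$del_hours) &
        sod >= rec2$del_start * 3600 & sod < (rec2$del_start + rec2$del_hours) * 3600
      recordings <- rec2[!drop, .(mrn, file_id, device_serial, timestamp, posture)]
      flags <- flags[recordings[, .(mrn, file_id, device_serial, timestamp)],
                     on = c("mrn", "file_id", "device_serial", "timestamp")]
    } else {
      recordings[, date := NULL]
    }
  }
  data.table::setorder(recordings, mrn, timestamp)

  patients <- data.table::data.table(
    mrn = mrns, archetype = arch_names, n_days = days,
    t(vapply(arch_names, function(a) c(
      dw = config$archetypes[[a]]$daytime_group_weights,
      nw = config$archetypes[[a]]$nighttime_group_weights), numeric(8))))

  cohort <- structure(list(recordings = recordings[], admissions = admissions,
                           truth = list(flags = flags[], patients = patients),
                           config = config),
                      class = "posture_cohort")
  if (config$frac_overlap_patients > 0)
    cohort <- inject_overlap(cohort, config$frac_overlap_patients)
  if (config$frac_inconsistent_patients > 0)
    cohort <- inject_inconsistency(cohort, config$frac_inconsistent_patients)
  cohort
}

#' @export
print.posture_cohort <- function(x, ...) {
  cat(sprintf("synthetic posture cohort: %d patients, %d recordings\n",
              nrow(x$admissions), nrow(x$recordings)))
  cat(sprintf("  injected: %d overlap rows, %d out-of-window rows, %d noise flips\n",
              sum(x$truth$flags$is_overlap_injected),
              sum(x$truth$flags$is_out_of_window),
              sum(x$truth$flags$is_noise_flip)))
  invisible(x)
}

#' Inject record-overlap errors
#'
#' For a fraction of patients, a contiguous segment of another patient's
#' recordings (keeping the donor's device serial and file ID) is relabeled
#' with the victim's MRN at timestamps the victim already occupies — the
#' signature of a recharged device reassigned without updating the patient
#' identifier. Every injected row is flagged
#' \code{is_overlap_injected} in the ground truth.
#'
#' @param cohort a \code{posture_cohort}.
#' @param frac proportion of patients to afflict.
#' @param max_hours maximum overlap segment length in hours.
#' @return the modified cohort.
#' @export
inject_overlap <- function(cohort, frac, max_hours = 24) {
  stopifnot(inherits(cohort, "posture_cohort"))
  assert_proportion(frac, "frac")
  if (frac == 0) return(cohort)
  mrns <- cohort$admissions$mrn
  if (length(mrns) < 2L)
    stop_config("overlap injection needs >= 2 patients")
  n_sel <- round(frac * length(mrns))
  if (n_sel == 0L) return(cohort)
  victims <- sample(mrns, n_sel)
  rec <- cohort$recordings
  new_rows <- list(); new_flags <- list()
  for (v in victims) {
    donor <- sample(setdiff(mrns, v), 1L)
    vts <- sort(rec[mrn == v, timestamp])
    drows <- rec[mrn == donor][order(timestamp)]
    k <- min(length(vts), nrow(drows),
             max(240L, as.integer(runif(1, 1, max_hours) * 240)))
    vstart <- sample.int(length(vts) - k + 1L, 1L)
    dstart <- sample.int(nrow(drows) - k + 1L, 1L)
    seg <- drows[dstart:(dstart + k - 1L)]
    inj <- data.table::data.table(
      mrn = v, file_id = seg$file_id, device_serial = seg$device_serial,
      timestamp = vts[vstart:(vstart + k - 1L)], posture = seg$posture)
    new_rows[[v]] <- inj
    new_flags[[v]] <- inj[, .(mrn, file_id, device_serial, timestamp,
                              true_group = NA_character_,
                              is_noise_flip = FALSE,
                              is_overlap_injected = TRUE,
                              is_out_of_window = FALSE)]
  }
  cohort$recordings <- data.table::rbindlist(c(list(rec), new_rows))
  data.table::setorder(cohort$recordings, mrn, timestamp)
  cohort$truth$flags <- data.table::rbindlist(c(list(cohort$truth$flags), new_flags))
  cohort
}

#' Inject admission-window inconsistency errors
#'
#' For a fraction of patients, grid-aligned recordings are appended strictly
#' before the admission time or strictly after the discharge time (the
#' mismatch can be large — up to \code{max_extension_hours}). Injected rows
#' are flagged \code{is_out_of_window}.
#'
#' @param cohort a \code{posture_cohort}.
#' @param frac proportion of patients to afflict.
#' @param max_extension_hours maximum extension length (default 48 h);
#'   lengths are drawn uniformly from (1, max) hours.
#' @param extension_hours optional fixed extension length in hours,
#'   overriding the random draw.
#' @return the modified cohort.
#' @export
#' @param side \code{"random"} (default), \code{"before"} (pre-admission
#'   rows) or \code{"after"} (post-discharge rows).
inject_inconsistency <- function(cohort, frac, max_extension_hours = 48,
                                 extension_hours = NULL,
                                 side = c("random", "before", "after")) {
  side <- match.arg(side)
  stopifnot(inherits(cohort, "posture_cohort"))
  assert_proportion(frac, "frac")
  if (frac == 0) return(cohort)
  adm <- cohort$admissions
  n_sel <- round(frac * nrow(adm))
  if (n_sel == 0L) return(cohort)
  sel <- sample(adm$mrn, n_sel)
  new_rows <- list(); new_flags <- list()
  for (v in sel) {
    a <- adm[mrn == v]
    this_side <- if (side == "random") sample(c("before", "after"), 1L) else side
    k <- if (is.null(extension_hours)) as.integer(runif(1, 1, max_extension_hours) * 240)
         else as.integer(extension_hours * 240)
    ts <- if (this_side == "before") a$admit_time - GRID_SECONDS * (k:1)
          else a$discharge_time + GRID_SECONDS * (1:k)
    groups <- sample(c("Lying", "Reclined", "Upright", "Unknown"), k,
                     replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
    inj <- data.table::data.table(
      mrn = v, file_id = sprintf("FX%s", v), device_serial = sprintf("DX%s", v),
      timestamp = ts, posture = sample_group_code(groups))
    new_rows[[v]] <- inj
    new_flags[[v]] <- inj[, .(mrn, file_id, device_serial, timestamp,
                              true_group = NA_character_,
                              is_noise_flip = FALSE,
                              is_overlap_injected = FALSE,
                              is_out_of_window = TRUE)]
  }
  cohort$recordings <- data.table::rbindlist(c(list(cohort$recordings), new_rows))
  data.table::setorder(cohort$recordings, mrn, timestamp)
  cohort$truth$flags <- data.table::rbindlist(c(list(cohort$truth$flags), new_flags))
  cohort
}

#' Write / read a cohort on disk
#'
#' Emits \code{recordings.csv} and \code{admissions.csv} in the canonical
#' dialects plus \code{ground_truth.csv} (recording key, realized group,
#' injection flags, archetype label) and \code{truth_patients.csv}.
#' \code{read_cohort()} reproduces the in-memory cohort field for field.
#'
#' @param cohort a \code{posture_cohort}.
#' @param out_dir output directory (created if needed).
#' @return \code{write_cohort}: the directory, invisibly;
#'   \code{read_cohort}: a \code{posture_cohort} (without config).
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_recordings(cohort$recordings, file.path(out_dir, "recordings.csv"))
  write_admissions(cohort$admissions, file.path(out_dir, "admissions.csv"))
  fl <- merge(cohort$truth$flags,
              cohort$truth$patients[, .(mrn, archetype)], by = "mrn", all.x = TRUE)
  fl[, timestamp := format_timestamp(timestamp)]
  data.table::setorder(fl, mrn, timestamp)
  data.table::fwrite(fl, file.path(out_dir, "ground_truth.csv"), na = "NA")
  data.table::fwrite(cohort$truth$patients, file.path(out_dir, "truth_patients.csv"))
  invisible(out_dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(out_dir) {
  fl <- data.table::fread(file.path(out_dir, "ground_truth.csv"),
                          colClasses = list(character = "timestamp"))
  fl[, timestamp := parse_timestamp(timestamp)]
  fl[, archetype := NULL]
  structure(list(
    recordings = read_recordings(file.path(out_dir, "recordings.csv")),
    admissions = read_admissions(file.path(out_dir, "admissions.csv")),
    truth = list(flags = fl[],
                 patients = data.table::fread(file.path(out_dir, "truth_patients.csv")))
  ), class = "posture_cohort")
}
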