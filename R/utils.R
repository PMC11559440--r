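# Internal helpers shared across modules.

#' @import data.table
#' @importFrom stats kmeans lm coef rgeom runif sd median quantile setNames
#'   complete.cases aggregate dist
#' @importFrom utils head tail
NULL

# Timestamps are naive local clock times stored as POSIXct in UTC: the
# daytime/nighttime windows are defined on the local clock, and storing in
# UTC avoids DST discontinuities that a true local zone would introduce.
TZ <- "UTC"

parse_timestamp <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = TZ)
}

format_timestamp <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%S", tz = TZ)
}

# seconds since local midnight
seconds_of_day <- function(ts) {
  as.integer(as.numeric(ts) %% 86400)
}

in_daytime <- function(ts) {
  s <- seconds_of_day(ts)
  s >= DT_START_SEC & s < DT_END_SEC
}

on_grid <- function(ts) {
  num <- as.numeric(ts)
  num == floor(num) & (as.integer(num) %% GRID_SECONDS == 0L)
}

snap_to_grid <- function(ts) {
  as.POSIXct(round(as.numeric(ts) / GRID_SECONDS) * GRID_SECONDS,
             tz = TZ, origin = "1970-01-01")
}

local_date <- function(ts) {
  as.Date(ts, tz = TZ)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_config("`%s` must be a single number in [0, 1]", name)
  invisible(x)
}
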