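# Independent oracles and small builders shared across the suite.
# Oracles deliberately use different formulations (explicit loops, table(),
# sort()) from the package implementations they check.

t0 <- as.POSIXct("2019-03-01 00:00:00", tz = "UTC")

# series builder: groups at consecutive 15-s slots starting at `start`;
# `gaps_after` = indices after which one grid slot is skipped
mk_series <- function(groups, mrn = "P1", start = t0, gaps_after = integer(0)) {
  off <- cumsum(c(0L, rep(1L, length(groups) - 1L) +
                       as.integer(seq_len(length(groups) - 1L) %in% gaps_after)))
  data.table::data.table(mrn = mrn, timestamp = start + 15 * off, group = groups)
}

# brute-force majority vote: per-position table() count over the 3-window,
# applied to the input values
brute_smooth <- function(groups, ts) {
  n <- length(groups)
  out <- groups
  if (n < 3L) return(out)
  for (i in 2:(n - 1)) {
    if (as.numeric(ts[i]) - as.numeric(ts[i - 1]) != 15) next
    if (as.numeric(ts[i + 1]) - as.numeric(ts[i]) != 15) next
    tab <- table(groups[(i - 1):(i + 1)])
    if (max(tab) >= 2) out[i] <- names(tab)[which.max(tab)]
  }
  out
}

# brute-force transition pair scan
brute_transitions <- function(groups, ts) {
  phys <- c("Lying", "Reclined", "Upright")
  cnt <- 0L
  for (i in seq_len(length(groups) - 1L)) {
    if (as.numeric(ts[i + 1]) - as.numeric(ts[i]) != 15) next
    if (!(groups[i] %in% phys) || !(groups[i + 1] %in% phys)) next
    if (groups[i] != groups[i + 1]) cnt <- cnt + 1L
  }
  cnt
}

# brute-force O(n^2) silhouette
brute_silhouette <- function(x, labels) {
  x <- as.matrix(x); n <- nrow(x)
  euclid <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- mean(vapply(which(own & seq_len(n) != i), euclid, numeric(1), i = i))
    b <- Inf
    for (l in setdiff(unique(labels), labels[i])) {
      m <- mean(vapply(which(labels == l), euclid, numeric(1), i = i))
      b <- min(b, m)
    }
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# random group series with optional gaps
random_series <- function(n, mrn = "P1",
                          groups = c("Lying", "Reclined", "Upright",
                                     "Unknown", "UserDefined"),
                          gap_prob = 0) {
  g <- sample(groups, n, replace = TRUE)
  gaps <- which(stats::runif(n - 1) < gap_prob)
  mk_series(g, mrn = mrn, gaps_after = gaps)
}

# a full synthetic day of identical groups (5760 slots)
full_day_series <- function(group_fun, mrn = "P1", date = as.Date("2019-03-01")) {
  start <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  ts <- start + 15 * (0:5759)
  data.table::data.table(mrn = mrn, timestamp = ts, group = group_fun(ts))
}

table1_fixture <- function() {
  data.table::fread(system.file("extdata", "posture_group_examples.csv",
                                package = "posturekit"),
                    colClasses = "character", na.strings = NULL)
}
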