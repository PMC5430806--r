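# Clock/grid arithmetic shared by the generator and the ingest stage.
# All times are UTC; a "slot" is a `slot_minutes` bin anchored at midnight,
# and the daytime observation window [lo, hi) is in hours of the day.

.as_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  as.POSIXct(x, tz = "UTC")
}

# absolute minutes since the epoch (real-valued)
.abs_minutes <- function(t) as.numeric(t) / 60

# cumulative daytime minutes in [epoch, m): days * span + partial day
.daytime_minutes_before <- function(m, window) {
  lo <- window[1] * 60
  hi <- window[2] * 60
  days <- floor(m / 1440)
  rem <- m - days * 1440
  days * (hi - lo) + pmin(pmax(rem, lo), hi) - lo
}

# daytime hours contained in the absolute interval [t0, t1)
.daytime_hours <- function(t0, t1, window) {
  m0 <- .abs_minutes(t0)
  m1 <- .abs_minutes(t1)
  pmax(0, .daytime_minutes_before(pmax(m1, m0), window) -
    .daytime_minutes_before(m0, window)) / 60
}

# number of slot starts in [epoch, m) whose minute-of-day lies in the window
.slots_before <- function(m, slot_minutes, window) {
  lo <- window[1] * 60
  hi <- window[2] * 60
  per_day <- ceiling((hi - lo) / slot_minutes)
  days <- floor(m / 1440)
  rem <- m - days * 1440
  days * per_day + pmax(0, ceiling((pmin(pmax(rem, lo), hi) - lo) / slot_minutes))
}

# count of daytime slot starts in [t0, t1)
.count_daytime_slots <- function(t0, t1, slot_minutes, window) {
  m0 <- .abs_minutes(t0)
  m1 <- .abs_minutes(t1)
  pmax(0, .slots_before(pmax(m1, m0), slot_minutes, window) -
    .slots_before(m0, slot_minutes, window))
}

# all daytime slot-start times in [t0, t1), as POSIXct
.daytime_slot_grid <- function(t0, t1, slot_minutes, window) {
  m0 <- .abs_minutes(t0)
  m1 <- .abs_minutes(t1)
  empty <- as.POSIXct(numeric(0), origin = "1970-01-01", tz = "UTC")
  if (m1 <= m0) return(empty)
  step <- slot_minutes
  first <- ceiling(m0 / step) * step
  if (first >= m1) return(empty)
  starts <- seq(first, by = step, length.out = floor((m1 - first - 1e-9) / step) + 1)
  mod <- starts %% 1440
  starts <- starts[mod >= window[1] * 60 & mod < window[2] * 60]
  as.POSIXct(starts * 60, origin = "1970-01-01", tz = "UTC")
}

.minute_of_day <- function(t) {
  m <- .abs_minutes(t)
  m - floor(m / 1440) * 1440
}

.format_iso <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

.parse_iso <- function(x) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  for (i in which(is.na(out) & !is.na(x) & nzchar(x))) {
    out[i] <- tryCatch(
      as.POSIXct(x[i], tz = "UTC",
                 tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d")),
      error = function(e) as.POSIXct(NA)
    )
  }
  out
}
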