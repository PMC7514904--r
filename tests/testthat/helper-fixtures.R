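# Shared fixtures and independent mini-oracles for the test suite.
# Everything here is deliberately naive (loops, minute sweeps) and
# independent of the package's vectorised code paths.

# The published worked-example hour: an event log whose encoding is the
# 60-sample sequence [3 x5, 9, 1 x4, 9, 1 x49].
worked_example_events <- function() {
  data.frame(
    timestamp = as.POSIXct(
      c("2024-01-01 09:00:01", "2024-01-01 09:05:22",
        "2024-01-01 09:06:00", "2024-01-01 09:06:00",
        "2024-01-01 09:09:59", "2024-01-01 09:11:00",
        "2024-01-01 10:00:00"), tz = "UTC"),
    location = c("Bedroom", "Corridor", "Living room", "Bathroom",
                 "Corridor", "Living room", "Kitchen"),
    state = 1L)
}

worked_example_sequence <- function() {
  c(rep(3L, 5), 9L, rep(1L, 4), 9L, rep(1L, 49))
}

household_map <- function() {
  build_code_map(c("Living room", "Bedroom", "Bathroom", "Kitchen",
                   "Corridor"))
}

# Wrap a bare code vector as a day-long activity sequence.
as_day <- function(codes, start = "2024-01-01", resolution = 1) {
  structure(as.integer(codes), start = as.POSIXct(start, tz = "UTC"),
            resolution = resolution, class = "activity_seq")
}

# Minute-sweep encoding oracle: scan minute by minute for the most recent
# activation at or before the minute midpoint, exact-duplicate timestamps
# deduplicated first-in-log. Naive O(minutes x events) scan.
sweep_encode <- function(events, code_map, start, duration) {
  t0 <- as.numeric(as.POSIXct(start, tz = "UTC"))
  ev <- events[events$state == 1, , drop = FALSE]
  ev <- ev[order(ev$timestamp), , drop = FALSE]
  ev <- ev[!duplicated(ev$timestamp), , drop = FALSE]
  ts <- as.numeric(ev$timestamp)
  out <- integer(duration)
  for (k in seq_len(duration)) {
    mid <- t0 + (k - 1) * 60 + 30
    occupant <- NA_character_
    for (i in seq_len(nrow(ev))) if (ts[i] <= mid) occupant <- ev$location[i]
    if (is.na(occupant))
      occupant <- ev$location[ts < t0 + duration * 60][1]
    out[k] <- code_map[[occupant]]
  }
  out
}

# Random event log over one day: activations at random seconds.
random_event_log <- function(n_events, rooms, day = "2024-01-01") {
  start <- as.POSIXct(day, tz = "UTC")
  secs <- sort(sample.int(86399, n_events))
  data.frame(timestamp = start + secs,
             location = sample(rooms, n_events, replace = TRUE),
             state = 1L)
}

# Minute-resolution overlap oracle: count sample minutes of the window
# whose [t, t+1) interval intersects the visit.
sweep_overlap <- function(vs, ve, ws, wlen) {
  mins <- 0
  for (t in seq(ws, ws + wlen - 1)) {
    lo <- max(vs, t); hi <- min(ve, t + 1)
    if (hi > lo) mins <- mins + (hi - lo)
  }
  100 * mins / wlen
}
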