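test_that("code maps are odd, injective, and canonically or dwell ordered", {
  cm <- household_map()
  expect_identical(cm[c("Living room", "Bedroom", "Bathroom", "Kitchen",
                        "Corridor")],
                   c("Living room" = 1L, "Bedroom" = 3L, "Bathroom" = 5L,
                     "Kitchen" = 7L, "Corridor" = 9L))
  expect_identical(build_code_map("Study"), c(Study = 1L))
  expect_error(build_code_map(c("A", "A")), "duplicate")

  set.seed(12)
  rooms <- paste0("room", 1:6)
  dwell <- stats::setNames(sample(1000, 6), rooms)
  cm2 <- build_code_map(rooms, dwell)
  # sort-based oracle: longest dwell takes the lowest code
  expect_identical(names(sort(cm2)), names(sort(-dwell)))
  expect_true(all(cm2 %% 2 == 1))
  expect_identical(sort(unname(cm2)), seq(1L, 11L, by = 2L))
})

test_that("the worked-example event list encodes to the published vector", {
  a <- encode_events(worked_example_events(), household_map(),
                     "2024-01-01 09:00:00", duration = 60)
  expect_length(a, 60)
  expect_identical(as.integer(a), worked_example_sequence())
  expect_identical(as.integer(a)[12:60], rep(1L, 49))
})

test_that("encoding length depends only on duration and resolution", {
  cm <- household_map()
  set.seed(22)
  for (i in 1:5) {
    ev <- random_event_log(sample(c(1, 5, 80), 1), names(cm))
    # anchor the day so even short windows have prior occupancy state
    ev <- rbind(data.frame(timestamp = as.POSIXct("2024-01-01 00:00:01",
                                                  tz = "UTC"),
                           location = "Bedroom", state = 1L), ev)
    for (dur in c(15, 60, 1440)) {
      a <- encode_events(ev, cm, "2024-01-01", duration = dur)
      expect_length(a, dur)
    }
    a5 <- encode_events(ev, cm, "2024-01-01", duration = 60, resolution = 5)
    expect_length(a5, 12)
  }
})

test_that("duplicating event records never changes the encoding", {
  cm <- household_map()
  set.seed(32)
  ev <- random_event_log(40, names(cm))
  base <- encode_events(ev, cm, "2024-01-01", duration = 1440)
  for (i in sample(nrow(ev), 5)) {
    dup <- rbind(ev, ev[i, ])
    expect_identical(as.integer(encode_events(dup, cm, "2024-01-01",
                                              duration = 1440)),
                     as.integer(base))
  }
})

test_that("code counts reproduce logged dwell times for clean logs", {
  cm <- household_map()
  start <- as.POSIXct("2024-01-01", tz = "UTC")
  stays <- data.frame(room = c("Bedroom", "Kitchen", "Living room",
                               "Bathroom"),
                      at = c(0, 100, 130, 400), stringsAsFactors = FALSE)
  ev <- data.frame(timestamp = start + stays$at * 60, location = stays$room,
                   state = 1L)
  a <- encode_events(ev, cm, start, duration = 500)
  counts <- table(factor(as.integer(a), levels = cm))
  expect_identical(as.integer(counts[as.character(cm[stays$room])]),
                   c(100L, 30L, 270L, 100L))
})

test_that("random logs match the minute-sweep oracle", {
  cm <- household_map()
  set.seed(42)
  for (i in 1:6) {
    ev <- random_event_log(sample(10:60, 1), names(cm))
    # add a simultaneous pair to exercise the first-activation rule
    ev <- rbind(ev, data.frame(timestamp = ev$timestamp[3],
                               location = "Corridor", state = 1L))
    a <- encode_events(ev, cm, "2024-01-01", duration = 720)
    expect_identical(as.integer(a),
                     sweep_encode(ev, cm, "2024-01-01", 720))
  }
})

test_that("carry-back and error cases behave as documented", {
  cm <- household_map()
  start <- as.POSIXct("2024-01-01", tz = "UTC")
  # first activation mid-window: its room is carried back to the start
  ev <- data.frame(timestamp = start + 600, location = "Kitchen", state = 1L)
  a <- encode_events(ev, cm, start, duration = 30)
  expect_identical(unique(as.integer(a)), cm[["Kitchen"]])
  # prior-day state carries forward into a later window
  ev2 <- rbind(ev, data.frame(timestamp = start + 86400 + 60,
                              location = "Bedroom", state = 1L))
  a2 <- encode_events(ev2, cm, start + 86400, duration = 1)
  expect_identical(as.integer(a2), cm[["Kitchen"]])

  empty <- ev[0, ]
  expect_error(encode_events(empty, cm, start, duration = 10),
               "no occupancy")
  bad <- data.frame(timestamp = start, location = "Garage", state = 1L)
  expect_error(encode_events(bad, cm, start, duration = 10),
               "missing from code map")
  expect_error(encode_events(ev, cm, start, duration = 7, resolution = 2),
               "divisible")
})

test_that("deactivations are ignored by the encoder", {
  cm <- household_map()
  start <- as.POSIXct("2024-01-01", tz = "UTC")
  ev <- data.frame(
    timestamp = start + c(0, 300, 600),
    location = c("Bedroom", "Bedroom", "Kitchen"),
    state = c(1L, 0L, 0L))
  a <- encode_events(ev, cm, start, duration = 20)
  expect_identical(unique(as.integer(a)), cm[["Bedroom"]])
})

test_that("multi-day encoding splits at midnight with state carry-over", {
  cm <- household_map()
  set.seed(52)
  ev <- rbind(random_event_log(30, names(cm), "2024-01-01"),
              random_event_log(30, names(cm), "2024-01-02"))
  days <- encode_days(ev, cm)
  expect_length(days, 2)
  expect_true(all(vapply(days, length, 0L) == 1440))
  expect_identical(attr(days[[2]], "start") - attr(days[[1]], "start"),
                   as.difftime(1, units = "days"))
})
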