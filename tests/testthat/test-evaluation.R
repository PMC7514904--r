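grid_1day <- function(window_len = 60) {
  start <- as.POSIXct("2024-01-01", tz = "UTC")
  n <- 1440 %/% window_len
  data.frame(window_start = start + (seq_len(n) - 1) * window_len * 60,
             length = window_len)
}

test_that("window truth labels follow the overlap rule", {
  w <- grid_1day()
  start <- as.POSIXct("2024-01-01", tz = "UTC")

  none <- label_windows(w, data.frame(start = start[0], end = start[0]))
  expect_false(any(none$truth))

  v <- data.frame(start = start + (9 * 60 + 20) * 60,
                  end = start + (9 * 60 + 40) * 60)   # 09:20-09:40
  lab <- label_windows(w, v, min_overlap = 30)
  expect_equal(lab$overlap_pct[10], 100 * 20 / 60, tolerance = 1e-9)
  expect_identical(which(lab$truth), 10L)            # the 09:00 window only
  expect_false(any(label_windows(w, v, min_overlap = 40)$truth))

  # overlapping visits are unioned before labelling
  v2 <- rbind(v, data.frame(start = v$start + 10 * 60, end = v$end + 30 * 60))
  lab2 <- label_windows(w, v2, min_overlap = 30)   # union is 09:20-10:10
  expect_equal(lab2$overlap_pct[10], 100 * 40 / 60, tolerance = 1e-9)

  expect_error(label_windows(w, data.frame(start = v$end, end = v$start)),
               "start < end")
})

test_that("random visit sets agree with a minute-sweep labelling oracle", {
  set.seed(14)
  start <- as.POSIXct("2024-01-01", tz = "UTC")
  for (rep in 1:5) {
    w <- grid_1day(sample(c(15, 60, 120), 1))
    nvis <- sample(1:4, 1)
    vs <- sort(runif(nvis, 0, 1300))
    visits <- data.frame(start = start + vs * 60,
                         end = start + (vs + runif(nvis, 5, 180)) * 60)
    lab <- label_windows(w, visits, min_overlap = 30)
    for (i in seq_len(nrow(w))) {
      mins <- 0
      ws <- as.numeric(w$window_start[i] - start, units = "mins")
      for (t in ws:(ws + w$length[i] - 1)) {
        covered <- FALSE
        for (vv in seq_len(nvis)) {
          v0 <- vs[vv]; v1 <- as.numeric(visits$end[vv] - start,
                                         units = "mins")
          if (min(v1, t + 1) > max(v0, t))
            covered <- TRUE
        }
        if (covered) mins <- mins + min(1, 1)
      }
      # sweep overlap at minute resolution bounds the exact one within 1 min
      expect_lt(abs(lab$overlap_pct[i] - 100 * mins / w$length[i]),
                100 / w$length[i] + 1e-9)
    }
  }
})

test_that("confusion tallies match direct enumeration", {
  expect_identical(unclass(confusion_counts(c(TRUE, TRUE, FALSE),
                                            c(TRUE, FALSE, FALSE))),
                   c(tp = 1L, fp = 1L, tn = 1L, fn = 0L))
  same <- rep(c(TRUE, FALSE), 10)
  cc <- confusion_counts(same, same)
  expect_identical(cc[["fp"]] + cc[["fn"]], 0L)
  allpos <- confusion_counts(rep(TRUE, 12), rep(FALSE, 12))
  expect_identical(allpos[["fp"]], 12L)

  set.seed(24)
  for (i in 1:10) {
    f <- sample(c(TRUE, FALSE), 50, replace = TRUE)
    t <- sample(c(TRUE, FALSE), 50, replace = TRUE)
    cc <- confusion_counts(f, t)
    manual <- c(0L, 0L, 0L, 0L)
    for (j in 1:50) {
      if (f[j] && t[j]) manual[1] <- manual[1] + 1L
      else if (f[j] && !t[j]) manual[2] <- manual[2] + 1L
      else if (!f[j] && !t[j]) manual[3] <- manual[3] + 1L
      else manual[4] <- manual[4] + 1L
    }
    expect_identical(unname(unclass(cc)), manual)
    expect_identical(sum(cc), 50L)
    # permutation safety
    p <- sample(50)
    expect_identical(unclass(confusion_counts(f[p], t[p])), unclass(cc))
  }
  expect_error(confusion_counts(TRUE, c(TRUE, FALSE)), "length")
})

test_that("metrics implement the percentage formulas with NA on 0/0", {
  m <- detection_metrics(c(tp = 3, fp = 0, tn = 69, fn = 0))
  expect_equal(c(m$accuracy, m$precision, m$recall), c(100, 100, 100))
  m2 <- detection_metrics(c(tp = 3, fp = 3, tn = 65, fn = 1))
  expect_equal(m2$precision, 50)
  expect_equal(m2$recall, 75)
  none <- detection_metrics(c(tp = 0, fp = 0, tn = 10, fn = 0))
  expect_equal(none$accuracy, 100)
  expect_true(is.na(none$precision) && is.na(none$recall))

  set.seed(34)
  for (i in 1:20) {
    cc <- c(tp = sample(0:9, 1), fp = sample(0:9, 1),
            tn = sample(0:9, 1), fn = sample(0:9, 1))
    mm <- detection_metrics(cc)
    expect_equal(mm$accuracy,
                 100 * (cc["tp"] + cc["tn"]) / sum(cc), ignore_attr = TRUE)
    for (v in c(mm$accuracy, mm$precision, mm$recall))
      if (!is.na(v)) expect_true(v >= 0 && v <= 100)
  }
})

test_that("lowering k trades precision for recall monotonically", {
  run <- simulate_adl("datasetB", seed = 5)
  fit <- detect_visitors(run)
  w <- fit$windows
  ks <- c(4, 2, 1, 0.5, 0)
  prec <- rec <- numeric(length(ks))
  for (i in seq_along(ks)) {
    det <- detect_windows(w[setdiff(names(w), c("threshold", "flag"))],
                          daily_profile(w, k = ks[i]))
    m <- detection_metrics(confusion_counts(det$flag, w$truth))
    prec[i] <- ifelse(is.na(m$precision), 100, m$precision)
    rec[i] <- m$recall
  }
  expect_true(all(diff(rec) >= 0))    # lowering k never loses recall
  expect_true(all(diff(prec) <= 0))   # and never gains precision
})
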