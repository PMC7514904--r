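# Total dwell minutes per room implied by an activation log (time from
# each activation to the next, last one to the end of the log).
.dwell_stats <- function(events) {
  ev <- .prepare_activations(events)
  if (nrow(ev) < 2L) return(stats::setNames(rep(1, length(unique(ev$location))),
                                            unique(ev$location)))
  gaps <- c(diff(as.numeric(ev$timestamp)), 60) / 60
  tapply(gaps, ev$location, sum)
}

#' Detect visitor episodes in an occupancy event log
#'
#' The central fitting function. The event log is encoded day by day into
#' per-minute room-code sequences, a windowed regularity statistic
#' (fuzzy/approximate/sample entropy, or the indoor-mobility transition
#' count) is computed on a clock-aligned grid, a time-of-day profile of
#' across-day mean and standard deviation is built, and every window whose
#' value strictly exceeds `mean + k * sd` for its slot is flagged as a
#' visitor window. With ground-truth visit intervals the flags are scored
#' at window level against labels defined by the `min_overlap` coverage
#' rule.
#'
#' Defaults are the headline regime: fuzzy entropy with `m = 2`, `r = 1`,
#' one-hour windows, no shift, `k = 1`, 30% minimum overlap.
#'
#' @param events Event data frame (`timestamp`, `location`, `state`), an
#'   `adl_sim` from [simulate_adl()], or a path to an event CSV.
#' @param code_map Optional named code vector; by default built from the
#'   log (canonical household order when the room names allow, otherwise
#'   dwell-ranked).
#' @param truth Optional visit data frame (`start`, `end`) or CSV path;
#'   taken from an `adl_sim` automatically.
#' @param measure,m,r,n Window statistic and its parameters.
#' @param window_len,shift Window grid in minutes.
#' @param k SD multiplier of the detection threshold.
#' @param resolution Minutes per encoded sample.
#' @param min_overlap Window coverage (percent) required for a
#'   ground-truth visitor label.
#' @param start,days Day span; inferred from the data when omitted.
#' @return A `visitor_detection` object: `windows` (per-window value,
#'   threshold, flag and, with truth, overlap/label), `profile`,
#'   `code_map`, `config`, and with truth `confusion` and `metrics`.
#' @seealso [entropy_series()], [daily_profile()], [detection_metrics()]
#' @examples
#' run <- simulate_adl("datasetA", seed = 42)
#' fit <- detect_visitors(run)
#' fit
#' @export
detect_visitors <- function(events, code_map = NULL, truth = NULL,
                            measure = c("fuzzyen", "apen", "sampen",
                                        "mobility"),
                            m = 2, r = 1, n = 2, window_len = 60, shift = 0,
                            k = 1, resolution = 1, min_overlap = 30,
                            start = NULL, days = NULL) {
  measure <- match.arg(measure)
  if (inherits(events, "adl_sim")) {
    if (is.null(truth)) truth <- events$truth
    if (is.null(start)) start <- events$start
    if (is.null(days)) days <- events$days
    events <- events$events
  }
  if (is.character(events)) events <- read_events(events)
  if (is.character(truth)) truth <- read_visits(truth)

  if (is.null(code_map)) {
    locs <- unique(.prepare_activations(events)$location)
    canonical <- c("Living room", "Bedroom", "Bathroom", "Kitchen",
                   "Corridor", "Other")
    code_map <- if (all(locs %in% canonical)) build_code_map(locs)
      else build_code_map(locs, dwell = .dwell_stats(events))
  }

  day_seqs <- encode_days(events, code_map, start = start, days = days,
                          resolution = resolution)
  series <- entropy_series(day_seqs, measure, m = m, r = r, n = n,
                           window_len = window_len, shift = shift)
  n_undef <- sum(is.na(series$value))
  if (n_undef > 0)
    message(n_undef, " window(s) with undefined entropy excluded from ",
            "profile and flagging")
  profile <- daily_profile(series, k = k)
  windows <- detect_windows(series, profile)

  confusion <- metrics <- NULL
  if (!is.null(truth)) {
    windows <- label_windows(windows, truth, min_overlap = min_overlap)
    confusion <- confusion_counts(windows$flag, windows$truth)
    metrics <- detection_metrics(confusion)
  }

  structure(list(windows = windows, profile = profile, code_map = code_map,
                 truth = truth, confusion = confusion, metrics = metrics,
                 n_undefined = n_undef,
                 config = list(measure = measure, m = m, r = r, n = n,
                               window_len = window_len, shift = shift,
                               k = k, resolution = resolution,
                               min_overlap = min_overlap),
                 call = match.call()),
            class = "visitor_detection")
}

#' @export
print.visitor_detection <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Visitor detection (%s, m = %g, r = %g%s)\n", cfg$measure,
              cfg$m, cfg$r,
              if (cfg$measure == "fuzzyen") sprintf(", n = %g", cfg$n) else ""))
  cat(sprintf("  %d windows of %g min (shift %g) over %d day(s); k = %g\n",
              nrow(x$windows), cfg$window_len, cfg$shift,
              length(unique(x$windows$day)), cfg$k))
  cat(sprintf("  flagged: %d window(s)", sum(x$windows$flag)))
  if (x$n_undefined > 0) cat(sprintf("  [%d undefined]", x$n_undefined))
  cat("\n")
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' @export
summary.visitor_detection <- function(object, ...) {
  out <- list(fit = object,
              flagged = object$windows[object$windows$flag,
                                       c("window_start", "value",
                                         "threshold")],
              profile_range = range(object$profile$threshold))
  class(out) <- "summary.visitor_detection"
  out
}

#' @export
print.summary.visitor_detection <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  threshold range: %.4g .. %.4g\n",
              x$profile_range[1], x$profile_range[2]))
  if (nrow(x$flagged)) {
    cat("  flagged windows:\n")
    print(format(data.frame(
      start = format(x$flagged$window_start, "%Y-%m-%d %H:%M", tz = "UTC"),
      value = signif(x$flagged$value, 4),
      threshold = signif(x$flagged$threshold, 4))), row.names = FALSE)
  }
  invisible(x)
}

#' Plot a fitted visitor detection
#'
#' Entropy series over the whole run with the time-varying threshold,
#' flagged windows highlighted and (when ground truth is present) visit
#' intervals shaded.
#'
#' @param x A `visitor_detection` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.visitor_detection <- function(x, ...) {
  w <- x$windows
  ylim <- range(c(w$value, w$threshold), na.rm = TRUE)
  graphics::plot(w$window_start, w$value, type = "n", ylim = ylim,
                 xlab = "time", ylab = x$config$measure, ...)
  if (!is.null(x$truth) && nrow(x$truth)) {
    usr <- graphics::par("usr")
    graphics::rect(as.numeric(x$truth$start), usr[3],
                   as.numeric(x$truth$end), usr[4],
                   col = grDevices::adjustcolor("skyblue", 0.3), border = NA)
  }
  graphics::lines(w$window_start, w$threshold, lty = 2, col = "grey40")
  graphics::lines(w$window_start, w$value)
  if (any(w$flag))
    graphics::points(w$window_start[w$flag], w$value[w$flag],
                     pch = 19, col = "red")
  invisible(x)
}
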