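#' Windowed entropy series over one or more days
#'
#' Cuts each day into consecutive non-overlapping windows of `window_len`
#' minutes starting at midnight + `shift`, computes the chosen statistic on
#' each window's samples, and returns one row per window. A trailing
#' partial window is dropped, not padded. Undefined sample-entropy windows
#' are kept as `NA`.
#'
#' @param days A single `activity_seq` or a list of them (one per day), as
#'   from [encode_days()].
#' @param measure `"fuzzyen"` (default), `"apen"`, `"sampen"`, or
#'   `"mobility"` for the room-transition baseline.
#' @param m,r,n Entropy parameters; see [fuzzyen()].
#' @param window_len Window length in minutes (15, 60, 120, or any positive
#'   length that fits the day).
#' @param shift Offset of the window grid from midnight, in minutes,
#'   `0 <= shift < window_len`.
#' @return Data frame with columns `day`, `slot` (window start, minutes
#'   after midnight), `window_start` (POSIXct), `length`, `shift`,
#'   `measure`, `value`.
#' @examples
#' day <- structure(rep(1L, 1440), start = as.POSIXct("2024-01-01", tz = "UTC"),
#'                  resolution = 1, class = "activity_seq")
#' es <- entropy_series(day, "fuzzyen", window_len = 60)
#' nrow(es)          # 24 windows
#' all(es$value == 0)
#' @export
entropy_series <- function(days, measure = c("fuzzyen", "apen", "sampen",
                                             "mobility"),
                           m = 2, r = 1, n = 2, window_len = 60, shift = 0) {
  measure <- match.arg(measure)
  if (inherits(days, "activity_seq")) days <- list(days)
  if (!length(days)) stop("no days supplied", call. = FALSE)
  if (window_len <= 0) stop("`window_len` must be positive", call. = FALSE)
  if (shift < 0 || shift >= window_len)
    stop("`shift` must satisfy 0 <= shift < window_len", call. = FALSE)
  res <- attr(days[[1L]], "resolution") %||% 1
  w <- window_len / res
  if (w != round(w))
    stop("`window_len` must be a multiple of the sample resolution",
         call. = FALSE)
  w <- as.integer(w)
  if (measure != "mobility" && w < m + 2)
    stop(sprintf("window of %d samples too short for m = %d (need m + 2)",
                 w, as.integer(m)), call. = FALSE)
  fun <- .measure_fun(measure, m, r, n)

  out <- lapply(seq_along(days), function(d) {
    codes <- as.numeric(days[[d]])
    day_start <- attr(days[[d]], "start")
    off <- as.integer(shift / res)
    nwin <- (length(codes) - off) %/% w
    if (nwin < 1L) stop("window longer than the day", call. = FALSE)
    slot <- shift + window_len * (seq_len(nwin) - 1L)
    value <- vapply(seq_len(nwin), function(i) {
      seg <- codes[(off + (i - 1L) * w + 1L):(off + i * w)]
      as.numeric(fun(seg))
    }, 0)
    data.frame(day = d, slot = slot,
               window_start = day_start + slot * 60,
               length = window_len, shift = shift,
               measure = measure, value = value)
  })
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Across-days time-of-day threshold profile
#'
#' For each time-of-day slot of the window grid, computes the mean and
#' population standard deviation of the statistic across days, and the
#' detection threshold `mean + k * sd`. Undefined (`NA`) window values are
#' excluded from both moments; a slot left with fewer than two defined
#' values gets `sd = 0` (with a warning) so that it can still carry a
#' threshold.
#'
#' The threshold therefore varies over the day rather than being a single
#' scalar: each slot is compared only with the same clock hour on other
#' days.
#'
#' @param series Window data frame from [entropy_series()], covering at
#'   least two days on a consistent grid.
#' @param k Standard-deviation multiplier (default 1).
#' @return A `daily_profile` data frame with columns `slot`, `mean`, `sd`,
#'   `threshold`, `n_defined`.
#' @export
daily_profile <- function(series, k = 1) {
  if (length(unique(series$day)) < 2L)
    stop("profile needs at least two days", call. = FALSE)
  slots <- sort(unique(series$slot))
  rows <- lapply(slots, function(s) {
    v <- series$value[series$slot == s]
    v <- v[!is.na(v)]
    mu <- if (length(v)) mean(v) else 0
    sd <- if (length(v) >= 2L) sqrt(mean((v - mu)^2)) else 0
    data.frame(slot = s, mean = mu, sd = sd,
               threshold = mu + k * sd, n_defined = length(v))
  })
  prof <- do.call(rbind, rows)
  if (any(prof$n_defined < 2L))
    warning(sum(prof$n_defined < 2L),
            " slot(s) with fewer than 2 defined values; sd set to 0",
            call. = FALSE)
  attr(prof, "k") <- k
  class(prof) <- c("daily_profile", "data.frame")
  prof
}

#' Flag windows exceeding the time-of-day threshold
#'
#' A window is flagged as a visitor window iff its value is defined and
#' strictly exceeds the threshold of its time-of-day slot. Undefined
#' values never flag.
#'
#' @param series Window data frame from [entropy_series()].
#' @param profile A [daily_profile()] built on the same window grid.
#' @return `series` with `threshold` and logical `flag` columns appended.
#' @export
detect_windows <- function(series, profile) {
  i <- match(series$slot, profile$slot)
  if (anyNA(i))
    stop("window grid does not match the profile slots", call. = FALSE)
  series$threshold <- profile$threshold[i]
  series$flag <- !is.na(series$value) & series$value > series$threshold
  series
}

#' Overlap between a visit interval and a computation window
#'
#' The percentage of the window covered by the visit:
#' `100 * |visit intersect window| / window length`. Disjoint intervals
#' give 0. All arguments are vectorised.
#'
#' @param visit_start,visit_end Visit interval bounds (POSIXct, or numeric
#'   minutes).
#' @param window_start Window start (same type as the visit bounds).
#' @param window_len Window length in minutes.
#' @return Numeric percentage(s) in \[0, 100\].
#' @examples
#' overlap_fraction(20, 40, 0, 60)  # visit 09:20-09:40 in a 09:00 window
#' @export
overlap_fraction <- function(visit_start, visit_end, window_start,
                             window_len) {
  scale <- if (inherits(window_start, "POSIXct") ||
               inherits(visit_start, "POSIXct")) 60 else 1
  vs <- as.numeric(visit_start); ve <- as.numeric(visit_end)
  ws <- as.numeric(window_start); we <- ws + window_len * scale
  ol <- pmax(0, pmin(ve, we) - pmax(vs, ws))
  100 * ol / (window_len * scale)
}
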