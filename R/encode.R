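#' Assign odd room codes to locations
#'
#' Builds the injective location-to-code map used by the activity encoder.
#' Codes are the odd integers 1, 3, 5, ... so that distinct rooms are always
#' at least 2 apart, which makes hard-tolerance entropy measures insensitive
#' to any tolerance below 2.
#'
#' With `dwell` supplied, codes are assigned in descending order of total
#' dwell time, so the room occupied longest gets code 1 and briefly-visited
#' rooms (typically a corridor) get the high codes. Without dwell
#' statistics, the conventional household order Living room = 1,
#' Bedroom = 3, Bathroom = 5, Kitchen = 7, Corridor/Other = 9 is used for
#' rooms with those names; any remaining rooms follow in input order.
#'
#' @param locations Character vector of distinct room names.
#' @param dwell Optional named numeric vector of total dwell time per room
#'   (any consistent unit); names must cover `locations`.
#' @return Named integer vector of odd codes, one per location.
#' @examples
#' build_code_map(c("Living room", "Bedroom", "Bathroom", "Kitchen", "Corridor"))
#' @export
build_code_map <- function(locations, dwell = NULL) {
  locations <- as.character(locations)
  if (length(locations) < 1L) stop("need at least one location", call. = FALSE)
  if (anyDuplicated(locations))
    stop("duplicate location names: ",
         paste(unique(locations[duplicated(locations)]), collapse = ", "),
         call. = FALSE)
  if (!is.null(dwell)) {
    if (is.null(names(dwell)) || !all(locations %in% names(dwell)))
      stop("`dwell` must be named and cover every location", call. = FALSE)
    ord <- order(-dwell[locations], seq_along(locations))
  } else {
    canonical <- c("Living room", "Bedroom", "Bathroom", "Kitchen",
                   "Corridor", "Other")
    rank <- match(locations, canonical)
    rank[is.na(rank)] <- length(canonical) + seq_len(sum(is.na(rank)))
    ord <- order(rank)
  }
  codes <- integer(length(locations))
  codes[ord] <- seq(1L, by = 2L, length.out = length(locations))
  names(codes) <- locations
  codes
}

#' @keywords internal
#' @noRd
.as_time <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  as.POSIXct(x, tz = "UTC")
}

# Activations only, stably time-sorted, simultaneous duplicates dropped
# (first in log order wins, as for co-triggered sensors).
.prepare_activations <- function(events) {
  stopifnot(is.data.frame(events))
  if (!all(c("timestamp", "location") %in% names(events)))
    stop("events need `timestamp` and `location` columns", call. = FALSE)
  ev <- events
  ev$timestamp <- .as_time(ev$timestamp)
  if ("state" %in% names(ev)) ev <- ev[ev$state == 1, , drop = FALSE]
  ev <- ev[order(ev$timestamp), , drop = FALSE]        # stable sort
  ev[!duplicated(ev$timestamp), , drop = FALSE]
}

#' Encode sensor events into a per-minute activity sequence
#'
#' Converts a binary occupancy event log into the encoded activity
#' sequence: one odd room code per sample interval, so that repetition of a
#' code reflects the time spent in the room. Only activations are used
#' (deactivations carry no location-change information); when several
#' sensors activate at the same timestamp the first in log order wins.
#'
#' Each sample interval takes the code of the room occupied at its
#' midpoint, i.e. the room of the most recent activation at or before the
#' midpoint — equivalent to rounding activation times to the nearest sample
#' boundary. Gaps carry the last room forward; minutes before the first
#' activation carry the last known room back from events preceding the
#' window, or, failing that, the first room activated within it.
#'
#' @param events Data frame with `timestamp` (POSIXct or parseable),
#'   `location`, and optionally `state` (1 = activation; other rows are
#'   ignored). May extend beyond the window; earlier events provide the
#'   carry-back state.
#' @param code_map Named integer vector from [build_code_map()].
#' @param start Window start time.
#' @param duration Window length in minutes (default one day).
#' @param resolution Minutes per sample (default 1).
#' @return An `activity_seq`: integer vector of codes with attributes
#'   `start` and `resolution`.
#' @examples
#' ev <- data.frame(
#'   timestamp = as.POSIXct("2024-01-01 09:00:01", tz = "UTC"),
#'   location = "Bedroom", state = 1
#' )
#' encode_events(ev, build_code_map("Bedroom"), "2024-01-01 09:00:00",
#'               duration = 10)
#' @export
encode_events <- function(events, code_map, start, duration = 1440,
                          resolution = 1) {
  start <- .as_time(start)
  if (duration %% resolution != 0)
    stop("`duration` must be divisible by `resolution`", call. = FALSE)
  ev <- .prepare_activations(events)
  unknown <- setdiff(unique(ev$location), names(code_map))
  if (length(unknown))
    stop("locations missing from code map: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  ns <- as.integer(duration / resolution)
  mid <- as.numeric(start) + (seq_len(ns) - 1) * resolution * 60 +
    resolution * 30
  idx <- findInterval(mid, as.numeric(ev$timestamp))
  if (any(idx == 0L)) {
    # no prior occupancy: carry the first in-window room back to the start
    wend <- as.numeric(start) + duration * 60
    first_in <- which(as.numeric(ev$timestamp) < wend)
    if (!length(first_in))
      stop("no occupancy information before or within the window",
           call. = FALSE)
    idx[idx == 0L] <- first_in[1L]
  }
  codes <- unname(code_map[ev$location[idx]])
  structure(as.integer(codes), start = start,
            resolution = resolution, class = "activity_seq")
}

#' Encode a multi-day event log day by day
#'
#' Splits the log at local midnights and encodes each day separately with
#' [encode_events()], so that windows never span a day boundary.
#'
#' @inheritParams encode_events
#' @param start Midnight opening the first day; defaults to the midnight
#'   (UTC) on or before the first event.
#' @param days Number of days; defaults to the number needed to cover the
#'   last event.
#' @return List of `activity_seq`, one per day.
#' @export
encode_days <- function(events, code_map, start = NULL, days = NULL,
                        resolution = 1) {
  ev <- .prepare_activations(events)
  if (!nrow(ev)) stop("no activation events to encode", call. = FALSE)
  if (is.null(start)) {
    start <- as.POSIXct(trunc(min(ev$timestamp), units = "days"), tz = "UTC")
  } else start <- .as_time(start)
  if (is.null(days))
    days <- ceiling(as.numeric(difftime(max(ev$timestamp), start,
                                        units = "days")))
  days <- max(1L, as.integer(days))
  lapply(seq_len(days) - 1L, function(d)
    encode_events(ev, code_map, start + d * 86400,
                  duration = 1440, resolution = resolution))
}

#' @export
print.activity_seq <- function(x, ...) {
  cat(sprintf("<activity_seq> %d samples @ %g min from %s\n",
              length(x), attr(x, "resolution"),
              format(attr(x, "start"), "%Y-%m-%d %H:%M", tz = "UTC")))
  codes <- as.integer(x)
  show <- if (length(codes) > 30) c(codes[1:30], NA) else codes
  cat(" ", paste(ifelse(is.na(show), "...", show), collapse = " "), "\n")
  invisible(x)
}

#' Indoor mobility: room-to-room transition count
#'
#' Baseline activity statistic: the number of sample positions at which the
#' encoded room code differs from the previous one.
#'
#' @param x An `activity_seq` or plain numeric code vector.
#' @return Integer transition count.
#' @examples
#' indoor_mobility(c(3, 3, 9, 1, 1, 9, 1))  # 4
#' @export
indoor_mobility <- function(x) {
  x <- as.numeric(x)
  if (!length(x)) stop("empty sequence", call. = FALSE)
  sum(diff(x) != 0)
}
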