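.TS_FMT <- "%Y-%m-%dT%H:%M:%S"

.parse_ts <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  out <- as.POSIXct(x, tz = "UTC", format = .TS_FMT)
  bad <- is.na(out) & !is.na(x)
  if (any(bad))  # tolerate a space separator too
    out[bad] <- as.POSIXct(x[bad], tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  if (anyNA(out[!is.na(x)])) stop("unparseable timestamp(s)", call. = FALSE)
  out
}

#' Read and write occupancy event logs
#'
#' Plain-CSV event-log dialect: columns `timestamp` (ISO-8601, second
#' resolution, UTC), `location`, `state` (1 = activation, 0 =
#' deactivation). The reader tolerates unsorted rows and sorts them stably;
#' the writer emits the same dialect. Lines starting with `#` are treated
#' as comments.
#'
#' @param path File path.
#' @return `read_events()`: data frame with POSIXct `timestamp`,
#'   character `location`, integer `state`.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c(location = "character"))
  if (!all(c("timestamp", "location") %in% names(df)))
    stop("event CSV needs timestamp, location[, state] columns",
         call. = FALSE)
  df$timestamp <- .parse_ts(df$timestamp)
  if (is.null(df$state)) df$state <- 1L
  df$state <- as.integer(df$state)
  df[order(df$timestamp), , drop = FALSE]
}

#' @rdname read_events
#' @param events Event data frame (`timestamp`, `location`, `state`).
#' @param header Optional character vector written as leading `#` comment
#'   lines (e.g. the generating parameters).
#' @export
write_events <- function(events, path, header = NULL) {
  df <- data.frame(timestamp = format(.as_time(events$timestamp), .TS_FMT,
                                      tz = "UTC"),
                   location = events$location,
                   state = if (is.null(events$state)) 1L else
                     as.integer(events$state))
  con <- file(path, "w"); on.exit(close(con))
  if (length(header)) writeLines(paste("#", header), con)
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read and write ground-truth visit intervals
#'
#' CSV dialect: `start`, `end` (ISO-8601, UTC) and `visitor_id`.
#'
#' @param path File path.
#' @return `read_visits()`: data frame with POSIXct `start`/`end` and
#'   character `visitor_id`.
#' @export
read_visits <- function(path) {
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c(visitor_id = "character"))
  df$start <- .parse_ts(df$start)
  df$end <- .parse_ts(df$end)
  df[order(df$start), , drop = FALSE]
}

#' @rdname read_visits
#' @param visits Visit data frame (`start`, `end`, `visitor_id`).
#' @inheritParams write_events
#' @export
write_visits <- function(visits, path, header = NULL) {
  df <- data.frame(start = format(.as_time(visits$start), .TS_FMT, tz = "UTC"),
                   end = format(.as_time(visits$end), .TS_FMT, tz = "UTC"),
                   visitor_id = if (is.null(visits$visitor_id)) "visitor"
                     else visits$visitor_id)
  con <- file(path, "w"); on.exit(close(con))
  if (length(header)) writeLines(paste("#", header), con)
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write per-window detection results
#'
#' One CSV row per window: `window_start`, `length`, `shift`, `measure`,
#' `value`, `threshold`, `flag` (plus `overlap_pct`/`truth` when ground
#' truth was supplied). The run configuration is recorded in `#` header
#' lines so every result file is self-describing.
#'
#' @param fit A [detect_visitors()] result.
#' @param path File path.
#' @export
write_detections <- function(fit, path) {
  stopifnot(inherits(fit, "visitor_detection"))
  w <- fit$windows
  w$window_start <- format(w$window_start, .TS_FMT, tz = "UTC")
  w$value <- formatC(w$value, digits = 15, format = "g")
  w$threshold <- formatC(w$threshold, digits = 15, format = "g")
  cfg <- fit$config
  hdr <- paste(names(cfg), vapply(cfg, function(v)
    paste(format(v), collapse = ","), ""), sep = "=")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste("#", hdr), con)
  utils::write.csv(w[setdiff(names(w), "day")], con, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}
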