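# Merge overlapping/adjacent visit intervals into a disjoint union.
.union_intervals <- function(start, end) {
  o <- order(start)
  start <- as.numeric(start)[o]; end <- as.numeric(end)[o]
  us <- start[1L]; ue <- end[1L]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= ue) ue <- max(ue, end[i])
    else { out_s <- c(out_s, us); out_e <- c(out_e, ue)
           us <- start[i]; ue <- end[i] }
  }
  cbind(start = c(out_s, us), end = c(out_e, ue))
}

#' Ground-truth labels for a window grid
#'
#' Labels each window as a visitor window iff the fraction of the window
#' covered by the union of the ground-truth visit intervals reaches
#' `min_overlap` percent. Overlapping visits are unioned before labelling,
#' so a window straddling two visits is credited with their combined
#' coverage.
#'
#' @param windows Window data frame with `window_start` (POSIXct) and
#'   `length` (minutes) columns, e.g. from [entropy_series()].
#' @param visits Data frame of visit intervals with `start` and `end`
#'   columns (POSIXct or parseable); zero rows mean no visits.
#' @param min_overlap Minimum covered percentage for a visitor label
#'   (default 30, the best-performing overlap regime).
#' @return `windows` with numeric `overlap_pct` and logical `truth`
#'   columns appended.
#' @export
label_windows <- function(windows, visits, min_overlap = 30) {
  if (min_overlap < 0 || min_overlap > 100)
    stop("`min_overlap` must be in [0, 100]", call. = FALSE)
  if (is.null(visits) || !nrow(visits)) {
    windows$overlap_pct <- 0
    windows$truth <- FALSE
    return(windows)
  }
  vs <- .as_time(visits$start); ve <- .as_time(visits$end)
  if (any(as.numeric(ve) <= as.numeric(vs)))
    stop("visit intervals must have start < end", call. = FALSE)
  u <- .union_intervals(vs, ve)
  ws <- as.numeric(windows$window_start)
  len <- windows$length * 60
  ol <- rep(0, nrow(windows))
  for (i in seq_len(nrow(u)))
    ol <- ol + pmax(0, pmin(u[i, "end"], ws + len) - pmax(u[i, "start"], ws))
  windows$overlap_pct <- 100 * ol / len
  windows$truth <- windows$overlap_pct >= min_overlap
  windows
}

#' Confusion counts for window-level detection
#'
#' Tallies flagged windows against truth labels on the same grid. The
#' evaluation unit is the window: a visit spanning several windows
#' contributes several positives.
#'
#' @param flag Logical vector of detection flags.
#' @param truth Logical vector of ground-truth labels, same length.
#' @return A `confusion_counts` named integer vector `(tp, fp, tn, fn)`.
#' @examples
#' confusion_counts(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
confusion_counts <- function(flag, truth) {
  if (length(flag) != length(truth))
    stop("flag/truth grids differ in length", call. = FALSE)
  flag <- as.logical(flag); truth <- as.logical(truth)
  if (anyNA(flag) || anyNA(truth))
    stop("flags and truth labels must not contain NA", call. = FALSE)
  structure(c(tp = sum(flag & truth), fp = sum(flag & !truth),
              tn = sum(!flag & !truth), fn = sum(!flag & truth)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion: TP %d  FP %d  TN %d  FN %d  (n = %d)\n",
              x["tp"], x["fp"], x["tn"], x["fn"], sum(x)))
  invisible(x)
}

#' Accuracy, precision and recall from confusion counts
#'
#' Percentages on 0-100: accuracy `100 (tp + tn) / n`, precision
#' `100 tp / (tp + fp)`, recall `100 tp / (tp + fn)`. A metric with a zero
#' denominator is undefined and reported as `NA` rather than substituted.
#'
#' @param counts A [confusion_counts()] vector, or anything coercible to a
#'   named numeric vector with elements tp, fp, tn, fn.
#' @return A `detection_metrics` list with `counts`, `accuracy`,
#'   `precision`, `recall`.
#' @examples
#' detection_metrics(confusion_counts(rep(TRUE, 3), rep(TRUE, 3)))
#' @export
detection_metrics <- function(counts) {
  stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(counts)))
  tp <- as.numeric(counts["tp"]); fp <- as.numeric(counts["fp"])
  tn <- as.numeric(counts["tn"]); fn <- as.numeric(counts["fn"])
  total <- tp + fp + tn + fn
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(list(counts = counts,
                 accuracy = ratio(tp + tn, total),
                 precision = ratio(tp, tp + fp),
                 recall = ratio(tp, tp + fn)),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, digits = 1, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else
    paste0(format(round(v, digits)), "%")
  print(x$counts)
  cat(sprintf("accuracy %s  precision %s  recall %s\n",
              fmt(x$accuracy), fmt(x$precision), fmt(x$recall)))
  invisible(x)
}
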