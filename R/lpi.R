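#' Labor Pain Index
#'
#' `LPI = TA * TLP`: the number of activity-flagged records in a time window
#' multiplied by the number of records the classifier labeled labor in that
#' window. The product rewards windows where the animal is both continuously
#' moving and holding the lateral labor posture. For example
#' `labor_pain_index(400, 40) == 16000`.
#'
#' @param ta Total activity count in the window (>= 0).
#' @param tlp Total labor-classified count in the window (>= 0).
#' @return `ta * tlp` (vectorized, exact integer product for integer input).
#' @export
labor_pain_index <- function(ta, tlp) {
  if (any(ta < 0) || any(tlp < 0)) {
    stop("labor_pain_index requires non-negative counts")
  }
  ta * tlp
}

#' Activity and labor counts within one time window
#'
#' Counts, over the half-open window `[window_start, window_start +
#' window_len_sec)`, the records flagged active (`ta`) and the records
#' classified as labor (`tlp`).
#'
#' @param records Record data.frame.
#' @param labels Integer label vector aligned 1:1 with `records`.
#' @param window_start POSIXct window start.
#' @param window_len_sec Window length, seconds.
#' @return Named vector `c(ta = ..., tlp = ...)`.
#' @export
window_counts <- function(records, labels, window_start, window_len_sec) {
  if (length(labels) != nrow(records)) {
    stop("labels are misaligned with records")
  }
  inside <- records$timestamp >= window_start &
    records$timestamp < window_start + window_len_sec
  c(ta = sum(records$activity[inside]), tlp = sum(labels[inside] == 1L))
}

#' Labor Pain Index series over a record stream
#'
#' Slides a window of `window_min` minutes over the stream, advancing by
#' `stride_sec` seconds from the first record's timestamp, and computes
#' `(TA, TLP, LPI)` for every window. Labels come either from a fitted
#' classifier (applied via [predict_stream()]) or from a precomputed label
#' vector.
#'
#' @param records Time-ordered record data.frame.
#' @param model Optional `labor_classifier`.
#' @param labels Optional precomputed label vector (used if `model` is
#'   `NULL`).
#' @param window_min Window length, minutes.
#' @param stride_sec Stride between consecutive window starts, seconds
#'   (default 60; set to `window_min * 60` for disjoint tiling windows).
#' @param goat_id Identifier attached to every window row.
#' @return data.frame of class `lpi_series` with columns
#'   `goat_id, window_start, window_end, ta, tlp, lpi` and attributes
#'   `window_min`, `stride_sec`.
#' @export
lpi_series <- function(records, model = NULL, labels = NULL, window_min = 10,
                       stride_sec = 60, goat_id = "goat") {
  if (window_min <= 0) stop("window_min must be positive")
  if (stride_sec <= 0) stop("stride_sec must be positive")
  if (nrow(records) > 1L && is.unsorted(as.numeric(records$timestamp))) {
    stop("records must be time-ordered")
  }
  if (!is.null(model)) {
    labels <- predict_stream(model, records)
  } else if (is.null(labels)) {
    stop("either model or labels must be supplied")
  }
  if (length(labels) != nrow(records)) {
    stop("labels are misaligned with records")
  }
  len <- window_min * 60
  if (nrow(records) == 0L) {
    out <- data.frame(goat_id = character(0),
                      window_start = as.POSIXct(character(0), tz = "UTC"),
                      window_end = as.POSIXct(character(0), tz = "UTC"),
                      ta = integer(0), tlp = integer(0), lpi = numeric(0))
    return(structure(out, window_min = window_min, stride_sec = stride_sec,
                     class = c("lpi_series", "data.frame")))
  }
  t <- as.numeric(records$timestamp)
  starts <- seq(t[1], t[length(t)], by = stride_sec)
  cum_a <- c(0L, cumsum(as.integer(records$activity)))
  cum_l <- c(0L, cumsum(as.integer(labels == 1L)))
  lo <- findInterval(starts - 0.5, t)        # records strictly before start
  hi <- findInterval(starts + len - 0.5, t)  # records before start + len
  ta <- cum_a[hi + 1L] - cum_a[lo + 1L]
  tlp <- cum_l[hi + 1L] - cum_l[lo + 1L]
  out <- data.frame(
    goat_id = goat_id,
    window_start = as.POSIXct(starts, tz = "UTC", origin = "1970-01-01"),
    window_end = as.POSIXct(starts + len, tz = "UTC", origin = "1970-01-01"),
    ta = ta, tlp = tlp, lpi = labor_pain_index(ta, tlp),
    stringsAsFactors = FALSE
  )
  structure(out, window_min = window_min, stride_sec = stride_sec,
            class = c("lpi_series", "data.frame"))
}

#' Restrict an LPI series to a time span
#'
#' Keeps windows whose start lies in `[from, to]`.
#'
#' @param series An `lpi_series`.
#' @param from,to POSIXct bounds (either may be `NULL`).
#' @return The filtered series (attributes preserved).
#' @export
window_slice <- function(series, from = NULL, to = NULL) {
  keep <- rep(TRUE, nrow(series))
  if (!is.null(from)) keep <- keep & series$window_start >= from
  if (!is.null(to)) keep <- keep & series$window_start <= to
  out <- series[keep, ]
  rownames(out) <- NULL
  attributes(out)$window_min <- attr(series, "window_min")
  attributes(out)$stride_sec <- attr(series, "stride_sec")
  class(out) <- class(series)
  out
}

#' Highest-LPI window of a day
#'
#' Returns the window with the maximal LPI among windows starting on the
#' given calendar day (or over the whole series if `day` is `NULL`). Ties
#' are broken in favor of the earliest window start.
#'
#' @param series An `lpi_series`.
#' @param day Optional `Date` restricting the search to windows starting on
#'   that UTC day.
#' @return The winning window as a one-row data.frame.
#' @export
daily_max_lpi <- function(series, day = NULL) {
  sub <- series
  if (!is.null(day)) {
    sub <- series[as.Date(series$window_start, tz = "UTC") == as.Date(day), ]
  }
  if (nrow(sub) == 0L) stop("no windows in the requested day")
  sub <- sub[order(sub$window_start), ]
  out <- sub[which.max(sub$lpi), ]
  rownames(out) <- NULL
  out
}

#' Write an LPI series to CSV
#'
#' @param series An `lpi_series`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_lpi_series <- function(series, path) {
  out <- as.data.frame(series)
  out$window_start <- format_ts(out$window_start)
  out$window_end <- format_ts(out$window_end)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
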