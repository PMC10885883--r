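#' @title Sensor record and label-interval file I/O
#' @description Read and write the cloud-server CSV dialect of the
#'   accelerometer stream (`data_number,gateway_id,timestamp,rssi,battery,
#'   activity,x,y,z`, timestamps ISO-8601 UTC at 1-s resolution, activity
#'   encoded 1/0) and behavior-label interval files
#'   (`goat_id,label,start,end`, half-open `[start, end)`), and assemble
#'   labeled training datasets from them.
#' @name sensor_io
NULL

RECORD_COLUMNS <- c("data_number", "gateway_id", "timestamp", "rssi",
                    "battery", "activity", "x", "y", "z")

format_ts <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

parse_ts <- function(s) {
  t <- as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  miss <- is.na(t) & !is.na(s) & nzchar(s)
  if (any(miss)) {
    t[miss] <- as.POSIXct(s[miss], format = "%Y-%m-%d %H:%M:%OS", tz = "UTC")
  }
  t
}

#' Write an accelerometer record stream to CSV
#'
#' @param records Record data.frame as produced by [simulate_goat()] or
#'   [read_records()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  out <- records[, RECORD_COLUMNS]
  out$timestamp <- format_ts(out$timestamp)
  out$activity <- as.integer(out$activity)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an accelerometer record stream from CSV
#'
#' Parses every row; rows with an unparseable timestamp, non-integer axis
#' values, or a missing activity flag are counted, reported with their line
#' numbers in a warning, and excluded from the returned data -- never
#' silently dropped. The axis columns are not clipped: raw streams may
#' legitimately contain out-of-range values destined for [range_filter()].
#'
#' @param path CSV file with header
#'   `data_number,gateway_id,timestamp,rssi,battery,activity,x,y,z`.
#' @return Record data.frame, time-ordered, with attributes `n_malformed`
#'   (count of rejected rows) and `malformed_lines` (their 1-based data line
#'   numbers).
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("record file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(RECORD_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("record file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  if (n == 0L) {
    rec <- empty_records()
    attr(rec, "n_malformed") <- 0L
    attr(rec, "malformed_lines") <- integer(0)
    return(rec)
  }
  ts <- parse_ts(raw$timestamp)
  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  x <- num("x"); y <- num("y"); z <- num("z")
  act <- raw$activity %in% c("1", "0", "TRUE", "FALSE")
  bad <- is.na(ts) | is.na(x) | is.na(y) | is.na(z) | !act
  if (any(bad)) {
    warning(sum(bad), " malformed row(s) in ", path, " at line(s) ",
            paste(utils::head(which(bad), 20), collapse = ", "),
            call. = FALSE)
  }
  keep <- which(!bad)
  rec <- data.frame(
    data_number = suppressWarnings(as.integer(raw$data_number[keep])),
    gateway_id = raw$gateway_id[keep],
    timestamp = ts[keep],
    rssi = suppressWarnings(as.integer(raw$rssi[keep])),
    battery = suppressWarnings(as.integer(raw$battery[keep])),
    activity = raw$activity[keep] %in% c("1", "TRUE"),
    x = as.integer(x[keep]), y = as.integer(y[keep]), z = as.integer(z[keep]),
    stringsAsFactors = FALSE
  )
  if (nrow(rec) > 1L && is.unsorted(rec$timestamp)) {
    rec <- rec[order(rec$timestamp), ]
    rownames(rec) <- NULL
  }
  attr(rec, "n_malformed") <- sum(bad)
  attr(rec, "malformed_lines") <- which(bad)
  rec
}

#' Write behavior-label intervals to CSV
#'
#' @param intervals data.frame with columns `goat_id, label, start, end`
#'   (half-open `[start, end)`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_label_intervals <- function(intervals, path) {
  out <- intervals[, c("goat_id", "label", "start", "end")]
  out$start <- format_ts(out$start)
  out$end <- format_ts(out$end)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read behavior-label intervals from CSV
#'
#' @param path CSV with header `goat_id,label,start,end`.
#' @return data.frame with POSIXct `start`/`end` and integer `label`.
#' @export
read_label_intervals <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  need <- c("goat_id", "label", "start", "end")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("interval file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  iv <- data.frame(goat_id = raw$goat_id, label = as.integer(raw$label),
                   start = parse_ts(raw$start), end = parse_ts(raw$end),
                   stringsAsFactors = FALSE)
  validate_intervals(iv)
  iv
}

validate_intervals <- function(iv) {
  if (!all(iv$label %in% c(0L, 1L))) stop("interval labels must be 0 or 1")
  if (any(!(iv$start < iv$end))) stop("intervals must satisfy start < end")
  for (g in unique(iv$goat_id)) {
    sub <- iv[iv$goat_id == g, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1L &&
        any(as.numeric(sub$start[-1]) < as.numeric(sub$end[-nrow(sub)]))) {
      stop("overlapping intervals for goat ", g)
    }
  }
  invisible(iv)
}

#' Derive training label intervals from simulation ground truth
#'
#' Labels the labor episode 1 and, by default, the stretch of the 12 hours
#' preceding the first birth that lies before labor onset 0 -- mirroring a
#' protocol in which non-labor reference behavior is drawn from the half-day
#' before parturition.
#'
#' @param truths List of `goat_truth` objects (or a `goat_herd`).
#' @param pre_birth_hours Hours before first birth from which non-labor
#'   data are drawn (default 12).
#' @return Interval data.frame (`goat_id, label, start, end`).
#' @export
make_label_intervals <- function(truths, pre_birth_hours = 12) {
  truths <- as_truth_list(truths)
  rows <- lapply(truths, function(tr) {
    if (is.na(tr$birth_time)) return(NULL)
    nl_start <- max(tr$start_time, tr$birth_time - pre_birth_hours * 3600)
    data.frame(
      goat_id = tr$goat_id,
      label = c(1L, 0L),
      start = c(tr$labor_onset, nl_start),
      end = c(tr$labor_end, tr$labor_onset),
      stringsAsFactors = FALSE
    )
  })
  iv <- do.call(rbind, rows)
  rownames(iv) <- NULL
  validate_intervals(iv)
}

as_truth_list <- function(x) {
  if (inherits(x, "goat_herd")) return(lapply(x, `[[`, "truth"))
  if (inherits(x, "goat_truth")) return(list(x))
  x
}

as_records_list <- function(x) {
  if (inherits(x, "goat_herd")) {
    return(stats::setNames(lapply(x, `[[`, "records"), names(x)))
  }
  if (is.data.frame(x)) return(list(x))
  x
}

#' Assemble a labeled training dataset
#'
#' Every record whose timestamp falls inside a labeled interval (half-open
#' `[start, end)`) contributes one sample carrying its axis counts and the
#' interval's label; records outside all intervals are excluded. Per-label
#' counts are attached as an attribute. Optionally the classes are balanced
#' by seeded downsampling to the size of the smaller class (or to
#' `per_class_n`).
#'
#' @param records A `goat_herd`, or a named list of per-goat record
#'   data.frames.
#' @param intervals Label interval data.frame
#'   (`goat_id, label, start, end`).
#' @param balance If `TRUE`, downsample so both classes have equal size.
#' @param per_class_n Optional cap on the per-class sample count (implies
#'   balancing to `min(per_class_n, class sizes)`).
#' @param seed Seed for the downsampling draw.
#' @return data.frame with columns
#'   `goat_id, timestamp, x, y, z, activity, label` and attribute
#'   `class_counts` (pre-balancing per-label tallies).
#' @export
build_dataset <- function(records, intervals, balance = FALSE,
                          per_class_n = NULL, seed = 1L) {
  recs <- as_records_list(records)
  missing_goats <- setdiff(unique(intervals$goat_id), names(recs))
  if (length(missing_goats) && !is.null(names(recs))) {
    stop("intervals reference goats absent from records: ",
         paste(missing_goats, collapse = ", "))
  }
  pieces <- lapply(seq_len(nrow(intervals)), function(i) {
    iv <- intervals[i, ]
    r <- if (is.null(names(recs))) recs[[1]] else recs[[iv$goat_id]]
    inside <- r$timestamp >= iv$start & r$timestamp < iv$end
    if (!any(inside)) return(NULL)
    data.frame(goat_id = iv$goat_id, timestamp = r$timestamp[inside],
               x = r$x[inside], y = r$y[inside], z = r$z[inside],
               activity = r$activity[inside], label = iv$label,
               stringsAsFactors = FALSE)
  })
  ds <- do.call(rbind, pieces)
  if (is.null(ds)) {
    ds <- data.frame(goat_id = character(0),
                     timestamp = as.POSIXct(character(0), tz = "UTC"),
                     x = integer(0), y = integer(0), z = integer(0),
                     activity = logical(0), label = integer(0))
  }
  rownames(ds) <- NULL
  counts <- table(factor(ds$label, levels = c(0L, 1L)))
  for (lab in unique(intervals$label)) {
    if (counts[as.character(lab)] == 0L) {
      stop("no samples found for requested label ", lab)
    }
  }
  if (balance || !is.null(per_class_n)) {
    target <- min(counts[counts > 0])
    if (!is.null(per_class_n)) target <- min(target, per_class_n)
    set.seed(seed)
    keep <- unlist(lapply(c(0L, 1L), function(lab) {
      i <- which(ds$label == lab)
      if (length(i) > target) sort(sample(i, target)) else i
    }))
    ds <- ds[sort(keep), ]
    rownames(ds) <- NULL
  }
  attr(ds, "class_counts") <- counts
  ds
}

#' Write a simulated herd to disk
#'
#' One sensor CSV per goat (`<goat_id>.csv`), a ground-truth behavior
#' interval file (`states.csv`: goat id, state, ISO-8601 start/end), and a
#' birth-time table (`births.csv`).
#'
#' @param herd A `goat_herd`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_herd <- function(herd, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(herd)) {
    write_records(herd[[nm]]$records, file.path(dir, paste0(nm, ".csv")))
  }
  states <- do.call(rbind, lapply(herd, function(g) {
    tr <- g$truth
    if (!length(tr$states)) return(NULL)
    r <- rle(tr$states)
    ends <- cumsum(r$lengths)
    starts <- c(1L, utils::head(ends, -1) + 1L)
    t0 <- as.numeric(tr$start_time)
    data.frame(goat_id = tr$goat_id, state = r$values,
               start = format_ts(as.POSIXct(t0 + starts - 1, tz = "UTC",
                                            origin = "1970-01-01")),
               end = format_ts(as.POSIXct(t0 + ends, tz = "UTC",
                                          origin = "1970-01-01")),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(states, file.path(dir, "states.csv"), row.names = FALSE,
                   quote = FALSE)
  births <- do.call(rbind, lapply(herd, function(g) {
    data.frame(goat_id = g$truth$goat_id,
               birth_time = ifelse(is.na(g$truth$birth_time), "",
                                   format_ts(g$truth$birth_time)),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(births, file.path(dir, "births.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}
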