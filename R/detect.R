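#' Scan one day's LPI series for a parturition crossing
#'
#' Raises a detection event at the first window whose LPI strictly exceeds
#' the three-sigma threshold; later crossings the same day are suppressed
#' (one alarm per goat per day). A window exactly at the threshold does not
#' trigger.
#'
#' @param series An `lpi_series` (typically the parturition-day slice).
#' @param tckg Calibrated LPI threshold (> 0).
#' @param mdv Optional mean detection-to-birth offset (minutes); if given,
#'   the event carries the predicted first-birth time `ppt = dpt + mdv`.
#' @return A `detection_event` (`goat_id`, `dpt`, `ppt`, `window` -- the
#'   triggering row), or `NULL` if no window crosses.
#' @export
detect_day <- function(series, tckg, mdv = NULL) {
  if (!is.numeric(tckg) || tckg <= 0) stop("tckg must be a positive threshold")
  if (nrow(series) == 0L) {
    warning("empty LPI series: no detection possible")
    return(NULL)
  }
  idx <- which(series$lpi > tckg)
  if (length(idx) == 0L) return(NULL)
  win <- series[idx[1], ]
  dpt <- win$window_start
  structure(
    list(goat_id = win$goat_id, dpt = dpt,
         ppt = if (is.null(mdv) || is.na(mdv)) as.POSIXct(NA)
               else predict_first_birth(dpt, mdv),
         window = win, tckg = tckg),
    class = "detection_event"
  )
}

#' Predict the first-birth time from a detection
#'
#' `PPT = DPT + MDV`: the predicted parturition (first-birth) time is the
#' detected parturition time plus the calibrated mean offset.
#'
#' @param dpt Detected parturition time (POSIXct).
#' @param mdv Mean detection-to-birth offset, minutes (finite).
#' @return Predicted first-birth time (POSIXct).
#' @export
predict_first_birth <- function(dpt, mdv) {
  if (!is.finite(mdv)) stop("mdv must be finite")
  dpt + mdv * 60
}

#' @export
print.detection_event <- function(x, ...) {
  cat(sprintf("Parturition detected for %s at %s (LPI %.0f > threshold %.2f)\n",
              x$goat_id, format(x$dpt, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
              x$window$lpi, x$tckg))
  if (!is.na(x$ppt)) {
    cat(sprintf("Predicted first birth: %s\n",
                format(x$ppt, "%Y-%m-%d %H:%M:%S", tz = "UTC")))
  }
  invisible(x)
}

round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Evaluate detection performance against ground truth
#'
#' A goat counts as detected when its parturition-day series raised an
#' event. Rates are percentages rounded half-up to one decimal (so 14 of 17
#' gives 82.4% detected / 17.6% missed). Lead time is `birth - dpt` in
#' minutes (positive when detection precedes birth). Events raised on
#' declared non-parturition (control) days count as false alarms.
#'
#' @param events Named list of `detection_event`s or `NULL`s, one entry per
#'   goat with a parturition day.
#' @param truths List of `goat_truth` objects (or a `goat_herd`) carrying
#'   the birth times.
#' @param control_events Optional list of events from non-parturition days
#'   (each non-`NULL` entry is a false alarm).
#' @return Object of class `evaluation_report`: `n_goats`, `n_detected`,
#'   `detection_rate`, `n_missed`, `failure_rate`, `false_alarms`,
#'   `n_control_days`, `lead_times_min` (named, detected goats only).
#' @export
evaluate_detection <- function(events, truths, control_events = list()) {
  truths <- as_truth_list(truths)
  names(truths) <- vapply(truths, `[[`, character(1), "goat_id")
  part_goats <- names(truths)[!vapply(truths, function(tr) is.na(tr$birth_time),
                                      logical(1))]
  unknown <- setdiff(names(events)[!vapply(events, is.null, logical(1))],
                     names(truths))
  if (length(unknown)) {
    stop("events refer to unknown goats: ", paste(unknown, collapse = ", "))
  }
  detected <- part_goats[vapply(part_goats, function(g) {
    !is.null(events[[g]])
  }, logical(1))]
  n <- length(part_goats)
  nd <- length(detected)
  lead <- vapply(detected, function(g) {
    as.numeric(difftime(truths[[g]]$birth_time, events[[g]]$dpt,
                        units = "mins"))
  }, numeric(1))
  structure(
    list(n_goats = n, n_detected = nd,
         detection_rate = if (n) round_half_up(100 * nd / n) else NA_real_,
         n_missed = n - nd,
         failure_rate = if (n) round_half_up(100 * (n - nd) / n) else NA_real_,
         false_alarms = sum(!vapply(control_events, is.null, logical(1))),
         n_control_days = length(control_events),
         lead_times_min = lead),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Parturition detection: %d of %d goats (%.1f%%); missed %d (%.1f%%)\n",
              x$n_detected, x$n_goats, x$detection_rate, x$n_missed,
              x$failure_rate))
  if (x$n_control_days > 0) {
    cat(sprintf("False alarms: %d on %d non-parturition days\n",
                x$false_alarms, x$n_control_days))
  }
  if (length(x$lead_times_min)) {
    cat(sprintf("Detection lead time: mean %.1f min (sd %.2f)\n",
                mean(x$lead_times_min),
                if (length(x$lead_times_min) > 1)
                  stats::sd(x$lead_times_min) else 0))
  }
  invisible(x)
}

#' Run the calibrated detector over a herd
#'
#' Classifies every record, computes the LPI series at the calibrated
#' window length, scans each goat's parturition day (the `day_hours` up to
#' its birth) for a threshold crossing, estimates the mean
#' detection-to-birth offset from the detected goats, and attaches
#' predicted first-birth times.
#'
#' Non-parturition days are evaluated the way a single-cohort field study
#' must: every goat's own pre-labor span (windows of the parturition day
#' that end before labor onset) is scanned as a labor-free day, and any
#' event there is a false alarm. An additional labor-free `control_herd`
#' can be supplied to scan out-of-sample days as well; note that the
#' three-sigma threshold is calibrated on the cohort's own non-labor
#' windows, so fresh streams probe a strictly harder condition than the
#' within-cohort protocol.
#'
#' @param herd A `goat_herd`.
#' @param model A fitted `labor_classifier`.
#' @param calibration A `calibration` (from [calibrate_herd()] or
#'   [read_calibration()]).
#' @param control_herd Optional labor-free `goat_herd` for an out-of-sample
#'   false-alarm check (its last `day_hours` per goat are scanned).
#' @param day_hours Length of the scanned day, hours (default 24).
#' @return List: `events` (per goat), `prelabor_events` (per-goat
#'   non-parturition-day scans), `control_events` (out-of-sample days, if
#'   any), `report` ([evaluate_detection()] with the non-parturition days
#'   as controls), `calibration` (with `mdv`/`mdv_sd` filled), `series`
#'   (per-goat parturition-day `lpi_series`).
#' @export
run_pipeline <- function(herd, model, calibration, control_herd = NULL,
                         day_hours = 24) {
  stopifnot(inherits(calibration, "calibration"))
  series <- list()
  events <- list()
  for (g in names(herd)) {
    tr <- herd[[g]]$truth
    s <- lpi_series(herd[[g]]$records, model = model,
                    window_min = calibration$window_min,
                    stride_sec = calibration$stride_sec, goat_id = g)
    if (!is.na(tr$birth_time)) {
      s <- window_slice(s, from = tr$birth_time - day_hours * 3600,
                        to = tr$birth_time)
    }
    series[[g]] <- s
    events[g] <- list(detect_day(s, calibration$tckg))
  }
  detected <- vapply(names(events), function(g) {
    !is.null(events[[g]]) && !is.na(herd[[g]]$truth$birth_time)
  }, logical(1))
  if (any(detected)) {
    dpts <- do.call(c, lapply(events[detected], `[[`, "dpt"))
    births <- do.call(c, lapply(names(events)[detected], function(g) {
      herd[[g]]$truth$birth_time
    }))
    off <- mean_offset(dpts, births)
    calibration$mdv <- off$mdv
    calibration$mdv_sd <- off$sd
    for (g in names(events)[detected]) {
      events[[g]]$ppt <- predict_first_birth(events[[g]]$dpt, off$mdv)
    }
  }
  # within-cohort non-parturition days: windows ending before labor onset
  prelabor_events <- list()
  for (g in names(herd)) {
    tr <- herd[[g]]$truth
    if (is.na(tr$birth_time)) next
    pre <- series[[g]][series[[g]]$window_end <= tr$labor_onset, ]
    prelabor_events[g] <- list(
      if (nrow(pre)) detect_day(pre, calibration$tckg) else NULL)
  }
  control_events <- list()
  if (!is.null(control_herd)) {
    for (g in names(control_herd)) {
      s <- lpi_series(control_herd[[g]]$records, model = model,
                      window_min = calibration$window_min,
                      stride_sec = calibration$stride_sec, goat_id = g)
      if (nrow(s)) {
        s <- window_slice(s, from = s$window_start[nrow(s)] - day_hours * 3600)
      }
      control_events[g] <- list(detect_day(s, calibration$tckg))
    }
  }
  report <- evaluate_detection(events, herd, prelabor_events)
  list(events = events, prelabor_events = prelabor_events,
       control_events = control_events, report = report,
       calibration = calibration, series = series)
}

#' Write detection events to CSV
#'
#' Columns `goat_id,dpt,ppt,lpi,ta,tlp`; goats without an event are
#' omitted.
#'
#' @param events Named list of `detection_event`s / `NULL`s.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  rows <- lapply(events[!vapply(events, is.null, logical(1))], function(ev) {
    data.frame(goat_id = ev$goat_id, dpt = format_ts(ev$dpt),
               ppt = if (is.na(ev$ppt)) "" else format_ts(ev$ppt),
               lpi = ev$window$lpi, ta = ev$window$ta, tlp = ev$window$tlp,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(goat_id = character(0), dpt = character(0),
               ppt = character(0), lpi = numeric(0), ta = integer(0),
               tlp = integer(0))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
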