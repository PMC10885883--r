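make_series <- function(lpis, t0 = as.POSIXct("2024-03-05 00:00:00",
                                              tz = "UTC")) {
  n <- length(lpis)
  data.frame(goat_id = rep("g", n), window_start = t0 + (seq_len(n) - 1) * 600,
             window_end = t0 + seq_len(n) * 600,
             ta = rep(1L, n), tlp = as.integer(lpis), lpi = lpis)
}

test_that("detection fires at the first strict threshold crossing only", {
  tckg <- 14240.92
  ev <- detect_day(make_series(c(0, 20000, 30000)), tckg)
  expect_s3_class(ev, "detection_event")
  expect_identical(ev$dpt, make_series(1:3)$window_start[2])
  expect_identical(ev$window$lpi, 20000)
  # a window exactly at the threshold does not trigger
  expect_null(detect_day(make_series(c(tckg, tckg)), tckg))
  # all below: the non-detected case
  expect_null(detect_day(make_series(c(100, 5000, 14000)), tckg))
  # never on an all-zero series
  expect_null(detect_day(make_series(rep(0, 10)), tckg))
  expect_warning(expect_null(detect_day(make_series(numeric(0)), tckg)),
                 "empty")
  expect_error(detect_day(make_series(1), 0), "positive")
})

test_that("the first crossing matches a full-scan oracle on random series", {
  set.seed(23)
  for (i in 1:100) {
    n <- sample(5:80, 1)
    lpis <- stats::rpois(n, 40) * sample(c(1, 100), n, TRUE)
    tckg <- stats::runif(1, 1, 4000)
    ev <- detect_day(make_series(lpis), tckg)
    above <- which(lpis > tckg)
    if (length(above) == 0) {
      expect_null(ev)
    } else {
      expect_identical(ev$dpt, make_series(lpis)$window_start[above[1]])
      expect_true(all(ev$dpt <= make_series(lpis)$window_start[above]))
    }
  }
})

test_that("predicted first birth adds the mean offset exactly", {
  dpt <- as.POSIXct("2024-03-05 10:00:00", tz = "UTC")
  expect_identical(predict_first_birth(dpt, 90.6),
                   as.POSIXct("2024-03-05 11:30:36", tz = "UTC"))
  expect_identical(predict_first_birth(dpt, 0), dpt)
  delta <- 1234
  expect_identical(predict_first_birth(dpt + delta, 90.6),
                   predict_first_birth(dpt, 90.6) + delta)
  expect_error(predict_first_birth(dpt, Inf), "finite")
})

test_that("detection and failure rates follow the one-decimal half-up convention", {
  mk_truth <- function(id, birth) {
    structure(list(goat_id = id, birth_time = birth,
                   labor_onset = birth - 5400, labor_end = birth - 3600,
                   start_time = birth - 86400, states = character(0)),
              class = "goat_truth")
  }
  t0 <- as.POSIXct("2024-03-05 12:00:00", tz = "UTC")
  truths <- lapply(sprintf("g%02d", 1:17), mk_truth, birth = t0)
  mk_event <- function(id) structure(
    list(goat_id = id, dpt = t0 - 5400, ppt = as.POSIXct(NA),
         window = NULL, tckg = 1), class = "detection_event")
  events <- stats::setNames(vector("list", 17), sprintf("g%02d", 1:17))
  for (id in sprintf("g%02d", 1:14)) events[[id]] <- mk_event(id)
  rep14 <- evaluate_detection(events, truths)
  expect_equal(rep14$detection_rate, 82.4)
  expect_equal(rep14$failure_rate, 17.6)
  expect_equal(rep14$detection_rate + rep14$failure_rate, 100)
  expect_equal(unname(rep14$lead_times_min[1]), 90)

  one <- stats::setNames(vector("list", 17), sprintf("g%02d", 1:17))
  one[["g01"]] <- mk_event("g01")
  expect_equal(evaluate_detection(one, truths)$detection_rate, 5.9)

  none <- stats::setNames(vector("list", 17), sprintf("g%02d", 1:17))
  expect_equal(evaluate_detection(none, truths)$detection_rate, 0)

  # control days without events count zero false alarms
  controls <- stats::setNames(vector("list", 17), sprintf("g%02d", 1:17))
  repc <- evaluate_detection(events, truths, control_events = controls)
  expect_identical(repc$false_alarms, 0L)
  expect_identical(repc$n_control_days, 17L)

  stranger <- list(gX = mk_event("gX"))
  expect_error(evaluate_detection(stranger, truths), "unknown")
})

test_that("the pipeline detects simulated labor deterministically", {
  herd <- small_herd()
  ds <- clean_samples(build_dataset(herd, make_label_intervals(herd),
                                    balance = TRUE, seed = 6L))
  clf <- train_labor_classifier(ds, "tree", seed = 6L)
  cal <- calibrate_herd(herd, clf, k = 20L)
  quiet <- simulate_herd(small_config(seed = 77L, include_labor = FALSE))
  run1 <- run_pipeline(herd, clf, cal, control_herd = quiet)
  run2 <- run_pipeline(herd, clf, cal, control_herd = quiet)
  expect_identical(run1$report, run2$report)
  expect_identical(run1$report$n_goats, 2L)
  expect_identical(run1$report$n_detected, 2L)
  # one non-parturition day is scanned per goat with a birth
  expect_identical(run1$report$n_control_days, 2L)
  # detection precedes birth and the labor episode brackets the alarm window
  for (g in names(run1$events)) {
    ev <- run1$events[[g]]
    tr <- herd[[g]]$truth
    expect_true(ev$dpt <= tr$birth_time)
    expect_true(ev$ppt == ev$dpt + run1$calibration$mdv * 60)
  }
  # every reported control event, if any, strictly exceeds the threshold
  for (ev in run1$control_events) {
    if (!is.null(ev)) expect_gt(ev$window$lpi, cal$tckg)
  }
  # a labor-free herd whose index never reaches the threshold stays silent
  quiet_cal <- cal
  quiet_max <- max(vapply(names(quiet), function(g) {
    s <- lpi_series(quiet[[g]]$records, model = clf,
                    window_min = cal$window_min,
                    stride_sec = cal$stride_sec, goat_id = g)
    max(s$lpi)
  }, numeric(1)))
  quiet_cal$tckg <- quiet_max + 1
  quiet_run <- run_pipeline(quiet, clf, quiet_cal)
  expect_true(all(vapply(quiet_run$events, is.null, logical(1))))
  expect_identical(quiet_run$report$n_goats, 0L)
})

test_that("events serialize with the documented columns", {
  herd <- small_herd()
  ds <- clean_samples(build_dataset(herd, make_label_intervals(herd),
                                    balance = TRUE, seed = 6L))
  clf <- train_labor_classifier(ds, "tree", seed = 6L)
  cal <- calibrate_herd(herd, clf, k = 20L)
  run <- run_pipeline(herd, clf, cal)
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(run$events, path)
  ev <- utils::read.csv(path)
  expect_identical(names(ev), c("goat_id", "dpt", "ppt", "lpi", "ta", "tlp"))
  expect_identical(nrow(ev), run$report$n_detected)
})
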