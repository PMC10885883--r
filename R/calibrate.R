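#' Group statistics of window-maximum LPIs
#'
#' Mean and sample standard deviation (n - 1 denominator) of a group of
#' LPIs, plus the group's inner boundary: for the labor group
#' `MSL = mean - sd` (its lower edge), for the non-labor group
#' `MSNL = mean + sd` (its upper edge).
#'
#' @param lpis Numeric vector with at least 2 values.
#' @param context `"labor"` or `"non_labor"`.
#' @return List of class `group_stats`: `context`, `mlpi`, `sdlpi`,
#'   `boundary`, `n`.
#' @export
group_stats <- function(lpis, context = c("labor", "non_labor")) {
  context <- match.arg(context)
  lpis <- lpis[!is.na(lpis)]
  if (length(lpis) < 2L) stop("group_stats needs at least 2 values")
  m <- mean(lpis)
  s <- stats::sd(lpis)
  structure(
    list(context = context, mlpi = m, sdlpi = s,
         boundary = if (context == "labor") m - s else m + s,
         n = length(lpis)),
    class = "group_stats"
  )
}

group_stats_from_moments <- function(m, s, context) {
  structure(
    list(context = context, mlpi = m, sdlpi = s,
         boundary = if (context == "labor") m - s else m + s, n = NA_integer_),
    class = "group_stats"
  )
}

#' Central range value
#'
#' `CRV = MSL - MSNL`, the gap between the labor group's lower boundary and
#' the non-labor group's upper boundary. A positive CRV means the two LPI
#' distributions separate by more than one standard deviation each; the
#' window length maximizing it is the optimal processing window.
#'
#' @param labor `group_stats` with context `"labor"`.
#' @param nonlabor `group_stats` with context `"non_labor"`.
#' @return The CRV (may be negative).
#' @export
central_range_value <- function(labor, nonlabor) {
  if (!inherits(labor, "group_stats") || !inherits(nonlabor, "group_stats") ||
      labor$context != "labor" || nonlabor$context != "non_labor") {
    stop("context mismatch: need labor and non_labor group_stats, in that order")
  }
  labor$boundary - nonlabor$boundary
}

#' Select the optimal processing time window by CRV
#'
#' Computes `MSL`, `MSNL` and `CRV` for each candidate window length and
#' chooses the window with the largest CRV; ties favor the shorter window
#' (earlier detection).
#'
#' Candidates may be given either as a data.frame of moments
#' (`window_min, labor_mean, labor_sd, nonlabor_mean, nonlabor_sd`) or as a
#' list of `list(window_min, labor = group_stats, nonlabor = group_stats)`.
#'
#' @param candidates Candidate window statistics (see above).
#' @return Object of class `window_selection`: `table` (one row per window
#'   with `msl`, `msnl`, `crv`), `chosen` (window minutes) and `crv` (its
#'   CRV).
#' @export
select_window <- function(candidates) {
  if (is.data.frame(candidates)) {
    if (nrow(candidates) == 0L) stop("no candidate windows")
    candidates <- lapply(seq_len(nrow(candidates)), function(i) {
      r <- candidates[i, ]
      list(window_min = r$window_min,
           labor = group_stats_from_moments(r$labor_mean, r$labor_sd, "labor"),
           nonlabor = group_stats_from_moments(r$nonlabor_mean, r$nonlabor_sd,
                                               "non_labor"))
    })
  }
  if (length(candidates) == 0L) stop("no candidate windows")
  tab <- do.call(rbind, lapply(candidates, function(cnd) {
    data.frame(window_min = cnd$window_min,
               labor_mean = cnd$labor$mlpi, labor_sd = cnd$labor$sdlpi,
               msl = cnd$labor$boundary,
               nonlabor_mean = cnd$nonlabor$mlpi,
               nonlabor_sd = cnd$nonlabor$sdlpi,
               msnl = cnd$nonlabor$boundary,
               crv = central_range_value(cnd$labor, cnd$nonlabor))
  }))
  tab <- tab[order(tab$window_min), ]
  rownames(tab) <- NULL
  best <- which(tab$crv == max(tab$crv))[1]  # sorted ascending: tie -> shorter
  structure(
    list(table = tab, chosen = tab$window_min[best], crv = tab$crv[best]),
    class = "window_selection"
  )
}

#' @export
print.window_selection <- function(x, ...) {
  cat("Window selection by central range value (CRV = MSL - MSNL):\n")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(v) sprintf("%.2f", v))
  print(tab, row.names = FALSE)
  cat(sprintf("Chosen window: %g min (CRV %.2f)\n", x$chosen, x$crv))
  invisible(x)
}

#' Three-sigma LPI threshold for parturition classification
#'
#' By the three-sigma rule, an LPI exceeding the non-labor group's mean plus
#' three sample standard deviations is an outlier of non-labor behavior and
#' is classified as parturition: `threshold = mean + 3 * sd`.
#'
#' @param nonlabor_lpis Non-labor LPI pool (>= 2 values).
#' @return The threshold.
#' @seealso [tckg_from_moments()] to apply the rule to precomputed moments.
#' @export
lpi_threshold <- function(nonlabor_lpis) {
  nonlabor_lpis <- nonlabor_lpis[!is.na(nonlabor_lpis)]
  if (length(nonlabor_lpis) < 2L) stop("lpi_threshold needs at least 2 values")
  mean(nonlabor_lpis) + 3 * stats::sd(nonlabor_lpis)
}

#' Three-sigma threshold from precomputed moments
#'
#' @param mean_nl,sd_nl Mean and standard deviation of the non-labor LPI
#'   pool.
#' @return `mean_nl + 3 * sd_nl`.
#' @export
tckg_from_moments <- function(mean_nl, sd_nl) {
  if (sd_nl < 0) stop("sd must be non-negative")
  mean_nl + 3 * sd_nl
}

#' Mean detection-to-first-birth offset
#'
#' Per-pair offset `birth - detection` in minutes; returns its mean (the
#' value added to a detection time to predict the first birth) and sample
#' standard deviation. Pairs with birth before detection are kept but
#' trigger a warning.
#'
#' @param detection_times,birth_times Equal-length POSIXct vectors.
#' @return List: `mdv` (mean offset, minutes), `sd`, `offsets`.
#' @export
mean_offset <- function(detection_times, birth_times) {
  if (length(detection_times) == 0L) stop("no detection/birth pairs")
  if (length(detection_times) != length(birth_times)) {
    stop("detection and birth time vectors must have equal length")
  }
  offsets <- as.numeric(difftime(birth_times, detection_times,
                                 units = "mins"))
  if (any(offsets < 0)) {
    warning("some detections occur after the recorded birth time")
  }
  list(mdv = mean(offsets),
       sd = if (length(offsets) > 1L) stats::sd(offsets) else 0,
       offsets = offsets)
}

#' Normality and mean-difference tests for LPI groups
#'
#' Kolmogorov-Smirnov test of each group against a normal distribution with
#' the group's own estimated mean and SD, and an independent two-sample
#' t-test (equal variances by default, Welch optional) of the parturition
#' versus non-parturition window-maximum LPIs.
#'
#' @param parturition_lpis,nonparturition_lpis Numeric vectors (>= 3 values
#'   each).
#' @param var_equal Use the classical equal-variance t-test (default
#'   `TRUE`).
#' @return List of class `group_validation`: `ks_parturition`,
#'   `ks_nonparturition` (htest objects), `t` (htest), `normal` (both KS
#'   p > 0.05) and `significant` (t-test p < 0.05).
#' @export
validate_groups <- function(parturition_lpis, nonparturition_lpis,
                            var_equal = TRUE) {
  if (length(parturition_lpis) < 3L || length(nonparturition_lpis) < 3L) {
    stop("validate_groups needs at least 3 values per group")
  }
  ks1 <- suppressWarnings(
    stats::ks.test(parturition_lpis, "pnorm", mean(parturition_lpis),
                   stats::sd(parturition_lpis)))
  ks2 <- suppressWarnings(
    stats::ks.test(nonparturition_lpis, "pnorm", mean(nonparturition_lpis),
                   stats::sd(nonparturition_lpis)))
  tt <- stats::t.test(parturition_lpis, nonparturition_lpis,
                      var.equal = var_equal)
  structure(
    list(ks_parturition = ks1, ks_nonparturition = ks2, t = tt,
         normal = ks1$p.value > 0.05 && ks2$p.value > 0.05,
         significant = tt$p.value < 0.05),
    class = "group_validation"
  )
}

#' @export
print.group_validation <- function(x, ...) {
  cat(sprintf("KS normality p: parturition %.3f, non-parturition %.3f (%s)\n",
              x$ks_parturition$p.value, x$ks_nonparturition$p.value,
              if (x$normal) "normality satisfied" else "normality rejected"))
  cat(sprintf("t-test: t = %.2f, p = %.3g (%s)\n", x$t$statistic,
              x$t$p.value,
              if (x$significant) "means differ" else "no significant difference"))
  invisible(x)
}

#' Calibrate the detector on a herd with known birth times
#'
#' For each candidate window length, builds the labor group (each goat's
#' highest LPI on its parturition day, the 24 h up to the first birth) and
#' the non-labor pool (windows in that day ending before labor onset),
#' takes the `k` highest non-labor LPIs (pooled across goats, or the top
#' `k / n_goats` per goat), and computes MSL, MSNL and CRV. The window with
#' the largest CRV is selected and the three-sigma threshold is computed
#' from its non-labor pool.
#'
#' Calibration windows tile the day (disjoint periods, stride equal to the
#' window length) by default, so the `k` highest values sample distinct
#' stretches of behavior rather than near-duplicate overlapping windows;
#' the detector itself slides at `stride_sec`.
#'
#' @param herd A `goat_herd` with labor episodes and birth times.
#' @param model A fitted `labor_classifier`.
#' @param windows Candidate window lengths in minutes (default
#'   `c(8, 10, 12, 14)`).
#' @param stride_sec Detection stride carried into the calibration result,
#'   seconds; `NULL` (default) makes the detector tile with the chosen
#'   window length, i.e. score one index per disjoint period. Set 60 for a
#'   sliding detector with per-minute time resolution.
#' @param pool_stride_sec Stride used when building the calibration window
#'   pools; `NULL` (default) tiles with `window_min * 60`.
#' @param pool `"pooled_topk"` (default) or `"per_goat_topk"`.
#' @param k Size of the non-labor calibration pool (default 110).
#' @param day_hours Span of the parturition day preceding the birth
#'   (default 24).
#' @return Object of class `calibration`: `window_min`, `tckg`, `selection`
#'   (the [select_window()] result), `nonlabor_stats`, `validation`
#'   ([validate_groups()] on the chosen window), `mdv`/`mdv_sd`
#'   (`NA` until filled by [run_pipeline()]), and provenance fields.
#' @export
calibrate_herd <- function(herd, model, windows = c(8, 10, 12, 14),
                           stride_sec = NULL, pool_stride_sec = NULL,
                           pool = c("pooled_topk", "per_goat_topk"),
                           k = 110L, day_hours = 24) {
  pool <- match.arg(pool)
  goats <- names(herd)
  labels <- lapply(herd, function(g) predict_stream(model, g$records))
  per_window <- lapply(windows, function(w) {
    w_stride <- if (is.null(pool_stride_sec)) w * 60 else pool_stride_sec
    labor_vals <- numeric(0)
    nl_vals_by_goat <- list()
    for (g in goats) {
      tr <- herd[[g]]$truth
      if (is.na(tr$birth_time)) next
      s <- lpi_series(herd[[g]]$records, labels = labels[[g]],
                      window_min = w, stride_sec = w_stride, goat_id = g)
      day <- window_slice(s, from = tr$birth_time - day_hours * 3600,
                          to = tr$birth_time)
      labor_vals <- c(labor_vals, max(day$lpi))
      nl <- day[day$window_end <= tr$labor_onset, ]
      nl_vals_by_goat[[g]] <- nl$lpi
    }
    nl_pool <- if (pool == "pooled_topk") {
      v <- sort(unlist(nl_vals_by_goat), decreasing = TRUE)
      utils::head(v, k)
    } else {
      per_goat <- max(1L, floor(k / length(nl_vals_by_goat)))
      unlist(lapply(nl_vals_by_goat, function(v) {
        utils::head(sort(v, decreasing = TRUE), per_goat)
      }))
    }
    nl_max <- vapply(nl_vals_by_goat,
                     function(v) if (length(v)) max(v) else NA_real_,
                     numeric(1))
    list(window_min = w,
         labor = group_stats(labor_vals, "labor"),
         nonlabor = group_stats(nl_pool, "non_labor"),
         labor_vals = labor_vals, nl_pool = nl_pool,
         nl_max = nl_max[!is.na(nl_max)])
  })
  sel <- select_window(per_window)
  chosen <- per_window[[which(windows == sel$chosen)[1]]]
  validation <- tryCatch(
    validate_groups(chosen$labor_vals, chosen$nl_max),
    error = function(e) NULL)
  structure(
    list(window_min = sel$chosen,
         tckg = lpi_threshold(chosen$nl_pool),
         selection = sel,
         nonlabor_stats = chosen$nonlabor,
         validation = validation,
         mdv = NA_real_, mdv_sd = NA_real_,
         pool = pool, k = k,
         stride_sec = if (is.null(stride_sec)) sel$chosen * 60 else stride_sec,
         day_hours = day_hours, n_goats = length(goats),
         n_nonlabor = length(chosen$nl_pool)),
    class = "calibration"
  )
}

#' @export
print.calibration <- function(x, ...) {
  print(x$selection)
  cat(sprintf("Three-sigma threshold (non-labor mean + 3 sd): %.2f\n", x$tckg))
  if (!is.na(x$mdv)) {
    cat(sprintf("Mean detection-to-birth offset: %.1f min (sd %.2f)\n",
                x$mdv, x$mdv_sd))
  }
  invisible(x)
}

#' Serialize / load a calibration result
#'
#' Plain key-value text (`dcf`) so the file is portable and diffable.
#'
#' @param calibration A `calibration` object.
#' @param path File path.
#' @return `path` invisibly / the restored `calibration`.
#' @export
write_calibration <- function(calibration, path) {
  df <- data.frame(window_min = calibration$window_min,
                   tckg = calibration$tckg,
                   mdv = calibration$mdv, mdv_sd = calibration$mdv_sd,
                   stride_sec = calibration$stride_sec,
                   pool = calibration$pool, k = calibration$k,
                   n_goats = calibration$n_goats,
                   n_nonlabor = calibration$n_nonlabor)
  write.dcf(df, path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path)
  df <- as.data.frame(read.dcf(path), stringsAsFactors = FALSE)
  # write.dcf omits NA fields (e.g. mdv before any detection)
  num <- function(col) {
    if (is.null(df[[col]])) NA_real_ else as.numeric(df[[col]])
  }
  structure(
    list(window_min = num("window_min"), tckg = num("tckg"),
         selection = NULL, nonlabor_stats = NULL, validation = NULL,
         mdv = num("mdv"), mdv_sd = num("mdv_sd"),
         pool = if (is.null(df$pool)) NA_character_ else df$pool,
         k = as.integer(num("k")),
         stride_sec = num("stride_sec"), day_hours = NA_real_,
         n_goats = as.integer(num("n_goats")),
         n_nonlabor = as.integer(num("n_nonlabor"))),
    class = "calibration"
  )
}
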