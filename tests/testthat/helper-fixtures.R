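# Shared fixtures and independent brute-force oracles.

# Small herd used by several suites; simulated once per test run.
small_config <- function(seed = 11L, n_goats = 2L, hours = 8L, ...) {
  simulation_config(n_goats = n_goats, duration_hours = hours,
                    birth_quantile_range = c(0.6, 0.9), seed = seed, ...)
}

small_herd <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_herd(small_config())
    cache
  }
})

# Hand-built record stream: n seconds from t0, given activity flags.
make_records <- function(activity, t0 = as.POSIXct("2024-01-01 00:00:00",
                                                   tz = "UTC"),
                         x = 192L, z = 128L) {
  n <- length(activity)
  data.frame(
    data_number = seq_len(n), gateway_id = "GW01",
    timestamp = t0 + seq_len(n) - 1L,
    rssi = -60L, battery = 99L, activity = activity,
    x = rep_len(x, n), y = 128L, z = rep_len(z, n),
    stringsAsFactors = FALSE
  )
}

# Brute-force per-record scan oracle for window counts.
bf_window_counts <- function(records, labels, start, len_sec) {
  ta <- 0L; tlp <- 0L
  for (i in seq_len(nrow(records))) {
    t <- records$timestamp[i]
    if (t >= start && t < start + len_sec) {
      ta <- ta + as.integer(records$activity[i])
      tlp <- tlp + as.integer(labels[i] == 1L)
    }
  }
  c(ta = ta, tlp = tlp)
}

# Confusion-matrix oracle for the metric suite.
bf_metrics <- function(y_true, y_pred) {
  per <- lapply(c(0L, 1L), function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(precision = p, recall = r, f1 = f, support = sum(y_true == cl))
  })
  list(class0 = per[[1]], class1 = per[[2]],
       accuracy = mean(y_true == y_pred))
}

# Double-loop entropy oracle for information gain (bits).
bf_info_gain <- function(feature, label) {
  h <- function(v) {
    p <- as.numeric(table(v)) / length(v)
    -sum(p * log2(p))
  }
  cond <- 0
  for (val in unique(feature)) {
    sub <- label[feature == val]
    cond <- cond + length(sub) / length(label) * h(sub)
  }
  h(label) - cond
}

# Classifier-free label stand-in: everything with z above 160 is "labor".
threshold_labels <- function(records) as.integer(records$z > 160)

# Table of printed per-window moments for the four candidate windows
# (labor / non-labor means and SDs of window-maximum indices).
published_window_moments <- function() {
  data.frame(
    window_min = c(8, 10, 12, 14),
    labor_mean = c(69359.59, 77780.06, 102674.63, 107822.07),
    labor_sd = c(66253.97, 68137.81, 99319.32, 102600.46),
    nonlabor_mean = c(3550.65, 4807.18, 6248.59, 7547.88),
    nonlabor_sd = c(1781.54, 3144.58, 3222.90, 4149.09)
  )
}
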