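#' Run the full study emulation end to end
#'
#' Simulates a herd of pregnant goats with labor episodes, builds a
#' balanced labeled dataset (labor episode records versus non-labor records
#' from the 12 h before first birth), cleans it with the range and
#' quartile outlier rules, ranks the axis features by gain ratio, trains
#' the decision-tree classifier (and the SVM comparison), calibrates the
#' optimal window and three-sigma threshold, runs detection on every
#' parturition day and on a labor-free control herd, and evaluates the
#' result.
#'
#' @param seed Master seed; every stochastic stage derives its seed from
#'   it.
#' @param n_goats Herd size (default 17).
#' @param duration_hours Stream length per goat (default 36).
#' @param per_class_n Per-class cap for the balanced training dataset
#'   (default 3938).
#' @param windows Candidate window lengths, minutes.
#' @param stride_sec Detection stride, seconds; `NULL` (default) scores one
#'   index per disjoint window-length period, 60 slides per minute.
#' @param pool,k Non-labor calibration pool strategy and size (see
#'   [calibrate_herd()]).
#' @param config Optional pre-built [simulation_config()]; when supplied,
#'   `seed` still controls the dataset shuffling and the control herd.
#' @return List with the intermediate artifacts: `herd`, `control_herd`,
#'   `dataset`, `ranking`, `tree`, `svm`, `calibration`, `events`,
#'   `control_events`, `report`, `validation`.
#' @export
run_study <- function(seed = 1L, n_goats = 17L, duration_hours = 36,
                      per_class_n = 3938L, windows = c(8, 10, 12, 14),
                      stride_sec = NULL, pool = "pooled_topk", k = 110L,
                      config = NULL) {
  seed <- as.integer(seed)
  if (is.null(config)) {
    config <- simulation_config(n_goats = n_goats,
                                duration_hours = duration_hours,
                                seed = seed)
  }
  herd <- simulate_herd(config)

  intervals <- make_label_intervals(herd)
  dataset <- build_dataset(herd, intervals, per_class_n = per_class_n,
                           seed = seed + 101L)
  dataset <- clean_samples(dataset)
  ranking <- rank_features(dataset)
  feats <- ranking$feature[ranking$selected]

  tree <- train_labor_classifier(dataset, kind = "tree", features = feats,
                                 seed = seed + 202L)
  svm <- train_labor_classifier(dataset, kind = "svm", features = feats,
                                seed = seed + 202L)

  calibration <- calibrate_herd(herd, tree, windows = windows,
                                stride_sec = stride_sec, pool = pool, k = k)

  control_config <- simulation_config(n_goats = config$n_goats,
                                      duration_hours = config$duration_hours,
                                      include_labor = FALSE,
                                      seed = seed + 1000L)
  control_herd <- simulate_herd(control_config)

  run <- run_pipeline(herd, tree, calibration, control_herd = control_herd)

  list(config = config, herd = herd, control_herd = control_herd,
       dataset = dataset, ranking = ranking, tree = tree, svm = svm,
       calibration = run$calibration, events = run$events,
       control_events = run$control_events, report = run$report,
       validation = calibration$validation, series = run$series)
}
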