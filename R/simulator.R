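#' Define a behavior state for the accelerometer simulator
#'
#' A behavior state describes how a leg-mounted triaxial accelerometer "sees"
#' one class of goat behavior: which sensor axis carries the static 1-g
#' gravity component (X when the leg is upright, Z in lateral recumbency),
#' how much movement noise the behavior produces, and how often the sensor's
#' motion trigger flags a second as active.
#'
#' @param name State name.
#' @param gravity_axis One of `"x"`, `"y"`, `"z"`: the axis aligned with
#'   gravity while the animal holds this posture.
#' @param jitter_sd Movement noise amplitude, in acceleration counts (>= 0).
#' @param activity_prob Probability that a given second in this state is
#'   flagged active by the sensor's motion trigger (in `[0, 1]`).
#' @return A list of class `behavior_state`.
#' @export
behavior_state <- function(name, gravity_axis, jitter_sd, activity_prob) {
  gravity_axis <- match.arg(gravity_axis, c("x", "y", "z"))
  if (!is.numeric(jitter_sd) || length(jitter_sd) != 1L || jitter_sd < 0) {
    stop("invalid behavior state '", name, "': jitter_sd must be >= 0")
  }
  if (!is.numeric(activity_prob) || length(activity_prob) != 1L ||
      activity_prob < 0 || activity_prob > 1) {
    stop("invalid behavior state '", name,
         "': activity_prob must lie in [0, 1]")
  }
  structure(
    list(name = name, gravity_axis = gravity_axis,
         jitter_sd = jitter_sd, activity_prob = activity_prob),
    class = "behavior_state"
  )
}

#' Default goat behavior repertoire
#'
#' Six states: quiet rest, standing, walking, feeding, sitting and
#' `labor_lateral`, the labor-pain posture of lying on the side with the
#' legs stretched out and constantly moving. Upright states put gravity on
#' the X axis (the sensor sits on the tibia, long axis vertical); recumbent
#' states rotate gravity onto Z. Labor has the highest activity probability
#' of the lying states, encoding the continuous leg movement that
#' accompanies labor pains.
#'
#' `sitting` models the occasional resting bouts in which the leg falls
#' sideways, so the record-level (x, z) signature matches the labor posture
#' and the classifier cannot separate the two -- the realistic, bounded
#' source of classifier error and of the non-labor Labor Pain Index tail.
#' Ordinary sternal rest, in which the instrumented leg stays folded
#' beneath the body and reads upright at the sensor, is part of
#' `inactive_rest`; lateral-reading rest is deliberately rare and brief
#' (a handful of short bouts per day), which is what gives the highest
#' non-labor window indices a wide spread rather than a dense ceiling.
#'
#' @return Named list of [behavior_state()] objects.
#' @export
default_behavior_states <- function() {
  list(
    inactive_rest = behavior_state("inactive_rest", "x", 1,  0.02),
    standing      = behavior_state("standing",      "x", 3,  0.30),
    walking       = behavior_state("walking",       "x", 12, 0.95),
    feeding       = behavior_state("feeding",       "x", 8,  0.70),
    sitting       = behavior_state("sitting",       "z", 2,  0.05),
    labor_lateral = behavior_state("labor_lateral", "z", 10, 0.85)
  )
}

#' Default behavior transition matrix
#'
#' Row-stochastic per-second transition matrix over the five non-labor
#' states. Diagonal entries set mean bout lengths (rest ~10 min, standing
#' ~2 min, walking ~1 min, feeding ~5 min, sitting ~5 min); off-diagonal
#' mass is split between plausible successor behaviors, with only a small
#' share routed into `sitting` so that lateral-reading rest occurs as a few
#' short bouts per day.
#'
#' @return A 5 x 5 row-stochastic matrix with dimnames over the non-labor
#'   states.
#' @export
default_transition_matrix <- function() {
  states <- c("inactive_rest", "standing", "walking", "feeding", "sitting")
  stay <- c(inactive_rest = 1 - 1 / 600, standing = 1 - 1 / 120,
            walking = 1 - 1 / 60, feeding = 1 - 1 / 300,
            sitting = 1 - 1 / 300)
  # off-diagonal weights, normalized to (1 - stay) per row
  w <- rbind(
    inactive_rest = c(0,   3,   0.5, 1,   0.12),
    standing      = c(2,   0,   3,   3,   0.18),
    walking       = c(0.5, 3,   0,   2,   0.03),
    feeding       = c(1,   3,   1,   0,   0.12),
    sitting       = c(2,   2,   0.5, 1,   0)
  )
  colnames(w) <- states
  p <- w / rowSums(w) * (1 - stay[states])
  diag(p) <- stay[states]
  p
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic herd generator: cohort size, stream
#' duration, labor episode placement, the behavior state set and transition
#' matrix, the count encoding of acceleration, the rate of out-of-range
#' corrupted records, and the seed.
#'
#' Acceleration is encoded as unsigned 8-bit counts:
#' `count = clip(round(encoding_offset + encoding_scale * g + jitter), 0, 255)`
#' where `g` is the gravity projection on the axis (0 or 1). The labor
#' episode occupies `[birth - labor_onset_lead, birth - labor_onset_lead +
#' labor_episode_len)`, i.e. labor onset leads the first birth by
#' `labor_onset_lead` minutes.
#'
#' @param n_goats Number of goats in the herd.
#' @param duration_hours Stream length per goat, hours.
#' @param labor_onset_lead Minutes before first birth at which the labor
#'   episode begins (default 90, the scale of lead times reported for
#'   leg-sensor parturition detection in this breed).
#' @param labor_episode_len Length of the lateral-recumbency labor episode,
#'   minutes (default 30). Must satisfy `0 < labor_episode_len <=
#'   labor_onset_lead`.
#' @param lead_jitter_sd Per-goat Gaussian jitter (SD, minutes) applied to
#'   `labor_onset_lead`; 0 disables it.
#' @param states Named list of [behavior_state()]s; must contain
#'   `labor_lateral` with gravity on Z and the highest `activity_prob` among
#'   the recumbent states.
#' @param state_transition_matrix Row-stochastic matrix over the non-labor
#'   states (rows must sum to 1 within 1e-9).
#' @param encoding_offset Counts at 0 g (default 128).
#' @param encoding_scale Counts per g (default 64). `encoding_offset +/-
#'   encoding_scale` must stay within `[0, 255]`.
#' @param outlier_rate Probability that an emitted record is corrupted with
#'   one axis outside `[0, 255]`.
#' @param include_labor If `FALSE`, no labor episode and no birth occur
#'   (control / non-parturition streams).
#' @param birth_quantile_range Fraction of the stream duration within which
#'   the birth time is placed uniformly at random (default `c(0.75, 0.95)`,
#'   so a full day of pre-parturition data precedes the birth at the default
#'   duration).
#' @param start_time Timestamp of the first simulated second (POSIXct, UTC).
#' @param seed Integer seed; the herd generator derives one sub-seed per
#'   goat from it.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_goats = 17,
                              duration_hours = 36,
                              labor_onset_lead = 90,
                              labor_episode_len = 30,
                              lead_jitter_sd = 0,
                              states = default_behavior_states(),
                              state_transition_matrix = default_transition_matrix(),
                              encoding_offset = 128,
                              encoding_scale = 64,
                              outlier_rate = 0.002,
                              include_labor = TRUE,
                              birth_quantile_range = c(0.75, 0.95),
                              start_time = as.POSIXct("2024-01-15 00:00:00",
                                                      tz = "UTC"),
                              seed = 1L) {
  if (!is.numeric(n_goats) || n_goats < 1) {
    stop("invalid config: n_goats must be >= 1")
  }
  if (!is.numeric(duration_hours) || duration_hours < 0) {
    stop("invalid config: duration_hours must be >= 0")
  }
  if (include_labor &&
      (!(labor_episode_len > 0) || labor_episode_len > labor_onset_lead)) {
    stop("invalid config: need 0 < labor_episode_len <= labor_onset_lead")
  }
  if (encoding_offset + encoding_scale > 255 ||
      encoding_offset - encoding_scale < 0) {
    stop("invalid config: encoding_offset +/- encoding_scale must lie in [0, 255]")
  }
  if (!is.numeric(outlier_rate) || outlier_rate < 0 || outlier_rate > 1) {
    stop("invalid config: outlier_rate must lie in [0, 1]")
  }
  if (is.null(states$labor_lateral) || states$labor_lateral$gravity_axis != "z") {
    stop("invalid config: labor_lateral must exist with gravity_axis 'z'")
  }
  lying <- states[vapply(states, function(s) s$gravity_axis == "z", logical(1))]
  lying <- lying[names(lying) != "labor_lateral"]
  if (length(lying) &&
      any(vapply(lying, function(s) s$activity_prob, numeric(1)) >=
          states$labor_lateral$activity_prob)) {
    stop("invalid config: labor_lateral must have the highest activity_prob among lying states")
  }
  tm <- state_transition_matrix
  non_labor <- setdiff(names(states), "labor_lateral")
  if (!is.matrix(tm) || nrow(tm) != ncol(tm) ||
      !setequal(rownames(tm), non_labor)) {
    stop("invalid config: state_transition_matrix must be square over the non-labor states")
  }
  if (any(tm < 0) || any(abs(rowSums(tm) - 1) > 1e-9)) {
    stop("invalid config: state_transition_matrix rows must sum to 1 (within 1e-9)")
  }
  structure(
    list(n_goats = as.integer(n_goats), duration_hours = duration_hours,
         labor_onset_lead = labor_onset_lead,
         labor_episode_len = labor_episode_len,
         lead_jitter_sd = lead_jitter_sd, states = states,
         state_transition_matrix = tm[non_labor, non_labor, drop = FALSE],
         encoding_offset = encoding_offset, encoding_scale = encoding_scale,
         outlier_rate = outlier_rate, include_labor = include_labor,
         birth_quantile_range = birth_quantile_range,
         start_time = as.POSIXct(start_time, tz = "UTC"),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# semi-Markov draw of a per-second state sequence of length n_sec
simulate_state_sequence <- function(tm, n_sec, start_state = "standing") {
  states <- rownames(tm)
  out <- character(0)
  cur <- start_state
  total <- 0L
  while (total < n_sec) {
    p_stay <- tm[cur, cur]
    dwell <- 1L + stats::rgeom(1, max(1 - p_stay, 1e-12))
    dwell <- min(dwell, n_sec - total)
    out <- c(out, rep(cur, dwell))
    total <- total + dwell
    if (total >= n_sec) break
    off <- tm[cur, ]
    off[cur] <- 0
    cur <- sample(states, 1L, prob = off)
  }
  out
}

#' Simulate one goat's accelerometer stream
#'
#' Draws a per-second behavior state sequence from the configured transition
#' matrix, overlays the labor episode (lateral recumbency ending
#' `labor_onset_lead - labor_episode_len` minutes before the birth of the
#' first kid), flags each second active with the state's activity
#' probability, and emits records at the sensor's dual rate: one record per
#' active second, one record per 10 consecutive inactive seconds
#' (timestamped at the emission second, i.e. the end of the 10-s interval).
#' Axis counts follow the 8-bit gravity + jitter encoding; with probability
#' `outlier_rate` one axis of a record is corrupted to a value in
#' `[-20, -1]` or `[256, 300]`.
#'
#' @param config A [simulation_config()].
#' @param goat_index Goat number within the herd (1-based,
#'   `<= config$n_goats`).
#' @return A list with elements `records` (data.frame with columns
#'   `data_number, gateway_id, timestamp, rssi, battery, activity, x, y, z`)
#'   and `truth` (class `goat_truth`: per-second `states`, `start_time`,
#'   `birth_time`, `labor_onset`, `labor_end`, `goat_id`).
#' @export
simulate_goat <- function(config, goat_index = 1L) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  if (goat_index < 1 || goat_index > config$n_goats) {
    stop("goat_index must be between 1 and n_goats")
  }
  set.seed((config$seed %% 20000L) * 100003L + goat_index * 7919L)
  goat_id <- sprintf("goat%02d", goat_index)
  n_sec <- as.integer(round(config$duration_hours * 3600))

  if (n_sec == 0L) {
    return(list(records = empty_records(), truth = structure(
      list(goat_id = goat_id, states = character(0),
           start_time = config$start_time, birth_time = as.POSIXct(NA),
           labor_onset = as.POSIXct(NA), labor_end = as.POSIXct(NA)),
      class = "goat_truth")))
  }

  st <- simulate_state_sequence(config$state_transition_matrix, n_sec)

  birth_time <- labor_onset <- labor_end <- as.POSIXct(NA)
  if (config$include_labor) {
    q <- config$birth_quantile_range
    birth_sec <- round(stats::runif(1, q[1], q[2]) * n_sec)
    lead_min <- config$labor_onset_lead
    if (config$lead_jitter_sd > 0) {
      lead_min <- max(config$labor_episode_len,
                      lead_min + stats::rnorm(1, 0, config$lead_jitter_sd))
    }
    onset_sec <- max(1, birth_sec - round(lead_min * 60))
    end_sec <- min(n_sec, onset_sec + round(config$labor_episode_len * 60))
    st[onset_sec:(end_sec - 1L)] <- "labor_lateral"
    t0 <- as.numeric(config$start_time)
    birth_time <- as.POSIXct(t0 + birth_sec, tz = "UTC",
                             origin = "1970-01-01")
    labor_onset <- as.POSIXct(t0 + onset_sec - 1, tz = "UTC",
                              origin = "1970-01-01")
    labor_end <- as.POSIXct(t0 + end_sec - 1, tz = "UTC",
                            origin = "1970-01-01")
  }

  act_p <- vapply(config$states, function(s) s$activity_prob, numeric(1))
  jit_sd <- vapply(config$states, function(s) s$jitter_sd, numeric(1))
  grav <- vapply(config$states, function(s) s$gravity_axis, character(1))

  active <- stats::runif(n_sec) < act_p[st]

  # dual-rate emission: every active second; every 10th second of an
  # inactive run (end-stamped)
  emit <- active
  r <- rle(active)
  pos_in_run <- sequence(r$lengths)
  inactive <- !active
  emit[inactive] <- pos_in_run[inactive] %% 10L == 0L
  idx <- which(emit)
  k <- length(idx)
  if (k == 0L) {
    rec <- empty_records()
  } else {
    sd_i <- jit_sd[st[idx]]
    g_ax <- grav[st[idx]]
    enc <- function(axis) {
      g <- as.numeric(g_ax == axis)
      v <- round(config$encoding_offset + config$encoding_scale * g +
                   stats::rnorm(k, 0, sd_i))
      pmin(pmax(v, 0), 255)
    }
    x <- enc("x"); y <- enc("y"); z <- enc("z")
    if (config$outlier_rate > 0) {
      bad <- which(stats::runif(k) < config$outlier_rate)
      if (length(bad)) {
        ax <- sample(3L, length(bad), replace = TRUE)
        corrupt <- sample(c(-20:-1, 256:300), length(bad), replace = TRUE)
        x[bad[ax == 1L]] <- corrupt[ax == 1L]
        y[bad[ax == 2L]] <- corrupt[ax == 2L]
        z[bad[ax == 3L]] <- corrupt[ax == 3L]
      }
    }
    rec <- data.frame(
      data_number = seq_len(k),
      gateway_id = "GW01",
      timestamp = as.POSIXct(as.numeric(config$start_time) + idx - 1,
                             tz = "UTC", origin = "1970-01-01"),
      rssi = round(-60 + stats::rnorm(k, 0, 4)),
      battery = pmax(1L, 100L - as.integer((idx - 1) / n_sec * 5)),
      activity = active[idx],
      x = as.integer(x), y = as.integer(y), z = as.integer(z),
      stringsAsFactors = FALSE
    )
  }

  truth <- structure(
    list(goat_id = goat_id, states = st, start_time = config$start_time,
         birth_time = birth_time, labor_onset = labor_onset,
         labor_end = labor_end),
    class = "goat_truth"
  )
  list(records = rec, truth = truth)
}

empty_records <- function() {
  data.frame(data_number = integer(0), gateway_id = character(0),
             timestamp = as.POSIXct(character(0), tz = "UTC"),
             rssi = integer(0), battery = integer(0), activity = logical(0),
             x = integer(0), y = integer(0), z = integer(0),
             stringsAsFactors = FALSE)
}

#' Simulate a herd of goats
#'
#' Runs [simulate_goat()] for each of `config$n_goats` animals, deriving one
#' sub-seed per goat from `config$seed` so that identical configurations
#' reproduce identical herds.
#'
#' @param config A [simulation_config()].
#' @return A named list (class `goat_herd`) of per-goat
#'   `list(records, truth)` elements.
#' @export
simulate_herd <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  herd <- lapply(seq_len(config$n_goats), function(i) simulate_goat(config, i))
  names(herd) <- vapply(herd, function(g) g$truth$goat_id, character(1))
  structure(herd, class = "goat_herd")
}
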