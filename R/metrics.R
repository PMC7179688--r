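# Per-fly, per-session behavioural metrics: activity level, cumulative
# active duration (CAD), state-conditional heat likelihood, exposure
# differential (ED), activity difference (AD).

metrics_error <- function(msg) abort(msg, class = "flyoperant_metrics_error")

check_fraction <- function(x, what) {
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad))
    metrics_error(sprintf("`%s` must lie in [0, 1]", what))
  invisible(x)
}

# Per-sample walk flag reconstructed from the bout table, aligned with the
# trace's sample intervals [t_i, t_i + dt).
sample_states <- function(bouts) {
  dt <- attr(bouts, "dt")
  n_per <- round(bouts$duration / dt)
  rep(bouts$state == "walk", times = n_per)
}

#' State-conditional heat likelihood
#'
#' The fraction of the time spent in a behavioural state during which the
#' fly was heated, within a window: time(laser ON and in state) /
#' time(in state). Undefined (NA) when the state is never occupied in the
#' window — a never-pausing fly has no pause-conditional likelihood, not a
#' zero one.
#'
#' @param trace A `fly_trace`.
#' @param bouts Its segmentation from [segment_trace()].
#' @param window A row of [session_windows()] (needs `start_idx`,
#'   `end_idx`).
#' @param state `"walk"` or `"pause"`.
#' @return Fraction in `[0, 1]`, or `NA` when the state is unoccupied.
#' @export
conditional_heat_likelihood <- function(trace, bouts, window,
                                        state = c("walk", "pause")) {
  state <- match.arg(state)
  id_t <- attr(trace, "fly_id")
  id_b <- attr(bouts, "fly_id")
  if (!is.null(id_t) && !is.null(id_b) && !identical(id_t, id_b))
    metrics_error(sprintf("trace fly_id '%s' does not match segmentation fly_id '%s'",
                          id_t, id_b))
  idx <- seq(window$start_idx, window$end_idx - 1L)
  walk <- sample_states(bouts)[idx]
  in_state <- if (state == "walk") walk else !walk
  occ <- sum(in_state)
  if (occ == 0) return(NA_real_)
  sum(trace$laser_on[idx] == 1L & in_state) / occ
}

#' Exposure differential (ED)
#'
#' How contingent the heat was on walking: `P(heated | walking) -
#' P(heated | pause)`. An ED of 1 means heat arrived only while walking; 0
#' means heat was independent of state. Missing inputs propagate.
#'
#' @param p_heat_walk,p_heat_pause Conditional heat likelihoods in `[0, 1]`.
#' @return ED in `[-1, 1]` (vectorized).
#' @export
#' @examples
#' exposure_differential(0.80, 0.30)
#' exposure_differential(0.50, 0.50)
exposure_differential <- function(p_heat_walk, p_heat_pause) {
  check_fraction(p_heat_walk, "p_heat_walk")
  check_fraction(p_heat_pause, "p_heat_pause")
  p_heat_walk - p_heat_pause
}

#' Cumulative active duration (CAD)
#'
#' Total walk time accumulated from the window start up to a cut time.
#' Non-decreasing and 1-Lipschitz in the cut, and bounded by the cut.
#'
#' @param bouts A `fly_bouts` tibble.
#' @param window A window with `start_s`, `end_s`.
#' @param cut Cut time from window start, seconds (vectorized).
#' @return Walk seconds in `[window start, window start + cut)`.
#' @export
#' @examples
#' tr <- fly_trace(seq(0, 10, 0.1), c(rep(0, 50), seq(0.1, 5.1, 0.1)), 0,
#'                 "Pre-test", validate = FALSE)
#' b <- segment_trace(tr)
#' cumulative_active_duration(b, list(start_s = 0, end_s = 10.1), 10)
cumulative_active_duration <- function(bouts, window, cut) {
  if (any(cut < 0)) metrics_error("`cut` must be non-negative")
  vapply(cut, function(ct) {
    walk_time_in(bouts, window$start_s, min(window$start_s + ct, window$end_s))
  }, numeric(1))
}

#' Activity level
#'
#' Fraction of a window spent walking; equals `CAD(window length) / window
#' length`.
#'
#' @param bouts A `fly_bouts` tibble.
#' @param window A window with `start_s`, `end_s`.
#' @return Fraction in `[0, 1]`.
#' @export
activity_level <- function(bouts, window) {
  len <- window$end_s - window$start_s
  if (len <= 0) metrics_error("window length must be positive")
  walk_time_in(bouts, window$start_s, window$end_s) / len
}

#' Activity difference (AD)
#'
#' A Test session's activity level minus the Pre-test activity level,
#' reported as a plain number (a change in level, not a percent change).
#' Negative values indicate learned suppression of walking.
#'
#' @param level_test,level_pretest Activity levels in `[0, 1]`.
#' @return AD in `[-1, 1]` (vectorized).
#' @export
#' @examples
#' activity_difference(0.40, 0.70)
activity_difference <- function(level_test, level_pretest) {
  check_fraction(level_test, "level_test")
  check_fraction(level_pretest, "level_pretest")
  level_test - level_pretest
}

# All per-session metrics for one fly. `cut` caps the CAD evaluation; the
# occupancy columns (walk_s, pause_s, heat_walk_s, heat_pause_s) support
# pooled whole-experiment EDs downstream.
session_metrics <- function(trace, bouts, cut) {
  wins <- session_windows(trace)
  dt <- attr(bouts, "dt")
  walk <- sample_states(bouts)
  laser <- trace$laser_on == 1L
  rows <- lapply(seq_len(nrow(wins)), function(i) {
    w <- wins[i, ]
    idx <- seq(w$start_idx, w$end_idx - 1L)
    wk <- walk[idx]; ls <- laser[idx]
    len <- w$end_s - w$start_s
    walk_s <- sum(wk) * dt
    pause_s <- len - walk_s
    heat_walk_s <- sum(ls & wk) * dt
    heat_pause_s <- sum(ls & !wk) * dt
    p_w <- if (walk_s > 0) heat_walk_s / walk_s else NA_real_
    p_p <- if (pause_s > 0) heat_pause_s / pause_s else NA_real_
    # a never-heated window has no heat-state contingency to measure:
    # its exposure differential is missing, not zero
    ed <- if (sum(ls) > 0) p_w - p_p else NA_real_
    runs <- rle(as.integer(ls))
    tibble::tibble(
      fly_id = attr(trace, "fly_id"),
      session = w$session,
      session_length_s = len,
      activity_level = walk_s / len,
      cad_at_cut = cumulative_active_duration(bouts, w, min(cut, len)),
      walk_s = walk_s, pause_s = pause_s,
      heat_walk_s = heat_walk_s, heat_pause_s = heat_pause_s,
      p_heat_walk = p_w, p_heat_pause = p_p,
      exposure_differential = ed,
      heat_exposure_s = sum(ls) * dt,
      episode_count = sum(runs$values == 1L)
    )
  })
  dplyr::bind_rows(rows)
}

# Re-evaluate the Train-session CAD at the common cut (the smaller of the
# configured cut and the cohort-minimum Train-session length) and stamp
# metadata. Blank flies' EDs stay NA (degenerate conditionals): a fly that
# was never heated has no heat-on-state contingency to measure.
finalize_metrics <- function(metrics, analysis, bouts_list, windows_list) {
  is_train <- metrics$session %in% TRAIN_SESSIONS
  cut_used <- min(analysis$common_train_cut, metrics$session_length_s[is_train])
  if (cut_used < analysis$common_train_cut) {
    idx <- which(is_train)
    metrics$cad_at_cut[idx] <- vapply(idx, function(i) {
      fid <- metrics$fly_id[i]
      w <- windows_list[[fid]]
      w <- w[w$session == metrics$session[i], ]
      cumulative_active_duration(bouts_list[[fid]], w, cut_used)
    }, numeric(1))
  }
  attr(metrics, "common_cut_used") <- cut_used
  attr(metrics, "speed_threshold") <- analysis$speed_threshold
  attr(metrics, "min_bout") <- analysis$min_bout
  metrics
}

#' Metrics table for a cohort
#'
#' Segments every trace and computes the per-fly, per-session metrics. Train
#' CAD values are evaluated at the common cut: the smaller of
#' `analysis$common_train_cut` and the cohort-minimum Train-session length
#' (recorded in the `common_cut_used` attribute).
#'
#' @param traces Named list of `fly_trace` objects.
#' @param records Fly records (see [read_attributes()]); every trace must
#'   have one.
#' @param analysis An [analysis_config()].
#' @return Tibble, one row per fly-session, with group and triplet columns.
#' @export
metrics_table <- function(traces, records, analysis = analysis_config()) {
  ids <- vapply(traces, function(tr) attr(tr, "fly_id"), character(1))
  missing_rec <- setdiff(ids, records$fly_id)
  if (length(missing_rec))
    metrics_error(sprintf("no attribute record for fly '%s'", missing_rec[1]))
  bouts_list <- list()
  windows_list <- list()
  rows <- lapply(traces, function(trace) {
    fid <- attr(trace, "fly_id")
    wins <- session_windows(trace)
    absent <- setdiff(SESSIONS, wins$session)
    if (length(absent))
      metrics_error(sprintf("fly '%s' is missing session '%s'", fid, absent[1]))
    bouts <- segment_trace(trace, speed_threshold = analysis$speed_threshold,
                           min_bout = analysis$min_bout)
    bouts_list[[fid]] <<- bouts
    windows_list[[fid]] <<- wins
    session_metrics(trace, bouts, cut = analysis$common_train_cut)
  })
  metrics <- dplyr::bind_rows(rows)
  metrics <- dplyr::left_join(
    metrics, records[, c("fly_id", "group", "triplet_id")], by = "fly_id")
  finalize_metrics(metrics, analysis, bouts_list, windows_list)
}

#' Per-fly summary of the session metrics
#'
#' Widens the session table to one row per fly: activity levels of the three
#' Test sessions, the activity differences AD(Test1) and AD(Test2) relative
#' to Pre-test, per-Train-session EDs, the whole-experiment ED (occupancy
#' and heat time pooled across both Train sessions before dividing), Train
#' CADs at the common cut, and total heat exposure over both Train sessions.
#'
#' @param metrics Output of [metrics_table()].
#' @return Tibble, one row per fly.
#' @export
fly_summary <- function(metrics) {
  act <- metrics |>
    dplyr::filter(.data$session %in% TEST_SESSIONS) |>
    dplyr::select("fly_id", "group", "triplet_id", "session",
                  "activity_level") |>
    tidyr::pivot_wider(names_from = "session",
                       values_from = "activity_level") |>
    dplyr::rename(activity_pretest = "Pre-test",
                  activity_test1 = "Test1", activity_test2 = "Test2")
  tr <- metrics |>
    dplyr::filter(.data$session %in% TRAIN_SESSIONS) |>
    dplyr::group_by(.data$fly_id) |>
    dplyr::summarise(
      ed_train1 = .data$exposure_differential[.data$session == "Train1"],
      ed_train2 = .data$exposure_differential[.data$session == "Train2"],
      ed_all = if (sum(.data$heat_exposure_s) > 0)
        (sum(.data$heat_walk_s) / sum(.data$walk_s)) -
          (sum(.data$heat_pause_s) / sum(.data$pause_s)) else NA_real_,
      cad_train1 = .data$cad_at_cut[.data$session == "Train1"],
      cad_train2 = .data$cad_at_cut[.data$session == "Train2"],
      heat_exposure_total = sum(.data$heat_exposure_s),
      .groups = "drop"
    )
  act |>
    dplyr::left_join(tr, by = "fly_id") |>
    dplyr::mutate(
      ad_test1 = activity_difference(.data$activity_test1, .data$activity_pretest),
      ad_test2 = activity_difference(.data$activity_test2, .data$activity_pretest)
    )
}

#' CAD step-function values on a time grid
#'
#' The full CAD curve of each Train session evaluated at the given times
#' from session start (clamped to the session length).
#'
#' @param bouts A `fly_bouts` tibble.
#' @param windows Output of [session_windows()] for the same fly.
#' @param times Cut times, seconds.
#' @return Tibble with `session`, `t`, `cad`; only Train sessions, and only
#'   grid points within each session's length.
#' @export
cad_curve_table <- function(bouts, windows, times) {
  wins <- windows[windows$session %in% TRAIN_SESSIONS, ]
  rows <- lapply(seq_len(nrow(wins)), function(i) {
    w <- wins[i, ]
    tt <- times[times <= (w$end_s - w$start_s)]
    tibble::tibble(session = w$session, t = tt,
                   cad = cumulative_active_duration(bouts, w, tt))
  })
  dplyr::bind_rows(rows)
}

#' Export the session metrics table
#'
#' @param metrics Output of [metrics_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  readr::write_csv(metrics, path, progress = FALSE)
  invisible(path)
}
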