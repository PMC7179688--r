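# Walk/pause bout segmentation.
#
# Per-sample speed is the first difference |dx|/dt; a sample is "walk" iff
# its speed meets the threshold. Runs shorter than the debounce are merged
# into their neighbours, shortest first (ties resolved toward pause, i.e. a
# short walk run is absorbed before an equally short pause run). Bouts are
# contiguous, alternating, half-open, and cover the whole trace, so walk
# time + pause time equals the trace duration exactly.

#' Segment a position trace into walk and pause bouts
#'
#' @param trace A `fly_trace` (at least 2 samples).
#' @param speed_threshold Speed at or above which a sample counts as
#'   walking, mm/s.
#' @param min_bout Debounce length, seconds; runs shorter than this are
#'   merged into the neighbouring state.
#' @return A `fly_bouts` tibble with `state`, `start_s`, `end_s`,
#'   `duration`; the fly id, sampling step and parameters are attributes.
#'   Each sample interval `[t_i, t_i + dt)` belongs to exactly one bout; the
#'   final sample inherits the preceding state.
#' @export
#' @examples
#' tr <- fly_trace(seq(0, 1, 0.1), rep(5, 11), 0, "Pre-test", validate = FALSE)
#' segment_trace(tr)
segment_trace <- function(trace, speed_threshold = 1.0, min_bout = 0.2) {
  n <- nrow(trace)
  if (n < 2) abort("trace must have at least 2 samples",
                   class = "flyoperant_segmentation_error")
  if (speed_threshold <= 0) config_error("`speed_threshold` must be positive")
  if (min_bout < 0) config_error("`min_bout` must be non-negative")
  dt <- attr(trace, "dt") %||% median(diff(trace$time_s))
  speed <- abs(diff(trace$position_mm)) / dt
  walk <- speed >= speed_threshold
  walk <- c(walk, walk[n - 1])          # last sample inherits previous state
  r <- rle(walk)
  merged <- merge_short_runs(r$lengths, r$values, min_samples = min_bout / dt)
  start_idx <- cumsum(c(0L, head(merged$lengths, -1)))
  bouts <- tibble::tibble(
    state = ifelse(merged$values, "walk", "pause"),
    start_s = trace$time_s[1] + start_idx * dt,
    end_s = trace$time_s[1] + (start_idx + merged$lengths) * dt,
    duration = merged$lengths * dt
  )
  attr(bouts, "fly_id") <- attr(trace, "fly_id")
  attr(bouts, "dt") <- dt
  attr(bouts, "trace_start_s") <- trace$time_s[1]
  attr(bouts, "n_samples") <- n
  attr(bouts, "speed_threshold") <- speed_threshold
  attr(bouts, "min_bout") <- min_bout
  class(bouts) <- c("fly_bouts", class(bouts))
  bouts
}

# Iteratively absorb runs shorter than min_samples into their neighbours.
# Shortest run first; ties resolved by absorbing walk runs before pause runs.
merge_short_runs <- function(lengths, values, min_samples) {
  repeat {
    k <- length(lengths)
    if (k <= 1) break
    short <- which(lengths < min_samples - 1e-9)
    if (!length(short)) break
    ord <- short[order(lengths[short], !values[short])]
    i <- ord[1]
    if (i == 1) {
      lengths[2] <- lengths[2] + lengths[1]
      lengths <- lengths[-1]; values <- values[-1]
    } else if (i == k) {
      lengths[k - 1] <- lengths[k - 1] + lengths[k]
      lengths <- lengths[-k]; values <- values[-k]
    } else {
      lengths[i - 1] <- lengths[i - 1] + lengths[i] + lengths[i + 1]
      keep <- setdiff(seq_len(k), c(i, i + 1))
      lengths <- lengths[keep]; values <- values[keep]
    }
  }
  list(lengths = lengths, values = values)
}

# Overlap of walk bouts with [start_s, end_s).
walk_time_in <- function(bouts, start_s, end_s) {
  w <- bouts$state == "walk"
  if (!any(w)) return(0)
  ov <- pmin(bouts$end_s[w], end_s) - pmax(bouts$start_s[w], start_s)
  sum(pmax(ov, 0))
}

#' Summarise bouts within a window
#'
#' Bouts are clipped to the window; clipped durations therefore sum exactly
#' to the window length.
#'
#' @param bouts A `fly_bouts` tibble.
#' @param window A one-row window (e.g. a row of [session_windows()]) or a
#'   list with `start_s` and `end_s`.
#' @return Tibble with one row per state: `n_bouts`, `total_s`.
#' @export
bout_summary <- function(bouts, window) {
  start_s <- window$start_s
  end_s <- window$end_s
  if (end_s <= start_s) abort("empty window",
                              class = "flyoperant_segmentation_error")
  clipped <- bouts |>
    dplyr::mutate(
      cs = pmax(.data$start_s, .env$start_s),
      ce = pmin(.data$end_s, .env$end_s)
    ) |>
    dplyr::filter(.data$ce > .data$cs)
  out <- clipped |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(n_bouts = dplyr::n(),
                     total_s = sum(.data$ce - .data$cs), .groups = "drop")
  missing_states <- setdiff(c("walk", "pause"), out$state)
  if (length(missing_states))
    out <- dplyr::bind_rows(
      out, tibble::tibble(state = missing_states, n_bouts = 0L, total_s = 0))
  dplyr::arrange(out, dplyr::desc(.data$state))
}

#' Export a bout table
#'
#' One row per bout: `fly_id,state,start_s,end_s`.
#'
#' @param bouts A `fly_bouts` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bouts <- function(bouts, path) {
  out <- tibble::tibble(
    fly_id = attr(bouts, "fly_id") %||% "fly",
    state = bouts$state,
    start_s = bouts$start_s,
    end_s = bouts$end_s
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
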