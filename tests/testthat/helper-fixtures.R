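# Shared fixtures: traces built from explicit bout plans, so every expected
# metric can be computed by hand.

# Build a trace from a plan of (state, duration) bouts. Walking moves at
# `speed` mm/s, bouncing between the walls; pausing holds position.
bout_plan_trace <- function(states, durations, dt = 0.01, speed = 10,
                            laser = NULL, session = "Pre-test",
                            fly_id = "fx", chamber_length = 48.7,
                            start_pos = 10) {
  n_per <- round(durations / dt)
  walk <- rep(states == "walk", times = n_per)
  n <- length(walk)
  pos <- numeric(n)
  p <- start_pos
  heading <- 1
  for (i in seq_len(n)) {
    pos[i] <- p
    if (walk[i]) {
      p <- p + speed * dt * heading
      if (p > chamber_length) { p <- 2 * chamber_length - p; heading <- -1 }
      if (p < 0) { p <- -p; heading <- 1 }
    }
  }
  if (is.null(laser)) laser <- integer(n)
  if (length(session) == 1) session <- rep(session, n)
  fly_trace(time_s = (seq_len(n) - 1) * dt, position_mm = pos,
            laser_on = laser, session = session, fly_id = fly_id,
            chamber_length = chamber_length, validate = FALSE)
}

# A minimal but complete five-session trace with prescribed per-session
# bout plans; plans is a named list of list(states=, durations=, laser=).
# Position is integrated continuously across session boundaries.
five_session_trace <- function(plans, dt = 0.01, fly_id = "fx",
                               chamber_length = 48.7, speed = 10) {
  sessions <- flyoperant::protocol_sessions()
  walk <- unlist(lapply(sessions, function(s) {
    p <- plans[[s]]
    rep(p$states == "walk", times = round(p$durations / dt))
  }))
  session <- unlist(lapply(sessions, function(s) {
    p <- plans[[s]]
    rep(s, sum(round(p$durations / dt)))
  }))
  laser <- unlist(lapply(sessions, function(s) {
    p <- plans[[s]]
    n <- sum(round(p$durations / dt))
    if (is.null(p$laser)) integer(n) else p$laser
  }))
  n <- length(walk)
  pos <- numeric(n)
  p <- 10; heading <- 1
  for (i in seq_len(n)) {
    pos[i] <- p
    if (walk[i]) {
      p <- p + speed * dt * heading
      if (p > chamber_length) { p <- 2 * chamber_length - p; heading <- -1 }
      if (p < 0) { p <- -p; heading <- 1 }
    }
  }
  fly_trace(time_s = (seq_len(n) - 1) * dt, position_mm = pos,
            laser_on = laser, session = session, fly_id = fly_id,
            chamber_length = chamber_length, validate = FALSE)
}

# Simple alternating walk/pause plan.
alternating_plan <- function(n_pairs, walk_s, pause_s, laser = NULL) {
  list(states = rep(c("walk", "pause"), n_pairs),
       durations = rep(c(walk_s, pause_s), n_pairs),
       laser = laser)
}

window_of <- function(trace, session) {
  w <- session_windows(trace)
  w[w$session == session, ]
}

tiny_cohort <- function(n_triplets = 2, seed = 101, ...) {
  simulate_cohort(sim_config(n_triplets = n_triplets, seed = seed, ...))
}
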