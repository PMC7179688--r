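# Cohort simulation: closed-loop train flies, laser-mirrored yoked partners,
# never-heated blank partners, run through the full five-session protocol.

controller_code <- function(controller) {
  match(controller, c("closed_loop", "random", "off"))
}

cpp_cfg <- function(sim, protocol) {
  list(
    dt = sim$dt,
    walk_speed = sim$walk_speed,
    pause_to_walk_rate = sim$pause_to_walk_rate,
    walk_to_pause_rate = sim$walk_to_pause_rate,
    learning_gain = sim$learning_gain,
    suppression_decay = sim$suppression_decay,
    suppression_effect = sim$suppression_effect,
    habituation_rate = sim$habituation_rate,
    chamber_length = protocol$chamber_length,
    controller_code = controller_code(sim$controller),
    random_on_rate = sim$random_on_rate,
    random_off_rate = sim$random_off_rate,
    latency_min = sim$controller_latency[1],
    latency_max = sim$controller_latency[2]
  )
}

cpp_proto <- function(protocol) {
  protocol[c("test_duration", "max_heat_episodes", "stationary_cutoff",
             "trigger_walk_duration", "edge_zone", "max_train_duration")]
}

# Per-fly child seeds from the root stream. Drawing with replacement keeps
# the first k triplets' seeds identical when the cohort grows.
triplet_seeds <- function(seed, n_triplets) {
  set.seed(seed)
  matrix(sample.int(.Machine$integer.max - 1L, 3L * n_triplets, replace = TRUE),
         nrow = 3L)
}

triplet_traces <- function(i, seeds, sim, protocol) {
  cfg <- cpp_cfg(sim, protocol)
  proto <- cpp_proto(protocol)
  set.seed(seeds[1, i])
  tr <- sim_train_fly_cpp(cfg, proto)
  set.seed(seeds[2, i])
  yk_pos <- sim_follower_fly_cpp(cfg, tr$laser)
  set.seed(seeds[3, i])
  bl_pos <- sim_follower_fly_cpp(cfg, integer(length(tr$laser)))
  n <- length(tr$position)
  time_s <- (seq_len(n) - 1) * sim$dt
  session <- SESSIONS[tr$session_code]
  tid <- sprintf("t%03d", i)
  mk <- function(pos, laser, group) {
    fly_trace(time_s, pos, laser, session,
              fly_id = paste0(tid, "_", group),
              chamber_length = protocol$chamber_length, validate = FALSE)
  }
  list(
    train = mk(tr$position, tr$laser, "train"),
    yoked = mk(yk_pos, tr$laser, "yoked"),
    blank = mk(bl_pos, integer(n), "blank"),
    episodes = tr$episodes
  )
}

#' Simulate a cohort of train/yoked/blank triplets
#'
#' Each triplet is three flies run simultaneously through the five-session
#' protocol: the train fly's own walking drives the laser via the virtual
#' operator; the yoked fly receives a sample-identical copy of that laser
#' channel; the blank fly is never heated. All three inherit the train fly's
#' session windows (Train sessions end on the train fly's termination rule).
#' Identical configuration and seed give bit-identical output.
#'
#' @param sim A [sim_config()].
#' @param protocol A [protocol_spec()].
#' @param n_triplets,seed Overrides for the corresponding `sim` fields.
#' @return List with `traces` (named list of `fly_trace`, 3 per triplet) and
#'   `records` (attribute tibble, one row per fly).
#' @export
#' @examples
#' co <- simulate_cohort(sim_config(n_triplets = 2, seed = 42))
#' names(co$traces)
simulate_cohort <- function(sim = sim_config(), protocol = protocol_spec(),
                            n_triplets = sim$n_triplets, seed = sim$seed) {
  if (n_triplets < 1) config_error("`n_triplets` must be at least 1")
  seeds <- triplet_seeds(seed, n_triplets)
  traces <- list()
  recs <- vector("list", n_triplets)
  for (i in seq_len(n_triplets)) {
    tri <- triplet_traces(i, seeds, sim, protocol)
    tid <- sprintf("t%03d", i)
    for (g in c("train", "yoked", "blank"))
      traces[[paste0(tid, "_", g)]] <- tri[[g]]
    recs[[i]] <- tibble::tibble(
      fly_id = paste0(tid, "_", c("train", "yoked", "blank")),
      group = c("train", "yoked", "blank"),
      triplet_id = tid,
      genotype = sim$genotype,
      sex = if (i %% 2 == 1) "f" else "m",
      eclosion_date = "2026-01-05",
      procedure_error = FALSE
    )
  }
  records <- fly_records(dplyr::bind_rows(recs))
  list(traces = traces, records = records)
}

# Simulate and immediately measure, discarding traces triplet by triplet.
# Used by the pipeline for large cohorts.
simulate_metrics <- function(sim = sim_config(), protocol = protocol_spec(),
                             analysis = analysis_config(),
                             n_triplets = sim$n_triplets, seed = sim$seed) {
  seeds <- triplet_seeds(seed, n_triplets)
  rows <- vector("list", n_triplets)
  curves <- vector("list", n_triplets)
  recs <- vector("list", n_triplets)
  bouts_list <- list()
  windows_list <- list()
  grid <- seq(0, analysis$common_train_cut, by = 1)
  for (i in seq_len(n_triplets)) {
    tri <- triplet_traces(i, seeds, sim, protocol)
    tid <- sprintf("t%03d", i)
    recs[[i]] <- tibble::tibble(
      fly_id = paste0(tid, "_", c("train", "yoked", "blank")),
      group = c("train", "yoked", "blank"),
      triplet_id = tid,
      genotype = sim$genotype,
      sex = if (i %% 2 == 1) "f" else "m",
      eclosion_date = "2026-01-05",
      procedure_error = FALSE
    )
    per_fly <- lapply(c("train", "yoked", "blank"), function(g) {
      trace <- tri[[g]]
      fid <- attr(trace, "fly_id")
      seg <- segment_trace(trace, speed_threshold = analysis$speed_threshold,
                           min_bout = analysis$min_bout)
      wins <- session_windows(trace)
      bouts_list[[fid]] <<- seg
      windows_list[[fid]] <<- wins
      m <- session_metrics(trace, seg, cut = analysis$common_train_cut)
      cc <- cad_curve_table(seg, wins, grid)
      cc$fly_id <- fid
      list(m = m, cc = cc)
    })
    rows[[i]] <- dplyr::bind_rows(lapply(per_fly, `[[`, "m"))
    curves[[i]] <- dplyr::bind_rows(lapply(per_fly, `[[`, "cc"))
  }
  records <- fly_records(dplyr::bind_rows(recs))
  metrics <- dplyr::bind_rows(rows)
  metrics <- dplyr::left_join(
    metrics, records[, c("fly_id", "group", "triplet_id")], by = "fly_id")
  list(metrics = finalize_metrics(metrics, analysis, bouts_list, windows_list),
       records = records,
       cad_curves = dplyr::bind_rows(curves))
}

#' Advance one simulated fly by one time step
#'
#' Reference single-step transition of the two-state model: state hazards
#' (with suppression and habituation acting multiplicatively on the
#' pause-to-walk hazard), suppression accrual while heated and walking,
#' exponential suppression decay otherwise, and walking motion with
#' reflection at the chamber walls. Pausing leaves position unchanged.
#'
#' @param state List with `position`, `behavioral_state` ("walk"/"pause"),
#'   `heading` (+1/-1), `suppression`, `time`.
#' @param laser_on Logical; heat applied during this step.
#' @param sim A [sim_config()].
#' @param chamber_length Chamber length, mm.
#' @return The updated state list.
#' @export
#' @examples
#' s <- fly_state(position = 24)
#' step_fly(s, laser_on = FALSE, sim_config())$position
step_fly <- function(state, laser_on, sim = sim_config(),
                     chamber_length = 48.7) {
  dt <- sim$dt
  u <- stats::runif(1)
  if (state$behavioral_state == "walk") {
    if (u < 1 - exp(-sim$walk_to_pause_rate * dt))
      state$behavioral_state <- "pause"
  } else {
    lam <- sim$pause_to_walk_rate *
      exp(-sim$suppression_effect * state$suppression) *
      exp(-sim$habituation_rate * state$time)
    if (u < 1 - exp(-lam * dt)) {
      state$behavioral_state <- "walk"
      state$heading <- if (stats::runif(1) < 0.5) -1 else 1
    }
  }
  if (laser_on && state$behavioral_state == "walk") {
    state$suppression <- state$suppression + sim$learning_gain * dt
  } else {
    state$suppression <- state$suppression * exp(-dt / sim$suppression_decay)
  }
  if (state$behavioral_state == "walk") {
    p <- state$position + sim$walk_speed * dt * state$heading
    if (p > chamber_length) { p <- 2 * chamber_length - p; state$heading <- -1 }
    if (p < 0) { p <- -p; state$heading <- 1 }
    state$position <- p
  }
  state$time <- state$time + dt
  state
}

#' Initial fly state for [step_fly()]
#'
#' @param position Position, mm.
#' @param behavioral_state "walk" or "pause".
#' @param heading +1 or -1.
#' @param suppression Initial suppression S.
#' @param time Elapsed time, seconds.
#' @return State list.
#' @export
fly_state <- function(position = 24.35, behavioral_state = "pause",
                      heading = 1, suppression = 0, time = 0) {
  list(position = position, behavioral_state = behavioral_state,
       heading = heading, suppression = suppression, time = time)
}

#' Operant heat-controller decision
#'
#' The trigger rule of the virtual operator: during a Train session the laser
#' is called ON when the fly has been walking continuously for more than
#' `trigger_walk_duration` seconds, or is within `edge_zone` of either wall
#' (in any state). During Test sessions the answer is always OFF. The
#' simulator applies this decision with a uniform operator latency on both
#' onset and release; this function exposes the latency-free decision rule.
#'
#' @param recent_walking Logical vector of per-sample walking flags, oldest
#'   first; the trailing TRUE run is the current continuous-walk duration.
#' @param position Current position, mm.
#' @param session Session label.
#' @param protocol A [protocol_spec()].
#' @param dt Sampling step of `recent_walking`, seconds.
#' @return Logical: laser ON.
#' @export
#' @examples
#' heat_controller(rep(TRUE, 60), 24, "Train1", protocol_spec(), dt = 0.01)
heat_controller <- function(recent_walking, position, session,
                            protocol = protocol_spec(), dt = 0.01) {
  if (!session %in% TRAIN_SESSIONS) return(FALSE)
  r <- rle(recent_walking)
  walk_run <- if (length(r$values) && tail(r$values, 1))
    tail(r$lengths, 1) * dt else 0
  at_edge <- position <= protocol$edge_zone ||
    position >= protocol$chamber_length - protocol$edge_zone
  walk_run > protocol$trigger_walk_duration || at_edge
}

#' Train-session termination rule
#'
#' A Train session concludes once the fly has received the full heat-episode
#' quota, or has been continuously stationary for the stationary cutoff.
#'
#' @param episodes_completed Completed heat episodes (maximal laser-ON runs).
#' @param current_pause_length Length of the ongoing pause, seconds.
#' @param protocol A [protocol_spec()].
#' @return Logical.
#' @export
#' @examples
#' session_terminated(20, 0)
#' session_terminated(5, 480)
#' session_terminated(19, 479)
session_terminated <- function(episodes_completed, current_pause_length,
                               protocol = protocol_spec()) {
  if (episodes_completed < 0 || current_pause_length < 0)
    config_error("termination counters must be non-negative")
  episodes_completed >= protocol$max_heat_episodes ||
    current_pause_length >= protocol$stationary_cutoff
}

#' One step of the body-temperature relaxation
#'
#' First-order relaxation toward the heated set point while the laser is on,
#' and back toward room temperature while it is off; the trajectory is
#' bounded by the two set points.
#'
#' @param temperature Current body temperature, degrees C.
#' @param laser_on Logical.
#' @param thermal A [thermal_model()].
#' @param dt Step, seconds.
#' @return Updated temperature.
#' @export
body_temperature_step <- function(temperature, laser_on,
                                  thermal = thermal_model(), dt = 0.01) {
  if (dt <= 0) config_error("`dt` must be positive")
  target <- if (laser_on) thermal$t_target else thermal$t_room
  tau <- if (laser_on) thermal$tau_heat else thermal$tau_cool
  temperature + (target - temperature) * (1 - exp(-dt / tau))
}

#' Body-temperature profile implied by a trace's laser channel
#'
#' @param trace A `fly_trace`.
#' @param thermal A [thermal_model()].
#' @param t0 Initial temperature (defaults to room).
#' @return Numeric vector, one temperature per sample.
#' @export
body_temperature_profile <- function(trace, thermal = thermal_model(),
                                     t0 = thermal$t_room) {
  dt <- attr(trace, "dt") %||% median(diff(trace$time_s))
  a_on <- exp(-dt / thermal$tau_heat)
  a_off <- exp(-dt / thermal$tau_cool)
  n <- nrow(trace)
  out <- numeric(n)
  temp <- t0
  laser <- trace$laser_on == 1L
  for (i in seq_len(n)) {
    out[i] <- temp
    if (laser[i]) temp <- thermal$t_target + (temp - thermal$t_target) * a_on
    else temp <- thermal$t_room + (temp - thermal$t_room) * a_off
  }
  out
}
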