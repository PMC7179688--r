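# Configuration objects: protocol, simulator, thermal model, analysis.

config_error <- function(msg) {
  abort(msg, class = "flyoperant_config_error")
}

check_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0)
    config_error(sprintf("`%s` must be a single positive number", what))
  invisible(x)
}

#' Behavioural protocol parameters
#'
#' Defines the five-session operant protocol: three 10-min unheated Test
#' sessions (Pre-test, Test1, Test2) interleaved with two Train sessions in
#' which walking triggers mild heat. A Train session ends when the fly has
#' received `max_heat_episodes` heat episodes or has been continuously
#' stationary for `stationary_cutoff` seconds. During Train sessions the heat
#' also comes on whenever the fly is within `edge_zone` mm of either chamber
#' wall, discouraging edge-sitting. The walking trigger requires continuous
#' walking for more than `trigger_walk_duration` seconds.
#'
#' @param test_duration Length of each Test session, seconds.
#' @param max_heat_episodes Heat-episode quota ending a Train session.
#' @param stationary_cutoff Continuous-pause duration ending a Train session,
#'   seconds.
#' @param trigger_walk_duration Continuous walking needed to arm the heat
#'   trigger, seconds.
#' @param edge_zone Width of the always-heated zone at each chamber end, mm.
#' @param chamber_length Length of the linear chamber, mm.
#' @param max_train_duration Safety cap on a Train session, seconds. Under
#'   ordinary parameters one of the two protocol rules fires long before this.
#'
#' @return A `protocol_spec` list.
#' @export
#' @examples
#' protocol_spec()
protocol_spec <- function(test_duration = 600,
                          max_heat_episodes = 20,
                          stationary_cutoff = 480,
                          trigger_walk_duration = 0.5,
                          edge_zone = 3.0,
                          chamber_length = 48.7,
                          max_train_duration = 1800) {
  check_positive(test_duration, "test_duration")
  check_positive(max_heat_episodes, "max_heat_episodes")
  check_positive(stationary_cutoff, "stationary_cutoff")
  check_positive(trigger_walk_duration, "trigger_walk_duration")
  check_positive(edge_zone, "edge_zone")
  check_positive(chamber_length, "chamber_length")
  check_positive(max_train_duration, "max_train_duration")
  if (edge_zone >= chamber_length / 2)
    config_error("`edge_zone` must be smaller than half the chamber length")
  structure(
    list(
      test_duration = test_duration,
      max_heat_episodes = as.integer(max_heat_episodes),
      stationary_cutoff = stationary_cutoff,
      trigger_walk_duration = trigger_walk_duration,
      edge_zone = edge_zone,
      chamber_length = chamber_length,
      max_train_duration = max_train_duration,
      session_order = SESSIONS
    ),
    class = "protocol_spec"
  )
}

#' Simulator parameters for the two-state fly model
#'
#' The simulated fly is a semi-Markov two-state (walk/pause) agent in a linear
#' chamber. Baseline hazards `pause_to_walk_rate` and `walk_to_pause_rate`
#' set the instinctive bout structure. Heat received while walking accrues a
#' suppression variable S at `learning_gain` per second; S decays with time
#' constant `suppression_decay` otherwise and multiplies the pause-to-walk
#' hazard by `exp(-suppression_effect * S)` — the learned inhibition of
#' walking. A slow non-specific `habituation_rate` scales the same hazard by
#' `exp(-habituation_rate * t)` in every fly, heated or not, producing the
#' mild activity decline seen in all groups. The virtual operator switches
#' the laser with a uniform reaction latency on both onset and release.
#'
#' @param dt Sampling step, seconds.
#' @param walk_speed Walking speed, mm/s.
#' @param pause_to_walk_rate Baseline pause-to-walk hazard, 1/s.
#' @param walk_to_pause_rate Walk-to-pause hazard, 1/s.
#' @param learning_gain Suppression accrual rate while heated and walking,
#'   1/s.
#' @param suppression_decay Suppression decay time constant, seconds.
#' @param suppression_effect Multiplier strength of S on the pause-to-walk
#'   hazard (dimensionless).
#' @param habituation_rate Non-specific activity decline rate, 1/s.
#' @param controller_latency Length-2 range of the operator reaction latency
#'   (uniform jitter), seconds, applied to both laser onset and release.
#' @param controller `"closed_loop"` for the operant controller, `"random"`
#'   for state-independent telegraph heat (a null control), `"off"` for no
#'   heat at all.
#' @param random_on_rate,random_off_rate Telegraph hazards for
#'   `controller = "random"`, 1/s.
#' @param n_triplets Number of train/yoked/blank triplets per cohort.
#' @param seed Integer seed; every simulation is bit-reproducible given it.
#' @param genotype Label written to the cohort attribute table.
#'
#' @return A `sim_config` list.
#' @seealso [sim_config_preset()] for the wild-type and reduced-learning
#'   presets.
#' @export
#' @examples
#' sim_config(n_triplets = 4, seed = 1)
sim_config <- function(dt = 0.01,
                       walk_speed = 10,
                       pause_to_walk_rate = 0.30,
                       walk_to_pause_rate = 0.20,
                       learning_gain = 0.008,
                       suppression_decay = 3000,
                       suppression_effect = 1.0,
                       habituation_rate = 1e-4,
                       controller_latency = c(0.3, 0.8),
                       controller = c("closed_loop", "random", "off"),
                       random_on_rate = 0.2,
                       random_off_rate = 0.2,
                       n_triplets = 60,
                       seed = 1L,
                       genotype = "CS") {
  controller <- match.arg(controller)
  check_positive(dt, "dt")
  check_positive(walk_speed, "walk_speed")
  check_positive(n_triplets, "n_triplets")
  for (nm in c("pause_to_walk_rate", "walk_to_pause_rate", "learning_gain",
               "habituation_rate", "random_on_rate", "random_off_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      config_error(sprintf("`%s` must be a single non-negative number", nm))
  }
  check_positive(suppression_decay, "suppression_decay")
  if (suppression_effect < 0)
    config_error("`suppression_effect` must be non-negative")
  if (length(controller_latency) != 2 || any(controller_latency < 0) ||
      controller_latency[2] < controller_latency[1])
    config_error("`controller_latency` must be an increasing non-negative range")
  structure(
    list(
      dt = dt,
      walk_speed = walk_speed,
      pause_to_walk_rate = pause_to_walk_rate,
      walk_to_pause_rate = walk_to_pause_rate,
      learning_gain = learning_gain,
      suppression_decay = suppression_decay,
      suppression_effect = suppression_effect,
      habituation_rate = habituation_rate,
      controller_latency = controller_latency,
      controller = controller,
      random_on_rate = random_on_rate,
      random_off_rate = random_off_rate,
      n_triplets = as.integer(n_triplets),
      seed = as.integer(seed),
      genotype = genotype
    ),
    class = "sim_config"
  )
}

#' Simulator presets
#'
#' `"wild_type"` is the default parameterization. The two reduced-learning
#' presets keep every parameter identical but scale `learning_gain` by 0.25,
#' an illustrative stand-in for dopamine-receptor mutants with attenuated
#' operant learning.
#'
#' @param preset Preset name.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config` list.
#' @export
#' @examples
#' sim_config_preset("reduced_learning", n_triplets = 10)$learning_gain
sim_config_preset <- function(preset = c("wild_type", "reduced_learning"),
                              ...) {
  preset <- match.arg(preset)
  base <- sim_config(...)
  if (preset == "reduced_learning") {
    base$learning_gain <- base$learning_gain * 0.25
    base$genotype <- if (base$genotype == "CS") "reduced-learning" else base$genotype
  }
  base
}

#' First-order thermal model of the fly body temperature
#'
#' The laser raises body temperature toward `t_target` with time constant
#' `tau_heat`; switching off relaxes it back toward room temperature with
#' `tau_cool`. The temperature trajectory is a diagnostic output: learning in
#' the simulator couples to the laser flag, not to temperature.
#'
#' @param t_room Room temperature, degrees C.
#' @param t_target Heated set point, degrees C (mild heat, 26-27).
#' @param tau_heat,tau_cool Heating and cooling time constants, seconds.
#' @return A `thermal_model` list.
#' @export
thermal_model <- function(t_room = 21.5, t_target = 26.5,
                          tau_heat = 4, tau_cool = 8) {
  check_positive(tau_heat, "tau_heat")
  check_positive(tau_cool, "tau_cool")
  if (t_target <= t_room)
    config_error("`t_target` must exceed `t_room`")
  structure(
    list(t_room = t_room, t_target = t_target,
         tau_heat = tau_heat, tau_cool = tau_cool),
    class = "thermal_model"
  )
}

#' Analysis parameters
#'
#' @param common_train_cut Common cut time for cumulative active duration
#'   comparisons across Train sessions, seconds. The pipeline uses the
#'   smaller of this value and the cohort-minimum Train-session length, and
#'   records the value actually used.
#' @param test_session_length Test-session length, seconds.
#' @param speed_threshold Walk/pause speed threshold for segmentation, mm/s.
#' @param min_bout Debounce: runs shorter than this are merged into their
#'   neighbours, seconds.
#' @param inactivity_threshold Curation rule: flies inactive for strictly
#'   more than this fraction of the Pre-test are excluded.
#' @param n_resamples Bootstrap resamples for median confidence intervals.
#' @param adjust Multiplicity adjustment for pairwise tests (see
#'   [stats::p.adjust()]); `"holm"` by default, `"none"` for unadjusted.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(common_train_cut = 163,
                            test_session_length = 600,
                            speed_threshold = 1.0,
                            min_bout = 0.2,
                            inactivity_threshold = 0.90,
                            n_resamples = 10000,
                            adjust = "holm") {
  check_positive(common_train_cut, "common_train_cut")
  check_positive(test_session_length, "test_session_length")
  check_positive(speed_threshold, "speed_threshold")
  if (min_bout < 0) config_error("`min_bout` must be non-negative")
  if (inactivity_threshold <= 0 || inactivity_threshold >= 1)
    config_error("`inactivity_threshold` must be in (0, 1)")
  check_positive(n_resamples, "n_resamples")
  structure(
    list(
      common_train_cut = common_train_cut,
      test_session_length = test_session_length,
      speed_threshold = speed_threshold,
      min_bout = min_bout,
      inactivity_threshold = inactivity_threshold,
      n_resamples = as.integer(n_resamples),
      adjust = adjust
    ),
    class = "analysis_config"
  )
}
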