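test_that("identical configuration and seed give bit-identical cohorts", {
  a <- simulate_cohort(sim_config(n_triplets = 2, seed = 77))
  b <- simulate_cohort(sim_config(n_triplets = 2, seed = 77))
  expect_identical(a$traces, b$traces)
  expect_identical(a$records, b$records)
})

test_that("growing the cohort leaves earlier triplets untouched", {
  small <- simulate_cohort(sim_config(n_triplets = 2, seed = 13))
  big <- simulate_cohort(sim_config(n_triplets = 4, seed = 13))
  for (id in names(small$traces))
    expect_identical(big$traces[[id]], small$traces[[id]])
})

test_that("yoked laser mirrors the train fly; blank is never heated", {
  co <- tiny_cohort(3, seed = 19)
  for (i in 1:3) {
    tid <- sprintf("t%03d", i)
    train <- co$traces[[paste0(tid, "_train")]]
    yoked <- co$traces[[paste0(tid, "_yoked")]]
    blank <- co$traces[[paste0(tid, "_blank")]]
    expect_identical(yoked$laser_on, train$laser_on)
    expect_true(all(blank$laser_on == 0L))
    # heat only in Train sessions
    test_rows <- train$session %in% c("Pre-test", "Test1", "Test2")
    expect_true(all(train$laser_on[test_rows] == 0L))
  }
})

test_that("positions stay inside the chamber at every sample", {
  co <- tiny_cohort(2, seed = 29)
  L <- protocol_spec()$chamber_length
  for (tr in co$traces) {
    expect_true(all(tr$position_mm >= 0 & tr$position_mm <= L))
    validate_trace(tr)
  }
})

test_that("every Train session ends by quota or stillness, within the episode cap", {
  co <- tiny_cohort(4, seed = 37)
  proto <- protocol_spec()
  dt <- 0.01
  for (i in 1:4) {
    tr <- co$traces[[sprintf("t%03d_train", i)]]
    seg <- segment_trace(tr)
    for (s in c("Train1", "Train2")) {
      w <- window_of(tr, s)
      idx <- seq(w$start_idx, w$end_idx - 1L)
      runs <- rle(tr$laser_on[idx])
      episodes <- sum(runs$values == 1L)
      expect_lte(episodes, proto$max_heat_episodes)
      # terminal condition: full quota, or the session ends in a pause
      # at least as long as the stationary cutoff
      final_pause <- if (tail(runs$values, 1) == 0L)
        tail(runs$lengths, 1) * dt else 0
      pause_end <- {
        b <- bout_summary(seg, w)  # touch: window is non-empty
        wl <- seg[seg$end_s >= w$end_s - 1e-9 & seg$start_s < w$end_s, ]
        if (nrow(wl) && wl$state[1] == "pause")
          w$end_s - wl$start_s[1] else 0
      }
      expect_true(episodes >= proto$max_heat_episodes ||
                    pause_end >= proto$stationary_cutoff - 1e-6 ||
                    w$n_samples * dt >= proto$max_train_duration - 1e-6,
                  label = sprintf("%s termination rule (episodes=%d)", s, episodes))
    }
  }
})

test_that("the controller decision follows the trigger, edge and session rules", {
  p <- protocol_spec()
  dt <- 0.01
  # walking continuously 0.6 s mid-chamber during Train1 -> ON
  expect_true(heat_controller(rep(TRUE, 60), 24, "Train1", p, dt))
  # walking only 0.4 s -> not yet
  expect_false(heat_controller(c(rep(FALSE, 10), rep(TRUE, 40)), 24, "Train1", p, dt))
  # paused mid-chamber -> OFF
  expect_false(heat_controller(rep(FALSE, 100), 24, "Train1", p, dt))
  # paused within 3 mm of a wall -> ON (edge rule)
  expect_true(heat_controller(rep(FALSE, 100), 1.5, "Train1", p, dt))
  expect_true(heat_controller(rep(FALSE, 100), 47.0, "Train1", p, dt))
  # Test sessions are never heated, whatever the state
  expect_false(heat_controller(rep(TRUE, 200), 1.5, "Pre-test", p, dt))
  expect_false(heat_controller(rep(TRUE, 200), 24, "Test2", p, dt))
})

test_that("step_fly holds position during pauses and accrues suppression when heated walking", {
  cfg <- sim_config()
  s <- fly_state(position = 20, behavioral_state = "pause")
  set.seed(1)
  s2 <- step_fly(s, laser_on = TRUE, cfg)
  expect_equal(s2$position, 20)
  # suppression decays during pauses
  s$suppression <- 1
  set.seed(1)
  s3 <- step_fly(s, laser_on = TRUE, cfg)
  expect_lt(s3$suppression, 1)
  # sustained laser during walking: S strictly increases by alpha*dt per step
  w <- fly_state(position = 20, behavioral_state = "walk")
  cfg_nolapse <- sim_config(walk_to_pause_rate = 0)
  set.seed(2)
  ss <- numeric(50)
  for (i in 1:50) {
    w <- step_fly(w, laser_on = TRUE, cfg_nolapse)
    ss[i] <- w$suppression
  }
  expect_true(all(diff(ss) > 0))
  expect_equal(ss[50], 50 * cfg$learning_gain * cfg$dt, tolerance = 1e-12)
  # walking advances the position by speed * dt
  expect_equal(abs(w$position - 20), 50 * cfg$walk_speed * cfg$dt,
               tolerance = 1e-9)
})

test_that("suppression shortens pauses' exit rate multiplicatively", {
  # with beta = 0 the suppression has no behavioural effect
  cfg0 <- sim_config(suppression_effect = 0, dt = 0.01)
  s <- fly_state(behavioral_state = "pause", suppression = 50)
  set.seed(11)
  n_exit0 <- sum(vapply(1:2000, function(i)
    step_fly(s, FALSE, cfg0)$behavioral_state == "walk", logical(1)))
  cfgb <- sim_config(suppression_effect = 1, dt = 0.01)
  set.seed(11)
  n_exitb <- sum(vapply(1:2000, function(i)
    step_fly(s, FALSE, cfgb)$behavioral_state == "walk", logical(1)))
  # beta = 0 keeps the baseline hazard; beta = 1 with S = 50 freezes the fly
  expect_gt(n_exit0, 0)
  expect_equal(n_exitb, 0)
})

test_that("simulated train flies are heated preferentially while walking", {
  co <- tiny_cohort(4, seed = 41)
  m <- metrics_table(co$traces, co$records)
  tr <- m[m$group == "train" & m$session == "Train1", ]
  expect_true(all(tr$p_heat_walk > tr$p_heat_pause))
})

test_that("with all heat disabled the three groups are exchangeable", {
  sm <- flyoperant:::simulate_metrics(
    sim_config(n_triplets = 8, seed = 71, controller = "off"),
    protocol = protocol_spec(max_train_duration = 600))
  fs <- fly_summary(sm$metrics)
  expect_true(all(sm$metrics$heat_exposure_s == 0))
  kw <- kruskal_wallis(fs, ad_test2, group)
  expect_gt(kw$p_value, 0.05)
  kw2 <- kruskal_wallis(fs, activity_pretest, group)
  expect_gt(kw2$p_value, 0.05)
})
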