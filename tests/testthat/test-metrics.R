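# A five-session trace with hand-designed Train-session laser patterns.
metric_fixture <- function(dt = 0.01) {
  n_of <- function(s) round(s / dt)
  # Train1 plan: 5 s walk with laser on for the last 4 s of walking,
  # then 5 s pause with laser on for 1 s.
  train1_laser <- c(rep(0L, n_of(1)), rep(1L, n_of(4)),
                    rep(1L, n_of(1)), rep(0L, n_of(4)))
  plans <- list(
    "Pre-test" = alternating_plan(5, 1, 1),
    "Train1" = list(states = c("walk", "pause"), durations = c(5, 5),
                    laser = train1_laser),
    "Test1" = alternating_plan(5, 1, 1),
    "Train2" = list(states = c("walk", "pause"), durations = c(5, 5),
                    laser = train1_laser),
    "Test2" = alternating_plan(2, 1, 4)
  )
  five_session_trace(plans, dt = dt, fly_id = "mfix")
}

test_that("conditional heat likelihood is a per-state time fraction", {
  tr <- metric_fixture()
  seg <- segment_trace(tr)
  w <- window_of(tr, "Train1")
  expect_equal(conditional_heat_likelihood(tr, seg, w, "walk"), 0.8)
  expect_equal(conditional_heat_likelihood(tr, seg, w, "pause"), 0.2)
  # laser off throughout -> 0 for both occupied states
  w0 <- window_of(tr, "Pre-test")
  expect_equal(conditional_heat_likelihood(tr, seg, w0, "walk"), 0)
  expect_equal(conditional_heat_likelihood(tr, seg, w0, "pause"), 0)
  # unoccupied state -> missing, not zero
  walk_only <- bout_plan_trace("walk", 5, session = "Train1", fly_id = "w")
  segw <- segment_trace(walk_only)
  ww <- window_of(walk_only, "Train1")
  expect_true(is.na(conditional_heat_likelihood(walk_only, segw, ww, "pause")))
  # mismatched fly ids are refused
  expect_error(conditional_heat_likelihood(walk_only, seg, ww, "walk"),
               class = "flyoperant_metrics_error")
})

test_that("exposure differential matches its defining worked examples", {
  expect_equal(exposure_differential(0.80, 0.30), 0.5)
  expect_equal(exposure_differential(0.50, 0.50), 0)
  expect_equal(exposure_differential(1.0, 0.0), 1.0)
  expect_true(is.na(exposure_differential(NA_real_, 0.3)))
  expect_error(exposure_differential(1.2, 0.3),
               class = "flyoperant_metrics_error")
  expect_error(exposure_differential(0.5, -0.1),
               class = "flyoperant_metrics_error")
})

test_that("CAD accumulates walk time up to the cut", {
  allpause <- segment_trace(bout_plan_trace("pause", 200))
  w <- list(start_s = 0, end_s = 200)
  expect_equal(cumulative_active_duration(allpause, w, 163), 0)
  allwalk <- segment_trace(bout_plan_trace("walk", 200))
  expect_equal(cumulative_active_duration(allwalk, w, 163), 163)
  alt <- segment_trace(bout_plan_trace(rep(c("walk", "pause"), 10), rep(1, 20)))
  expect_equal(cumulative_active_duration(alt, list(start_s = 0, end_s = 20), 10), 5)
  expect_error(cumulative_active_duration(alt, w, -1),
               class = "flyoperant_metrics_error")
})

test_that("CAD is non-decreasing, 1-Lipschitz, and ties out with activity level", {
  co <- tiny_cohort(1, seed = 23)
  tr <- co$traces[["t001_train"]]
  seg <- segment_trace(tr)
  w <- window_of(tr, "Train1")
  cuts <- seq(0, w$end_s - w$start_s, by = 0.5)
  cad <- cumulative_active_duration(seg, w, cuts)
  expect_true(all(diff(cad) >= -1e-9))
  expect_true(all(diff(cad) <= 0.5 + 1e-9))
  expect_true(all(cad <= cuts + 1e-9))
  len <- w$end_s - w$start_s
  expect_equal(activity_level(seg, w) * len,
               cumulative_active_duration(seg, w, len))
})

test_that("activity level and activity difference follow their definitions", {
  alt <- segment_trace(bout_plan_trace(rep(c("walk", "pause"), 5), rep(1, 10)))
  expect_equal(activity_level(alt, list(start_s = 0, end_s = 10)), 0.5)
  expect_equal(activity_difference(0.40, 0.70), -0.30)
  expect_equal(activity_difference(0.55, 0.55), 0)
  expect_equal(activity_difference(0.0, 1.0), -1.0)
  expect_error(activity_difference(1.4, 0.7),
               class = "flyoperant_metrics_error")
})

test_that("metrics are invariant under re-origin of the time axis", {
  tr <- metric_fixture()
  shifted <- fly_trace(tr$time_s + 1000, tr$position_mm, tr$laser_on,
                       tr$session, fly_id = "mfix", validate = FALSE)
  for (t in list(tr, shifted)) {
    seg <- segment_trace(t)
    w <- window_of(t, "Train1")
    expect_equal(conditional_heat_likelihood(t, seg, w, "walk"), 0.8)
    expect_equal(activity_level(seg, w), 0.5)
    expect_equal(cumulative_active_duration(seg, w, 5), 5)
  }
})

test_that("the metrics table assembles per-session rows with pooled EDs", {
  tr <- metric_fixture()
  records <- suppressWarnings(fly_records(tibble::tibble(
    fly_id = "mfix", group = "train", triplet_id = "t1",
    genotype = "CS", sex = "f", eclosion_date = "2026-01-05")))
  m <- metrics_table(list(tr), records)
  expect_equal(nrow(m), 5)
  t1 <- m[m$session == "Train1", ]
  expect_equal(t1$p_heat_walk, 0.8)
  expect_equal(t1$p_heat_pause, 0.2)
  expect_equal(t1$exposure_differential, 0.6)
  expect_equal(t1$heat_exposure_s, 5)
  expect_equal(t1$episode_count, 1L)
  fs <- fly_summary(m)
  expect_equal(fs$ad_test1, 0.5 - 0.5)
  expect_equal(fs$ad_test2, 0.2 - 0.5)
  # pooled ED equals the per-session value here (identical sessions)
  expect_equal(fs$ed_all, 0.6)
  expect_equal(fs$heat_exposure_total, 10)
})

test_that("a missing session or record is an explicit error", {
  tr <- bout_plan_trace("walk", 5, session = "Pre-test", fly_id = "solo")
  recs <- suppressWarnings(fly_records(tibble::tibble(
    fly_id = "solo", group = "train", triplet_id = "t1")))
  expect_error(metrics_table(list(tr), recs), "missing session",
               class = "flyoperant_metrics_error")
  expect_error(metrics_table(list(tr), recs[0, ]), "record",
               class = "flyoperant_metrics_error")
})

test_that("blank flies have missing EDs and zero exposure; ED stays bounded", {
  co <- tiny_cohort(2, seed = 31)
  m <- metrics_table(co$traces, co$records)
  blank <- m[m$group == "blank" & m$session %in% c("Train1", "Train2"), ]
  expect_true(all(blank$heat_exposure_s == 0))
  expect_true(all(is.na(blank$exposure_differential)))
  ed <- m$exposure_differential
  expect_true(all(is.na(ed) | (ed >= -1 & ed <= 1)))
})

test_that("a state-independent Bernoulli laser yields near-zero cohort ED", {
  set.seed(7)
  eds <- vapply(1:30, function(i) {
    k <- 40
    states <- rep(c("walk", "pause"), k)
    durs <- stats::rexp(2 * k, 1 / 2) + 0.3
    n <- sum(round(durs / 0.01))
    laser <- as.integer(stats::runif(n) < 0.4)
    tr <- bout_plan_trace(states, durs, laser = laser, session = "Train1",
                          fly_id = "b")
    seg <- segment_trace(tr)
    w <- window_of(tr, "Train1")
    exposure_differential(
      conditional_heat_likelihood(tr, seg, w, "walk"),
      conditional_heat_likelihood(tr, seg, w, "pause"))
  }, numeric(1))
  expect_lt(abs(mean(eds)), 0.02)
})
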