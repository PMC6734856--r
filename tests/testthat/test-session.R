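straight_fixture <- function(len = 100, r = 3) {
  tube_fixture(rbind(c(0, 0, 0), c(0, 0, len)), r)
}

test_that("session_config and catheter_state validate", {
  expect_error(session_config(dt = 0.2), "dt")
  expect_error(session_config(base_speed = -1), "positive")
  expect_error(catheter_state(c(0, 0, 0), heading = c(1, 1, 0)), "unit")
  st <- catheter_state(c(0, 0, 0), inside = FALSE)
  expect_identical(st$color, "red")
  expect_identical(catheter_state(c(0, 0, 0))$color, "white")
})

test_that("step kinematics: hold, displacement, speed modes", {
  fx <- straight_fixture()
  cfg <- session_config(dt = 0.05, base_speed = 10)
  st <- catheter_state(c(0, 0, 50))
  held <- step(st, c(0, 0, 0), cfg, fixture = fx)
  expect_equal(held$state$tip, st$tip)
  expect_equal(held$state$t, 0.05)
  moved <- step(st, c(1, 0, 0), cfg, fixture = fx)
  expect_equal(moved$state$tip, c(0.5, 0, 50))
  st2x <- catheter_state(c(0, 0, 50), speed_mode = "2x")
  moved2 <- step(st2x, c(1, 0, 0), cfg, fixture = fx)
  expect_equal(moved2$state$tip, c(1.0, 0, 50))
  expect_error(step(st, c(NA, 0, 0), cfg, fixture = fx), "invalid command")
})

test_that("step updates containment, color, and events; correction snaps", {
  fx <- straight_fixture()
  cfg <- session_config(dt = 0.05, base_speed = 100)  # 5 mm per step
  st <- catheter_state(c(0, 0, 50))
  out <- step(st, c(1, 0, 0), cfg, fixture = fx)      # tip at x = 5 > radius 3
  expect_false(out$state$inside)
  expect_identical(out$state$color, "red")
  expect_s3_class(out$event, "collision_event")
  expect_equal(out$event$penetration, 2)
  # staying outside: no second event
  out2 <- step(out$state, c(1, 0, 0), cfg, fixture = fx)
  expect_null(out2$event)
  # correction: event recorded, then snapped onto the centerline
  cfgc <- session_config(dt = 0.05, base_speed = 100, position_correction = TRUE,
                         correction_threshold = 6)
  stc <- catheter_state(c(4.9, 0, 50), inside = FALSE)
  outc <- step(stc, c(1, 0, 0), cfgc, fixture = fx)   # would reach x = 9.9 > 6
  expect_equal(distance_to_centerline(outc$state$tip, fx)$distance, 0)
  expect_true(outc$state$inside)
})

test_that("correction example: one event then zero fixture distance", {
  env <- fixture_env()
  sc <- build_scenario(1, env)
  fx <- tube_fixture(sc$centerline, sc$tube_radius)
  cfg <- session_config(position_correction = TRUE,
                        correction_threshold = 2 * sc$tube_radius)
  st <- catheter_state(sc$centerline[10, ])
  events <- 0L
  # drive the tip hard off-path (3x radius) in several steps
  for (i in 1:30) {
    out <- step(st, c(1, 0, 0), cfg, fixture = fx)
    st <- out$state
    if (!is.null(out$event)) events <- events + 1L
    if (distance_to_centerline(st$tip, fx)$distance == 0 && events > 0) break
  }
  expect_identical(events, 1L)
  expect_equal(distance_to_centerline(st$tip, fx)$distance, 0)
})

test_that("perfect follower: completes, zero collisions, time from arc length", {
  env <- fixture_env()
  cfg <- session_config()
  for (id in 1:4) {
    sc <- build_scenario(id, env)
    rec <- run_session(sc, perfect_controller(sc, cfg), cfg)
    expect_true(rec$completed)
    expect_identical(rec$n_collisions, 0L)
    # stops at the first dt multiple with the tip within epsilon of C
    L <- sum(sqrt(rowSums(diff(sc$centerline)^2)))
    t_pred <- ceiling((L - cfg$completion_epsilon) / cfg$base_speed / cfg$dt) * cfg$dt
    expect_lte(abs(rec$completion_time - t_pred), cfg$dt + 1e-9)
  }
})

test_that("zero controller times out; controller errors abort", {
  env <- fixture_env()
  sc <- build_scenario(1, env)
  cfg <- session_config(max_time = 2)
  rec <- run_session(sc, function(state) c(0, 0, 0), cfg)
  expect_false(rec$completed)
  expect_equal(rec$completion_time, cfg$max_time)
  bad <- run_session(sc, function(state) stop("controller died"), cfg)
  expect_true(bad$aborted)
  expect_false(bad$completed)
})

test_that("completion time is non-increasing in base_speed (perfect controller)", {
  env <- fixture_env()
  sc <- build_scenario(1, env)
  speeds <- c(5, 10, 20, 40)
  times <- vapply(speeds, function(v) {
    cfg <- session_config(base_speed = v)
    run_session(sc, perfect_controller(sc, cfg), cfg)$completion_time
  }, numeric(1))
  expect_true(all(diff(times) <= 0))
})

test_that("2x speed mode roughly halves completion time", {
  env <- fixture_env()
  sc <- build_scenario(1, env)
  cfg <- session_config()
  t1 <- run_session(sc, perfect_controller(sc, cfg), cfg)$completion_time
  t2 <- run_session(sc, perfect_controller(sc, cfg, speed_mode = "2x"), cfg,
                    speed_mode = "2x")$completion_time
  expect_lt(abs(t2 - t1 / 2), 3 * cfg$dt)
})

test_that("color is red exactly during excursions of a logged session", {
  env <- fixture_env()
  sc <- build_scenario(1, env)
  cfg <- session_config(seed = 21)
  prof <- agent_profile("beginner", sigma0 = 0.5, sigma_inf = 0.5, learn_rate = 0)
  ctrl <- make_controller(prof, sc, 1, seed = 21)
  fx <- tube_fixture(sc$centerline, sc$tube_radius)
  st <- catheter_state(sc$centerline[1, ])
  for (i in 1:200) {
    out <- step(st, ctrl(st), cfg, fixture = fx)
    st <- out$state
    contained <- distance_to_centerline(st$tip, fx)$distance <= fx$radius
    expect_identical(st$color == "white", contained)
    expect_identical(st$inside, contained)
  }
})

test_that("finalize_results agrees with an independent recount of the log", {
  env <- fixture_env()
  sc <- build_scenario(1, env)
  cfg <- session_config(seed = 5)
  prof <- agent_profile("beginner", sigma0 = 0.6, sigma_inf = 0.6, learn_rate = 0)
  rec <- run_session(sc, make_controller(prof, sc, 1, seed = 5), cfg)
  fin <- finalize_results(rec)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_events_jsonl(rec, path)
  recount <- if (file.size(path) == 0) 0L else length(read_events_jsonl(path))
  expect_identical(unname(fin["n_collisions"]), as.numeric(recount))
  expect_identical(unname(fin["completion_time"]), rec$completion_time)
  empty <- rec; empty$events <- list(); empty$n_collisions <- 0L
  expect_identical(unname(finalize_results(empty)["n_collisions"]), 0)
})

test_that("identical seeds give bit-identical session records", {
  env <- fixture_env()
  sc <- build_scenario(2, env)
  cfg <- session_config(seed = 99)
  prof <- default_profiles()$beginner
  r1 <- run_session(sc, make_controller(prof, sc, 3, seed = 99), cfg)
  r2 <- run_session(sc, make_controller(prof, sc, 3, seed = 99), cfg)
  expect_identical(r1[c("n_collisions", "completion_time", "completed")],
                   r2[c("n_collisions", "completion_time", "completed")])
  expect_identical(events_df_of(r1), events_df_of(r2))
})
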