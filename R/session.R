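#' Session configuration
#'
#' Defaults: 20 Hz integration (`dt` 0.05 s), base tip speed 10 mm/s,
#' completion within 5 mm of the destination, 300 s time budget, position
#' correction off with a snap threshold of two tube radii (6 mm).
#'
#' @param dt integration step, s (0 < dt <= 0.1).
#' @param base_speed tip speed at 1x, mm/s.
#' @param completion_epsilon proximity to the destination counting as
#'   completion, mm.
#' @param max_time session time budget, s.
#' @param position_correction snap the tip back to the path when it deviates
#'   beyond `correction_threshold`?
#' @param correction_threshold deviation triggering the snap, mm.
#' @param seed integer session seed.
#' @return an object of class `session_config`.
#' @export
session_config <- function(dt = 0.05, base_speed = 10, completion_epsilon = 5,
                           max_time = 300, position_correction = FALSE,
                           correction_threshold = 6, seed = 1L) {
  vals <- c(dt = dt, base_speed = base_speed,
            completion_epsilon = completion_epsilon, max_time = max_time,
            correction_threshold = correction_threshold)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("session_config values must be positive")
  if (dt > 0.1) stop("dt must be <= 0.1 s")
  structure(list(dt = dt, base_speed = base_speed,
                 completion_epsilon = completion_epsilon, max_time = max_time,
                 position_correction = isTRUE(position_correction),
                 correction_threshold = correction_threshold,
                 seed = as.integer(seed)),
            class = "session_config")
}

#' Catheter tip state
#'
#' The color field is the visual feedback contract: the tooltip is white
#' while contained and turns red for the duration of an excursion.
#'
#' @param tip tip position, mm.
#' @param heading unit direction of the last motion.
#' @param speed_mode `"1x"` or `"2x"`.
#' @param inside containment flag.
#' @param t simulation time, s.
#' @return an object of class `catheter_state`.
#' @export
catheter_state <- function(tip, heading = c(0, 0, 1), speed_mode = c("1x", "2x"),
                           inside = TRUE, t = 0) {
  speed_mode <- match.arg(speed_mode)
  heading <- as.numeric(heading)
  if (abs(vnorm(heading) - 1) > 1e-9) stop("heading must be a unit vector")
  structure(list(tip = as.numeric(tip), heading = heading,
                 speed_mode = speed_mode, inside = isTRUE(inside),
                 color = if (isTRUE(inside)) "white" else "red", t = t),
            class = "catheter_state")
}

speed_multiplier <- function(state) if (state$speed_mode == "2x") 2 else 1

#' Advance the catheter one timestep
#'
#' Moves the tip by `normalize(command) * base_speed * multiplier * dt` (a
#' zero command holds position), updates containment, color and the
#' collision event via the fixture geometry, then — if position correction
#' is on and the tip has deviated beyond the threshold — snaps the tip to
#' its nearest path point after the event is recorded.
#'
#' @param state a [catheter_state()].
#' @param command direction 3-vector (need not be unit; zero = hold).
#' @param config a [session_config()].
#' @param fixture a [tube_fixture()] for guided mode, else `NULL`.
#' @param organs an [organ_set()] for free mode, else `NULL`.
#' @param path guidance polyline used for position correction in free mode
#'   (defaults to the fixture centerline in guided mode).
#' @return list `(state, event)` where `event` is a [collision_event()] or
#'   `NULL`.
#' @export
step <- function(state, command, config, fixture = NULL, organs = NULL,
                 path = NULL) {
  command <- as.numeric(command)
  if (length(command) != 3 || any(!is.finite(command)))
    stop("invalid command: need a finite 3-vector")
  tip <- state$tip
  heading <- state$heading
  if (any(command != 0)) {
    dir <- normalize(command)
    tip <- tip + dir * config$base_speed * speed_multiplier(state) * config$dt
    heading <- dir
  }
  t_new <- state$t + config$dt
  cont <- containment(tip, fixture, organs)
  event <- NULL
  if (isTRUE(state$inside) && !cont$inside)
    event <- collision_event(t_new, tip, cont$penetration, cont$segment,
                             cont$source, cont$label)
  inside <- cont$inside

  if (config$position_correction) {
    ref <- if (!is.null(fixture)) fixture$centerline else path
    if (!is.null(ref)) {
      q <- cpp_polyline_query(matrix(tip, nrow = 1), ref)
      if (q[1, 1] > config$correction_threshold) {
        tip <- q[1, 4:6]
        inside <- if (!is.null(fixture)) TRUE else containment(tip, NULL, organs)$inside
      }
    }
  }
  new_state <- catheter_state(tip, heading, state$speed_mode, inside, t_new)
  list(state = new_state, event = event)
}

#' A controller that walks the centerline exactly
#'
#' At each step it aims at the path point one kinematic step ahead of the
#' tip's current arc length, so the tip tracks the polyline to within a
#' fraction of a step length. Used as the noise-free reference trainee.
#'
#' @param path n x 3 polyline (or a scenario, whose centerline is used).
#' @param config a [session_config()].
#' @param speed_mode `"1x"` or `"2x"`.
#' @return a controller `function(state) -> command`.
#' @export
perfect_controller <- function(path, config, speed_mode = "1x") {
  if (inherits(path, "scenario")) path <- path$centerline
  path <- as.matrix(path)
  total <- polyline_length(path)
  mult <- if (speed_mode == "2x") 2 else 1
  advance <- config$base_speed * mult * config$dt
  function(state) {
    q <- cpp_polyline_query(matrix(state$tip, nrow = 1), path)
    target <- cpp_point_at_arclength(path, min(q[1, 2] + advance, total))[1, ]
    d <- target - state$tip
    if (vnorm(d) < 1e-12) c(0, 0, 0) else d
  }
}

#' Run one training session
#'
#' The training loop: start at landmark A, repeatedly ask the controller for
#' a direction and [step()] the catheter, until the tip is within
#' `completion_epsilon` of the destination C or the time budget runs out.
#' Guided scenarios are scored against their tube fixture; the free scenario
#' is scored against the environment's organs, with the scenario-1 route (or
#' `reference_path`) serving as the agents' guidance path.
#'
#' @param scenario a [build_scenario()] result.
#' @param controller `function(state) -> command` 3-vector.
#' @param config a [session_config()].
#' @param env environment; required in free mode.
#' @param trainee_id,group,repetition session metadata for the record.
#' @param reference_path optional guidance polyline for free mode.
#' @param speed_mode `"1x"` or `"2x"`.
#' @param log_positions keep the per-step tip trace (post-correction) plus a
#'   snap flag, for replay verification.
#' @return an object of class `session_record`.
#' @export
run_session <- function(scenario, controller, config, env = NULL,
                        trainee_id = "t1", group = "beginner", repetition = 1L,
                        reference_path = NULL, speed_mode = "1x",
                        log_positions = FALSE) {
  if (scenario$id == "free") {
    if (is.null(env)) stop("free scenario needs the environment (organs)")
    organs <- organ_set(env$organs)
    fixture <- NULL
    path <- reference_path %||% build_scenario("1", env)$centerline
  } else {
    organs <- NULL
    fixture <- tube_fixture(scenario$centerline, scenario$tube_radius)
    path <- fixture$centerline
  }
  dest <- path[nrow(path), ]
  state <- catheter_state(path[1, ], speed_mode = speed_mode,
                          inside = containment(path[1, ], fixture, organs)$inside)
  max_steps <- round(config$max_time / config$dt)
  events <- list()
  trace <- if (log_positions) matrix(NA_real_, max_steps, 4) else NULL
  completed <- FALSE
  aborted <- FALSE
  completion_time <- config$max_time
  k <- 0L
  while (k < max_steps) {
    command <- tryCatch(controller(state), error = function(e) e)
    if (inherits(command, "error")) { aborted <- TRUE; break }
    res <- step(state, command, config, fixture, organs, path)
    state <- res$state
    k <- k + 1L
    if (!is.null(res$event)) events[[length(events) + 1L]] <- res$event
    if (log_positions) trace[k, ] <- c(state$tip, 0)  # snap flag patched below
    if (vnorm(state$tip - dest) <= config$completion_epsilon) {
      completed <- TRUE
      completion_time <- k * config$dt
      break
    }
  }
  rec <- structure(list(
    trainee_id = trainee_id, group = group, scenario_id = scenario$id,
    repetition = as.integer(repetition),
    n_collisions = length(events),
    completion_time = completion_time, completed = completed,
    aborted = aborted, events = events, seed = config$seed,
    config = config), class = "session_record")
  if (log_positions) rec$positions <- trace[seq_len(k), , drop = FALSE]
  rec
}

#' Final training results of a session
#'
#' @param record a [run_session()] result.
#' @return named vector `(n_collisions, completion_time)`, consistent with
#'   the event log by construction.
#' @export
finalize_results <- function(record) {
  stopifnot(inherits(record, "session_record"))
  n <- length(record$events)
  if (n != record$n_collisions)
    stop("session record inconsistent: collision count does not match events")
  c(n_collisions = n, completion_time = record$completion_time)
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record> %s/%s scenario %s rep %d: %d collisions, %.2f s%s\n",
              x$trainee_id, x$group, x$scenario_id, x$repetition,
              x$n_collisions, x$completion_time,
              if (x$completed) " (completed)" else " (timeout)"))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Results CSV and event JSONL
# ---------------------------------------------------------------------------

events_to_df <- function(events) {
  if (length(events) == 0)
    return(data.frame(t = numeric(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), penetration = numeric(0),
                      segment = integer(0), source = character(0),
                      organ_label = character(0)))
  do.call(rbind, lapply(events, function(e)
    data.frame(t = e$t, x = e$position[1], y = e$position[2], z = e$position[3],
               penetration = e$penetration, segment = e$segment_index,
               source = e$source, organ_label = e$organ_label)))
}

#' Write collision events as JSONL
#'
#' One JSON record per line:
#' `{"t","type":"collision","source","pos_mm","penetration_mm","segment"}`.
#'
#' @param events list of [collision_event()] or a `session_record`.
#' @param path output file.
#' @export
write_events_jsonl <- function(events, path) {
  if (inherits(events, "session_record")) events <- events$events
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (e in events) {
    obj <- list(t = e$t, type = "collision", source = e$source,
                pos_mm = e$position, penetration_mm = e$penetration,
                segment = e$segment_index)
    if (!is.na(e$organ_label)) obj$organ <- e$organ_label
    writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                                             na = "null")), con)
  }
  invisible(path)
}

#' @rdname write_events_jsonl
#' @export
read_events_jsonl <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(l) jsonlite::fromJSON(l))
}

#' Write / read a results table as CSV
#'
#' Columns: `trainee_id, group, scenario, repetition, n_collisions,
#' completion_time_s, completed, seed`.
#'
#' @param results data.frame of session summaries.
#' @param path file path.
#' @export
write_results_csv <- function(results, path) {
  need <- c("trainee_id", "group", "scenario", "repetition", "n_collisions",
            "completion_time_s", "completed", "seed")
  stopifnot(all(need %in% names(results)))
  write.csv(results[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
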