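#' Synthetic trainee profile
#'
#' A trainee is a noisy path-following controller. Skill is an angular noise
#' level (radians, sd of the per-step perturbation of the aim direction);
#' learning is an exponential decay of that level across repetitions.
#' Default profiles are calibrated qualitatively, not to human data:
#' beginners start noisy and improve, experts start at the beginner's
#' asymptote and stay there (no learning effect).
#'
#' @param group `"beginner"` or `"expert"`.
#' @param sigma0 initial angular noise sd, radians.
#' @param sigma_inf asymptotic noise sd, radians (`sigma0 >= sigma_inf >= 0`).
#' @param learn_rate per-repetition exponential decay rate (>= 0).
#' @param lookahead aim distance along the path, mm (> 0). Larger lookahead
#'   smooths steering but lets noise build into larger lateral excursions.
#' @param seed profile-level RNG seed component.
#' @return an object of class `agent_profile`.
#' @export
agent_profile <- function(group = c("beginner", "expert"), sigma0 = 0.45,
                          sigma_inf = 0.15, learn_rate = 0.12,
                          lookahead = 8, seed = 1L) {
  group <- match.arg(group)
  if (!(sigma0 >= sigma_inf && sigma_inf >= 0))
    stop("need sigma0 >= sigma_inf >= 0")
  if (learn_rate < 0) stop("learn_rate must be >= 0")
  if (lookahead <= 0) stop("lookahead must be > 0")
  structure(list(group = group, sigma0 = sigma0, sigma_inf = sigma_inf,
                 learn_rate = learn_rate, lookahead = lookahead,
                 seed = as.integer(seed)),
            class = "agent_profile")
}

#' Default beginner/expert profiles
#'
#' Beginner: sigma 0.45 -> 0.15 rad at rate 0.12 per repetition. Expert:
#' constant 0.15 rad (no learning), matching the observed pattern that only
#' the beginner group improves across repetitions.
#'
#' @return named list with elements `beginner` and `expert`.
#' @export
default_profiles <- function() {
  list(beginner = agent_profile("beginner", 0.45, 0.15, 0.12),
       expert = agent_profile("expert", 0.15, 0.15, 0))
}

#' Noise schedule across repetitions
#'
#' `sigma_k = sigma_inf + (sigma0 - sigma_inf) * exp(-learn_rate * (k - 1))`:
#' the standard exponential skill-acquisition (learning-curve) form, anchored
#' at `sigma0` for the first repetition.
#'
#' @param profile an [agent_profile()].
#' @param k repetition number (>= 1).
#' @return noise sd in radians.
#' @export
noise_schedule <- function(profile, k) {
  stopifnot(all(k >= 1))
  profile$sigma_inf + (profile$sigma0 - profile$sigma_inf) *
    exp(-profile$learn_rate * (k - 1))
}

#' Make a noisy path-following controller
#'
#' At each step the controller aims at the path point `lookahead` mm ahead
#' of the tip's current arc length, then rotates the aim direction by an
#' angle drawn from `N(0, sigma_k^2)` about a uniformly random axis
#' perpendicular to it. Deterministic given the seed; the RNG stream is
#' private, so sessions do not disturb (or depend on) the caller's RNG.
#'
#' @param profile an [agent_profile()].
#' @param scenario a scenario with a centerline, or a bare polyline matrix
#'   (the guidance path in free mode).
#' @param repetition repetition number, sets `sigma_k` via [noise_schedule()].
#' @param seed integer seed of the controller's private stream.
#' @return a controller `function(state) -> command`.
#' @export
make_controller <- function(profile, scenario, repetition = 1L,
                            seed = profile$seed) {
  path <- if (inherits(scenario, "scenario")) scenario$centerline else as.matrix(scenario)
  if (nrow(path) < 2) stop("controller needs a guidance path with >= 2 points")
  sigma <- noise_schedule(profile, repetition)
  total <- polyline_length(path)
  draw <- make_rng_stream(seed)
  function(state) {
    q <- cpp_polyline_query(matrix(state$tip, nrow = 1), path)
    target <- cpp_point_at_arclength(path, min(q[1, 2] + profile$lookahead, total))[1, ]
    d <- target - state$tip
    n <- vnorm(d)
    if (n < 1e-12) return(c(0, 0, 0))
    d <- d / n
    if (sigma > 0) {
      z <- draw(c(rnorm(1), runif(1)))
      d <- rotate_about_perpendicular(d, sigma * z[1], 2 * pi * z[2])
    }
    d
  }
}

# rotate unit vector d by theta about the perpendicular axis at angle psi
rotate_about_perpendicular <- function(d, theta, psi) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- normalize(c(d[2] * ref[3] - d[3] * ref[2],
                    d[3] * ref[1] - d[1] * ref[3],
                    d[1] * ref[2] - d[2] * ref[1]))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  ax <- cos(psi) * e1 + sin(psi) * e2
  axd <- c(ax[2] * d[3] - ax[3] * d[2],
           ax[3] * d[1] - ax[1] * d[3],
           ax[1] * d[2] - ax[2] * d[1])
  cos(theta) * d + sin(theta) * axd
}

#' Cohort design
#'
#' The reference study design is 2 groups of 8 trainees performing 20
#' repetitions in the free scenario.
#'
#' @param n_per_group trainees per group (>= 1).
#' @param repetitions repetitions per trainee (>= 1).
#' @param scenario_id scenario trained (default `"free"`).
#' @param base_seed global seed from which all session seeds derive.
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(n_per_group = 8L, repetitions = 20L,
                          scenario_id = "free", base_seed = 1L) {
  if (n_per_group < 1 || repetitions < 1)
    stop("n_per_group and repetitions must be >= 1")
  structure(list(n_per_group = as.integer(n_per_group),
                 repetitions = as.integer(repetitions),
                 scenario_id = as.character(scenario_id),
                 base_seed = as.integer(base_seed)),
            class = "cohort_design")
}

#' Simulate a training cohort
#'
#' Runs `n_per_group x 2 x repetitions` sessions. Each session's seed is a
#' pure function of `(base_seed, group, subject, repetition)`, so simulating
#' in any order — or extending the design — reproduces identical sessions.
#' The fast C++ session runner is used by default; `engine = "r"` runs the
#' (much slower) R loop through [run_session()] with identical semantics.
#'
#' In the free scenario the agents navigate the full scenario-1 route while
#' collisions are scored against the organs (there is no fixture).
#'
#' @param design a [cohort_design()].
#' @param beginner,expert [agent_profile()]s.
#' @param config a [session_config()].
#' @param env an environment.
#' @param engine `"cpp"` or `"r"`.
#' @return results data.frame (see [write_results_csv()] for columns).
#' @export
simulate_cohort <- function(design, beginner = default_profiles()$beginner,
                            expert = default_profiles()$expert,
                            config = session_config(), env,
                            engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  scenario <- build_scenario(design$scenario_id, env)
  free <- scenario$id == "free"
  path <- if (free) build_scenario("1", env)$centerline else scenario$centerline
  radius <- if (free) 0 else scenario$tube_radius
  omat <- if (free) organ_set(env$organs) else
    matrix(numeric(0), nrow = 0, ncol = 8)
  profiles <- list(beginner = beginner, expert = expert)

  rows <- vector("list", 2L * design$n_per_group * design$repetitions)
  i <- 0L
  for (grp in c("beginner", "expert")) {
    prof <- profiles[[grp]]
    for (subj in seq_len(design$n_per_group)) {
      tid <- sprintf("%s%02d", substr(grp, 1, 1), subj)
      for (rep_k in seq_len(design$repetitions)) {
        sseed <- derive_seed(design$base_seed, grp, subj, rep_k)
        sigma <- noise_schedule(prof, rep_k)
        if (engine == "cpp") {
          res <- cpp_agent_session(path, radius, unclass(omat), sigma,
                                   prof$lookahead, config$dt, config$base_speed,
                                   1, config$completion_epsilon, config$max_time,
                                   config$position_correction,
                                   config$correction_threshold, sseed, FALSE)
          row <- data.frame(trainee_id = tid, group = grp,
                            scenario = scenario$id, repetition = rep_k,
                            n_collisions = res$n_collisions,
                            completion_time_s = res$completion_time,
                            completed = res$completed, seed = sseed)
        } else {
          ctrl <- make_controller(prof, path, rep_k, seed = sseed)
          cfg <- session_config(config$dt, config$base_speed,
                                config$completion_epsilon, config$max_time,
                                config$position_correction,
                                config$correction_threshold, sseed)
          rec <- run_session(scenario, ctrl, cfg, env, tid, grp, rep_k,
                             reference_path = path)
          row <- data.frame(trainee_id = tid, group = grp,
                            scenario = scenario$id, repetition = rep_k,
                            n_collisions = rec$n_collisions,
                            completion_time_s = rec$completion_time,
                            completed = rec$completed, seed = sseed)
        }
        i <- i + 1L
        rows[[i]] <- row
      }
    }
  }
  do.call(rbind, rows)
}
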