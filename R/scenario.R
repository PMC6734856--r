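#' Built-in landmark sequences of the four training scenarios
#'
#' The four guided scenarios differ in whether the dorsal-to-ventral detour
#' landmark B is present (scenarios 1-2) or absent (scenarios 3-4), and in
#' which secondary landmarks the detailed path visits. Scenario 1's detailed
#' path is A, S4, S3, B, S2, S1, C. The companion sequences for scenarios
#' 2-4 mirror that structure with destinations at different disc levels;
#' they are defaults, overridable in scenario JSON, because only the detour
#' topology is fixed by the training design.
#'
#' @return named list: per scenario id, `primary` and `detailed` id vectors.
#' @export
scenario_sequences <- function() {
  list(
    "1" = list(primary = c("A", "B", "C"),
               detailed = c("A", "S4", "S3", "B", "S2", "S1", "C")),
    "2" = list(primary = c("A", "B", "C"),
               detailed = c("A", "S4", "S3", "B", "S2", "C")),
    "3" = list(primary = c("A", "C"),
               detailed = c("A", "S4", "S3", "S2", "S1", "C")),
    "4" = list(primary = c("A", "C"),
               detailed = c("A", "S3", "S2", "C")),
    "free" = list(primary = c("A", "C"), detailed = c("A", "C")))
}

# concatenate chain waypoints along a landmark sequence, deduplicating the
# shared junction points
thread_centerline <- function(env, detailed) {
  out <- NULL
  for (i in seq_len(length(detailed) - 1)) {
    key <- paste(detailed[i], detailed[i + 1], sep = "-")
    rkey <- paste(detailed[i + 1], detailed[i], sep = "-")
    ch <- env$chains[[key]]
    wp <- if (!is.null(ch)) ch$waypoints else {
      ch <- env$chains[[rkey]]
      if (is.null(ch)) stop("incomplete environment: no chain between ",
                            detailed[i], " and ", detailed[i + 1])
      ch$waypoints[rev(seq_len(nrow(ch$waypoints))), , drop = FALSE]
    }
    out <- if (is.null(out)) wp else rbind(out, wp[-1, , drop = FALSE])
  }
  out
}

#' Build a training scenario from an environment
#'
#' Looks up the scenario's primary and detailed landmark sequences and
#' threads a centerline through the detailed-sequence positions using the
#' environment's waypoint chains. Scenario `"free"` has no tube and an empty
#' centerline: training happens against the raw organs.
#'
#' @param id scenario id: `1:4` or `"free"`.
#' @param env an [generate_environment()] result.
#' @param sequences sequence table, defaulting to [scenario_sequences()].
#' @return an object of class `scenario`.
#' @export
build_scenario <- function(id, env, sequences = scenario_sequences()) {
  key <- as.character(id)
  if (!key %in% names(sequences)) stop("invalid scenario id: '", key, "'")
  sq <- sequences[[key]]
  for (lid in unique(c(sq$primary, sq$detailed))) landmark_position(env, lid)
  if (key == "free") {
    centerline <- matrix(numeric(0), ncol = 3)
    tube_radius <- NA_real_
    side_profile <- character(0)
  } else {
    centerline <- thread_centerline(env, sq$detailed)
    tube_radius <- env$params$tube_radius
    side <- setNames(env$landmarks$side, env$landmarks$id)
    side_profile <- side[sq$detailed[-1]]
  }
  sc <- structure(list(id = key, primary_sequence = sq$primary,
                       detailed_sequence = sq$detailed, centerline = centerline,
                       tube_radius = tube_radius,
                       side_profile = unname(side_profile),
                       landmarks = env$landmarks),
                  class = "scenario")
  check_scenario(sc)
  sc
}

check_scenario <- function(sc) {
  sq <- sc$detailed_sequence
  if (sq[1] != "A" || sq[length(sq)] != "C")
    stop("scenario invariant violated: detailed sequence must run from A to C")
  prim <- sq[sq %in% c("A", "B", "C")]
  if (!identical(prim, sc$primary_sequence))
    stop("scenario invariant violated: detailed sequence restricted to primary",
         " landmarks must equal the primary sequence")
  if (sc$id %in% c("1", "2") && !"B" %in% sc$primary_sequence)
    stop("scenario invariant violated: scenarios 1-2 include the detour landmark B")
  if (sc$id %in% c("3", "4") && "B" %in% sc$primary_sequence)
    stop("scenario invariant violated: scenarios 3-4 must not include B")
  if (sc$id != "free") {
    if (nrow(sc$centerline) < 2) stop("scenario centerline needs >= 2 points")
    seg <- diff(sc$centerline)
    if (any(rowSums(seg^2) == 0))
      stop("scenario invariant violated: consecutive centerline points must differ")
  }
  invisible(sc)
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario", x$id, "> ", paste(x$detailed_sequence, collapse = " -> "),
      if (x$id == "free") " (no fixture)" else
        sprintf(" (tube r=%.1f mm, length %.1f mm)", x$tube_radius,
                polyline_length(x$centerline)), "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Cognitive-map graph and hierarchical (primary-then-detailed) routing
# ---------------------------------------------------------------------------

#' Cognitive-map graph
#'
#' The cognitive map is modeled as landmarks (nodes) connected by waypoint
#' chains (edges); route selection is hierarchical: a coarse route over
#' primary landmarks is fixed first, then each leg is solved independently
#' over the detailed graph — the divide-and-conquer reading of hierarchical
#' spatial cognition.
#'
#' @param landmarks data.frame with columns `id`, `x`, `y`, `z`.
#' @param edges list of `list(from, to, waypoints)` where `waypoints` is an
#'   n x 3 matrix starting at `from`'s position and ending at `to`'s.
#' @return an object of class `cm_graph`.
#' @export
cognitive_map_graph <- function(landmarks, edges) {
  ids <- landmarks$id
  for (e in edges) {
    if (!e$from %in% ids || !e$to %in% ids)
      stop("edge endpoints must be graph nodes: ", e$from, "-", e$to)
    wp <- e$waypoints
    p1 <- as.numeric(landmarks[landmarks$id == e$from, c("x", "y", "z")])
    p2 <- as.numeric(landmarks[landmarks$id == e$to, c("x", "y", "z")])
    if (vnorm(wp[1, ] - p1) > 1e-9 || vnorm(wp[nrow(wp), ] - p2) > 1e-9)
      stop("edge waypoint chain must join its endpoint landmarks: ",
           e$from, "-", e$to)
  }
  lengths <- vapply(edges, function(e) polyline_length(e$waypoints), numeric(1))
  g <- structure(list(landmarks = landmarks, edges = edges,
                      edge_lengths = lengths), class = "cm_graph")
  # connectivity
  comp <- reachable_from(g, ids[1])
  if (!all(ids %in% comp)) stop("cognitive map graph must be connected")
  g
}

reachable_from <- function(g, start) {
  seen <- start
  repeat {
    grew <- FALSE
    for (e in g$edges) {
      if (e$from %in% seen && !e$to %in% seen) { seen <- c(seen, e$to); grew <- TRUE }
      if (e$to %in% seen && !e$from %in% seen) { seen <- c(seen, e$from); grew <- TRUE }
    }
    if (!grew) return(seen)
  }
}

#' Graph of a scenario's detailed route
#'
#' @param env an environment; @param id scenario id.
#' @return a [cognitive_map_graph()] whose edges are the chains between
#'   consecutive detailed-sequence landmarks.
#' @export
scenario_graph <- function(env, id) {
  sq <- scenario_sequences()[[as.character(id)]]
  if (is.null(sq)) stop("invalid scenario id: '", id, "'")
  det <- sq$detailed
  edges <- lapply(seq_len(length(det) - 1), function(i) {
    key <- paste(det[i], det[i + 1], sep = "-")
    ch <- env$chains[[key]]
    if (is.null(ch)) stop("incomplete environment: missing chain ", key)
    list(from = ch$from, to = ch$to, waypoints = ch$waypoints)
  })
  lm <- env$landmarks[env$landmarks$id %in% det, , drop = FALSE]
  cognitive_map_graph(lm, edges)
}

# shortest path between two nodes: minimal total chain length, ties broken
# by fewer nodes then lexicographically smaller id sequence. Label-correcting
# relaxation; graphs are small (a handful of landmarks).
shortest_leg <- function(g, from, to) {
  ids <- g$landmarks$id
  best <- setNames(vector("list", length(ids)), ids)
  best[[from]] <- list(len = 0, path = from)
  better <- function(a, b) {
    if (is.null(b)) return(TRUE)
    tol <- 1e-9 * max(1, abs(a$len), abs(b$len))
    if (a$len < b$len - tol) return(TRUE)
    if (a$len > b$len + tol) return(FALSE)
    if (length(a$path) != length(b$path)) return(length(a$path) < length(b$path))
    for (i in seq_along(a$path)) {
      if (a$path[i] < b$path[i]) return(TRUE)
      if (a$path[i] > b$path[i]) return(FALSE)
    }
    FALSE
  }
  repeat {
    grew <- FALSE
    for (k in seq_along(g$edges)) {
      e <- g$edges[[k]]
      w <- g$edge_lengths[k]
      for (dir in list(c(e$from, e$to), c(e$to, e$from))) {
        u <- dir[1]; v <- dir[2]
        if (!is.null(best[[u]]) && !v %in% best[[u]]$path) {
          cand <- list(len = best[[u]]$len + w, path = c(best[[u]]$path, v))
          if (better(cand, best[[v]])) { best[[v]] <- cand; grew <- TRUE }
        }
      }
    }
    if (!grew) break
  }
  if (is.null(best[[to]]))
    stop("unroutable leg: no path from ", from, " to ", to)
  best[[to]]$path
}

#' Hierarchical route selection
#'
#' Solves the detailed path leg by leg between consecutive primary landmarks
#' and concatenates the legs, removing duplicated junction nodes. Each leg
#' minimizes total waypoint-chain length (ties: fewer nodes, then
#' lexicographic ids).
#'
#' @param graph a [cognitive_map_graph()].
#' @param start,dest landmark ids.
#' @param primary_hops ordered primary landmark ids, beginning with `start`
#'   and ending with `dest`.
#' @return character vector of landmark ids.
#' @export
hierarchical_route <- function(graph, start, dest, primary_hops) {
  stopifnot(inherits(graph, "cm_graph"))
  if (primary_hops[1] != start || primary_hops[length(primary_hops)] != dest)
    stop("primary_hops must begin with start and end with dest")
  if (length(primary_hops) == 1) return(start)
  route <- primary_hops[1]
  for (i in seq_len(length(primary_hops) - 1)) {
    if (primary_hops[i] == primary_hops[i + 1]) next
    leg <- shortest_leg(graph, primary_hops[i], primary_hops[i + 1])
    route <- c(route, leg[-1])
  }
  route
}

# ---------------------------------------------------------------------------
# Scenario JSON round trip
# ---------------------------------------------------------------------------

#' Write / read a scenario as JSON
#'
#' Schema: `id`, `tube_radius_mm`, `landmarks` (id/level/role/position_mm),
#' `primary_sequence`, `detailed_sequence`, `centerline_mm`, `side_profile`.
#' The reader validates all scenario invariants and names the offending
#' field on failure.
#'
#' @param scenario a [build_scenario()] result.
#' @param path file path.
#' @return `read_scenario_json` returns the scenario.
#' @export
write_scenario_json <- function(scenario, path) {
  lm <- scenario$landmarks
  obj <- list(
    id = scenario$id,
    tube_radius_mm = scenario$tube_radius,
    landmarks = lapply(seq_len(nrow(lm)), function(i)
      list(id = lm$id[i], level = lm$level[i], role = lm$role[i],
           side = lm$side[i], position_mm = as.numeric(lm[i, c("x", "y", "z")]))),
    primary_sequence = scenario$primary_sequence,
    detailed_sequence = scenario$detailed_sequence,
    centerline_mm = scenario$centerline,
    side_profile = scenario$side_profile)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario_json
#' @export
read_scenario_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  for (f in c("id", "landmarks", "primary_sequence", "detailed_sequence"))
    if (is.null(obj[[f]])) stop("malformed scenario JSON: missing field '", f, "'")
  lm <- obj$landmarks
  pos <- do.call(rbind, lm$position_mm)
  landmarks <- data.frame(id = lm$id, level = lm$level, role = lm$role,
                          side = lm$side, x = pos[, 1], y = pos[, 2], z = pos[, 3],
                          stringsAsFactors = FALSE)
  if (sum(landmarks$role == "start") != 1 || sum(landmarks$role == "destination") != 1)
    stop("malformed scenario JSON: field 'landmarks' needs exactly one start",
         " and one destination")
  centerline <- obj$centerline_mm
  if (is.null(centerline) || length(centerline) == 0)
    centerline <- matrix(numeric(0), ncol = 3)
  centerline <- as.matrix(centerline)
  storage.mode(centerline) <- "double"
  for (cc in c("x", "y", "z")) landmarks[[cc]] <- as.numeric(landmarks[[cc]])
  sc <- structure(list(id = as.character(obj$id),
                       primary_sequence = obj$primary_sequence,
                       detailed_sequence = obj$detailed_sequence,
                       centerline = centerline,
                       tube_radius = as.numeric(obj$tube_radius_mm %||% NA_real_),
                       side_profile = obj$side_profile %||% character(0),
                       landmarks = landmarks),
                  class = "scenario")
  check_scenario(sc)
  sc
}
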