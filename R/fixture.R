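#' Tube virtual fixture
#'
#' A virtual fixture is a software constraint that guides the motion of a
#' controlled instrument along a specified path. Here it is a tube: an
#' arc-length-parameterized polyline centerline plus a radius. The catheter
#' tip is "inside" while its distance to the centerline does not exceed the
#' radius; leaving the tube is an excursion, scored as one collision.
#' Beyond the first/last vertex the distance is taken to the terminal vertex
#' (capped tube ends).
#'
#' @param centerline n x 3 matrix of ordered waypoints, mm (n >= 2,
#'   consecutive points distinct).
#' @param radius tube radius, mm (> 0).
#' @return an object of class `tube_fixture` with fields `centerline`,
#'   `radius`, `cumulative_arclength` and `length`.
#' @export
tube_fixture <- function(centerline, radius) {
  centerline <- as.matrix(centerline)
  if (nrow(centerline) < 2) stop("centerline needs at least 2 points")
  if (ncol(centerline) != 3) stop("centerline must be n x 3")
  seg <- sqrt(rowSums((centerline[-1, , drop = FALSE] -
                       centerline[-nrow(centerline), , drop = FALSE])^2))
  if (any(seg == 0)) stop("consecutive centerline points must be distinct")
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0)
    stop("tube radius must be a single positive number")
  cum <- c(0, cumsum(seg))
  structure(list(centerline = centerline, radius = radius,
                 cumulative_arclength = cum, length = cum[length(cum)]),
            class = "tube_fixture")
}

#' Distance from a point to the fixture centerline
#'
#' Exact minimum over all segments using the point-to-segment closed form;
#' ties are broken toward the smaller segment index. Also locates the nearest
#' centerline point by arc length.
#'
#' @param point 3-vector or n x 3 matrix, mm.
#' @param fixture a [tube_fixture()].
#' @return data.frame with columns `distance`, `arclength`, `segment`
#'   (1-based), and the nearest point `nx`, `ny`, `nz` (all mm).
#' @export
distance_to_centerline <- function(point, fixture) {
  stopifnot(inherits(fixture, "tube_fixture"))
  pts <- as_point_matrix(point)
  q <- cpp_polyline_query(pts, fixture$centerline)
  data.frame(distance = q[, 1], arclength = q[, 2], segment = as.integer(q[, 3]),
             nx = q[, 4], ny = q[, 5], nz = q[, 6])
}

#' Point on the centerline at a given arc length
#'
#' @param fixture a [tube_fixture()] (or bare n x 3 polyline matrix).
#' @param s arc length(s), mm; clamped to `[0, length]`.
#' @return m x 3 matrix of points.
#' @export
centerline_point_at <- function(fixture, s) {
  line <- if (inherits(fixture, "tube_fixture")) fixture$centerline else as.matrix(fixture)
  cpp_point_at_arclength(line, as.numeric(s))
}

#' Collision event record
#'
#' One event is emitted per contiguous excursion: the tip leaving the tube
#' (fixture source) or entering an organ (organ source, free scenario).
#'
#' @param t simulation time, s.
#' @param position tip position at detection, mm.
#' @param penetration distance beyond the tube radius or organ surface, mm
#'   (> 0).
#' @param segment_index active centerline segment (fixture source only).
#' @param source `"fixture"` or `"organ"`.
#' @param organ_label label of the organ struck (organ source only).
#' @return an object of class `collision_event`.
#' @export
collision_event <- function(t, position, penetration, segment_index = NA_integer_,
                            source = c("fixture", "organ"),
                            organ_label = NA_character_) {
  source <- match.arg(source)
  if (!is.finite(penetration) || penetration <= 0)
    stop("collision penetration must be > 0")
  structure(list(t = t, position = as.numeric(position),
                 penetration = penetration,
                 segment_index = as.integer(segment_index),
                 source = source, organ_label = organ_label),
            class = "collision_event")
}

# containment of a tip position: list(inside, penetration, segment, label)
containment <- function(tip, fixture = NULL, organs = NULL) {
  if (!is.null(fixture)) {
    q <- distance_to_centerline(tip, fixture)
    pen <- q$distance[1] - fixture$radius
    list(inside = pen <= 0, penetration = pen, segment = q$segment[1],
         source = "fixture", label = NA_character_)
  } else if (!is.null(organs)) {
    d <- min_organ_distance(tip, organs)
    list(inside = d$distance[1] >= 0, penetration = -d$distance[1],
         segment = NA_integer_, source = "organ", label = d$label[1])
  } else {
    stop("misconfigured mode: supply either a fixture or an organ set")
  }
}

#' Detect a collision between two consecutive simulator states
#'
#' Emits an event only on an inside-to-outside transition of the containment
#' signal, so a contiguous excursion produces exactly one event no matter how
#' many timesteps it spans. Motion between steps is checked at the endpoints
#' only (the timestep is small relative to the geometry).
#'
#' @param prev,next_state consecutive [catheter_state()] objects.
#' @param fixture a [tube_fixture()] (guided scenarios), or `NULL`.
#' @param organs an [organ_set()] (free scenario), or `NULL`.
#' @param t event time, s (defaults to `next_state$t`).
#' @return a [collision_event()], or `NULL` if no boundary was crossed.
#' @export
detect_collision <- function(prev, next_state, fixture = NULL, organs = NULL,
                             t = next_state$t) {
  cont <- containment(next_state$tip, fixture, organs)
  if (isTRUE(prev$inside) && !cont$inside) {
    collision_event(t, next_state$tip, cont$penetration, cont$segment,
                    cont$source, cont$label)
  } else {
    NULL
  }
}

#' Guidance/penalty force of the tube fixture
#'
#' The force contract of the processing loop: zero while the tip is inside
#' the tube; outside, a linear penalty spring of magnitude
#' `stiffness * penetration` directed from the tip toward its nearest
#' centerline point. The magnitude is continuous across the tube wall.
#'
#' @param point tip position, mm.
#' @param fixture a [tube_fixture()].
#' @param stiffness spring constant, N/mm (>= 0; default 0.2).
#' @return a 3-vector force, N.
#' @export
fixture_force <- function(point, fixture, stiffness = 0.2) {
  if (stiffness < 0) stop("stiffness must be >= 0")
  q <- distance_to_centerline(point, fixture)
  pen <- q$distance[1] - fixture$radius
  if (pen <= 0) return(c(0, 0, 0))
  dir <- c(q$nx[1], q$ny[1], q$nz[1]) - as.numeric(point)
  stiffness * pen * dir / vnorm(dir)
}
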