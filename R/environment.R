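#' Geometry parameters of the synthetic epidural-space environment
#'
#' All dimensions are millimetres and are declared synthetic: they are
#' plausible magnitudes for a sacral/lumbar epidural canal, not
#' patient-derived measurements. Coordinate convention: right-handed, +z from
#' the sacral hiatus toward the head, +y dorsal, +x to the patient's left.
#'
#' @param canal_length canal length from entry (A) to lesion (C), mm.
#' @param path_radius radial offset of the dorsal/ventral insertion paths
#'   from the canal axis, mm.
#' @param dura_radius radius of the dural-sac capsule on the canal axis, mm.
#' @param tube_radius radius of the tube virtual fixture, mm.
#' @param nerve_radius,nerve_half_length radius and lateral half-length of
#'   the sacral-nerve capsules, mm.
#' @param wall_inner,wall_thickness inner face offset and thickness of the
#'   bony canal walls, mm.
#' @param gate_clearance free clearance between the insertion path and the
#'   narrowing primitives (dorsal bone spurs, ventral disc protrusions), mm.
#'   These narrowings are what make free-scenario collision counts sensitive
#'   to steering noise.
#' @param gate_radius radius of the narrowing spheres, mm.
#' @param jitter half-width of the uniform jitter applied to landmark
#'   z-positions, mm.
#' @param waypoint_spacing approximate spacing of generated path waypoints,
#'   mm.
#' @return a validated parameter list of class `env_params`.
#' @export
env_params <- function(canal_length = 200, path_radius = 11, dura_radius = 8,
                       tube_radius = 3, nerve_radius = 2, nerve_half_length = 6,
                       wall_inner = 14.5, wall_thickness = 6,
                       gate_clearance = 0.6, gate_radius = 2,
                       jitter = 2, waypoint_spacing = 5) {
  p <- list(canal_length = canal_length, path_radius = path_radius,
            dura_radius = dura_radius, tube_radius = tube_radius,
            nerve_radius = nerve_radius, nerve_half_length = nerve_half_length,
            wall_inner = wall_inner, wall_thickness = wall_thickness,
            gate_clearance = gate_clearance, gate_radius = gate_radius,
            jitter = jitter, waypoint_spacing = waypoint_spacing)
  pos <- setdiff(names(p), "jitter")
  bad <- pos[vapply(pos, function(nm) !is.numeric(p[[nm]]) || p[[nm]] <= 0, logical(1))]
  if (length(bad)) stop("invalid parameter (must be > 0): ", paste(bad, collapse = ", "))
  if (!is.numeric(jitter) || jitter < 0) stop("invalid parameter: jitter must be >= 0")
  if (path_radius >= wall_inner) stop("invalid parameter: path_radius must be < wall_inner")
  if (dura_radius >= path_radius) stop("invalid parameter: dura_radius must be < path_radius")
  structure(p, class = "env_params")
}

# position on the canal-wall cylinder: theta = 0 dorsal, pi ventral (via +x)
cyl_pos <- function(theta, z, rho) c(rho * sin(theta), rho * cos(theta), z)

# straight or crossing waypoint chain between two landmarks, all points on
# the cylinder of radius rho
make_chain <- function(th1, z1, th2, z2, rho, spacing) {
  arc <- sqrt((rho * abs(th2 - th1))^2 + (z2 - z1)^2)
  n <- max(2L, as.integer(ceiling(arc / spacing)) + 1L)
  t <- seq(0, 1, length.out = n)
  th <- th1 + t * (th2 - th1)
  z <- z1 + t * (z2 - z1)
  wp <- cbind(rho * sin(th), rho * cos(th), z)
  dimnames(wp) <- NULL
  wp
}

#' Generate a synthetic epidural-space environment
#'
#' Procedurally builds the training scene: the seven landmarks (A at the
#' sacral hiatus, B at the dorsal-to-ventral detour point, C at the lesion
#' disc, sacral nerves S1-S4 as secondary reference points), the dorsal and
#' ventral waypoint chains connecting them on a cylinder around the dural
#' sac, and the organ collision primitives (bony canal walls, dura capsule,
#' disc protrusions, nerve capsules, narrowing spurs). Regeneration with the
#' same seed and parameters is bit-identical.
#'
#' @param seed integer RNG seed.
#' @param params an [env_params()] list.
#' @return an object of class `epi_environment` with fields `landmarks`
#'   (data.frame), `chains` (named list of waypoint matrices with endpoints),
#'   `organs` (list of [organ_primitive()]), `bounds`, `seed`, `params`.
#' @export
generate_environment <- function(seed = 1L, params = env_params()) {
  if (!inherits(params, "env_params")) params <- do.call(env_params, params)
  L <- params$canal_length
  rho <- params$path_radius
  j <- params$jitter

  # landmark order along the canal from the hiatus: A, S4, S3, B, S2, S1, C
  z_nerve <- with_seed(seed, {
    base <- L * (1:4) / 5                      # S4, S3, S2, S1 equally spaced
    if (j > 0) base + runif(4, -j, j) else base
  })
  zs <- c(A = 0, S4 = z_nerve[1], S3 = z_nerve[2],
          B = (z_nerve[2] + z_nerve[3]) / 2, S2 = z_nerve[3],
          S1 = z_nerve[4], C = L)
  side <- c(A = "dorsal", S4 = "dorsal", S3 = "dorsal", B = "dorsal",
            S2 = "ventral", S1 = "ventral", C = "ventral")
  theta <- ifelse(side == "dorsal", 0, pi)
  landmarks <- data.frame(
    id = names(zs),
    level = ifelse(names(zs) %in% c("A", "B", "C"), "primary", "secondary"),
    role = c(A = "start", S4 = "reference", S3 = "reference", B = "detour",
             S2 = "reference", S1 = "reference", C = "destination")[names(zs)],
    side = unname(side),
    x = rho * sin(theta), y = rho * cos(theta), z = unname(zs),
    stringsAsFactors = FALSE)
  rownames(landmarks) <- NULL

  pairs <- list(c("A", "S4"), c("S4", "S3"), c("S3", "B"), c("B", "S2"),
                c("S2", "S1"), c("S1", "C"), c("S3", "S2"), c("A", "S3"),
                c("S2", "C"))
  th_of <- function(id) if (side[[id]] == "dorsal") 0 else pi
  chains <- lapply(pairs, function(pr) {
    wp <- make_chain(th_of(pr[1]), zs[[pr[1]]], th_of(pr[2]), zs[[pr[2]]],
                     rho, params$waypoint_spacing)
    list(from = pr[1], to = pr[2], waypoints = wp)
  })
  names(chains) <- vapply(pairs, paste, character(1), collapse = "-")

  # organs -------------------------------------------------------------
  wi <- params$wall_inner
  wt <- params$wall_thickness
  wc <- wi + wt / 2
  zc <- L / 2
  zh <- L / 2 + 10
  xy_half <- wi + wt
  organs <- list(
    organ_primitive("dura", "capsule", "dural sac",
                    a = c(0, 0, -5), b = c(0, 0, L + 5), radius = params$dura_radius),
    organ_primitive("bone", "box", "dorsal wall", center = c(0, wc, zc),
                    half_extents = c(xy_half, wt / 2, zh)),
    organ_primitive("bone", "box", "ventral wall", center = c(0, -wc, zc),
                    half_extents = c(xy_half, wt / 2, zh)),
    organ_primitive("bone", "box", "left wall", center = c(-wc, 0, zc),
                    half_extents = c(wt / 2, xy_half, zh)),
    organ_primitive("bone", "box", "right wall", center = c(wc, 0, zc),
                    half_extents = c(wt / 2, xy_half, zh)))
  hl <- params$nerve_half_length
  for (sid in c("S1", "S2", "S3", "S4")) {
    lm <- landmarks[landmarks$id == sid, ]
    organs <- c(organs, list(organ_primitive(
      "nerve", "capsule", sid,
      a = c(-hl, lm$y, lm$z), b = c(hl, lm$y, lm$z), radius = params$nerve_radius)))
  }
  # narrowings of the epidural space: bone spurs over the dorsal path,
  # disc protrusions under the ventral path, midway between landmarks
  gy <- rho + params$gate_clearance + params$gate_radius
  gates <- rbind(
    c(kind = "bone", label = "spur A-S4",  y = gy,  z = (zs[["A"]] + zs[["S4"]]) / 2),
    c(kind = "bone", label = "spur S4-S3", y = gy,  z = (zs[["S4"]] + zs[["S3"]]) / 2),
    c(kind = "bone", label = "spur S3-B",  y = gy,  z = (zs[["S3"]] + zs[["B"]]) / 2),
    c(kind = "disc", label = "disc S2-S1", y = -gy, z = (zs[["S2"]] + zs[["S1"]]) / 2),
    c(kind = "disc", label = "disc S1-C",  y = -gy, z = (zs[["S1"]] + zs[["C"]]) / 2))
  for (i in seq_len(nrow(gates))) {
    organs <- c(organs, list(organ_primitive(
      gates[i, "kind"], "sphere", gates[i, "label"],
      center = c(0, as.numeric(gates[i, "y"]), as.numeric(gates[i, "z"])),
      radius = params$gate_radius)))
  }
  # the lesion disc itself, past the destination so completion stays clean
  organs <- c(organs, list(organ_primitive(
    "disc", "sphere", "lesion disc", center = c(0, -rho, L + 8), radius = 3)))

  bounds <- list(min = c(-xy_half, -xy_half, -10), max = c(xy_half, xy_half, L + 10))

  env <- structure(list(landmarks = landmarks, chains = chains, organs = organs,
                        bounds = bounds, seed = as.integer(seed), params = params),
                   class = "epi_environment")
  check_environment(env)
  env
}

# invariants enforced at generation and on JSON read
check_environment <- function(env) {
  lm <- env$landmarks
  pts <- as.matrix(lm[, c("x", "y", "z")])
  bmin <- env$bounds$min; bmax <- env$bounds$max
  if (any(t(pts) < bmin - 1e-9) || any(t(pts) > bmax + 1e-9))
    stop("environment invariant violated: landmark outside bounds")
  bones <- Filter(function(o) o$kind == "bone", env$organs)
  for (o in bones) {
    d <- organ_distance(pts, o)
    if (any(d < env$params$tube_radius - 1e-9))
      stop("environment invariant violated: landmark within one tube radius of bone '",
           o$label, "'")
  }
  for (ch in env$chains) {
    wp <- ch$waypoints
    p1 <- as.numeric(lm[lm$id == ch$from, c("x", "y", "z")])
    p2 <- as.numeric(lm[lm$id == ch$to, c("x", "y", "z")])
    if (vnorm(wp[1, ] - p1) > 1e-9 || vnorm(wp[nrow(wp), ] - p2) > 1e-9)
      stop("environment invariant violated: chain ", ch$from, "-", ch$to,
           " does not join its landmarks")
  }
  invisible(env)
}

landmark_position <- function(env, id) {
  lm <- env$landmarks[env$landmarks$id == id, ]
  if (nrow(lm) != 1) stop("incomplete environment: missing landmark '", id, "'")
  as.numeric(lm[, c("x", "y", "z")])
}

#' @export
print.epi_environment <- function(x, ...) {
  cat("<epi_environment> seed", x$seed, "-", nrow(x$landmarks), "landmarks,",
      length(x$chains), "chains,", length(x$organs), "organs\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# JSON round trip
# ---------------------------------------------------------------------------

#' Write / read an environment as JSON
#'
#' Full-precision serialization: a round trip reproduces the environment
#' exactly (and re-validates its invariants on read).
#'
#' @param env an `epi_environment`.
#' @param path file path.
#' @return `read_environment_json` returns the environment.
#' @export
write_environment_json <- function(env, path) {
  organs <- lapply(env$organs, function(o) {
    base <- list(kind = o$kind, shape = o$shape, label = o$label)
    if (o$shape == "sphere") c(base, list(center_mm = o$row[2:4], radius_mm = o$row[8]))
    else if (o$shape == "capsule") c(base, list(a_mm = o$row[2:4], b_mm = o$row[5:7],
                                                radius_mm = o$row[8]))
    else c(base, list(center_mm = o$row[2:4], half_extents_mm = o$row[5:7]))
  })
  obj <- list(
    seed = env$seed,
    params = unclass(env$params),
    bounds = env$bounds,
    landmarks = env$landmarks,
    chains = lapply(unname(env$chains), function(ch)
      list(from = ch$from, to = ch$to, waypoints_mm = ch$waypoints)),
    organs = organs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_environment_json
#' @export
read_environment_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  for (f in c("seed", "params", "landmarks", "chains", "organs", "bounds"))
    if (is.null(obj[[f]])) stop("malformed environment JSON: missing field '", f, "'")
  params <- do.call(env_params, obj$params)
  chains <- lapply(seq_len(nrow(obj$chains)), function(i) {
    list(from = obj$chains$from[i], to = obj$chains$to[i],
         waypoints = obj$chains$waypoints_mm[[i]])
  })
  names(chains) <- paste(obj$chains$from, obj$chains$to, sep = "-")
  og <- jsonlite::read_json(path, simplifyVector = FALSE)$organs
  organs <- lapply(seq_along(og), function(i) {
    o <- og[[i]]
    num <- function(x) as.numeric(unlist(x))
    sh <- o$shape %||% "?"
    if (sh == "sphere")
      organ_primitive(o$kind, sh, o$label, center = num(o$center_mm),
                      radius = num(o$radius_mm))
    else if (sh == "capsule")
      organ_primitive(o$kind, sh, o$label, a = num(o$a_mm), b = num(o$b_mm),
                      radius = num(o$radius_mm))
    else if (sh == "box")
      organ_primitive(o$kind, sh, o$label, center = num(o$center_mm),
                      half_extents = num(o$half_extents_mm))
    else stop("malformed environment JSON: organ ", i, " has unsupported shape '",
              sh, "'")
  })
  landmarks <- as.data.frame(obj$landmarks)
  for (cc in c("x", "y", "z")) landmarks[[cc]] <- as.numeric(landmarks[[cc]])
  chains <- lapply(chains, function(ch) {
    storage.mode(ch$waypoints) <- "double"
    ch
  })
  env <- structure(list(landmarks = landmarks,
                        chains = chains, organs = organs,
                        bounds = list(min = obj$bounds$min, max = obj$bounds$max),
                        seed = as.integer(obj$seed), params = params),
                   class = "epi_environment")
  check_environment(env)
  env
}
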