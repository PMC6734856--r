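#' Analytic organ primitives
#'
#' The synthetic epidural-space environment is built from analytic collision
#' primitives (sphere, capsule, axis-aligned box) rather than meshes, so that
#' signed distances — and therefore collision decisions — are exact and
#' testable. Each primitive carries an anatomical kind and a label.
#'
#' @param kind one of `"bone"`, `"dura"`, `"disc"`, `"nerve"`.
#' @param shape one of `"sphere"`, `"capsule"`, `"box"`.
#' @param label free-text label (nerve primitives use `"S1"`..`"S4"`).
#' @param center sphere/box center, mm.
#' @param radius sphere/capsule radius, mm (strictly positive).
#' @param a,b capsule axis endpoints, mm.
#' @param half_extents box half extents, mm (strictly positive).
#' @return an object of class `organ_primitive`.
#' @export
organ_primitive <- function(kind, shape, label = kind,
                            center = NULL, radius = NULL,
                            a = NULL, b = NULL, half_extents = NULL) {
  kind <- match.arg(kind, c("bone", "dura", "disc", "nerve"))
  shape <- match.arg(shape, c("sphere", "capsule", "box"))
  row <- numeric(8)
  if (shape == "sphere") {
    stopifnot(length(center) == 3, length(radius) == 1)
    if (radius <= 0) stop("organ radius must be strictly positive")
    row <- c(1, center, 0, 0, 0, radius)
  } else if (shape == "capsule") {
    stopifnot(length(a) == 3, length(b) == 3, length(radius) == 1)
    if (radius <= 0) stop("organ radius must be strictly positive")
    row <- c(2, a, b, radius)
  } else {
    stopifnot(length(center) == 3, length(half_extents) == 3)
    if (any(half_extents <= 0)) stop("box half extents must be strictly positive")
    row <- c(3, center, half_extents, 0)
  }
  structure(list(kind = kind, shape = shape, label = label, row = row),
            class = "organ_primitive")
}

#' Signed distance from a point to an organ primitive
#'
#' Exact closed form per shape: negative inside the organ, positive outside,
#' zero on the surface. The signed distance is 1-Lipschitz, which collision
#' detection relies on.
#'
#' @param point a 3-vector or an n x 3 matrix of query points, mm.
#' @param organ an [organ_primitive()].
#' @return numeric vector of signed distances, mm.
#' @export
organ_distance <- function(point, organ) {
  if (!inherits(organ, "organ_primitive")) stop("organ must be an organ_primitive")
  if (!organ$shape %in% c("sphere", "capsule", "box"))
    stop("unsupported organ shape: ", organ$shape)
  pts <- as_point_matrix(point)
  cpp_organ_sdf(pts, organ$row)
}

#' Compile a list of organ primitives for fast batched queries
#'
#' @param organs list of [organ_primitive()] objects.
#' @return an `organ_set`: the 8-column parameter matrix with kind/label
#'   metadata attached.
#' @export
organ_set <- function(organs) {
  stopifnot(length(organs) > 0)
  mat <- do.call(rbind, lapply(organs, function(o) o$row))
  structure(mat,
            kinds = vapply(organs, function(o) o$kind, character(1)),
            labels = vapply(organs, function(o) o$label, character(1)),
            class = c("organ_set", "matrix"))
}

# minimum signed distance over a set; returns data.frame(distance, organ, label)
min_organ_distance <- function(point, oset) {
  pts <- as_point_matrix(point)
  res <- cpp_min_organ_sdf(pts, unclass(oset))
  data.frame(distance = res[, 1], organ = as.integer(res[, 2]),
             label = attr(oset, "labels")[as.integer(res[, 2])])
}
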