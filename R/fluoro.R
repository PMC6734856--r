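#' Orthographic fluoroscopy projection specification
#'
#' The survey-map view: an orthographic, C-arm-like projection of the scene
#' onto a raster. `"lateral"` views along +x (image plane z-y), the default
#' C-arm orientation here; `"anteroposterior"` views along +y (image plane
#' z-x). The canal axis (z) always maps to the image column dimension.
#'
#' @param view_axis `"lateral"` or `"anteroposterior"`.
#' @param pixel_spacing mm per pixel (> 0).
#' @param image_size `(width, height)` in pixels.
#' @param origin planar mm coordinates mapped to pixel `(row = 0, col = 0)`.
#' @return an object of class `projection_spec`.
#' @export
projection_spec <- function(view_axis = c("lateral", "anteroposterior"),
                            pixel_spacing = 0.5, image_size = c(512, 128),
                            origin = c(-10, -25)) {
  view_axis <- match.arg(view_axis)
  if (pixel_spacing <= 0) stop("pixel_spacing must be > 0")
  if (any(image_size < 1)) stop("image_size must be positive")
  structure(list(view_axis = view_axis, pixel_spacing = pixel_spacing,
                 image_size = as.integer(image_size), origin = as.numeric(origin)),
            class = "projection_spec")
}

# planar (u, v) mm coordinates: u along the canal axis (columns), v the
# retained transverse coordinate (rows)
to_planar <- function(p, spec) {
  p <- as_point_matrix(p)
  if (spec$view_axis == "lateral") cbind(p[, 3], p[, 2]) else cbind(p[, 3], p[, 1])
}

round_half_up <- function(x) floor(x + 0.5)

#' Project a 3D point to pixel coordinates
#'
#' Drops the view-axis coordinate, maps the remaining two through the origin
#' and pixel spacing, and rounds half-up. Pixel `(0, 0)` is the image corner
#' at `origin`; out-of-frame points give `NA` rows.
#'
#' @param p 3-vector or n x 3 matrix, mm.
#' @param spec a [projection_spec()].
#' @return n x 2 integer matrix of `(row, col)` (0-based).
#' @export
project_point <- function(p, spec) {
  uv <- to_planar(p, spec)
  col <- round_half_up((uv[, 1] - spec$origin[1]) / spec$pixel_spacing)
  row <- round_half_up((uv[, 2] - spec$origin[2]) / spec$pixel_spacing)
  w <- spec$image_size[1]; h <- spec$image_size[2]
  out <- cbind(row = as.integer(row), col = as.integer(col))
  bad <- row < 0 | row >= h | col < 0 | col >= w
  out[bad, ] <- NA_integer_
  out
}

# gray levels per organ kind; bone brightest, drawn last within organs
.fluoro_levels <- c(background = 16, dura = 96, nerve = 64, disc = 176,
                    bone = 255, centerline = 208, landmark = 240, tip = 230)

#' Render the fluoroscopic view
#'
#' Deterministic raster of organ silhouettes (kind-specific gray levels,
#' bone brightest), the scenario centerline, landmark markers and the
#' catheter tip marker. Identical inputs give identical bytes; the scene is
#' never mutated.
#'
#' @param env environment (organs, landmarks); may be `NULL` for an empty
#'   scene.
#' @param scenario optional scenario whose centerline is drawn.
#' @param state optional [catheter_state()] whose tip is drawn.
#' @param spec a [projection_spec()].
#' @return a `fluoro_image`: integer matrix (height x width) of intensities
#'   0-255 with the spec attached as attribute `spec`.
#' @export
render_fluoro <- function(env = NULL, scenario = NULL, state = NULL,
                          spec = projection_spec()) {
  w <- spec$image_size[1]; h <- spec$image_size[2]
  img <- matrix(.fluoro_levels[["background"]], nrow = h, ncol = w)
  u <- spec$origin[1] + (0:(w - 1)) * spec$pixel_spacing
  v <- spec$origin[2] + (0:(h - 1)) * spec$pixel_spacing
  U <- matrix(u, nrow = h, ncol = w, byrow = TRUE)
  V <- matrix(v, nrow = h, ncol = w)

  paint_organ <- function(img, organ, level) {
    r <- organ$row
    if (organ$shape == "sphere") {
      c2 <- to_planar(r[2:4], spec)
      hit <- (U - c2[1])^2 + (V - c2[2])^2 <= r[8]^2
    } else if (organ$shape == "capsule") {
      a2 <- to_planar(r[2:4], spec); b2 <- to_planar(r[5:7], spec)
      ab <- c(b2[1] - a2[1], b2[2] - a2[2])
      den <- sum(ab^2)
      t <- if (den == 0) matrix(0, h, w) else
        pmin(1, pmax(0, ((U - a2[1]) * ab[1] + (V - a2[2]) * ab[2]) / den))
      hit <- (U - (a2[1] + t * ab[1]))^2 + (V - (a2[2] + t * ab[2]))^2 <= r[8]^2
    } else {
      c2 <- to_planar(r[2:4], spec)
      he <- if (spec$view_axis == "lateral") c(r[7], r[6]) else c(r[7], r[5])
      hit <- abs(U - c2[1]) <= he[1] & abs(V - c2[2]) <= he[2]
    }
    img[hit] <- level
    img
  }

  if (!is.null(env)) {
    ord <- c("dura", "nerve", "disc", "bone")   # bone brightest, on top
    for (kind in ord)
      for (o in Filter(function(x) x$kind == kind, env$organs))
        img <- paint_organ(img, o, .fluoro_levels[[kind]])
  }
  if (!is.null(scenario) && nrow(scenario$centerline) >= 2) {
    L <- polyline_length(scenario$centerline)
    s <- seq(0, L, by = spec$pixel_spacing / 2)
    pts <- cpp_point_at_arclength(scenario$centerline, s)
    px <- project_point(pts, spec)
    px <- px[stats::complete.cases(px), , drop = FALSE]
    img[px + 1L] <- .fluoro_levels[["centerline"]]
  }
  if (!is.null(env)) {
    lm <- as.matrix(env$landmarks[, c("x", "y", "z")])
    px <- project_point(lm, spec)
    for (i in seq_len(nrow(px))) {
      if (anyNA(px[i, ])) next
      for (d in -2:2) {          # cross marker
        rr <- px[i, 1] + d; cc <- px[i, 2]
        if (rr >= 0 && rr < h) img[rr + 1L, cc + 1L] <- .fluoro_levels[["landmark"]]
        rr <- px[i, 1]; cc <- px[i, 2] + d
        if (cc >= 0 && cc < w) img[rr + 1L, cc + 1L] <- .fluoro_levels[["landmark"]]
      }
    }
  }
  if (!is.null(state)) {
    px <- project_point(state$tip, spec)
    if (!anyNA(px[1, ])) {
      rows <- pmax(0, pmin(h - 1, px[1, 1] + (-1:1)))
      cols <- pmax(0, pmin(w - 1, px[1, 2] + (-1:1)))
      img[rows + 1L, cols + 1L] <- .fluoro_levels[["tip"]]
    }
  }
  structure(img, spec = spec, class = c("fluoro_image", "matrix"))
}

#' Write / read an 8-bit binary PGM (P5) image
#'
#' Dependency-free, bit-exact image output for deterministic comparisons.
#'
#' @param img integer matrix of intensities 0-255 (height x width).
#' @param path file path.
#' @return `read_pgm` returns the integer matrix.
#' @export
write_pgm <- function(img, path) {
  img <- unclass(img)
  stopifnot(all(img >= 0), all(img <= 255))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(img), nrow(img)), con, eos = NULL)
  writeBin(as.raw(as.integer(t(img))), con)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  hdr <- character(0)
  while (length(hdr) < 4) {            # P5, width, height, maxval
    ch <- readChar(con, 1, useBytes = TRUE)
    tok <- ""
    while (!ch %in% c(" ", "\n", "\t", "\r")) {
      tok <- paste0(tok, ch)
      ch <- readChar(con, 1, useBytes = TRUE)
    }
    if (nzchar(tok)) hdr <- c(hdr, tok)
  }
  stopifnot(hdr[1] == "P5", hdr[4] == "255")
  w <- as.integer(hdr[2]); h <- as.integer(hdr[3])
  px <- as.integer(readBin(con, "raw", n = w * h))
  matrix(px, nrow = h, ncol = w, byrow = TRUE)
}
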