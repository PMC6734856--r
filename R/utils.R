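#' @useDynLib cathtrain, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif pf qf sd var optimize cor
#' @importFrom utils write.csv read.csv modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a base seed and a key
#'
#' Stable integer hash used to give every subject/repetition/session its own
#' RNG stream as a pure function of the global seed, so reordering or
#' extending a simulation never perturbs existing sessions. The result is
#' always in `[1, 2^31 - 2]`.
#'
#' @param base_seed integer base seed.
#' @param ... further components (strings or integers) identifying the stream.
#' @return a single integer seed.
#' @export
derive_seed <- function(base_seed, ...) {
  m <- 2147483629  # largest prime < 2^31
  h <- as.numeric(base_seed) %% m
  for (part in list(...)) {
    codes <- if (is.character(part)) utf8ToInt(paste(part, collapse = "|")) else as.numeric(part)
    for (v in codes) h <- (h * 31 + (v %% m) + 7) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# evaluate expr under a private RNG stream without disturbing the caller's
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# make a stateful RNG sampler: fn(expr) evaluates expr under its own
# persistent stream (used by agent controllers so sessions are reproducible
# and isolated from the global RNG)
make_rng_stream <- function(seed) {
  state <- NULL
  function(expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) outer <- get(".Random.seed", envir = globalenv())
    if (is.null(state)) set.seed(seed) else assign(".Random.seed", state, envir = globalenv())
    out <- expr
    state <<- get(".Random.seed", envir = globalenv())
    if (has) assign(".Random.seed", outer, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
    out
  }
}

as_point_matrix <- function(p) {
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 3)
    p
  } else {
    stopifnot(length(p) == 3)
    matrix(as.numeric(p), nrow = 1)
  }
}

vnorm <- function(v) sqrt(sum(v^2))

normalize <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize the zero vector")
  v / n
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}
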