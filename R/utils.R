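# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.clamp <- function(x, lo, hi) pmin.int(pmax.int(x, lo), hi)

# cubic smoothstep on [0, 1]
.smoothstep <- function(t) {
  t <- .clamp(t, 0, 1)
  t * t * (3 - 2 * t)
}

# coerce a length-3 vector or n x 3 matrix/data.frame to an n x 3 matrix
.as_points <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.null(dim(points))) {
    if (length(points) != 3L) stop("a point must have 3 coordinates")
    points <- matrix(points, nrow = 1L)
  }
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix")
  storage.mode(points) <- "double"
  points
}

.rownorm <- function(m) sqrt(rowSums(m * m))

# run code with a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
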