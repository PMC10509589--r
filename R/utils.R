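# Internal numerical helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Trapezoidal integral of a cycle-periodic series sampled at the N snapshot
# times of a TimeGrid (value(T) == value(0) convention): all samples carry
# equal weight dt = T/N.
periodic_integral <- function(values, grid) {
  dt <- grid$period / length(grid$times)
  if (is.matrix(values)) colSums(values) * dt else sum(values) * dt
}

# Time-average over one cycle under the periodic convention.
periodic_mean <- function(values) {
  if (is.matrix(values)) colMeans(values) else mean(values)
}

# Plain trapezoid on a possibly non-uniform, non-periodic grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Run expr with a fixed RNG state, restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Row-wise euclidean norms of an n x 3 matrix.
row_norms <- function(m) sqrt(rowSums(m * m))

# Row-wise cross product of two n x 3 matrices.
row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

stop_hp <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "haemopost_error")))
}
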