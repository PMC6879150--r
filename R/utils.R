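# Small numeric helpers shared across modules. All angles in the package are
# degrees, counter-clockwise from +x, with +y pointing up in the visual field.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap an angle to (-180, 180] degrees
#'
#' @param x numeric vector of angles in degrees.
#' @return angles mapped into the half-open interval (-180, 180].
#' @export
wrap180 <- function(x) {
  w <- x %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

#' Circular difference a - b in degrees, wrapped to (-180, 180]
#'
#' @param a,b numeric vectors of angles in degrees.
#' @return signed circular difference.
#' @export
circ_diff <- function(a, b) wrap180(a - b)

# log-spaced sequence
logspace <- function(from, to, length.out) {
  exp(seq(log(from), log(to), length.out = length.out))
}

# Run expr with a fixed RNG state, restoring the caller's state afterwards.
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

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}
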