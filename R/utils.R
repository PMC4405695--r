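#' @keywords internal
"_PACKAGE"

## Parameter validation helpers. Every generator and estimator rejects bad
## input with a message naming the offending field.

stop_field <- function(field, msg) {
  stop(sprintf("parameter '%s' %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, min = -Inf, strict_min = FALSE,
                         max = Inf, integer = FALSE) {
  if (length(x) != 1 || !is.numeric(x) || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (strict_min && x <= min)
    stop_field(field, sprintf("must be > %g", min))
  if (!strict_min && x < min)
    stop_field(field, sprintf("must be >= %g", min))
  if (x > max)
    stop_field(field, sprintf("must be <= %g", max))
  if (integer && x != round(x))
    stop_field(field, "must be an integer")
  invisible(x)
}

## Seeded evaluation that does not disturb the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Euclidean step lengths of an n x 2 position matrix.
step_lengths <- function(xy) {
  d <- diff(xy)
  sqrt(rowSums(d^2))
}

## Derive a child seed from a base seed and salts without integer overflow.
derive_seed <- function(seed, ...) {
  x <- as.numeric(seed) %% 2147483647
  for (s in c(...)) x <- (x * 69069 + as.numeric(s)) %% 2147483647
  as.integer(x)
}
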