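#' @keywords internal
"_PACKAGE"

## Angle helpers. Angles cross the package boundary in degrees (explicit
## *_deg names in serialized output); internal trigonometry uses radians.

deg2rad <- function(deg) deg * pi / 180

rad2deg <- function(rad) rad * 180 / pi

#' Wrap angles in degrees into [0, period)
#'
#' @param deg numeric vector of angles in degrees.
#' @param period wrap period in degrees (default 360).
#' @return angles wrapped into `[0, period)`.
#' @export
wrap_deg <- function(deg, period = 360) {
  out <- deg %% period
  # guard against -1e-15 %% 360 == 360 on some platforms
  out[out >= period] <- out[out >= period] - period
  out
}

## Wrap radians into (-pi, pi]
wrap_pi <- function(rad) {
  out <- (rad + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## Derive a stream-specific child seed from a master seed (kept < 2^31).
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 48271 + 7919 * stream) %% 2147483647
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
}
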