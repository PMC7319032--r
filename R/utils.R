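# Internal helpers shared across modules.

#' Wrap angles into (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped to the half-open interval (-180, 180].
#' @keywords internal
wrap180 <- function(x) {
  w <- x %% 360
  w[w > 180] <- w[w > 180] - 360
  # x %% 360 can return 360 - eps artifacts only for negative zero; keep 180 positive
  w[w == -180] <- 180
  w
}

# Signed circular difference a - b in (-180, 180].
circ_diff <- function(a, b) wrap180(a - b)

# Absolute circular distance in [0, 180].
circ_dist <- function(a, b) abs(circ_diff(a, b))

#' Derive a child seed from a global seed
#'
#' One global seed fans out to per-stage child seeds by fixed offsets so that
#' every stage draws from its own stream and recorded child seeds allow exact
#' replay of a single stage. Values stay below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage integer stage offset (each pipeline stage uses a fixed one).
#' @return an integer seed.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(stage))
  as.integer((as.double(seed) + 104729 * as.double(stage)) %% 2147483629 + 1)
}

#' Evaluate an expression under a local RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' seeded computations do not disturb surrounding randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
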