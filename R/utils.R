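#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed`, so seeded generators inside
#' the package never perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed
#'
#' Deterministic fan-out of one master seed into per-stage, per-case child
#' seeds, so adding cases or stages never perturbs earlier draws. The scheme
#' is `(seed * 100003 + stage * 1009 + index) mod (2^31 - 1)`.
#'
#' @param seed master integer seed.
#' @param stage integer stage identifier (each pipeline stage uses its own).
#' @param index integer case index within the stage.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, stage, index = 0L) {
  m <- 2147483647 # 2^31 - 1
  s <- (as.numeric(seed) %% m) * 100003 + as.numeric(stage) * 1009 +
    as.numeric(index)
  as.integer(s %% m)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

`%||%` <- function(a, b) if (is.null(a)) b else a
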