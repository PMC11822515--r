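#' Derive a stage seed from a global seed
#'
#' Stage seeds are a stable polynomial hash of the stage name folded into
#' the global seed, so adding a pipeline stage never shifts the random
#' streams of the others. The result is always a valid 32-bit seed.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1, keeps arithmetic exact in doubles
  h <- 0
  for (cc in utf8ToInt(stage)) h <- (h * 31 + cc) %% m
  as.integer((abs(seed) %% m + h) %% m)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded helpers do not perturb the
#' caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

abort_config <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
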