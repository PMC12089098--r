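#' Derive a per-stage seed from one global seed
#'
#' Every stage of a pipeline run draws its randomness from a seed derived
#' deterministically from the global run seed and the stage name, so stages
#' never share an RNG stream and reruns are reproducible.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name (e.g. `"encoding"`).
#' @return An integer seed strictly below `2^31`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) + h * 10007) %% .Machine$integer.max)
}

# Run an expression under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

abort_if <- function(cond, msg, class) {
  if (cond) stop(structure(class = c(class, "brainalign_error", "error", "condition"),
                           list(message = msg, call = sys.call(-1))))
  invisible(NULL)
}

assert_finite_matrix <- function(x, what = "data") {
  abort_if(!is.numeric(x), sprintf("%s must be numeric", what), "validation_error")
  abort_if(any(!is.finite(x)), sprintf("%s contains non-finite values", what),
           "validation_error")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
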