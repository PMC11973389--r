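#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores `.Random.seed` so that seeded helpers do not disturb the
#' caller's random stream. `seed = NULL` evaluates the expression as-is.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Fan a master seed out into stage-scoped seeds
#'
#' Deterministically derives one sub-seed per named stage so each pipeline
#' stage can be re-run in isolation with the same stream. Derived seeds are
#' kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param stages character vector of stage names.
#' @return named integer vector of seeds.
#' @export
fan_seeds <- function(seed, stages) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  out <- vapply(seq_along(stages), function(i) {
    x <- (as.double(seed) * 2654435761 + i * 40503) %% 2147483647
    as.integer(x)
  }, integer(1))
  names(out) <- stages
  out
}

# internal: consistent condition classes so callers can distinguish
# configuration errors from data/convergence errors
ubt_stop <- function(msg, class = "ubtnet_error", ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

config_error <- function(msg) ubt_stop(msg, class = c("ubtnet_config_error", "ubtnet_error"))
data_error   <- function(msg) ubt_stop(msg, class = c("ubtnet_data_error", "ubtnet_error"))

`%||%` <- function(a, b) if (is.null(a)) b else a
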