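#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the R random seed for the duration of `expr` and restores the
#' caller's RNG state afterwards, so library functions never perturb the
#' global random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
#' @examples
#' with_seed(1, rnorm(2))
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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

#' Derive a deterministic child seed from a global seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the run's
#' global seed and a stage label, so stages are reproducible independently
#' of each other and of evaluation order. The derived seed is kept inside
#' the 32-bit integer range.
#'
#' @param seed integer global seed.
#' @param stage character stage label (e.g. `"trials"`, `"observer"`).
#' @param index optional integer sub-index (e.g. a shuffle counter).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' child_seed(1, "trials")
child_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1, Lehmer modulus
  h <- (as.double(seed) %% m)
  for (code in c(utf8ToInt(stage), as.integer(index %% m))) {
    h <- (h * 48271 + code + 1) %% m
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("readoutbias_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_that <- function(ok, ...) if (!isTRUE(ok)) stop_config(...)

# signum with explicit handling of exact zero left to callers
sign_lr <- function(x) ifelse(x > 0, "right", ifelse(x < 0, "left", NA_character_))
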