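#' @keywords internal
"_PACKAGE"

#' Logistic task-to-task connectivity transform
#'
#' Maps an unconstrained coupling parameter beta to the connectivity
#' factor alpha = 1 / (1 + exp(-beta)), strictly inside (0, 1).
#'
#' @param beta Numeric vector or matrix of finite coupling parameters.
#' @return Values of the same shape as `beta`, strictly in (0, 1).
#' @examples
#' ttc_alpha(0)        # 0.5
#' ttc_alpha(log(3))   # 0.75
#' @export
ttc_alpha <- function(beta) {
  if (any(!is.finite(beta))) stop("beta must be finite", call. = FALSE)
  1 / (1 + exp(-beta))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# deterministic small-integer hash of a string, for per-task RNG streams
task_seed <- function(seed, task_id) {
  h <- 0L
  for (v in utf8ToInt(task_id)) h <- (h * 31L + v) %% 1000003L
  (as.integer(seed) %% 1000003L) * 1009L %% 2147483629L + h
}

# evaluate expr under a local RNG stream without disturbing the caller's
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

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
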