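#' @importFrom stats pnorm pchisq pt phyper sd var median quantile cor rnorm
#'   runif rexp rpois rbinom prcomp uniroot p.adjust setNames complete.cases
#' @importFrom utils head tail write.table read.table
NULL

# internal: stop with a consistent error class
abort <- function(msg, class = "ptmfuse_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert <- function(cond, msg) if (!isTRUE(cond)) abort(msg)

# run expr under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

is_count_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}
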