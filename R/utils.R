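# Classed conditions so callers can distinguish failure modes programmatically.
vm_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(paste0("vm_", class, "_error"), "vm_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded package internals
#' never disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    vm_stop("parameter", "seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from one master seed, all < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Two-decimal percentage reporting uses the conventional "half up" rule
#' rather than R's round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

check_flag <- function(x, what) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    vm_stop("parameter", "%s must be TRUE or FALSE", what)
  x
}

check_number <- function(x, what, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    vm_stop("parameter", "%s must be a single number", what)
  if (strict && x <= min) vm_stop("parameter", "%s must be > %g", what, min)
  if (!strict && x < min) vm_stop("parameter", "%s must be >= %g", what, min)
  x
}
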