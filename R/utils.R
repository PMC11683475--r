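`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Evaluate an expression under a fixed RNG seed
#'
#' Thin wrapper over [withr::with_seed()] so that every stochastic draw in
#' the package goes through one seeded entry point.
#' @param seed integer seed
#' @param code expression to evaluate
#' @keywords internal
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# smallest count c such that P(X >= c | Poisson(lambda)) < p
poisson_threshold_count <- function(lambda, p) {
  if (lambda <= 0) return(Inf)
  cc <- 0L
  while (ppois(cc - 1L, lambda, lower.tail = FALSE) >= p) cc <- cc + 1L
  cc
}
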