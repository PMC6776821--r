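.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Fixed-point rounding with halves rounded up, matching how percentages
#' are conventionally printed in registry descriptive tables (R's
#' `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# deterministic child seed derivation; keeps results within 32-bit range
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) + 1000003 * offset) %% 2147483647)
}

# seed the local RNG if a seed is supplied; restores caller RNG state
local_seed_if <- function(seed, envir = parent.frame()) {
  if (!is.null(seed)) withr::local_seed(as.integer(seed), .local_envir = envir)
  invisible(NULL)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == round(x)
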