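#' @keywords internal
#' @useDynLib vancopk, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Run an expression under a fixed RNG seed, restoring the caller's RNG state.
# Every stochastic operation in the package funnels through this so that it is
# a pure function of (inputs, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a stream of child seeds from a master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_na = FALSE) {
  if (allow_na && (is.null(x) || length(x) == 0 || all(is.na(x)))) {
    return(invisible(TRUE))
  }
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (strict_lower && x <= lower) {
    stop(sprintf("'%s' must be > %g (got %g)", name, lower, x), call. = FALSE)
  }
  if (!strict_lower && x < lower) {
    stop(sprintf("'%s' must be >= %g (got %g)", name, lower, x), call. = FALSE)
  }
  if (x > upper) {
    stop(sprintf("'%s' must be <= %g (got %g)", name, upper, x), call. = FALSE)
  }
  invisible(TRUE)
}

vlog <- function(verbose, fmt, ...) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}
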