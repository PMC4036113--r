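#' Derive a child seed from a parent seed
#'
#' All randomness in the package flows from a single user-supplied seed;
#' component seeds (ensemble members, k-means restarts, cross-validation
#' shuffles, constraint draws) are derived deterministically from it with a
#' Lehmer-style multiplicative step, so that any stochastic run is exactly
#' reproducible while the derived streams stay decoupled.
#'
#' @param seed integer parent seed.
#' @param ... one or more non-negative integer offsets (e.g. run index, fold
#'   index) distinguishing the child stream.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  offs <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (o in offs) {
    # 48271 is the MINSTD multiplier; exact in double precision here
    s <- (s * 48271 + as.double(o) + 1) %% 2147483647
  }
  as.integer(s %% 2147483645) + 1L
}

# stop() with sprintf formatting, no call in message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is_count(x) || x < min) {
    abort("`%s` must be a single integer >= %d (got %s)", name, min,
          paste(format(x), collapse = ","))
  }
  as.integer(x)
}
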