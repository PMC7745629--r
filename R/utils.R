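#' Round half away from zero
#'
#' Deterministic mm-to-pixel rounding used everywhere eccentricities are
#' converted to column indices. Base R `round()` rounds half to even, which
#' would make window placement depend on the parity of the nearest integer;
#' half-away-from-zero is symmetric about the fovea.
#'
#' @param x numeric vector.
#' @return integer vector, `sign(x) * floor(|x| + 0.5)`.
#' @export
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# Internal: stop with a classed condition so callers/tests can match on class.
rit_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "ritmap_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Derive a child seed from a base seed; keeps results < 2^31 and reproducible.
child_seed <- function(base_seed, offset) {
  (as.integer(base_seed) + as.integer(offset)) %% .Machine$integer.max
}

stopifnot_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    rit_stop("ritmap_config_error", "'%s' must be a finite scalar in [%s, %s]",
             name, format(lo), format(hi))
  }
  invisible(x)
}
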