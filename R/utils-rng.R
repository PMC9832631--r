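#' Deterministic substream seeds
#'
#' Derives a reproducible child seed from a master seed and one or two stream
#' indices.  The engine assigns substream `(i, 0)` to the parameter, BSV and
#' criteria draws of outer replicate `i`, and substream `(i, 1)` to that
#' replicate's subject-level random effects; with common random numbers off,
#' dose `d` uses substreams `(i, 2d)` and `(i, 2d + 1)`.  The mixing is a
#' double Lehmer step modulo 2^31 - 1, so all derived seeds stay within the
#' 32-bit integer range that `set.seed()` accepts.
#'
#' @param seed master seed (single finite number).
#' @param i primary stream index (outer replicate).
#' @param k secondary stream index within the replicate.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @examples
#' pops_substream(42, 1)
#' pops_substream(42, 1, 1)
#' @export
pops_substream <- function(seed, i, k = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647
  s <- as.double(seed) %% m
  s <- (s * 48271 + as.double(i)) %% m
  s <- (s * 48271 + as.double(k)) %% m
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assert_scalar_num <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stopf("'%s' must be a single finite number", name)
  if (strict && x <= lower) .stopf("'%s' must be > %g", name, lower)
  if (!strict && x < lower) .stopf("'%s' must be >= %g", name, lower)
  invisible(x)
}
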