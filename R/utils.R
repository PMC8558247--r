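#' @keywords internal
"_PACKAGE"

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# near-integer check for sample-count arithmetic (fs * seconds)
is_whole <- function(x, tol = 1e-8) abs(x - round(x)) < tol

#' Derive reproducible child seeds from one master seed
#'
#' All randomness in the package flows from a single integer seed; stages and
#' substreams (per-trial noise, fold shuffling, weight initialisation) each get
#' a deterministic child seed so that partial re-runs are reproducible.
#'
#' @param seed master integer seed.
#' @param n number of child seeds.
#' @return integer vector of `n` seeds, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  if (!is_count(n)) stopf("`n` must be a positive integer")
  if (!is_number(seed)) stopf("`seed` must be a single finite number")
  # LCG fan-out keeps every derived seed inside 32-bit integer range
  s <- as.double(seed) %% 2147483647
  out <- integer(n)
  for (i in seq_len(n)) {
    s <- (s * 48271 + 11) %% 2147483647
    out[i] <- as.integer(s) + 1L
  }
  out
}
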