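# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom rlang abort
wp_abort <- function(message, class = "whiskerpad_validation_error", ...) {
  rlang::abort(message, class = class, ...)
}

# Trapezoidal integral of y over x (x strictly increasing).
trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
}

# Periodic Hann window of length n.
hann <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)
}

# Run code under a seed without disturbing the caller's RNG state; seed = NULL
# leaves the RNG stream alone.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Derive a per-component seed from a master seed; kept strictly below 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 9973) %% 2147483629) + 1L
}

# Centered moving average with shrinking edge windows.
moving_average <- function(x, n) {
  if (n <= 1L) return(x)
  as.numeric(data.table::frollmean(x, n, align = "center", algo = "exact",
                                   adaptive = FALSE, fill = NA)) -> y
  # fall back to the raw value where the full window does not fit
  y[is.na(y)] <- x[is.na(y)]
  y
}
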