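#' @keywords internal
#' @importFrom withr with_seed
"_PACKAGE"

# Round half away from zero, as clinical tables are conventionally printed
# (base round() is half-to-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

geom_mean <- function(x) {
  stopifnot(all(x > 0))
  exp(mean(log(x)))
}

# Run `expr` under an explicit seed without disturbing the caller's RNG
# state; a NULL seed uses (and advances) the current stream.
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}
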