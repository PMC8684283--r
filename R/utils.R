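# Internal helpers shared across modules.

# Round half away from zero (so 0.5 -> 1, -0.5 -> -1). Used wherever integer
# summaries are reported; base round() would apply banker's rounding instead.
roundHalfAwayFromZero <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Smallest integer count x such that x / n >= threshold, robust to the
# representation of threshold * n (e.g. 0.95 * 20 must give 19, not 20).
.minCountAtOrAbove <- function(threshold, n) {
  as.integer(ceiling(threshold * n - 1e-9))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.msgf <- function(fmt, ...) message(sprintf(fmt, ...))
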