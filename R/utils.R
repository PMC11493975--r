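# Internal helpers shared across modules.

# Run expr under a fixed seed without disturbing the caller's RNG state;
# seed = NULL runs expr as-is.
maybe_with_seed <- function(seed, expr) {
  if (is.null(seed)) expr
  else withr::with_seed(as.integer(seed), expr)
}

logit <- function(p) log(p / (1 - p))

inv_logit <- function(x) 1 / (1 + exp(-x))

# Comparison tolerant to floating representation of thresholds like 0.8.
.geq <- function(x, cutoff, eps = 1e-9) x >= cutoff - eps
.leq <- function(x, cutoff, eps = 1e-9) x <= cutoff + eps
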