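# Small shared helpers.

# Deterministic fan-out of one user seed into independent per-stage seeds,
# kept below 2^31 so they remain valid R integers.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

logistic <- function(x) 1 / (1 + exp(-x))
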