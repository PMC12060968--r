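# Seed derivation. Random draws are purpose-keyed: each consumer of
# randomness (sequence generation, planted signal, site sampling, noise,
# splits, fine-tuning) derives its own stream from the user seed, so
# changing one knob never reshuffles unrelated draws.

stream_seed <- function(seed, purpose) {
  stopifnot(length(seed) == 1, is.finite(seed))
  h <- sum(utf8ToInt(purpose) * seq_len(nchar(purpose)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629)
}
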