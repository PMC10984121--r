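# Deterministic seed lineage: every stochastic stage derives its own seed
# from the master seed plus a label path, so any repetition/series can be
# regenerated in isolation. Linear-congruential fold, kept < 2^31.
derive_seed <- function(master, ...) {
  h <- as.numeric(master) %% 2147483647
  for (p in list(...)) {
    v <- if (is.character(p)) {
      u <- utf8ToInt(p)
      sum(u * seq_along(u))
    } else {
      as.numeric(p)
    }
    h <- (h * 48271 + v * 101 + 7) %% 2147483647
  }
  as.integer(h)
}
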