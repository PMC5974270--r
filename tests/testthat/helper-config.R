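# Small, fast study configurations used across the suite. The generator
# defaults (1 kHz, 8 channels, 30 trials/class) are exercised in the
# acceptance tests; unit tests run the same model at reduced sampling rate
# and channel/unit counts to keep the suite quick.
fast_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_trials_per_class = 15, channels = 4, fs = 250,
                   n_units = 4)
  do.call(synth_config, utils::modifyList(defaults, args))
}

# All ERS gains at their null value (1: no stimulus-locked power change) and
# no spike-rate modulation -> labels carry no information.
null_gain <- function() {
  g <- default_ers_gain()
  g[, ] <- 1
  g
}

null_cfg <- function(...) {
  fast_cfg(ers_gain = null_gain(), modulated_rate_gain = 1, ...)
}

make_fast_session <- function(seed = 1, pair = c("NS", "HS"),
                              condition = "naive", cfg = fast_cfg(), ...) {
  make_session(cfg, pair, condition, seed = seed)
}
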