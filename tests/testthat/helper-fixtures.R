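# shared fixture builders for detection tests

# noise-free trace with inward biexponential events at known onsets
make_event_trace <- function(onsets_s, amps_pa, duration_s = 2, fs = 10000,
                             tau_rise = 0.5, tau_decay = 5, noise_sd = 0,
                             seed = 1) {
  n <- round(duration_s * fs)
  x <- if (noise_sd > 0) striatools:::with_seed(seed, rnorm(n, 0, noise_sd)) else numeric(n)
  kt <- (seq_len(round(0.08 * fs)) - 1) / fs
  kern <- psc_kernel(kt, tau_rise, tau_decay)
  for (i in seq_along(onsets_s)) {
    i0 <- floor(onsets_s[i] * fs) + 1L
    idx <- i0:min(n, i0 + length(kern) - 1L)
    x[idx] <- x[idx] - amps_pa[i] * kern[seq_along(idx)]
  }
  trace(x, fs, units = "pA")
}
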