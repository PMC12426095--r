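# Shared fixtures, all generated in code.

sinusoid_trial <- function(freq = 1.33, duration = 40, rate = 50,
                           amplitude = 1, phase = 0, ...) {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  movement_trial(amplitude * sin(2 * pi * freq * t + phase), rate, ...)
}

# naive O(n^2) recurrence-count oracle: per-pair distances, no matrix algebra
brute_recurrence_count <- function(a, b, radius) {
  count <- 0L
  for (i in seq_len(nrow(a))) {
    d <- sqrt(rowSums((b - matrix(a[i, ], nrow(b), ncol(b), byrow = TRUE))^2))
    count <- count + sum(d <= radius)
  }
  count
}

# small dyad trial with head channels, preprocessed
make_preprocessed_dyad <- function(arm_k = 1, head_k = 1, seed = 42,
                                   phase_noise_sd = 0.3) {
  ps <- oscillator_params(4 / 3 + 0.05, coupling_strength = arm_k,
                          phase_noise_sd = phase_noise_sd)
  pp <- oscillator_params(4 / 3)
  tr <- generate_dyad_trial(ps, pp, 45, 50, seed = seed)
  tr <- generate_head_channel(tr, head_k, seed = seed + 1)
  preprocess_dyad(tr)
}
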