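# Shared fixtures: tiny graphs, quick simulation configs, and raw
# constructors for phase tensors / label vectors so connectivity internals
# can be fed controlled inputs.

tiny_graph <- function(spec, n, labels = letters[seq_len(n)]) {
  W <- matrix(0, n, n, dimnames = list(labels, labels))
  for (e in spec) W[e[1], e[2]] <- W[e[2], e[1]] <- e[3]
  W
}

triangle_half <- function() tiny_graph(list(c(1, 2, .5), c(1, 3, .5),
                                            c(2, 3, .5)), 3)

unit_star <- function() tiny_graph(list(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1)), 4)

make_phase_tensor <- function(phase, rate = 250,
                              labels = sprintf("ch%02d", nrow(phase))) {
  structure(list(phase = phase,
                 valid = matrix(TRUE, nrow(phase), ncol(phase)),
                 rate = rate,
                 labels = sprintf("ch%02d", seq_len(nrow(phase))),
                 band = NULL),
            class = "phase_tensor")
}

make_labels <- function(labels, k, rate = 250) {
  structure(list(labels = as.integer(labels), k = as.integer(k),
                 rate = rate), class = "label_vector")
}

# A clean low-noise recording driven by 4 planted templates.
quick_ms_config <- function(seed, duration = 60) {
  sim_config(n_subjects = 4, duration = duration, ms_amp = 10,
             bg_amp = 0.2, noise_sd = 0.3, seed = seed)
}

# A sinusoidal multichannel recording (every channel identical frequency,
# configurable per-channel phase offsets and amplitudes).
sine_recording <- function(freq, duration = 20, rate = 250,
                           phases = 0, amps = 1) {
  t <- seq_len(round(duration * rate)) / rate
  data <- t(mapply(function(ph, a) a * cos(2 * pi * freq * t + ph),
                   phases, amps))
  eeg_recording(data, rate, sprintf("s%02d", seq_along(phases)))
}
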