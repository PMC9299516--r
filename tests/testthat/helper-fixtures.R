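# Shared fixtures, all generated in code.

# A flat trace matrix at a constant value (frame times as column names).
flat_traces <- function(n_cells = 1, value = 100, duration = 45,
                        frame_rate = 2) {
  t <- (seq_len(round(duration * frame_rate)) - 1) / frame_rate
  m <- matrix(value, n_cells, length(t),
              dimnames = list(sprintf("cell_%03d", seq_len(n_cells)),
                              format(t)))
  m
}

default_protocol <- function() stimulation_protocol(c(A = 10), duration = 45)

double_protocol <- function() stimulation_protocol(c(A = 10, B = 27),
                                                   duration = 45)

# Small noise- and bleach-free well with known responders (both overridable).
quiet_well <- function(n_cells = 30, seed = 1, probs = NULL, noise_sd = 0,
                       bleach_rate = 0, ...) {
  if (is.null(probs)) {
    probs <- c(none = 0.25, A_only = 0.40, B_only = 0.10, both = 0.25)
  }
  simulate_well(sim_well_config(n_cells = n_cells, noise_sd = noise_sd,
                                bleach_rate = bleach_rate,
                                class_probabilities = probs,
                                seed = seed, ...))
}
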