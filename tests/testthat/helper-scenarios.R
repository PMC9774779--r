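# Shared builders for short test scenarios.

quick_config <- function(presentation = "parallel",
                         dilution_mode = "fixed_count", n_cycles = 3, ...) {
  protocol_config(presentation = presentation, dilution_mode = dilution_mode,
                  n_cycles = n_cycles, ...)
}

asym_params <- function(gen = c(17, 17), r = 0.3) {
  kinetic_params(burst_A = 20, burst_B = 10, burst_AB = gen, r = r)
}

# relative difference, guarding the zero-zero case
rel_diff <- function(a, b) {
  d <- abs(a - b)
  s <- pmax(abs(a), abs(b))
  ifelse(s == 0, 0, d / s)
}
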