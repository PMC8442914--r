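# Headline parameter set used across tests: CCI territory at A = 13, K = 0.9.
mp_default <- function(...) model_params(...)
cp_auto <- function(C = 0, ...) control_params(C = C, alpha = 0, ...)
sc_short <- function(...) sim_config(n_transient = 500, n_samples = 4000,
                                     n_trials = 3, seed = 42, ...)

# Independent scalar reference loop for the uncontrolled map (oracle for
# iterate() in the degenerate C = 0, alpha = 0, D = 0 case).
ref_pure_map <- function(x0, mp, n_transient, n_samples) {
  x <- x0
  for (i in seq_len(n_transient)) x <- mp$K * (mp$B * tanh(mp$w2 * x) - mp$A * tanh(mp$w1 * x))
  out <- numeric(n_samples)
  for (i in seq_len(n_samples)) {
    out[i] <- x
    x <- mp$K * (mp$B * tanh(mp$w2 * x) - mp$A * tanh(mp$w1 * x))
  }
  out
}
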