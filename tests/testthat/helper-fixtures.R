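# Randomized parameter/state draws for property-style tests. Ranges span the
# physically sensible region: populations up to ~10 K, rates within a few
# orders of magnitude of the growth rate.

random_single_params <- function() {
  single_spacer_params(
    f0 = runif(1, 0.5, 2), r = runif(1, 0.5, 2),
    K = 10^runif(1, 3, 6), kappa = 10^runif(1, -4, -1),
    g = 10^runif(1, -6, -3), eta = runif(1), alpha = runif(1, 0, 0.5),
    mu = runif(1, 0.5, 2), b = runif(1, 1, 200),
    dilution = sample(c(0, 10^runif(1, -4, -2)), 1),
    phage_decay = sample(c(0, 10^runif(1, -4, -2)), 1))
}

random_single_state <- function(K = 1e5) {
  single_state(n0 = 10^runif(1, 0, log10(K)), n1 = 10^runif(1, 0, log10(K)),
               I0 = 10^runif(1, 0, 3), I1 = 10^runif(1, 0, 3),
               v = 10^runif(1, 0, 6))
}

random_multi_params <- function(N = sample(2:6, 1)) {
  a <- runif(N)
  multi_spacer_params(
    f = runif(1, 0.5, 2), K = 10^runif(1, 3, 6),
    kappa = 10^runif(1, -4, -1), g = 10^runif(1, -6, -3),
    mu = runif(1, 0.5, 2), b = runif(1, 1, 200),
    alpha_vec = a / sum(a) * runif(1, 0.01, 0.9),
    eta_vec = runif(N),
    dilution = sample(c(0, 10^runif(1, -4, -2)), 1),
    phage_decay = sample(c(0, 10^runif(1, -4, -2)), 1))
}

random_multi_state <- function(N, K = 1e5) {
  multi_state(n0 = 10^runif(1, 0, log10(K)),
              n_vec = 10^runif(N, 0, log10(K)),
              I0 = 10^runif(1, 0, 3), I_vec = 10^runif(N, 0, 3),
              v = 10^runif(1, 0, 6))
}

# relative agreement scaled for heavy cancellation: |a - b| against the
# magnitude of the summed terms
rel_cancel <- function(a, b, scale) {
  abs(a - b) / max(1, scale)
}
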