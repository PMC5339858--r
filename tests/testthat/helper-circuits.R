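# Shared parameter sets for the canonical circuits.

# fully decoupled: three independent birth-death transcripts + translation
params_decoupled <- function(...) {
  update_params(cerna_params(kplus_T = 0, kplus_C = 0), ...)
}

# single birth-death species: only the target transcribes and decays
params_birth_death <- function(b = 10, d = 0.1) {
  cerna_params(b_T = b, d_T = d, b_C = 0, beta = 0, kplus_T = 0, kplus_C = 0,
               alpha_T = 0, alpha_C = 0)
}

# two-stage expression: unregulated mRNA -> protein for the target only
params_two_stage <- function() {
  cerna_params(b_T = 15, b_C = 0, beta = 0, kplus_T = 0, kplus_C = 0,
               alpha_C = 0)
}

# baseline ceRNA circuit (defaults) and miRNA-only variant
params_cerna <- function(...) update_params(cerna_params(), ...)
params_mirna_only <- function(...) update_params(cerna_params(kplus_C = 0), ...)

# protein-protein interaction module switched on (complex formation rates)
ppi_on <- list(kP_plus = 0.002, kP_minus = 0.001, deltap_P = 0.1)

# count strict interior local maxima of a numeric vector
n_local_maxima <- function(x) sum(diff(sign(diff(x))) == -2)
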