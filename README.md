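# cernanoise

Stochastic modelling of miRNA-mediated ceRNA crosstalk and its
consequences for protein expression noise.

## The problem

MicroRNAs repress their target transcripts, but every transcript carrying a
binding site also *sequesters* the miRNA. Transcripts sharing a regulator
therefore compete for it and acquire an effective positive coupling — the
competing-endogenous-RNA (ceRNA) effect. This package asks what that
competition does one level downstream, at the proteins: does a competitor
stabilize or destabilize a target protein's copy-number fluctuations, how
does catalytic complex processing (miRNA recycling) change the picture, how
do the correlations of two interacting proteins respond, and how precisely
can a transcription rate tune a protein or protein-complex level through
such a channel? It is aimed at systems-biology researchers studying
post-transcriptional regulation and gene-expression noise.

## The model

One miRNA (μ), two ceRNAs (a target m_T with tunable transcription rate
b_T, and a competitor m_C), their miRNA-bound complexes c_T and c_C, two
proteins p_T and p_C, and an optional binary protein complex C_p — 21
elementary mass-action reactions in total. Complexes decay either
stoichiometrically (both molecules lost, rate σ_i) or catalytically (the
miRNA is recycled, rate κ_i). Three computational routes are built on the
network:

* **Exact stochastic simulation** — direct-method Gillespie algorithm
  (compiled core), with stationary moments, CVs and Pearson correlations
  estimated from time averages with autocorrelation-corrected errors.
* **Linear Noise Approximation** — deterministic steady states by damped
  Newton, fluctuation covariance Σ from the stationary Lyapunov equation
  A·Σ + Σ·Aᵀ + Γ = 0 with A the mass-action Jacobian and
  Γ = Σ_r a_r s_r s_rᵀ.
* **Information channel analysis** — derepression size
  Δ_C = max m̄_C − min m̄_C over the input range, and channel capacity
  I_max(b_T → O) under the Small Noise Approximation: optimal input density
  P_opt(b) ∝ |dŌ/db|/σ_O(b), capacity estimated from the sampled joint
  histogram (Miller–Madow corrected) with the closed form
  log₂[∫ |dŌ/db|/(σ_O √(2πe)) db] as a diagnostic.

`run_scenario()` packages the five canonical analyses (crossover and CV
curves, circuit comparison with capacity and derepression sweeps, miRNA
recycling, Pearson sign reversal of interacting proteins, complex-channel
capacity maps); a thin command-line wrapper lives in `inst/cli/`.

## Worked example

```r
library(cernanoise)

p <- cerna_params()        # baseline rates; b_T = 15, competitor coupled
s <- lna_summary(p)        # deterministic steady state + LNA moments
round(s$steady$state, 2)
#>    m_T    m_C     mu    c_T    c_C    p_T    p_C    C_p
#>  29.05  29.05   8.34  12.08  12.08 145.24 145.24   0.00
round(s$lna$cv, 3)
#>   m_T   m_C    mu   c_T   c_C   p_T   p_C
#> 0.294 0.294 0.427 0.282 0.282 0.210 0.210

net <- build_network(p)
tr <- simulate_ssa(net, t_end = 1500, seed = 1)   # exact Gillespie run
sm <- stationary_summary(tr, burn_in = 500)
round(sm$mean, 1)
#>   m_T   m_C    mu   c_T   c_C   p_T   p_C   C_p
#>  29.0  29.7   8.7  12.0  12.1 145.6 150.9   0.0
round(sm$pearson["m_T", "m_C"], 2)
#> [1] 0.69
```

At b_T = 15 the circuit sits in the *susceptible* regime: the free miRNA
pool is almost fully titrated (8 molecules free out of a 250-molecule
unbound capacity), transcripts and miRNA are near-equimolar, and the two
transcripts are strongly positively correlated (ρ ≈ 0.7) although neither
regulates the other — the signature of miRNA-mediated crosstalk. The
protein CV (0.21) sits well above the Poisson-limit 1/√145 ≈ 0.08,
reflecting the noise that miRNA regulation adds near the crossover; the
LNA (line 1) and the simulation (line 3) agree on the means to within
sampling error.

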