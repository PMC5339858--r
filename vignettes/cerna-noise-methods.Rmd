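---
title: "Modelling miRNA-mediated ceRNA crosstalk and protein expression noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling miRNA-mediated ceRNA crosstalk and protein expression noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernanoise)
```

## The model

A single microRNA species ($\mu$) post-transcriptionally represses two
coding transcripts that therefore compete for it: a *target* ceRNA
($m_T$) whose transcription rate $b_T$ is the tunable input of every
analysis in this package, and a *competitor* ceRNA ($m_C$) transcribed at a
fixed rate. The miRNA binds either transcript reversibly, forming the
complexes $c_T$ and $c_C$. A bound complex is processed through two
channels:

* **stoichiometric decay** (rate $\sigma_i$): the complex is degraded and
  *both* molecules are lost;
* **catalytic decay** (rate $\kappa_i$): the transcript is cleaved and the
  miRNA returns intact to the free pool ("miRNA recycling").

Free transcripts are translated into proteins $p_T$ and $p_C$, which decay
spontaneously and can additionally associate into a binary complex $C_p$
(a protein--protein interaction, PPI, module that is switched off by
default). All 21 reactions are elementary mass action; there are no Hill or
Michaelis--Menten lumped steps, no transcriptional feedback, and no bursty
transcription. Species are ordered $(m_T, m_C, \mu, c_T, c_C, p_T, p_C,
C_p)$ in every matrix and serialized output.

Because the miRNA is a shared, consumable resource, raising $b_T$ titrates
it away from the competitor: the two transcripts acquire an effective
*positive* coupling (the ceRNA effect) even though each is only negatively
regulated. The package quantifies the consequences of that coupling for
protein noise, protein--protein correlations, and the fidelity of the
$b_T \to$ output regulatory channel.

## Parameters

Defaults follow the baseline used throughout the scenario analyses
(units: molecules/min for synthesis, 1/min for first-order rates,
1/(molecule min) for bimolecular rates):

| parameter | meaning | default |
|---|---|---|
| `b_T` | target transcription (input) | swept over `[0, 60]` |
| `b_C` | competitor transcription | 15 |
| `beta` | miRNA transcription | 25 |
| `d_T`, `d_C`, `delta` | free RNA decay | 0.1 |
| `kplus_T`, `kplus_C` | miRNA--ceRNA association | 0.05 |
| `kminus_T`, `kminus_C` | complex dissociation | 0.001 |
| `sigma_T`, `sigma_C` | stoichiometric complex decay | 1 |
| `kappa_T`, `kappa_C` | catalytic complex decay | 0.001 |
| `alpha_T`, `alpha_C` | translation per mRNA | 0.5 |
| `deltap_T`, `deltap_C` | protein decay | 0.1 |
| `kP_plus`, `kP_minus`, `deltap_P` | PPI module | 0 (off); 0.002 / 0.001 / 0.1 when on |

With these rates the complex is processed almost exclusively through the
stoichiometric channel ($\sigma \gg \kappa, k^-$), so miRNA molecules are
consumed when they act, and the free-miRNA supply flux $\beta$ caps the
total transcript flux that regulation can absorb.

**Choice of the binding strengths.** The association rates are the one
genuinely open knob of the model: the analyses require only that the
target's crossover from the repressed to the free regime falls inside the
input window $b_T \in [0, 60]$, and sensitivity to them is why scenario
functions expose them as configuration. We fix
`kplus_T = kplus_C = 0.05` /molecule/min once, by the equimolarity
heuristic: the crossover sits where the target's transcription flux matches
the miRNA flux left over for it ($b_T^\ast \approx \beta = 25$ for the
miRNA-only circuit, $b_T^\ast \approx \beta - b_C \approx 10$ once the
competitor takes its share), and binding at the crossover is fast compared
with free-transcript decay ($k^+ \bar\mu \gg d_T$), which makes the
threshold sharp. These are package choices, not literature measurements.
The `fig2` scenario additionally sweeps `kplus_T` over
$\{0.002, 0.01, 0.05, 0.25\}$ to show how the crossover sharpens with
binding strength.

## Stochastic simulation

`simulate_ssa()` implements the exact direct-method Gillespie algorithm in
compiled code: the time to the next event is exponential in the total
propensity, the reaction is drawn proportionally to its propensity, and the
state jumps by the reaction's stoichiometric vector. Copy numbers here stay
below a few thousand, so exact simulation is affordable and no tau-leaping
approximation is provided. The state is recorded on an equally spaced grid
(sample-and-hold, default 1 min). R's own RNG drives the kernel, so a
`seed` fully determines a trajectory.

Stationary moments come from a single long trajectory (ergodic
time-averaging, which is also what the analytical treatment assumes), with:

* **burn-in** 500 min by default — 50 times the slowest decay timescale
  (all decay rates are $\ge 0.1$/min), started from the deterministic
  steady state rounded to integers so the transient is short;
* **standard errors** from non-overlapping batch means (30 batches), which
  absorb the sample autocorrelation; the implied effective sample size is
  reported per species;
* CVs of species with zero mean flagged undefined rather than infinite,
  and Pearson coefficients of zero-variance species reported as `NA`.

## Linear Noise Approximation

`solve_steady_state()` finds the fixed point of the macroscopic rate
equations by damped Newton iteration with the closed-form mass-action
Jacobian, warm-started along $b_T$ sweeps; if Newton stalls it first
relaxes the system by stiff ODE integration (`deSolve::lsoda`) and then
polishes. Species untouched by any nonzero-rate reaction (e.g. $C_p$ with
the PPI off) are excluded, which keeps the Jacobian invertible.

Fluctuations around a stable steady state are Gaussian at leading order,
with covariance $\Sigma$ solving the stationary Lyapunov equation
$A\Sigma + \Sigma A^\top + \Gamma = 0$, where $A$ is the Jacobian and
$\Gamma = \sum_r a_r \, s_r s_r^\top$ is the propensity-weighted sum of
stoichiometric outer products. We solve it through the Kronecker-product
linear system, which is robust when eigenvalues of $A$ nearly coincide; the
textbook eigen-decomposition form is implemented separately
(`lna_covariance_eigen()`) and used as a cross-check in the test suite. CVs
and Pearson coefficients derive from $\Sigma$; a species with mean below
$10^{-9}$ gets an undefined CV rather than an infinite one.

## Derepression size and channel capacity

The **derepression size** $\Delta_C$ is the spread
$\max \bar m_C - \min \bar m_C$ of the competitor's stationary mean as the
input $b_T$ runs over its full range: a direct, model-free readout of how
strongly the ceRNA effect couples the two transcripts. It vanishes when the
competitor is uncoupled and peaks at intermediate competitor binding
strength — too weak and the competitor ignores the miRNA, too strong and it
is saturated regardless of $b_T$.

The **channel capacity** $I_{\max}$ of the map from $b_T$ to an output
observable $O$ (the target protein, or the protein complex) is computed
under the Small Noise Approximation, in four steps:

1. measure the response curve $\bar O(b_T) \pm \sigma_O(b_T)$ over the
   input grid (SSA or LNA);
2. form the small-noise optimal input density
   $P_{\mathrm{opt}}(b) \propto |\mathrm{d}\bar O/\mathrm{d}b| /
   \sigma_O(b)$. The derivative is taken from a smoothing-spline fit
   (smoothing chosen by generalized cross-validation, overridable via
   `spar`) because SSA means carry sampling noise;
3. draw inputs from $P_{\mathrm{opt}}$ and outputs from the Gaussian
   conditional $N(\bar O(b), \sigma_O(b)^2)$ — exactly the channel the SNA
   optimizes; re-simulating one trajectory per Monte-Carlo draw would add
   nothing under that approximation while costing orders of magnitude more;
4. estimate the mutual information of the sampled pairs on an equal-width
   2-D histogram (default $30 \times 30$ bins) with the Miller--Madow
   bias correction. This histogram estimate is the headline value; the
   closed form $\log_2\!\big[\int |\mathrm{d}\bar O/\mathrm{d}b| /
   (\sigma_O \sqrt{2\pi e})\, \mathrm{d}b\big]$ is reported alongside as a
   consistency diagnostic, and a disagreement between the two flags a
   breakdown of the small-noise assumption (typically at very strong
   binding, where the response develops a sharp threshold).

A zero-molecule boundary point ($\bar O = \sigma_O = 0$, e.g. $b_T = 0$
with no other source) carries no information and is excluded from the
density; zero noise at a point with actual gain is an error, since the SNA
capacity would be infinite. For the complex-channel capacity map the output
histogram window is frozen at the range realized at the reference binding
strengths (`kplus_T = kplus_C = 0.05`), so capacities at different
$(k^+_T, k^+_C)$ are comparable on a common output window.

**A flux bound worth knowing about.** Because the competitor's transcription
flux ($b_C = 15$) is smaller than the miRNA's ($\beta = 25$), even an
infinitely strong competitor binding rate can divert at most
$b_C\,\sigma_C/(\sigma_C + \kappa_C + k^-_C) \approx 15$ molecules/min of
miRNA flux: the large-`kplus_C` limit of the target channel remains
partially repressed (residual miRNA flux $\approx 10$ molecules/min) and
does *not* converge to a post-transcriptionally unregulated channel. This
is a structural property of the baseline fluxes, not of the binding
strengths.

**Population scales.** The same flux accounting fixes the attainable copy
numbers: transcripts and miRNA stay within a few hundred molecules across
the whole input window, while the proteins amplify their transcript
five-fold ($\alpha/\delta_p = 5$), so the target protein exceeds $10^3$
molecules at the upper end of the input range ($\bar p_T \ge 5\,(b_T -
\beta)/d_T = 1750$ at $b_T = 60$ even under maximal stoichiometric
repression). A design bound of $10^3$ molecules can therefore hold for the
RNA species only.

## Recycling comparison protocol

`recycling_noise_reduction()` quantifies the noise benefit of catalytic
processing at the target node: CV-vs-mean curves of $p_T$ are measured at
slow ($\kappa_T = 0.001$/min) and fast ($\kappa_T = 7$/min) catalytic
decay, the slow curve's CV is interpolated onto the fast curve's means
inside the overlapping mean range (means increase monotonically with
$b_T$), and the maximal value of $100\,(\mathrm{CV}_{\mathrm{slow}} -
\mathrm{CV}_{\mathrm{fast}})/\mathrm{CV}_{\mathrm{slow}}$ is reported.
Means below one molecule are excluded from the matching window — CVs
diverge as $1/\sqrt{\bar p}$ there and the comparison would be dominated by
the empty-cell corner. With fast recycling the miRNA is barely consumed, so
the free-miRNA pool stays high and the fast curve spans a much smaller mean
range than the slow one; the matched-mean window is set by the overlap.

The stochastic protocol used by the acceptance script and tests is an
11-point $b_T$ grid on $[0, 60]$, 5 independent seeds per grid point
(curves averaged across seeds), 7000 min per trajectory with 500 min
burn-in and 1-min sampling; the trajectory length is set so that the
maximum-over-the-grid statistic is not inflated by per-point sampling
noise. These problem sizes are the package's
standing choices for a laptop-scale run; doubling them changes the
reported reductions by less than the seed-to-seed spread.

## What the generator does and does not emulate

The Gillespie engine *is* the data generator of every analysis: all
statistics consume its stationary trajectories (or their LNA
approximation). It faithfully reproduces intrinsic copy-number noise of the
mass-action network — molecular discreteness, titration thresholds,
binding-driven correlations. It does **not** emulate transcriptional
bursting, extrinsic (cell-to-cell) parameter variability, cell division
and dilution, spatial effects, or networks larger than one miRNA and two
ceRNAs. Conclusions validated here therefore speak to the competition
mechanism in isolation; in real cells the effects documented by these
analyses sit on top of extrinsic noise floors that the model deliberately
omits, and observed protein CVs will generally be larger than the intrinsic
values computed here.

## Numerical choices and edge cases

* Newton tolerance $10^{-9}$ molecules/min on the drift residual;
  Lyapunov residual checked against $10^{-8}\,\lVert\Gamma\rVert$.
* SSA copy numbers are carried exactly; exceeding $2^{31}-1$ molecules
  aborts with an overflow error rather than wrapping.
* A trajectory whose total propensity hits zero freezes at its current
  state until the end time — a valid absorbing outcome, not an error.
* Histogram MI bins default to $30 \times 30$; the Miller--Madow
  correction uses occupied-bin counts. Capacity estimates are reproducible
  given (`seed`, curve) and the scenario runner offsets seeds per grid
  point and replicate, so no two stochastic stages share a stream.
* `fig6` capacity maps use a $5 \times 5$ logarithmic grid of binding
  strengths by default; the reference output window is widened by
  $\pm 3$ SD of the reference curve before reuse.

## Known limitations

The LNA underestimates fluctuations close to the crossover at strong
binding, where the response is nearly threshold-like; the SSA is the
arbiter there (the test suite pins their agreement away from the
crossover). The SNA capacity protocol inherits the same limitation: at very
strong binding its closed form and the histogram estimate diverge, and both
should then be read as diagnostics rather than capacities. Finally, the
matched-mean recycling comparison is only defined on the overlap of the two
curves' mean ranges, which fast recycling itself compresses; reported
maxima typically sit at the upper edge of that window.
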