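---
title: "Single-turnover kinetics of the MnmE GTPase cycle: model, fitting and design choices"
author: "mnmekinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-turnover kinetics of the MnmE GTPase cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnmekinetics)
```

## The system and the model

MnmE is a homodimeric GTPase required for modification of the wobble
uridine of several tRNAs. Unlike Ras-family proteins it has low
nucleotide affinity and needs no exchange factors or activating
proteins: its two G-domains dimerize in *cis* upon GTP and potassium
binding, hydrolyse GTP, and then reopen. Under single-turnover
conditions (enzyme at or above substrate, so each site fires at most
once) the observed kinetics resolve the cycle into five sequential
steps, which this package models as

```
E_apo + GTP  -->  E.T  -->  D.T  -->  D.P  -->  E.D (+ Pi)
   binding      dimerize   hydrolyse  dissociate   release
```

* `E_apo`: open, nucleotide-free G-domain pair (the two G-domains of
  one MnmE dimer are treated as a single cooperative unit, because the
  observed kinetics are mono- or biphasic, never per-protomer),
* `E.T`: open, GTP-bound,
* `D.T`: closed G-domain dimer with GTP,
* `D.P`: closed dimer with GDP and Pi after hydrolysis,
* `E.D`: open, GDP-bound, Pi released.

All rate constants are stored in min^-1 and all time grids in seconds;
the factor of 60 is applied exactly once, on entry to the integrator
and to the fitting routines, and a unit test pins this down. Default
wild-type constants (`wt_parameters()`): binding maximum rate 3896
min^-1 with K_D 0.60 uM, dimerization 717 min^-1, hydrolysis 201
min^-1, dissociation 12.4 min^-1, instantaneous Pi release, GDP
off-rate 300 min^-1, K_D for GDP 0.5 uM.

**Binding.** GTP binding is modelled as a rapid-equilibrium encounter
(dissociation constant K_D) followed by an isomerization at maximum
rate k_max. The simulator integrates the flux

v_bind = k_max [E_avail] / (K_D + [E_avail]) * [GTP]

which is genuinely bimolecular: under enzyme excess it reduces to the
hyperbolic pseudo-first-order law k_obs = k_max [E]/(K_D + [E]) used
for titration analysis, and at equimolar 2.5 uM mixing it correctly
slows as free enzyme is consumed. A consequence worth knowing: at
equimolar concentrations the last fraction of substrate binds slowly
(second-order tail), so the observed "binding rate" from a biphasic
fit is an effective value, not the instantaneous hyperbola value.

**Two binding fixtures.** The titration-derived hyperbola (3896
min^-1, 0.60 uM) predicts 3141 min^-1 at the 2.5 uM reference
condition, whereas the directly observed wild-type binding rate at
that condition is 3528 min^-1; the source data do not reconcile the
two. The package keeps both: `wt_parameters()` carries the hyperbola,
and `cycle_parameters_from_profile()` back-solves k_max from a panel
entry so that the simulated binding rate at 2.5 uM equals the
tabulated per-construct value.

**Product inhibition.** GDP is a competitive dead-end inhibitor of
GTP binding: available free enzyme is scaled by `1/(1 + [GDP]/K_IE)`
with K_IE = 41.2 uM, and the effect on later steps follows from the
upstream block. Pi acts twice: on the free enzyme
(`1/(1 + [Pi]/K_IE)`, K_IE = 670 uM, applied to binding) and on
transition-state stabilization (`1/(1 + [Pi]/K_IES)`, K_IES = 5800 uM,
applied to the hydrolysis rate). Free Pi produced during a run feeds
back into these factors. Dead-end binding is treated as an
instantaneous equilibrium; the sequestered fraction is reported as the
`E_I` column. Above ~2 mM Pi the real system also shows an atypical
fluorescence contribution from dissociation of GTP-containing dimers;
this is not modelled.

**Product release.** GDP remains enzyme-bound after hydrolysis (its
affinity, ~0.5 uM, is far below the micromolar product concentration),
so `GDP_free` stays zero in plain simulations; release requires a
competitor chase, modelled by `simulate_chase()` as a single
exponential at the exchange-limited off-rate (~300 min^-1) whose
amplitude — but not rate — grows with competitor concentration through
the partition fraction `comp/(comp + [mGDP])`. Pi release is
instantaneous upon G-domain dissociation by default (`k_pi_rel = Inf`);
a finite k5 inserts an extra open-but-Pi-retaining state, used for
variants with retarded release. A panel entry whose observed k5 is at
least 75% of its k4 is treated as dissociation-limited, i.e.
instantaneous intrinsic release.

**Observables.** Four channels project the species onto signals:
mant fluorescence (0 for apo/free, 0.095 for `E.T`, 0.15 for `D.T` and
`D.P`, 0.10 for `E.D`, as fractions of total enzyme — note hydrolysis
itself is fluorescence-silent, so the decay reports dissociation
only); FRET (any bound mant nucleotide); quench (percent uncleaved
GTP, `100 (T_free + E.T + D.T)/t0`, non-increasing); and the Pi sensor
(proportional to free Pi). The MDCC-labelled phosphate-binding protein
is treated as an instantaneous, non-depleting reporter; sensor
saturation is ignored, a documented simplification since real sensor
concentrations exceed single-turnover Pi only marginally.

## The analytic oracle

`bateman_chain()` gives the closed-form occupancies of an irreversible
first-order chain and serves as the independent oracle for the
integrator: under pseudo-first-order conditions (50 uM enzyme, 0.01 uM
substrate) the ODE solution matches it to 1e-6. At the 0.1 uM
substrate sometimes quoted for such checks the *true* second-order
depletion of enzyme (0.2%) already produces a ~4e-6 discrepancy — a
property of the chemistry, not the solver (mass is conserved to
1e-15). Duplicate rates make the closed form singular; the function
either errors or, on request, separates them by a 1e-6 relative
perturbation with a warning.

## Synthetic data

The generators reproduce the statistical structure of the
experiments: optical traces sampled at 10 ms with a 2 ms instrument
dead time discarded, at least six replicates averaged; quench-flow
time courses of 12 points (t = 0 plus 11 log-spaced up to 12 s) at
50 uM post-mix; k_obs titrations over 0.5-50 uM; and initial-rate
grids over substrate x inhibitor. Noise is additive i.i.d. Gaussian:
0.003 relative-fluorescence units per optical replicate, 2% relative
for quench points, 3% relative for initial rates, 5% for titration
rates — plausible instrument-grade defaults; the true replicate noise
of the original experiments is not reported, so these are exposed as
arguments. One integer seed fixes everything; replicate r draws with
seed + r, and repeated calls are bit-identical.

What the generator does *not* emulate: photobleaching, mixing
artefacts, baseline drift, correlated noise, sensor depletion.
Passing recovery tests therefore demonstrates correctness of the
inference chain under the stated noise model, not robustness to every
instrument pathology of real traces.

## Fitting

All nonlinear fits are initialized by a log-spaced grid search over
rates (1e-1 to 1e5 min^-1) with the linear parameters profiled out,
then polished with Levenberg-Marquardt. Exact-model refits recover
generating parameters to at least six significant digits.

* **Biphasic rise** (binding + dimerization, fitted on 0-0.5 s by
  convention): phases are labelled by magnitude (k_fast >= k_slow).
  If the rates are within a factor of 3 the phases are poorly
  separable: a warning is raised and the fit is compared with a single
  exponential by AIC, falling back when the simpler model wins.
* **Dissociation decay** (0.5-17 s window): single exponential with
  free offset. An amplitude below 3x the trace noise SD is flagged
  "no transition detected". For constructs whose hydrolysis rate is
  below 3x the dissociation rate the fitted decay is a composite of
  both steps and the pipeline flags it as such; no correction formula
  is applied, mirroring how such composite rates are conventionally
  reported.
* **Quench decay**: `plateau + (100 - plateau) exp(-k max(t - t0, 0))`
  with a short fitted onset delay, iteratively reweighted with
  variances proportional to the squared fitted signal. The delay
  absorbs the burst during which binding and dimerization are still
  loading the hydrolysis-competent dimer, and the weighting matches
  the proportional error of chromatographic quantification. Without
  these two refinements the chain structure biases the fitted rate
  ~30-40% low; with them the wild-type recovery is within ~2%. Both
  can be disabled (`delay = FALSE`, `weighting = "none"`).
* **Lag detection**: the delay between the fluorescence peak and the
  first (smoothed) excursion more than 3 noise-SD below the plateau
  mean. The 3-sigma criterion is a package choice — the source
  describes the lag only graphically. On simulated wild-type traces
  the lag is ~0.6 s, the window occupied by the fluorescence-silent
  hydrolysis step.
* **Percent conventions**: all printed percentages round half away
  from zero; amplitude-based Pi retention reports one decimal.

## Inhibition analysis

Dixon (1/v vs [I]) and Cornish-Bowden ([S]/v vs [I]) lines are fitted
per substrate level; the common intersection is computed as the
least-squares common point of all lines rather than read graphically.
On noiseless model-generated grids the intersections land exactly at
-K_IE and -K_IES — analytic properties of the competitive and mixed
rate laws that the tests use as oracles.

Two statistical refinements matter on noisy grids:

* **Parallelism** is diagnosed, not assumed: exactly shared slopes
  (the uncompetitive-Dixon / competitive-[S]/v signature) are an
  error; slopes whose largest pairwise difference is within one joint
  standard error only warn ("poorly determined"). A fixed slope-ratio
  cutoff is unusable here because the mixed law with Km/K_IE >>
  s/K_IES produces slope spreads of only a few percent that are
  nonetheless real.
* **K_IES** read off the intersection is attenuation-biased under
  noise (errors-in-variables: slope noise inflates the denominator of
  the intersection estimator), by roughly a factor of two at 3% noise
  on the default design. `cornish_bowden_fit()` therefore reports the
  constant from a global fit of the mixed rate law in log space (the
  maximum-likelihood estimate under proportional error) and returns
  the intersection estimate alongside. Dixon slopes span an order of
  magnitude across substrate levels, so the Dixon intersection is
  essentially unbiased and remains the primary K_IE estimate, with a
  global competitive fit as cross-check.

Classification uses the apparent-parameter trends across inhibitor
levels: competitive if Km rises monotonically while kcat does not
*fall* by more than 25%; mixed if Km rises and kcat falls by more; the
threshold is a package choice, since only qualitative criteria are
conventional, and upward kcat drift is deliberately treated as
"unchanged" (a competitive inhibitor cannot raise kcat; such drift is
fit noise).

The IC50 helpers evaluate the standard formulas literally:
`IC50 = K_IE (1 + S/Km)` for competitive inhibition, and for mixed
inhibition the bracketed reading `K_IE / ((Km/S) + (K_IE/K_IES))` of
the conventional shorthand, with the textbook form
`(S + Km)/(Km/K_IE + S/K_IES)` returned alongside — the shorthand is
ambiguous as printed and the two readings differ (2602 vs 2971 uM at
the wild-type constants and 5 mM cellular GTP). Note that the
competitive formula with K_IE = 41.2 uM, Km = 710 uM and 5 mM GTP
gives 331 uM, not the 470 uM sometimes quoted for the same inputs;
`ic50_competitive()` is the literal evaluation.
`fraction_inhibited()` defines the inhibited fraction as the dead-end
equilibrium occupancy for competitive inhibitors and as the rate
reduction 1 - v(i)/v(0) for mixed ones; these are this package's
definitions, stated because the basis of loosely quoted "about 75% /
almost 90% inhibited" figures is not specified at the source.

## Numerical choices and problem sizes

The ODE is integrated with `deSolve::lsoda` at rtol 1e-10 / atol
1e-12, comfortably below the 1e-6 conservation and oracle tolerances.
Default problem sizes were chosen so the whole test suite and the
acceptance script run in well under a minute on a laptop: traces of
1700 points, quench courses of 12 points, grids of 15 cells, 20-100
seeds per recovery experiment (medians over seeds are reported;
recovery biases of the single-exponential convention on chain-shaped
data are ~2-3%, well inside the experimental spreads of the reference
constants). Degenerate inputs (flat traces, duplicate rates, parallel
lines, non-monotone times, all-equal titration concentrations) error
or flag rather than returning numbers silently.

## Known limitations

* The cooperative-unit granularity cannot describe per-protomer
  asymmetry or half-of-sites behaviour.
* Potassium dependence is a boolean: an NaCl buffer is modelled as
  `k_dim = 0`, nothing finer.
* Multi-turnover behaviour is available only as the steady-state rate
  law; no progress-curve integration of repeated cycles.
* The quench one-phase-decay rate is an *apparent* constant whenever
  upstream steps are not much faster than hydrolysis; the delay +
  weighting defaults reduce, but cannot eliminate, the residual ~2%
  bias.
* Tight-binding and slow-onset inhibition are out of scope.
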