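# mnmekinetics

Pre-steady-state kinetic analysis of the MnmE GTPase cycle in R.

MnmE is a homodimeric, potassium-dependent GTPase required for the
modification of the wobble uridine of several bacterial tRNAs. Its
cycle differs from the Ras paradigm: the two G-domains of one dimer
close upon GTP + K⁺ binding, hydrolyse GTP, and reopen — and the
*reopening* (G-domain dissociation), not hydrolysis, limits the
overall rate and drives the tRNA-modifying "ON" state. The cycle is
further feedback-inhibited by its own products, GDP (competitive) and
Pi (mixed).

This package is for enzymologists who want to simulate, generate and
analyse single-turnover data for this kind of multi-step GTPase cycle:

* a mechanistic ODE model of the five-step scheme

  E_apo + GTP → E·T → D·T → D·P → E·D (+ Pi)

  (binding k₁, G-domain dimerization k₂, hydrolysis k₃, dissociation
  k₄, Pi release k₅; all rates min⁻¹) with GDP/Pi product inhibition
  and projections onto four instrument channels: stopped-flow mant
  fluorescence, quench-flow % uncleaved GTP, MDCC-PBP Pi-sensor
  fluorescence, and FRET competitor chase;
* the Bateman closed form of the sequential chain as an independent
  analytic oracle for the integrator;
* seeded synthetic-data generators (replicated noisy traces,
  quench-flow time courses, k_obs titrations, inhibition grids, and
  the 14-construct mutant panel fixture);
* the trace-inference chain: grid-initialized single/double
  exponential fits, one-phase quench decay with burst delay and
  proportional-error weighting, hyperbolic titration fit
  `k_obs = k_max·[E]/(K_D + [E])`, lag-phase detection,
  amplitude-based Pi retention;
* product-inhibition inference: Michaelis–Menten fits under
  inhibitor, Dixon (`1/v` vs `[I]`) and Cornish–Bowden (`[S]/v` vs
  `[I]`) analyses for K_IE and K_IES, inhibition-type classification,
  IC50 and fraction-inhibited at cellular GTP/GDP/Pi concentrations;
* `run_pipeline()`: construct panel → synthetic data → all fits →
  table-style report (CSV/JSON + log), deterministic under a seed.

## Worked example

Simulate the wild-type cycle at the reference condition (2.5 µM
enzyme and mant-GTP after 1:1 mixing), average six noisy replicates,
and fit the dissociation phase:

```r
library(mnmekinetics)

params <- cycle_parameters_from_profile("wt")
g <- generate_traces(params, "mant", e0 = 2.5, t0 = 2.5, duration = 17,
                     noise_sd = 0.003, n_replicates = 6, seed = 101)
fit_single_exponential(g$average, "decay", window = c(0.5, 17))
#> fit [single_exponential]
#>                   k           A       y_inf
#> estimate 12.1632000 0.048471000 9.99312e-02
#> se        0.0825885 0.000113501 9.28961e-05
#> residual SD 0.001186 over 1651 points
```

The fitted rate, 12.16 ± 0.08 min⁻¹, recovers the generating
G-domain dissociation constant (12.4 min⁻¹) to within the small bias
that the single-exponential convention carries on chain-shaped decays;
the amplitude (0.048) and offset (0.100) reproduce the 0.15 → 0.10
relative-fluorescence decay of the closed dimer reopening.

```r
detect_lag(g$average)
#> [1] 0.64
```

The 0.64 s lag between the fluorescence peak and the decay onset is
the fluorescence-silent window in which hydrolysis (k₃ = 201 min⁻¹)
converts D·T to D·P without any signal change.

```r
q <- generate_quench_flow(wt_parameters(), seed = 101)
fit_one_phase_decay(q)$estimates[["k"]]
#> [1] 196.5221
```

The quench-flow fit returns the hydrolysis step rate (~197 vs the
generating 201 min⁻¹) — an order of magnitude faster than the
fluorescence decay, the signature observation that dissociation, not
hydrolysis, limits the cycle.

```r
rate_percentages(201, 301)$percent_of_reference
#> [1] 67
```

Full-length MnmE hydrolyses at 67% of the isolated G-domain's rate —
the reporting arithmetic used throughout the panel tables.

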