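---
title: "Demand-directed dynamic FBA: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demand-directed dynamic FBA: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dddfba)
```

## The method in one page

Constraint-based models predict steady-state fluxes by linear programming:
maximise the biomass reaction subject to `S v = 0` and flux bounds, then
(parsimonious FBA) minimise total flux within the growth optimum as a proxy
for minimal enzyme investment. Dynamic FBA with the static optimisation
approach chops a batch culture into short quasi-steady-state intervals,
solves one FBA per interval and integrates biomass and external
concentrations in between.

Demand-directed dynamic FBA adds an explicit gene-expression layer for a
selected set of *balanced* enzymes. Each balanced reaction $i$ carries

$$\frac{d[\mathrm{mRNA}_i]}{dt} = s_{b,i} + R_i(t)\,s_{a,i}
  - (\mu + \gamma_i)[\mathrm{mRNA}_i], \qquad
\frac{d[P_i]}{dt} = s_{P,i}[\mathrm{mRNA}_i] - \mu [P_i],$$

with the demand signal

$$R_i(t) = \begin{cases} 0 & j_i(t) < \theta\, b_i(t) \\
                         1 & j_i(t) \ge \theta\, b_i(t) \end{cases}
\qquad\text{and}\qquad b_i(t) = k_{cat,i}\,[P_i](t)$$

closing the loop: the parsimonious flux $j_i$ relative to the current
capacity bound $b_i$ decides whether activated transcription runs, and the
protein level sets the next interval's bound. Protein degradation is
neglected (dilution only), and translation follows transcription without
delay — both reasonable for *E. coli* on the sub-hour time scale, where
transcription and translation are co-localised. The protein synthesis rate
is inversely proportional to the template length, $s_{P,i} = \tau/\Lambda_i$,
because ribosomes traverse the transcript at finite speed; for an enzyme
complex the longest subunit gene is rate-limiting, and if the complex needs
$n > 1$ copies of that subunit the queueing of ribosomes adds $n$ times the
interribosomal spacing to the apparent length,
$\Lambda = \Lambda_\mathrm{raw} + n \cdot 72\,\mathrm{bp}$ (the
2-oxoglutarate dehydrogenase example: $2802 + 12\cdot72 = 3666$ bp). With a
single copy we use the raw length — the literal reading of the
multiple-copy rule; `apparent_gene_length(add_single = TRUE)` switches to
always adding.

Each simulation step runs: (1) growth maximisation, (2) total-flux
minimisation at the fixed optimum, (3) culture integration, (4) bound
recalculation. Fluxes at time $t$ are solved under the bounds derived from
proteins at time $t$; the signal evaluated on those fluxes drives
expression over $[t, t+\Delta t]$. The alternative (regulate on the previous
step's fluxes) differs by $O(\Delta t)$ and is not exposed.

## Parameters

| parameter | unit | default | role |
|---|---|---|---|
| `theta` | – | 0.6 | demand threshold; enzymes typically operate above half-saturation, and fluxes prove insensitive to it (only expression-episode lengths respond) |
| `tau` | bp mmol h⁻¹ RPKM⁻¹ gDCW⁻¹ | 0.6 | translation constant; sets the scale of all capacity bounds (t = 0 bounds are exactly linear in it) |
| `spacing_bp` | bp | 72 | interribosomal distance in the apparent gene length |
| `dt_min` | min | 0.5 | SOA step; halving it changes toy trajectories by well under 1% |
| `mu_anaerobic` | 1/h | 0.26 | growth rate used for the basal (pre-shift) steady-state initial condition |
| `glc_max`, `o2_max` | mmol h⁻¹ gDCW⁻¹ | 10, 20 | uptake capacities; glucose optionally Michaelis–Menten in the external concentration |
| `kcat` | – (numeric value of s⁻¹) | per enzyme | scales protein to the capacity bound |

On the `kcat` convention: the bound is the plain numeric product
`b = kcat * P` with protein in mmol/gDCW. Applying a literal s⁻¹→h⁻¹
conversion (×3600) to the tabulated turnover numbers yields bounds of order
10⁴ mmol h⁻¹ gDCW⁻¹ — far beyond any realistic flux — whereas the numeric
convention puts the initial bounds of the terminal oxidases and NADH
dehydrogenases at the few-mmol scale where the capacity story plays out
(the efficient oxidase starts near 4.4, the efficient NADH dehydrogenase
near 0.2). A `unit_factor` knob in `flux_bound()`/`ddd_config()` restores
any other convention.

Units are deliberately mixed, following the parameter table they come from:
transcription rates and `gamma` are per minute (mRNA is stepped in
minutes), growth and fluxes per hour (protein and the culture are stepped
in hours). User-facing functions take `mu` in 1/h and convert internally;
the low-level steps carry explicit `mu_min`/`dt_min` arguments.

## Parameter estimation

Replacing the flux-driven signal by a Heaviside step at dead time $T_d$
gives a closed-form mRNA time course: basal level $s_b/(\mu/60+\gamma)$
before $T_d$, exponential approach to $(s_b+s_a)/(\mu/60+\gamma)$ after.
`estimate_basal()` inverts the pre-shift steady state; `fit_activation()`
fits $(s_a, T_d)$ by profiled least squares — for fixed $T_d$ the model is
linear in $s_a$, so the conditional optimum is closed-form and only $T_d$
is searched (dense grid on $[0, \max t]$ plus local refinement; RSS ties
break toward smaller $T_d$). This replaces the stochastic global optimiser
used historically for this problem with a deterministic, reproducible
search that cannot miss the one-dimensional profile minimum.

Confidence intervals for $s_a$ come from a seeded bootstrap whose
resampling respects how RPKM noise actually behaves: variance grows with
expression level, so resampling *raw* residuals mixes the tiny pre-shift
residuals into the high-signal points and produces intervals that are far
too narrow (we measured 61/100 nominal-95% coverage under 5% multiplicative
noise). The default therefore resamples *relative* residuals
(`y* = fitted · (1 + e*)`, small-sample inflated by $\sqrt{n/(n-2)}$),
which restored 95/100 coverage in the same experiment; when replicate
standard deviations are supplied, parametric per-point normal draws are
used instead (and the fit itself becomes `1/sd²`-weighted). A linearised
(Jacobian, t-quantile) interval is reported alongside for comparison; it
ignores the $s_a$–$T_d$ ridge and is narrower.

## The flux–expression correlation pipeline

Reactions sharing the same enzyme set (identical gene sets in the GPR,
regardless of AND/OR tree shape) are lumped by summing absolute fluxes, so
cofactor variants pool; gene-free reactions never lump. Gene fold changes
map to reactions by taking, per isoenzyme, the subunit logFC of minimal
magnitude (a barely-changing subunit caps the complex) and averaging across
isoenzymes; a signed-minimum mode is available. Differential expression
requires fold change ≥ 1.25, mean logCPM ≥ 2 and FDR ≤ 0.05 (the
shift-analysis profile; a stricter fold-change-2 profile ships as
`de_profile("strict")`). A lump is differentially fluxed when the flux
difference reaches 0.25 mmol h⁻¹ gDCW⁻¹ **and** the two FVA intervals are
disjoint — the conjunction is the stricter reading of the two listed
criteria, and `criteria = "either"` relaxes it. Spearman's ρ gets an exact
permutation p-value by full enumeration for n ≤ 8 points without ties
(40320 permutations at most; beyond that the t-approximation takes over —
full enumeration at n = 9–10 costs 0.4–3.6 million permutations for no
practical gain) and an ordinary least-squares line with pointwise 95%
confidence band.

## Numerical choices

- **LP solver.** The package ships a dense two-phase primal simplex with
  Bland's smallest-index anti-cycling rule (`R/lp.R`), written for the
  highly degenerate polytopes of flux models at toy-to-subnetwork scale.
  Fluxes are split into non-negative forward/reverse parts; finite caps
  become slack rows; zero-capacity parts are eliminated up front. Bounds
  beyond ±1000 mmol h⁻¹ gDCW⁻¹ are capped at that conventional value, so
  unboundedness cannot arise in practice. Tests cross-check every objective
  against an independent interior-point/HiGHS formulation.
- **pFBA norms.** L1 (flux splitting) is the default — "total fluxes" is
  the natural linear reading — with the squared-L2 norm available because
  minimised *squared* fluxes are equally defensible and produce smoother,
  unique solutions; the driver exposes `parsimony = "l1"|"l2"`. L1 optima
  can be non-unique (parallel identical routes); the driver pins the solver
  configuration so runs are reproducible, and per-step FVA quantifies the
  remaining freedom.
- **L2 implementation.** The quadratic program is solved in the
  constant-growth null space anchored at the L1 solution, after pinning
  zero-variability coordinates found by FVA — active-set QP solvers
  otherwise report spurious inconsistency on the degenerate equality-like
  bound pairs.
- **Growth fixing.** `mu*` is enforced as
  `mu*(1 − 10⁻⁶) ≤ v_biomass ≤ mu*` to avoid numerical infeasibility at
  the optimum; reported growth rates therefore agree with the FBA optimum
  to the same relative tolerance.
- **Exact ODE updates.** Both balances are linear with piecewise-constant
  coefficients, so one step is the exact exponential relaxation toward the
  current steady state; the degenerate `mu + gamma = 0` (resp. `mu = 0`)
  cases fall back to linear growth. The updates form a semigroup: 100
  sub-steps equal one step to 10⁻¹⁰, and against an adaptive integrator
  they agree to 10⁻⁸ over a broad random parameter grid.
- **Degenerate demand.** The literal rule gives `R = 1` when
  `j = b = 0`; with any basal transcription the steady-state bound is
  strictly positive, so the case does not arise in the shipped scenarios.
- **Infeasibility policy.** When the constrained LP cannot grow (substrate
  exhausted), the step records a dormant state (`mu = 0`, zero fluxes) and
  the simulation continues, so batch ends are simulatable.

## What the synthetic data emulate — and what they do not

`toy_model()` condenses central aerobic carbon metabolism into ~30
reactions: lumped glycolysis, pyruvate dehydrogenase, a TCA leg with the
2-oxoglutarate-dehydrogenase step, the glyoxylate bypass, an ETC with
proton-translocating (NADH16, CYTBO) and less-translocating (NADH5, CYTBD)
parallel branches, malate:quinone and lactate:quinone shortcuts, ATP
synthase, fermentative outlets, and a biomass reaction consuming pyruvate,
ATP and NADH (25:75:25 per unit growth, scaled so the anaerobic optimum
lands at 0.267 1/h near the measured 0.26, and the unconstrained aerobic
optimum at 0.70 1/h at a glucose uptake of 10). Proton stoichiometries are
small integers chosen once — 4 per NADH for the efficient dehydrogenase
versus 0, 4 versus 2 per quinol for the oxidases, 4 per ATP — which makes
every yield hand-checkable and gives the strict efficiency ordering the
MLE classification needs. Three structurally necessary components came out
of validating the network against independent LP solutions: a non-growth
ATP maintenance reaction (without a dissipative ATP sink, surplus
respiratory ATP is infeasible and capacity-limited respiration would never
be recruited), redox-neutral pyruvate overflow secretion (the acetate
analogue; otherwise every surplus pyruvate drags one NADH into
fermentation), and malic enzyme (the glyoxylate shunt has no steady-state
outlet without a malate drain). All three are standard fixtures of real
metabolic models.

The six balanced reactions carry literature-derived kinetics (gene lengths,
transcription and degradation rates, turnover numbers) — including the
12-copy largest-subunit correction for the 2-oxoglutarate dehydrogenase —
so the toy scenario reproduces the qualitative aeration phenotype: the
efficient oxidase saturates its bound immediately, the less-efficient
oxidase carries flux on an interior time interval and is transiently
expressed, the less-efficient NADH dehydrogenase stays recruited while the
bulky efficient complex remains capacity-limited, and growth steps from the
fermentative to an aerobic rate.

What the toy does *not* emulate: genome-scale redundancy (thousands of
alternative routes buffer real FVA intervals), elemental/charge balancing,
realistic biomass composition, membrane or crowding constraints, dissolved
oxygen dynamics, or the absolute flux magnitudes of a genome-scale
reconstruction. Passing tests on the toy therefore certify the method's
mechanics — LP correctness, the expression/bound feedback, estimation and
correlation machinery — not quantitative predictions for real cultures; a
genome-scale model file in SBML-FBC or BiGG-style JSON can be supplied to
`read_metabolic_model()` for the latter.

`synth_expression()` generates RPKM courses from the delayed-activation
model with multiplicative Gaussian noise (default σ = 0.05), floored at 0
(the floor only matters beyond σ ≈ 0.3), because RPKM variance grows with
expression level; replicates report per-time mean and SD.
`synth_de_table()` plants an exact number of genes passing the shift
thresholds. Both are seed-deterministic.

## Problem sizes used in the shipped checks

Simulations in tests and the acceptance script run the toy network for
45–70 minutes of culture time at 0.5-minute steps (≈ 90–140 LP pairs),
parameter sweeps use 2–3-point grids, the estimation coverage study uses
100 repetitions with 200 bootstrap draws each, and exact permutation
checks use n = 6 points. These sizes were chosen so each property is
measured well inside its stated tolerance while the whole suite stays
interactive.

## Known limitations

- No post-transcriptional or allosteric regulation, no ribosome/polymerase
  competition: capacity bounds are upper bounds only, so inhibited
  solutions remain inside the feasible set but are not distinguished.
- The demand signal acts on the possibly non-unique L1 pFBA vertex; under
  degeneracy the realised demand can depend on the vertex the solver
  returns. The configuration is pinned for reproducibility and per-step FVA
  flags wide intervals.
- The shipped simplex is dense and targets models up to a few hundred
  reactions; genome-scale work would want a sparse industrial LP backend
  behind the same `fba()`/`pfba()`/`fva()` surface.
- Estimated transcription rates are condition-specific: parameters fitted
  to one shift experiment do not transfer to other media or strains
  without refitting.
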