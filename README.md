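# dddfba: demand-directed dynamic flux balance analysis

When a facultative anaerobe such as *Escherichia coli* is suddenly aerated,
the enzymes of efficient aerobic metabolism — the proton-translocating NADH
dehydrogenase (*nuo*), the cytochrome *bo3* oxidase (*cyo*), the TCA-cycle
dehydrogenases — are barely expressed, so the fluxes they could carry are
capacity-limited. Expression data from such shifts show transient
upregulation of *metabolically less efficient* (MLE) enzymes: the
non-translocating NADH dehydrogenase (*ndh*), the cytochrome *bd* oxidase
(*cyd*), the glyoxylate shunt. `dddfba` implements demand-directed dynamic
flux balance analysis, a dynamic FBA variant that explains this pattern
mechanistically: enzyme capacity limits flux, and flux demand switches
transcription on.

The model couples three layers per expression-balanced enzyme *i*:

- an mRNA balance
  `d[mRNA_i]/dt = s_b,i + R_i(t) s_a,i − (μ + γ_i)[mRNA_i]`,
  with basal rate `s_b`, activated rate `s_a` (RPKM/min), degradation `γ`
  (1/min) and dilution by growth `μ`;
- a demand signal `R_i(t) = 1` iff `j_i(t) ≥ θ·b_i(t)` — transcription
  activates when the parsimonious flux `j_i` approaches the fraction `θ`
  (default 0.6) of the current capacity bound;
- a protein balance `d[P_i]/dt = s_P,i [mRNA_i] − μ [P_i]` with
  `s_P,i = τ/Λ_i` (translation constant `τ` over the apparent gene length of
  the largest subunit), and the capacity bound `b_i(t) = k_cat,i [P_i](t)`.

Each time step of the batch simulation (1) maximises growth by FBA,
(2) minimises total flux at the growth optimum (parsimonious FBA, L1 or L2),
(3) integrates biomass and external metabolite concentrations under
exponential within-step growth, and (4) recomputes uptake and
enzyme-capacity bounds from the advanced expression state. Flux variability
analysis (FVA) brackets alternative optima. The package also estimates
transcription parameters (`s_a`, dead time `T_d`) from RPKM time courses via
the closed-form Heaviside-activated solution of the mRNA balance, and
quantifies the association between flux changes and transcript fold changes
(enzyme-set flux lumping, differential-expression and differential-flux
filters, Spearman rank correlation with regression band).

A built-in ~30-reaction toy network of central aerobic metabolism —
fermentation, TCA cycle, glyoxylate shunt, and an electron transport chain
with efficient and less-efficient parallel branches — exercises the whole
method without external downloads; its six balanced reactions carry
literature-derived kinetic parameters.

## Worked example

```r
library(dddfba)
library(dplyr)

model <- toy_model()
model
#> <ddd_model> toy_shift
#>   metabolites: 24 (6 external)
#>   reactions:   31 (6 exchange)
#>   objective:   BIOMASS

kin <- toy_kinetics()                    # six balanced reactions
cfg <- ddd_config(horizon_min = 45, dt_min = 0.5, t_aer_min = 5)
tr  <- ddd_simulate(model, kin, cfg)     # aeration at t = 5 min

episode_summary(tr)
#> # A tibble: 6 × 3
#>   reaction expression_min binding_min
#> 1 AKGDH              40          40
#> 2 CYTBD               1.5         0
#> 3 CYTBO               6.5         4.5
#> 4 NADH16             40          40
#> 5 NADH5              40          40
#> 6 PDH                40           0

tr$culture |> filter(time_min %in% c(0, 5, 10, 20, 44.5)) |>
  select(time_min, biomass, growth_rate, glc_e)
#> # A tibble: 5 × 4
#>   time_min biomass growth_rate glc_e
#> 1      0     0.1         0.267  25
#> 2      5     0.102       0.373  24.9
#> 3     10     0.106       0.408  24.8
#> 4     20     0.113       0.414  24.6
#> 5     44.5   0.134       0.425  24.1
```

Reading the output: before aeration the culture grows fermentatively at
μ = 0.267 1/h. At aeration the efficient oxidase (CYTBO) immediately hits
its capacity bound (`binding_min` = 4.5 min) and its transcription switches
on for 6.5 min; during those minutes the less-efficient oxidase (CYTBD)
carries the overflow electron flux and is itself transiently expressed
(1.5 min) before its flux drops back to zero. The NADH dehydrogenases and
the TCA dehydrogenase stay demand-activated for the whole run — their
capacity never catches up with demand on this horizon — and growth climbs
toward the aerobic optimum. `autoplot(tr)` draws the flux/bound and mRNA
panels per balanced reaction.

Parameter estimation and the correlation analysis follow the same
tibble-in/tibble-out style:

```r
truth  <- tibble::tibble(gene = "cydA", s_b = 116.3, s_a = 759.1,
                         T_d = 2, gamma = 0.187)
series <- synth_expression(truth, times = c(-10, 0, 1, 2, 3, 4, 6, 8),
                           sigma = 0.05, seed = 1)
fit <- fit_activation(series |> select(time_min, rpkm),
                      s_b = 116.3, gamma = 0.187)
tidy(fit)      # s_b, s_a (with bootstrap 95% CI), T_d
```

A thin command-line front end (`inst/cli/dddfba.R`) exposes `simulate`,
`sweep`, `toy`, `synth-expr` and `correlate` subcommands over TSV/JSON/YAML
files.

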