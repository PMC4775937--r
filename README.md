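# ampsynergy

Pharmacodynamic analysis of antimicrobial peptide (AMP) time-kill
experiments, for single peptides and fixed-ratio two- and three-way
mixtures: net-growth-rate estimation from CFU time series, Hill-model
fitting (least squares and Bayesian MCMC), and Loewe combination-index
profiling with synergy/additivity/antagonism calls.

## Who this is for

Microbiologists and quantitative pharmacologists running time-kill
assays: a dilution series of an antimicrobial (2-fold from 100× MIC, plus
a drug-free control), CFU counts every 20 min for an hour, replicated.
Mixtures are built the fixed-ratio way — 100×-MIC stocks combined 1:1 or
1:1:1 — so each component's concentration is halved or thirded and Loewe
additivity makes a sharp prediction: a mixture exactly as potent, per
MIC-unit, as its components. The package quantifies departures from that
prediction.

## The model

Net bacterial growth at concentration *a* follows the four-parameter Hill
pharmacodynamic function

ψ(a) = ψ_max − μ(a),  μ(a) = (ψ_max − ψ_min) (a/zMIC)^κ / ((a/zMIC)^κ − ψ_min/ψ_max)

with ψ_max > 0 the drug-free growth rate, ψ_min < 0 the kill plateau
(E_max = ψ_max − ψ_min), κ the Hill steepness, and zMIC the zero-growth
concentration (ψ(zMIC) = 0). The Loewe combination index at effect
fraction *f* is

CI(f) = Σᵢ C_iso,i(f) / Cᵢ(f),

the sum over components of (concentration inside the mixture dose reaching
*f* of the mixture's maximal effect) / (concentration at which the drug
alone reaches *f* of its own maximal effect). CI < 1 is synergy, CI = 1
additivity, CI > 1 antagonism; profiles run across *f* ∈ [0.05, 0.95]
with 95% intervals from posterior propagation, and the headline call is
read at E50.

A synthetic-data generator with known ground truth (including a potency
factor γ giving true CI = 1/γ) emulates the full assay — inoculum 2×10⁶
CFU, 100-CFU detection limit with left-censoring, Poisson plating noise —
so the entire pipeline is testable without external data.

## Worked example

Two peptides with a synergistic (γ = 2) 1:1 mixture, simulated and pushed
through the whole chain:

```r
library(ampsynergy)

drugs <- list(pexiganan = PDParams(1.2, -8, 3, 1),
              melittin  = PDParams(1.2, -8, 2, 1))
sc <- simScenario(
  drugs = drugs, mic = c(pexiganan = 16, melittin = 2),
  mixtures = list(PexMel = MixtureDesign(c("pexiganan", "melittin"),
                                         mic = c(16, 2))),
  gamma = 2, seed = 11)

curves <- simulateScenario(sc)       # tidy CFU records
rates  <- estimateRates(curves)      # ln-CFU slopes, h^-1
head(rates, 3)
#>   treatment_id concentration      rate        se n_points censored_used bound
#> 1     melittin           100 -7.680955 0.1712575       12         FALSE FALSE
#> 2     melittin            50 -8.307786 0.1633022       12         FALSE FALSE
#> 3     melittin            25 -7.634329 0.1165563       12         FALSE FALSE

post <- list()
for (tid in c("pexiganan", "melittin", "PexMel"))
  post[[tid]] <- fitPDMCMC(rates[rates$treatment_id == tid, ], seed = 11)
post$pexiganan
#> PDPosterior: 8000 retained draws, 4 chains
#>   converged: yes (split-Rhat threshold 1.05)
#>            2.5%     50%  97.5%
#> psi_max  0.8972  1.2180  1.499
#> psi_min -8.3030 -8.0400 -7.791
#> kappa    2.2990  2.8410  3.486
#> zmic     0.8273  0.9827  1.105

prof <- ciProfile(post[c("pexiganan", "melittin")], post$PexMel,
                  sc@mixtures$PexMel, seed = 11)
prof
#> CIProfile for 'pexiganan+melittin': 19 fractions in [0.05, 0.95]
#>   CI at E50 = 0.506; summary call: synergistic
```

Reading the output: the first rows of `rates` are the strongest dilutions
of melittin, killing at ≈ −8 h⁻¹ (its plateau). The posterior for
pexiganan brackets the generating truth (ψ_max 1.2, ψ_min −8, κ 3,
zMIC 1 on its MIC-multiple axis). The mixture was generated with γ = 2,
i.e. a true combination index of 1/γ = 0.5 at every fraction; the
estimated profile recovers CI ≈ 0.50 with a clear `synergistic` call.

`runPipeline(runConfig(scenario = sc, outdir = "run1", seed = 1))` runs
the same chain end to end and writes every artifact (kill curves, rates,
fits, CI profiles, summary, manifest) with full seed provenance; a thin
CLI wrapper lives at `inst/scripts/ampsynergy.R`
(`--config --seed --outdir --stage --verbose`).

## Layout

- `R/` — S4 classes (`PDParams`, `PDPosterior`, `MixtureDesign`,
  `SimulationScenario`, `CIProfile`) and the module functions;
- `tests/testthat/` — unit, property and end-to-end calibration tests;
- `vignettes/amp-combination-pharmacodynamics.Rmd` — the methods
  vignette: model, priors, censoring rule, Loewe construction, generator
  scope and limitations;
- `scripts/acceptance.R` — see above.
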