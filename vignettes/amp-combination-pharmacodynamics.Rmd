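---
title: "Pharmacodynamics and Loewe synergy of antimicrobial peptide combinations"
author: "ampsynergy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pharmacodynamics and Loewe synergy of antimicrobial peptide combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampsynergy)
```

## The scientific problem

Antimicrobial peptides (AMPs) are short, fast-acting bactericidal effectors
of innate immunity, increasingly developed as drugs. When AMPs are applied
together — as drug cocktails, or as a drug meeting the patient's own
peptides — the practical questions are quantitative: how steeply does
killing switch on with concentration, and is a mixture more or less potent
than its components predict? `ampsynergy` answers both from time-kill
experiments: serial CFU counts of a bacterial culture exposed to a dilution
series of a peptide or a fixed-ratio peptide mixture.

The package covers the full chain: simulating or importing tidy kill-curve
tables, extracting a net growth rate per concentration, fitting a
four-parameter Hill pharmacodynamic model per treatment (deterministic
least squares and Bayesian MCMC), and quantifying interaction with Loewe
combination indices profiled across the effect range.

## The pharmacodynamic model

Net bacterial growth under concentration $a$ follows
$$\psi(a) = \psi_{max} - \mu(a), \qquad
\mu(a) = \frac{(\psi_{max}-\psi_{min})\,(a/zMIC)^\kappa}
              {(a/zMIC)^\kappa - \psi_{min}/\psi_{max}},$$

with four parameters:

* $\psi_{max}$ (h$^{-1}$, $>0$): drug-free net growth rate;
* $\psi_{min}$ (h$^{-1}$, $<0$): net growth at saturating drug — the
  bactericidal plateau; $E_{max} = \psi_{max}-\psi_{min}$ is the maximal
  kill effect;
* $\kappa$ (dimensionless, $>0$): the Hill coefficient; larger $\kappa$
  means a sharper switch from growth to killing. AMPs characteristically
  show much larger $\kappa$ than conventional antibiotics;
* $zMIC$ ($>0$): the zero-growth concentration, the pharmacodynamic MIC.

This parameterisation is algebraically identical to the classical Hill
form $\mu(a) = E_{max}(a/EC_{50})^\kappa/(1+(a/EC_{50})^\kappa)$ with
$EC_{50} = zMIC\,(|\psi_{min}|/\psi_{max})^{1/\kappa}$; the test suite
verifies the equivalence numerically to $10^{-10}$ on randomized parameter
sets. Built-in identities: $\psi(0)=\psi_{max}$, $\psi(zMIC)=0$,
$\psi(a)\to\psi_{min}$, and the closed-form inverse
$$a_f = zMIC\left(\frac{f\,|\psi_{min}|}{\psi_{max}(1-f)}\right)^{1/\kappa}$$
returns the *isoeffective concentration* at which $\mu = f\,E_{max}$
(`isoeffectiveConc()`).

A note on the denominator: some typeset versions of this model are
ambiguous about the sign of the $\psi_{min}/\psi_{max}$ term. We use the
form above, the only reading under which $\mu(zMIC)=\psi_{max}$ and hence
$zMIC$ is the concentration of zero net growth — the standard
pharmacodynamic convention.

```{r}
p <- PDParams(psiMax = 1.2, psiMin = -8, kappa = 3, zmic = 1)
netGrowth(c(0, 0.5, 1, 2, 50), p)
isoeffectiveConc(0.5, p)   # equals ec50(p)
```

## From kill curves to rates

Rates are extracted per treatment $\times$ concentration by ordinary
least-squares regression of $\ln$ CFU on time, pooling all replicates in
one regression (fixed-effect pooling; per-replicate averaging is not
used), starting at the first measurement. The logarithm base is an
internal detail — slopes are reported in natural-log h$^{-1}$ and any base
change is a linear rescaling that cancels in the fit.

**Detection-limit censoring.** Plating cannot count below the detection
limit (100 CFU in the emulated design), so fast-kill curves are
left-censored. Discarding censored points entirely would bias fast-kill
rates toward zero; we therefore include observations up to and *including
the first* fully censored time point (at the limit value) and discard
later ones. Even so the retained floor value understates the true kill
rate — the `censored_used` flag propagates this caveat into the rate
table, and the pipeline warns when more than half of a treatment's
concentrations are affected. When *every* post-baseline point is censored
the slope through the first censored point is only an upper bound on the
kill rate; such rows carry `bound = TRUE` and are excluded from model
fitting by default (`includeBounds = TRUE` opts in).

## Fitting: least squares and MCMC

`fitPDLS()` minimises the weighted sum of squares of observed versus
predicted rates (weights $1/se^2$ where a positive regression SE exists,
unit weights otherwise) over a deterministic multi-start grid:
$\kappa_0 \in \{0.5, 1, 2, 4, 8\}$ crossed with $zMIC_0$ candidates placed
at the observed growth-to-kill sign change and at quartiles of the dose
range. Optimisation runs in $(\psi_{max}, \psi_{min}, \ln\kappa,
\ln zMIC)$ so positivity is structural; ties in the final loss break
toward the smallest $\kappa$ (the least steep curve consistent with the
data). Data with no sign change in the rates are refused: $zMIC$ is not
identifiable outside the sampled range, and refusing loudly beats
extrapolating silently.

`fitPDMCMC()` samples the posterior under independent Gaussian likelihoods
for the rate estimates using an adaptive random-walk Metropolis sampler
(4 chains, 2000 warmup + 2000 retained each by default) initialised at the
least-squares fit. During warmup the proposal scale follows a
Robbins–Monro recursion targeting 30% acceptance and the proposal
covariance is re-estimated from the recent half of the warmup draws,
freezing before the end of warmup so the retained draws come from a fixed
kernel. Priors are weakly informative and scale-aware:
$\psi_{max}\sim N(1,1)$ truncated positive, $\psi_{min}\sim N(-5,5^2)$
truncated negative, $\ln\kappa\sim N(0,1)$, and $\ln zMIC$ normal with SD 2
centred on the log-midpoint of the positive dose grid. They are dominated
by the data in all simulation checks.

**Observation noise.** The regression SE of a slope fitted to 3 replicates
$\times$ 4 time points has very few degrees of freedom, so by default the
likelihood instead samples a single global observation SD $\sigma$
(lognormal prior, `sigmaMode = "global"`); `sigmaMode = "se"` plugs the
per-point SEs in directly for designs dense enough to estimate them well.
Split-$\hat R$ and an effective sample size are computed per parameter;
fits with any split-$\hat R > 1.05$ are returned but flagged (and warned
about) as unconverged.

## Loewe additivity and the combination index

Mixtures follow the fixed-ratio stock design: each component is stocked at
$100\times$ its own MIC and stocks are combined at volume ratio 1:1 (or
1:1:1), so the mixture's dose axis is the stock fraction $g \in (0,1]$ and
component $i$ contributes $g \cdot 100 \cdot r_i$ multiples of its own MIC
(`componentConcentrations()`). Under this convention Loewe additivity
predicts a mixture MIC at which every component sits at $1/n$ of its own
MIC — i.e. a combination exactly as potent, per MIC-unit, as its parts.

The combination index at effect fraction $f$ is
$$CI(f) = \sum_i \frac{C_{iso,i}(f)}{C_i(f)},$$
where $C_{iso,i}$ are the component concentrations inside the mixture dose
achieving $f$ of the mixture's maximal effect and $C_i$ is the dose at
which drug $i$ alone achieves $f$ of *its* maximal effect. $CI<1$ is
synergy, $CI>1$ antagonism. `ciProfile()` evaluates this on a grid
(default 0.05–0.95 in steps of 0.05; the range is standard, the step a
package choice) for every tuple of posterior draws, giving a median and a
95% interval per fraction; the per-fraction call is `additive` exactly
when the interval contains 1, and the summary call is read at the 50%
effect level (E50). Because treatments are fitted independently, draws
from the different posteriors are paired by index after a seeded random
permutation — independent propagation, matching how the fits were made.

Two conventions for "fraction" are supported. The default (`mode = "own"`)
references each curve's own $E_{max}$, matching the isoeffective-fraction
design of the assay; `mode = "absolute"` fixes one absolute kill rate
across curves and reports `NA` (never an extrapolation) at fractions a
weaker component cannot reach. When the components' plateaus are
indistinguishable — the empirical situation for the AMPs that motivated
this package — the two conventions nearly coincide.

`compareGroups()` reproduces the group-level contrasts: a Welch t-test on
CI values pooled across the fraction grid between two- and three-component
mixtures, and regression ANOVA of $zMIC$, $\kappa$ and $\psi_{min}$ with
combination size as a *numeric* covariate (1 numerator df). The numeric
coding is deliberate: the scientific question is a monotone trend with
the number of components, and it matches the single-df F statistics such
analyses conventionally report.

## The synthetic-data generator

`simScenario()`/`simulateScenario()` emulate the study design the package
targets: inoculum $2\times10^6$ CFU per 100 µl well, sampling every 20 min
for 1 h, a 2-fold dilution series from $100\times$ MIC (10 levels plus a
drug-free control), detection limit 100 CFU, three replicates. None of
these defaults is tuned; they are the design constants of the emulated
assay, and replicate count (unreported in such designs) defaults to the
conventional three.

Single-drug curves follow $N(t) = N_0 e^{\psi(a) t}$. Mixture ground
truth is built by *inverting* Loewe additivity: at stock fraction $g$ the
additive kill rate $E^*(g)$ solves $\sum_i C_{iso,i}(g)/C_i(E) = 1$ by
bracketed root finding over $E$ between 0 and the smallest component
$E_{max}$ (the bracket's lower end is extended adaptively at very small
doses, and doses beyond the range where the additive null exists are
clipped to the attainable maximum, with a warning). A dimensionless
interaction factor $\gamma$ rescales potency, $\mu_{mix}(g) =
E^*(\gamma g)$: every isoeffective dose is divided by $\gamma$, so the
analytic combination index is $1/\gamma$ at every fraction — $\gamma = 1$
is exact additivity, $\gamma = 2$ synergy at $CI = 0.5$. The mixture's
drug-free growth rate is the mean of the component $\psi_{max}$ values
(one culture grows beneath all curves).

Noise is multiplicative log-normal overdispersion on the expected count
(SD 0.1 on the ln scale, mean-preserving) followed by Poisson plating at
a 1:100 plated fraction, so observed counts are multiples of the detection
limit; zero colonies are recorded *at* the limit with `censored = TRUE`.
Randomness uses one top-level seed with a deterministic sub-stream per
(treatment, replicate) — hashed, not sequential — so adding treatments to
a scenario never perturbs existing ones, and output is bit-reproducible.

What the generator does **not** emulate: lag phases or biphasic kill
(a single exponential per concentration), time-varying drug concentration
(no pharmacokinetics, no degradation), inoculum effects, resistance
emergence, plate-to-plate batch effects, or mechanistic interactions —
$\gamma$ is a phenomenological potency scale. Passing the simulation-based
checks therefore demonstrates that the estimation chain is *internally
consistent and calibrated for data of this structure*, not that real
kill curves satisfy the model; on real data the rate regression's
single-slope assumption and the censoring rule are the first things to
scrutinise.

## Numerical and design choices

* **Effect-range profiling** is restricted to fractions 0.05–0.95: both
  dose limits ($f \to 0, 1$) are unbounded, and the closed-form inverse is
  exact to $10^{-10}$ inside the range (tested by round trip and against a
  bisection oracle).
* **Additive-null root finding** uses `uniroot()` at tolerance $10^{-13}$
  with an adaptively extended lower bracket; the isobole sum is verified
  in tests against a brute-force grid search at $10^{-4}$ dose resolution.
* **Degenerate inputs**: duplicate observation keys, zero CFU without a
  censoring flag, all-one-sign rate tables, and mixtures naming unknown
  drugs are rejected with specific errors rather than coerced.
* **Sham invariance** is the package's strongest self-check: a drug
  combined with itself must give $CI \equiv 1$ at every fraction, ratio
  and $\kappa$ — exact to $10^{-8}$ in the tests, with no estimation in
  the loop.
* **Simulation-study sizes**: the calibration checks in the test suite use
  50 seeded repetitions per claim (posterior coverage; additivity-call
  rates; $\gamma = 2$ recovery) with a reduced sampler budget of 2 chains
  $\times$ (1000 warmup + 1000 retained), while single-fit checks exercise
  the full default budget. These sizes are the package's simulation-study
  design: large enough that an 80% coverage claim has a standard error of
  about 5 percentage points, small enough to run routinely.

## Known limitations

* The additive null is undefined above the smallest component $E_{max}$;
  with markedly unequal plateaus the own-$E_{max}$ CI convention is itself
  biased away from 1 for a truly additive mixture (the generator clips and
  warns). Compare components with similar plateaus, or use
  `mode = "absolute"` and accept `NA`s.
* Censoring-heavy treatments (very fast kill) yield rate *bounds*; the
  fitted $\psi_{min}$ can then understate the true kill plateau, a caveat
  inherited from the assay's 20-min sampling resolution.
* Rates feeding one Hill fit share no information across treatments
  (no hierarchy); with very noisy data the per-treatment posteriors are
  correspondingly wide.
* The MCMC sampler is a general-purpose adaptive random-walk; for the
  4–5 dimensional posteriors here it is entirely adequate (verified by
  split-$\hat R$, ESS and coverage), but it is not meant for reuse on
  high-dimensional models.

## A complete run

```{r, eval = FALSE}
sc <- simScenario(
  drugs = list(A = PDParams(1.2, -8, 3, 1), B = PDParams(1.2, -8, 2, 1)),
  mic = c(A = 8, B = 16),
  mixtures = list(AB = MixtureDesign(c("A", "B"), mic = c(8, 16))),
  gamma = 1, seed = 1)
cfg <- runConfig(scenario = sc, outdir = "run1", seed = 1)
manifest <- runPipeline(cfg)
```

writes `killcurves.csv`, `truth.yaml`, `rates.csv`, `fits.json`,
`ci_profile.csv`, `summary.json` and `manifest.json` under `run1/`; an
identical config reproduces them bit-for-bit. A thin command-line wrapper
with the same capabilities ships at
`system.file("scripts", "ampsynergy.R", package = "ampsynergy")`.
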