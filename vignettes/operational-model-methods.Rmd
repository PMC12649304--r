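---
title: "Methods: operational-model exposure-response for contraceptive efficacy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: operational-model exposure-response for contraceptive efficacy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocer)
```

## The problem

Pearl-Index (PI) dose-response is unmeasurable below therapeutic doses —
running trials at subtherapeutic contraceptive exposure would cause
unintended pregnancies — while ovulation rate (OR) is ethically measurable
across the whole dose range. `cocer` implements a quantitative bridge
between the two endpoints across progestins: a drug-class-level
exposure-response model in which drug-specific receptor affinity (KD) and a
drug-specific intrinsic-efficacy constant (tau) are separated from
system-level parameters (baseline, maximum suppression, Hill factor), so
that what is learned about one endpoint or one drug constrains the others.

## Model and assumptions

For drug $i$ and trial arm $j$, with $x = \log_{10} C_{avg}$ (pmol/L) and
$k_i = \log_{10} K_{D,i}$ (pmol/L),

$$E_{ij} = BL\left(1 - I_{max}\,
  \frac{(\tau_i x)^H}{(k_i + x)^H + (\tau_i x)^H}\right) + \varepsilon_{ij},
  \qquad \varepsilon_{ij} \sim N\!\left(0, \sigma_i^2 / n_{ij}\right).$$

This is the classical operational model of agonism with a slope factor. Two
reading choices deserve comment, both of which were genuinely open:

* **Functional form.** Published renderings of this model family are often
  typeset ambiguously. We adopt the canonical form above — numerator
  $(\tau x)^H$, denominator $(k + x)^H + (\tau x)^H$, a single Hill factor
  per endpoint — which is the standard operational model with slope and is
  consistent with one $H$ per endpoint in the reference parameter sets.
* **Concentration scale.** The model operates by default on
  $x = \log_{10}$ of the molar concentration, with KD on the same log10
  pmol/L scale (`default_drug_registry()` carries 3.556 for LNG, 2.949 for
  DRSP, i.e. $K_D \approx 3.6$ and $0.9$ nmol/L — physiological for
  progestin-receptor binding). Because the log-versus-linear reading of the
  published model is ambiguous, `operational_response()` and the fitters
  also accept `scale = "linear"`, applying the identical form to the molar
  concentration directly. Neither scale is claimed to reproduce published
  absolute scenario predictions: those depend on external PBPK exposure
  distributions that are not available (see *Limitations*).

Assumptions worth keeping in mind: a common baseline and $I_{max}$ across
drugs of the class; additive Gaussian residuals on the endpoint scale whose
variance shrinks as $1/n_{ij}$ (this is the only weighting mechanism — no
random effects, matching a naive-pooled meta-analysis); and independence of
arms.

### Numerical behaviour at the domain boundary

On the log scale the operating variable must be positive ($C > 1$ pmol/L).
At or below that boundary the suppression term is undefined (negative base
to a real power), so `operational_response()` returns the baseline — no
suppression — and warns, rather than producing `NaN`. The suppression
fraction is evaluated in log space,
$1/(1 + \exp(H[\log(k+x) - \log\tau - \log x]))$, so extreme Hill factors
(the OR set has $H \approx 25$) cannot overflow.

As exposure grows the response tends to
$BL\,(1 - I_{max}\,\tau^H/(1+\tau^H))$. Convergence is slow in $x$ — the
deviation of the suppression ratio from its limit is
$(1 + k/x)^H - 1 \approx Hk/x$ — so numeric checks of the asymptote are done
either at very large operating values or in regimes where $k \ll x$.

## Parameters, units, defaults

| Parameter | Units | PI default | OR default | Status |
|---|---|---|---|---|
| BL | endpoint units | 85 | 100 | fixed |
| Imax | fraction | 1 | 1 | fixed |
| H | — | 9.653 | 25.462 | estimated |
| tau LNG / DRSP | — | 3.046 / 2.602 | 2.172 / 1.867 | estimated |
| log10 KD LNG / DRSP | log10 pmol/L | 3.556 / 2.949 | same | fixed |
| sigma LNG / DRSP | endpoint units | 0.493 / 0.572 | 6.572 / 2.260 | estimated |

Molecular weights (312.45 g/mol LNG, 366.49 g/mol DRSP) are standard
chemistry values, overridable through `drug_spec()`. PI is counted per 100
woman-years; OR is a percentage, hence its baseline of 100.

## Estimation

`fit_operational()` maximises the exact Gaussian likelihood over
$(\log\tau_i, \log H)$ with the residual standard deviations profiled out in
closed form: $\hat\sigma_i^2 = \mathrm{mean}_j\, n_{ij} r_{ij}^2$, the MLE of
the stated error model (`profile_sigma()`, floored at $10^{-6}$ so
noise-free fixtures do not degenerate the likelihood). Choices the method
description leaves open were resolved as follows:

* **Optimizer.** Bounded quasi-Newton (`L-BFGS-B`, projected-gradient
  tolerance $10^{-8}$) on log-transformed parameters, bounds
  $\tau \in [10^{-2}, 10^3]$, $H \in [0.1, 100]$, from a deterministic
  9-point multistart grid. Because the line search can stall marginally
  short of an optimum, the best start is alternately polished with a
  derivative-free pass (Nelder-Mead; Brent in one dimension) and restarted;
  convergence is declared only when a polish pass fails to improve the
  objective — a stationary point confirmed from two directions.
* **Uncertainty.** Wald: central finite-difference Hessian
  (`pracma::hessian`) of the full likelihood over
  $(\log\tau, \log H, \log\sigma)$ at the optimum, inverted and
  delta-method back-transformed ($SE_\theta = \theta\,SE_{\log\theta}$).
  CV% is $100\,SE/\hat\theta$ and the 95% CI is
  $\hat\theta \pm 1.96\,SE$ on the natural scale, matching the symmetric
  intervals conventionally reported for such fits. Whether published
  intervals of this kind are Wald or profile-based is usually unstated;
  Wald is the assumption here. A simulation check in the test suite finds
  the empirical coverage of the tau interval around 93-94% for a 20-arm
  design — acceptable for a Wald interval with estimated variance.
* **Identifiability.** Each drug needs at least two distinct exposure
  levels (enforced); drugs are processed in lexicographic order so that
  symmetric designs break ties deterministically. The $\tau$-$H$ likelihood
  valley is intrinsically correlated (both enter through $H\log\tau$);
  the optimizer-versus-grid oracle test therefore uses a design with a wide
  spread in $\log(1+k/x)$, where the valley is well-conditioned.

`fit_emax()` applies the same machinery to the single-drug Emax model
(free IC50), the baseline the operational model generalises.

## The tau covariance construction

The joint distribution of $(\tau_{PI}, \tau_{OR})$ is bivariate log-normal:
component means are the per-endpoint means of $\ln\tau$ across drugs and the
covariance is the sample covariance of the per-drug $\ln\tau$ vectors
(denominator $n_{drugs}-1$). Natural logs are used here, even though model
fitting log-transforms concentrations in base 10 — the two scales serve
different objects.

With only two drugs the two-point sample covariance is singular and every
simulated pair falls on a line: the log-scale correlation is exactly
$\pm 1$, which cannot support a meaningful correlation analysis. The package
therefore optionally adds the Wald variances of $\ln\tau$ (approximately
$(CV\%/100)^2$) to the diagonal (`se_inflation`;
`tau_correlation_analysis()` enables this by default). This is a design
decision, not a published construction: how a non-degenerate covariance was
obtained from two drugs in the source analysis is not described, so the
package makes no attempt to reproduce the published correlation
($r = 0.52$) or mean difference ($0.75$) numerically — both the plain and
the inflated construction are available and documented. Sampling is by
eigendecomposition square root (tolerating eigenvalues down to $-10^{-10}$
before declaring the matrix non-PSD), with an explicit integer seed.

The paired t-test and the Pearson correlation with Fisher-z interval use
the textbook formulas (two-sided; sidedness is unstated in the sources this
mirrors) and are cross-checked in the tests against `t.test()` and
`cor.test()`, plus an analytic log-normal-correlation oracle.

## Exposure table and scenario engine

The external PBPK exposure models are out of scope. In their place sits a
plain dose-to-exposure table: one row per drug, dose, EE dose, BMI group
(`lt25`, `25to30`, `ge30`) and inducer (`none`, `CBZ400`, `RIF600`,
`custom`) with a mean Cavg (ng/mL) and a geometric CV. The packaged default
anchors the no-induction, BMI<25 rows to the published steady-state ranges
(0.54-3.63 ng/mL across LNG 30-150 ug; 5.47-43.72 ng/mL dose-proportional
across DRSP 500-4000 ug). The BMI multipliers (0.82, 0.78) and inducer
multipliers (0.55 carbamazepine 400 mg, 0.45 rifampicin 600 mg) are
**illustrative placeholders** — plausible directions and magnitudes for
CYP3A4 induction and body-size effects, but not derived from any study —
and are arguments, not constants. The copy in
`inst/extdata/exposure_synthetic.csv` is generated by
`default_exposure_table()` and named accordingly.

Lookup is exact-match with dose-proportional linear interpolation inside a
stratum; BMI and inducer strata are never interpolated across, and a dose
outside a stratum's hull is an error — silent extrapolation would fabricate
exposure. Virtual subjects are log-normal around the stratum mean with
geometric CV 30% by default (typical inter-individual PK variability for
steroids; the sources state no value), median equal to the stratum mean.
Scenario summaries report the subject-level mean with a 2.5/97.5 percentile
interval (the published interval construction is unstated; percentiles make
no distributional claim). Printed percent changes round half away from zero
to one decimal — the convention evident in published summary tables, which
base R's round-half-to-even would violate — with unrounded values kept
alongside. One published percent-change cell (DRSP 3000/EE 20, rifampicin,
BMI<25) is internally inconsistent with its own printed inputs by 0.1
percentage point; the test suite asserts the value recomputed from the
printed pair (30.4) and documents the discrepancy.

## What the synthetic generator emulates — and what it does not

`generate_arms()` reproduces exactly the statistical structure the fit
assumes: the operational-model mean at specified log10-pmol/L exposures plus
additive $N(0, \sigma_i^2/n)$ noise, untruncated (a very precise arm can
yield a slightly negative observation, as the additive-normal model
implies). Exposure grids are specified directly on the log10-pmol/L scale to
decouple recovery experiments from the exposure fixture. The default
recovery design — 20 arms per drug on $x \in [1.8, 5.2]$ — spans the steep
transition regions of both drugs' curves, which is what makes steep Hill
slopes identifiable; real meta-analytic designs are sparser (a handful of
dose levels), and a sparse preset is available through custom grids.

The generator does **not** emulate: heterogeneity of ovulation-detection
methodology across OR studies; the count nature of pregnancies (PI is
modelled on the continuous additive-error scale throughout, as in the
pooled analysis it mirrors); varying study durations; or between-study
random effects. Passing recovery tests therefore demonstrates correctness
of the estimation machinery under the model's own assumptions — not
robustness to the ways real meta-analytic data violate them.

## Problem sizes and reproducibility

The recovery experiment used by the acceptance script runs 20 replicates of
20 arms/drug at 5000 subjects/arm and refits each — about half a minute on
one core. Unit and property tests use smaller designs (8-20 arms, 100-2000
subjects) chosen to keep the full suite around a minute while leaving
comfortable statistical margins. Every random draw flows from an explicit
integer seed: `run_pipeline()` rerun with the same seed writes byte-identical
files, and this is asserted in the tests.

## Known limitations

* Absolute scenario predictions depend on the placeholder exposure fixture;
  they demonstrate the pipeline, not clinical predictions. Reproducing
  published absolute PI/OR scenario values would require the external PBPK
  virtual-population exposures, which are not available.
* The tau covariance inflation is one defensible construction among
  several; conclusions about the PI-OR correlation are conditional on it.
* Two drugs is the minimum for the class-level claim; the framework is
  written to take more (`drug_spec()` registry, named tau/KD/sigma maps),
  but nothing here validates extrapolation to progestins outside the data.
* Wald intervals degrade near parameter bounds and for near-singular
  Hessians; `fit_operational()` reports `NA` standard errors rather than
  fabricating them when the Hessian cannot be inverted.
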