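# cocer — exposure–response modelling of contraceptive efficacy

`cocer` links dose, average steady-state progestin exposure and the two
efficacy endpoints of hormonal-contraceptive development — the **Pearl Index**
(PI, contraceptive failures per 100 woman-years) and the **ovulation rate**
(OR, percent of women ovulating per treatment cycle) — across progestins with
the Black–Leff **operational model of agonism**. It is written for
pharmacometricians and quantitative clinical pharmacologists who pool
summary-level trial data (model-based meta-analysis) and who need to ask
questions such as: *does a CYP3A4-inducer-driven drop in levonorgestrel or
drospirenone exposure translate into a clinically meaningful loss of
contraceptive efficacy, and how does that depend on BMI?*

## The model

For drug *i*, arm *j*, with x = log10(Cavg in pmol/L) and
kd_i = log10(KD_i in pmol/L):

    E_ij = BL * (1 - Imax * (tau_i * x)^H / ((kd_i + x)^H + (tau_i * x)^H)) + eps_ij,
    eps_ij ~ N(0, sigma_i^2 / n_ij)

* **BL** — endpoint with no drug on board (85 for PI, 100 for OR), fixed;
* **Imax** — maximum fractional suppression (1: full suppression possible), fixed;
* **tau_i** — the transducer constant, the drug's intrinsic efficacy: how
  efficiently receptor occupancy is converted into response;
* **KD_i** — receptor dissociation constant, fixed from literature;
* **H** — Hill factor shared across drugs of the class;
* **sigma_i^2 / n_ij** — residual variance shrinking with arm size, which is
  what makes the naive-pooled maximum-likelihood fit subject-weighted.

Fitting profiles the sigmas out in closed form and maximises the exact
Gaussian likelihood over (tau per drug, H) by bounded quasi-Newton multistart;
uncertainty is Wald (inverse finite-difference Hessian, delta-method
back-transform). Fitted transducer constants feed a bivariate log-normal
simulation of (tau_PI, tau_OR) pairs — paired t-test and Pearson correlation
with Fisher-z interval — and a scenario engine that turns CYP3A4-inducer and
BMI-driven exposure changes into predicted endpoints, percent changes and
incidence-rate ratios (IRR = scenario rate / no-induction reference rate).

Exposure comes from a configurable dose→Cavg table
(`default_exposure_table()`) emulating external PBPK models, anchored to the
published steady-state ranges (0.54–3.63 ng/mL for LNG, 5.47–43.72 ng/mL for
DRSP); its BMI and inducer multipliers are illustrative placeholders, so
scenario outputs demonstrate the machinery rather than reproduce published
absolute predictions.

## Worked example

```r
library(cocer)

## simulate a meta-analytic PI dataset at the published parameters and refit
grid  <- seq(1.8, 5.2, length.out = 20)          # log10 pmol/L
truth <- default_operational_params("PI")
arms  <- generate_arms(synth_design(list(LNG = grid, DRSP = grid),
                                    n_per_arm = 1000, true_params = truth,
                                    seed = 42))
fit <- fit_operational(arms)
print(fit)
#> <op_fit> endpoint PI, converged, 40 arms / 40000 subjects, logLik 100.218
#>            estimate   cv%             ci95
#> tau_DRSP      2.602  0.01   (2.602, 2.602)
#> tau_LNG       3.046  0.01   (3.045, 3.046)
#> hill           9.65  0.04   (9.642, 9.659)
#> sigma_DRSP   0.6308 15.81 (0.4353, 0.8263)
#> sigma_LNG    0.6186 15.81 (0.4269, 0.8103)
#> fixed: baseline=85, imax=1, log10_kd_DRSP=2.949, log10_kd_LNG=3.556
```

The generating transducer constants (3.046, 2.602) and Hill factor (9.653)
are recovered to three decimals; the sigma CIs reflect having only 20
residuals per drug.

```r
## correlation between the PI and OR intrinsic efficacies
d <- build_tau_distribution(
  tau_pi = c(LNG = 3.046, DRSP = 2.602),
  tau_or = c(LNG = 2.172, DRSP = 1.867),
  se_inflation = list(pi = default_tau_cv("PI") / 100,
                      or = default_tau_cv("OR") / 100))
pairs <- simulate_tau_pairs(d, n = 500, seed = 44)
paired_t_test(pairs)$mean_diff     # 0.829 (95% CI 0.804 to 0.854)
pearson_correlation(pairs)$r       # 0.793 (95% CI 0.758 to 0.823)
```

With only two drugs the raw two-point covariance would force a correlation of
exactly ±1; adding the estimation uncertainty of log tau (the `se_inflation`
argument) is what makes the simulated correlation informative. tau_PI sits
consistently above tau_OR: suppressing pregnancy risk takes less intrinsic
efficacy than fully suppressing ovulation.

```r
## DDI x BMI scenario table (illustrative exposure fixture)
ddi <- ddi_summary_table(default_scenarios(seed = 45), truth)
subset(ddi, drug_id == "LNG" & bmi_group == "lt25",
       c(dose_ug, ee_dose_ug, inducer, mean_endpoint, irr, percent_change_printed))
#>    dose_ug ee_dose_ug inducer mean_endpoint   irr percent_change_printed
#> 25     100         20  CBZ400        1.3292 1.392                   39.2
#> 26     100         20    none        0.9549 1.000                    0.0
#> 27     100         20  RIF600        1.5169 1.589                   58.9
#> 34     150         30  CBZ400        1.0705 1.363                   36.3
#> 35     150         30    none        0.7855 1.000                    0.0
#> 36     150         30  RIF600        1.2062 1.536                   53.6
```

Each row is a virtual population of 100 subjects: induction lowers exposure,
which raises the predicted Pearl Index; `irr` and the percent change compare
against the no-induction row of the same stratum.

A thin command-line wrapper over the same functions ships in
`inst/cli/cocer.R` (`fit`, `tau-sim`, `ddi-table`, `synth`, `predict`,
`pipeline` subcommands); `run_pipeline()` is the seeded end-to-end driver.

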