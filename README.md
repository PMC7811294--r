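# glnamm

ODE models of the bidirectional glutamine/ammonium exchange between breast
cancer cells and cancer-associated fibroblasts (CAFs), with least-squares
parameter estimation and parametric-bootstrap uncertainty.

## The problem

In glutamine-hungry tumors, glutaminolysis floods the microenvironment with
ammonium (NH4+), a toxic waste.  CAFs — and, at a cost, the cancer cells
themselves — can convert NH4+ back into glutamine (Gln), drawing on a
composite pool of alternative chemical energy.  This package is for
modelers and experimentalists who want to simulate and fit that exchange:
it implements the monoculture model

    dA/dt = -k1*A*X + c2*k2*W*R*X
    dW/dt =  c1*k1*A*X - k2*W*R*X + h*X
    dR/dt = -k2*W*R*X - k3*R*X
    dX/dt = (r1*A/(K1+A) + r2*R/(K2+R) - d1*W - d2) * X

(A Gln mM, W NH4+ mM, R alternative energy mM, X live cells; cancer cells
have r2 = 0), the merged coculture model (both cell types sharing one
environment), a stress-factor extension (dL/dt = g*X*Y with an extra
per-capita death term m*L^2), and a "renormalized fibroblast"
counterfactual (CAF k2 = 0).  Around the models it provides:

* `simulate_scenario()` — adaptive Dormand-Prince 5(4) integration
  (compiled), lsoda fallback, medium-replenishment hook;
* `generate_data()` — synthetic experiments with the published dosing design
  (Gln 0/1/2/4 mM, NH4Cl 0/5/10/25 mM, triplicate-averaged Gaussian noise);
* `glnfit()` — joint Nelder-Mead least squares over log-transformed
  parameters, with pinning masks and the usual `coef`/`summary`/`predict`/
  `residuals`/`plot` methods;
* `bootstrap_ci()` / `estimate_sigmas()` / `sensitivity_table()` —
  parametric-bootstrap percentile CIs and sensitivity ranking by normalized
  CI width;
* `run_monoculture_suite()`, `run_coculture_suite()`,
  `run_renormalization_comparison()`, `write_report()` — scenario suites
  over the packaged fitted parameter tables (`published_params()`).

## Worked example

Fit the CAF model to a synthetic noisy experiment and bootstrap the three
best-identified parameters:

```r
library(glnamm)

truth <- published_params("caf")
d <- generate_data(design_spec("CAF", noise = 0.3), truth, seed = 42)

init <- params_to_theta(truth)
init[c("r1", "d1", "k1")] <- init[c("r1", "d1", "k1")] * 1.3
fit <- glnfit(d, init = init, free = c("r1", "d1", "k1"))
boot <- bootstrap_ci(fit, n_replicates = 300, seed = 7)
print(boot)
```

```
Parametric bootstrap: 300 replicates (0 failed), 95% percentile CIs, seed 7
    estimate    ci_low   ci_high
r1 2.557e-02 2.490e-02 2.610e-02
d1 1.298e-03 1.255e-03 1.333e-03
k1 4.342e-07 4.149e-07 4.519e-07
noise variances (weighted scale): CAF=0.02221
```

The generating values (r1 = 2.5e-2 1/h, d1 = 1.3e-3 1/(mM h),
k1 = 4.13e-7 1/(cell h)) fall inside the r1 and d1 intervals; k1 sits just
below its lower bound on this seed, as a 95% interval will do for roughly
one parameter draw in twenty (the package's calibration test measures
89-92% empirical coverage per parameter over 100 experiments).  The estimated
noise variance 0.022 on the weighted scale corresponds to the injected
per-replicate SD 0.3 averaged over triplicates (0.3^2/3 = 0.03) less the
variance absorbed by truncation at zero.  The normalized interval widths
(`sensitivity_table(boot)`) reproduce the sensitivity reading: narrow
intervals for r1 and d1 mean the data pin those parameters down tightly.

Simulate the coculture and the renormalization counterfactual:

```r
cs <- run_coculture_suite(variant = "coculture_merged", nh4_doses = 5,
                          gln_dose = numeric())
cs$composition[, c("time_h", "cells_total", "pct_cc")]
#   time_h cells_total   pct_cc
# 1      0    80000.00 50.00000
# 2     24    72094.64 47.63482
# 3     48    72719.19 48.06805
# 4     72    73565.23 48.25808

rn <- run_renormalization_comparison(dose = 5)
rn$delta[4, c("total_merged", "total_normalized")]
#   total_merged total_normalized
# 4     73565.23         45496.15
```

The live-cell composition stays near 1:1 under 5 mM NH4+, and removing the
CAFs' recycling capacity (k2 = 0) drops the 72-h population by roughly 40%
— the model's case for fibroblast renormalization as a therapy concept.

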