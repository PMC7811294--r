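---
title: "Modeling bidirectional glutamine/ammonium exchange between cancer cells and CAFs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling bidirectional glutamine/ammonium exchange between cancer cells and CAFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glnamm)
```

## The model

Solid tumors behave like small ecosystems: cancer cells (CC) consume
glutamine (Gln) at high rates, and the ammonium (NH4+) produced by
glutaminolysis accumulates as a toxic waste.  Cancer-associated fibroblasts
(CAF) — and, at a price, the cancer cells themselves — can convert NH4+ back
to Gln, drawing on a composite pool of other metabolites ("alternative
chemical energy") to do so.  `glnamm` implements deterministic ODE models of
this exchange at three levels.

**Monoculture.**  With $A$ the Gln concentration (mM), $W$ the NH4+
concentration (mM), $R$ the alternative-energy pool (mM) and $X$ the
live-cell count, the single-cell-type model is

$$
\begin{aligned}
\dot A &= -k_1 A X + c_2 k_2 W R X, \\
\dot W &= c_1 k_1 A X - k_2 W R X + h X, \\
\dot R &= -k_2 W R X - k_3 R X, \\
\dot X &= \Big( r_1 \tfrac{A}{K_1+A} + r_2 \tfrac{R}{K_2+R}
          - d_1 W - d_2 \Big) X.
\end{aligned}
$$

$k_1$ is the per-cell Gln→NH4+ conversion rate and $c_1$ its yield; $k_2,
c_2$ describe the reverse conversion, which also consumes $R$; $h$ is basal
NH4+ production; $k_3$ a conversion-independent drain on $R$.  Growth is
Monod-type on Gln ($r_1$, $K_1$) and, for CAFs only, on the alternative pool
($r_2$, $K_2$); death is linear in NH4+ ($d_1$) plus a background rate
($d_2$).  Cancer cells cannot grow on the alternative pool, so their set has
$r_2 = 0$ exactly and $K_2$ is inert (kept in the type so one container
serves both cell types).  Every term carries a factor $X$, which gives the
key structural guarantees: nothing happens without cells, each state's
derivative is nonnegative on its zero boundary (so trajectories stay
nonnegative), $R$ is nonincreasing, and in the limit $c_1 = c_2 = 1$, $h=0$
the total $A + W$ is conserved.  These are exactly the properties the test
suite checks, symbolically per equation and numerically along randomized
trajectories.

**Merged coculture.**  The coculture model is the union of the CAF equations
(cell count $X$) and the CC equations (cell count $Y$) sharing one
environment $(A, W, R)$; each conversion/production/consumption term appears
twice, once per cell type with its own constants.  Units are natural (mM,
cells, hours) throughout, so published table values drop in verbatim.

**Stress extension.**  The merged model reproduces the observed composition
but not the concave decline of the total population after 48 h.  The stress
variant adds a dimensionless crowding factor $L$ with $\dot L = g X Y$,
$L(0) = 0$, and an extra per-capita loss $-mL^2$ in both growth equations —
a pure loss that grows quadratically, so it only bites late in the run.  The
merged model is the special case $g = m = 0$.

**Renormalization counterfactual.**  A therapy that returns CAFs to normal
fibroblast behavior is modeled by setting the CAF $k_2$ to zero (variant
`coculture_normalized`): fibroblasts stop recycling NH4+ to Gln, and the
total population declines faster.

The fitted parameter sets for both cell types, the two adjusted coculture
growth rates, and the stress constants ship as plain-text fixtures
(`published_params()`); tests pin their checksums so they cannot drift
silently.

## Simulation

`simulate_scenario()` integrates any variant with an adaptive Dormand–Prince
5(4) Runge–Kutta pair implemented in compiled code, with relative tolerance
$10^{-8}$ and absolute tolerance $10^{-10}$ per component by default.  The
dynamics at the published values are only mildly stiff, and an explicit
embedded pair is accurate and fast enough that the fitting loops below can
afford roughly a million integrations; `solver = "lsoda"` (via **deSolve**)
is available as a stiff fallback.  Correctness is cross-checked in the tests
against a fixed-step explicit-Euler oracle with step $10^{-3}$ h whose
right-hand sides are written out independently, and against `deSolve`.
States are clipped to zero only within solver tolerance ($10^{-6}$ by
default); any larger negative excursion raises an error rather than being
masked.  Cell counts are integrated as continuous quantities — the
deterministic reading of the model, with no demographic stochasticity.  Time
is hours everywhere; configuration values in days are rejected, not
converted.  A `r_reset` hook supports the medium-replenishment thought
experiment (reset $R$ at a chosen time).

```{r sim-example}
tr <- simulate_scenario(scenario("caf_mono", A0 = 4, X0 = 8e4),
                        published_params("caf"))
tr$states
```

## The synthetic-data generator

The raw culture data behind the published fits are not redistributable, so
the package generates synthetic experiments with the same design:
monocultures seeded at $8\times10^4$ cells, dosed with Gln at 0/1/2/4 mM or
NH4Cl at 0/5/10/25 mM (one scenario per dose, including the 0 doses);
cocultures seeded 1:1 at the same total; $R(0) = 20$ mM in all scenarios;
observations at 0/24/48/72 h.  Each reported observation is the average of
three independently noised replicates, mimicking triplicate averaging; the
measurement model is additive Gaussian (no process noise), matching the
error model assumed by the bootstrap.

Noise is specified on the *weighted* scale of `stream_weights()`
(concentrations in mM, counts in units of $10^4$ cells) so a single
per-cell-type sigma spans streams of different physical units.  The default
per-replicate SD of 0.3 corresponds to 0.3 mM on a concentration assay and
3,000 cells on an automated count at a seeding density of $8\times10^4$ —
typical for colorimetric kits and automated counters at these scales.
Averaged observations are truncated at zero (a physical constraint) and cell
counts rounded to whole cells; with zero noise the generator returns the
model output exactly.

Two features of real data the generator deliberately does not emulate:
heteroscedastic (proportional) measurement error, and the truncation-induced
variance loss near zero.  The latter is visible in the package's own
calibration test: pooled variance estimates are slightly conservative when
many observations sit near zero, so the calibration property is asserted on
the cell-count stream, whose values sit far from the boundary.  Passing
tests therefore demonstrate correct inference under the stated additive
error model, not robustness to assay-specific error structure.

## Fitting

`glnfit()` minimizes
$$ F(\theta) = \sum_k \lvert u(t_k;\theta) - w(t_k)\rvert^2 $$
over all data points of all scenarios of one cell type jointly — Gln-dosed
and NH4+-dosed alike — where $u$ is the model solution and $w$ the
observations, each stream first divided by its weight scale.  The raw
(unweighted) sum would be dominated entirely by cell counts, which are four
to five orders of magnitude larger than the concentrations; the default
scales make stream magnitudes comparable, and
`stream_weights("unweighted")` restores the literal sum for comparison.

Minimization is Nelder–Mead (`stats::optim`) over log-transformed free
parameters, so positivity is enforced by the transform rather than by
penalties.  Because the simplex can stall in 10–12 dimensions, the optimizer
restarts deterministically from the incumbent best vertex (twice by
default); the whole fit is deterministic given data, start and options.  A
parameter-vector that breaks the integration is assigned a large finite
penalty ($10^{12}$) so the simplex can step past it.  Any subset of
parameters can be pinned via the `free` mask — pinned values are returned
bit-identical — which reproduces the published coculture refit strategy of
freeing only the two growth rates.  Initial conditions during fitting are the
nominal design values (dosed concentrations, $R_0 = 20$, $8\times10^4$
cells); `use_measured_t0 = TRUE` substitutes the measured $t=0$
concentrations instead.  Scenarios with 0 mM dosing take part in the joint
fit whenever they are present in the dataset.

On noiseless synthetic data at the published CAF values, a joint fit of all
12 parameters from a start perturbed by a factor of 2 recovers the sensitive
parameters $r_1$, $d_1$, $k_1$ to well under 5% relative error; weakly
identified parameters ($r_2$, $K_2$, $d_2$) are not pinned down by this
design, which is exactly what the sensitivity analysis below quantifies.

## Bootstrap confidence intervals and sensitivity

The error model is $d = d_\psi + \varepsilon$ with independent mean-zero
Gaussian components per cell type.  `estimate_sigmas()` pools weighted
residuals within each error group (per cell type by default; coculture
concentration streams form a shared third group; per-stream grouping is
available) and returns unbiased sample variances.  `bootstrap_ci()` then
simulates replicate datasets at the fitted parameters plus that noise,
truncates negatives at zero, refits each replicate from the point estimate,
and takes percentile intervals (2.5th/97.5th for the default 95% level; a
normal-approximation alternative is available).  The published analysis used
300 replicates; everything is reproducible bit-for-bit given the seed, and
zero estimated noise collapses every interval to zero width.

`sensitivity_table()` turns intervals into a sensitivity ranking: each
parameter's bounds are divided by its point estimate and parameters are
sorted by relative width, narrowest first.  A narrow normalized interval
means the objective deteriorates quickly when the parameter moves, i.e. the
parameter is well identified.  Applied to the published tables, the Gln
growth rate $r_1$ and the NH4+ death rate $d_1$ rank among the narrowest
intervals for both cell types:

```{r sens}
tab <- published_params("caf", ci = TRUE)
names(tab)[names(tab) == "value"] <- "estimate"
head(sensitivity_table(tab), 5)
```

## Scenario suites

`run_monoculture_suite()`, `run_coculture_suite()` and
`run_renormalization_comparison()` reproduce the computational experiments
end-to-end from the packaged fixtures: dose panels per cell type, coculture
composition tracking ($\%CC$ computed on live counts only, as the model
tracks live cells), and the renormalization comparison at 5 mM NH4+.
Qualitative statements are encoded as explicit tolerance bands in the tests
— e.g. "composition stays roughly 1:1" becomes $\%CC \in [40\%, 60\%]$
through 72 h at 5 mM NH4+ — and these bands are engineering choices of this
package, not published numbers.  `write_report()` writes all tables as tidy
tab-separated text with a `run_info.txt` logging seed, solver settings and
package version; reports are byte-identical across reruns.

```{r coculture}
cs <- run_coculture_suite(variant = "coculture_merged", nh4_doses = 5,
                          gln_dose = numeric())
cs$composition
```

## Design notes and numerical choices

* **Equation typography.** The source equations print one conversion term
  with a lowercase "x"; the units of $k_2$ (1/(cell·mM·h)) force the factor
  to be the cell count, and it is implemented uniformly as $X$.  Similarly a
  growth-rate unit printed as h$^{-2}$ is dimensionally h$^{-1}$.
* **Weighting of the objective.** Whether the published fits rescaled
  streams is not documented; both modes are provided and the scaled mode is
  the default (see above).
* **Stress constants.** Whether $g$ and $m$ were fitted or hand-tuned is not
  documented; they are treated as given constants, with fitting optionally
  enabled by freeing them.
* **Optimizer internals.** Published work names only the Nelder–Mead
  algorithm.  This package uses `stats::optim`'s simplex construction with
  deterministic restarts; a maximum of $10^5$ function evaluations is more
  than any fit here needs.
* **CI method.** Only "95% confidence intervals" is documented; the
  percentile method is the default, normal approximation optional.
* **Interfaces.** The package's surface is its exported functions, the test
  suite, and `scripts/acceptance.R`; no shell CLI is shipped, since every
  suite operation is a one-line R call.
* **Problem sizes.** The test suite scales Monte-Carlo components to
  desk-scale sizes chosen once: 100 randomized scenarios for the invariant
  sweep, 100 synthetic experiments with 50 bootstrap replicates each for the
  calibration check, 200 repetitions for the variance-estimator calibration,
  and one full 300-replicate bootstrap matching the published replicate
  count.

## Limitations

The models assume a well-mixed environment (no spatial structure), a single
composite alternative-energy pool that is never decomposed into actual
metabolites, measurement noise that is additive, homoscedastic and
independent across observations, and deterministic population dynamics.
Identifiability is uneven by design: with the 72-h, four-time-point design
several parameters (notably $r_2$, $K_2$, $h$) carry wide intervals, and
conclusions about them should rest on the sensitivity ranking, not the point
estimates.
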