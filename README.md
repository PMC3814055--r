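# radvol

Tumor volume regression modelling for fractionated radiotherapy.

Serial CT volumetry during a course of radiotherapy carries early
information about treatment response, but turning measured volumes into a
prediction needs a mechanistic model. `radvol` implements a clinically
minimal one: a modified linear-quadratic (LQ) cell-survival law combined
with a two-compartment cell-population model, for radiation oncologists,
medical physicists and modellers who want to simulate volume regression
under arbitrary fractionation schedules and fit the model to measured
volume time series.

## The model

Per fraction of dose $D$ (Gy), the surviving fraction is

$$S = e^{-A\,(\alpha D + \beta D^2) + B}$$

where $\alpha$ (Gy⁻¹) and $\beta$ (Gy⁻²) are the usual LQ coefficients,
$A > 0$ rescales the lethal-event count (hypoxia, potentially lethal
damage, microenvironment) and $B$ absorbs kill outside the
$\alpha/\beta$ bookkeeping (e.g. single-strand-break damage leading to
reproductive death). $A = 1, B = 0$ recovers the conventional LQ model
$S_0 = e^{-(\alpha D + \beta D^2)}$.

The tumor is a viable pool $N_l$ plus a lethally damaged pool $N_d$. Each
fraction moves $(1-S) N_l$ into the damaged pool (total conserved at the
instant of irradiation); between events

$$N_l \mapsto N_l e^{\lambda \Delta t}, \quad
  N_d \mapsto N_d e^{-\mu \Delta t}, \qquad
  \lambda = \tfrac{\ln 2}{T_{pot}}, \quad \mu = \tfrac{\ln 2}{T_{1/2}},$$

with $T_{pot}$ the potential doubling time and $T_{1/2}$ the clearance
halving time of damaged cells. Volume is proportional to the total count:
$V(t) = V_0 (N_l + N_d)$ with the initial count normalized to 1.

Fitting estimates $(A, B)$ by deterministic least squares (grid search
plus bounded local refinement) and scores fits with
$R^2 = 1 - \mathrm{SS}_{res}/\mathrm{SS}_{tot}$ against the zero-parameter
conventional comparator ($R_0^2$). A key structural caveat, documented in
the vignette: under a uniform-dose schedule $A$ and $B$ are only jointly
identifiable through the per-fraction survival; separating them requires
dose variation, provided by the designed two-level `probe_schedule()`.

## Worked example

Simulate a patient under a two-level probe schedule (2 Gy at day 0, 8 Gy
at day 10), add 5 % lognormal measurement noise, and fit:

```r
library(radvol)

sched <- probe_schedule()
kin   <- kinetic_params(t_pot = 5.5, t_half = 40.5)   # lung kinetics, days

noisy <- generate_trajectory(synthetic_patient(
  v0 = 80, t_half = 40.5, corr_a = 0.6, corr_b = -1.5,
  schedule = sched, sample_times = c(0, 14, 28, 42),
  noise_cv = 0.05, seed = 2024))
noisy
#> # A tibble: 4 × 3
#>   time_days volume_true_cm3 volume_cm3
#>       <dbl>           <dbl>      <dbl>
#> 1         0            80         84.0
#> 2        14            90.3       92.4
#> 3        28            74.5       74.1
#> 4        42            78.8       77.9

cmp <- compare_models(noisy[, c("time_days", "volume_cm3")], sched, kin)
cmp
#> Modified-LQ volume fit
#>   A = 0.5751, B = -1.6394  (bounds A [0.01, 3], B [-5, 1])
#>   R^2 = 0.9893, RSS = 2.057 (absolute residuals), 4 timepoints, converged: TRUE
#>   conventional comparator R0^2 = -60.4597
```

The fitted correction factors (0.58, −1.64) sit close to the ground truth
(0.6, −1.5) despite the noise; $R^2 = 0.989$ says the modified model
explains 98.9 % of the measured volume variance, while the negative
$R_0^2$ says the conventional model — which for these parameters kills far
too few cells — predicts worse than the mean of the measurements. Results
are tidyverse-friendly (`tidy()`, `glance()`, `augment()`,
`ggplot2::autoplot()`), and `radvol_cli()` (or
`Rscript inst/scripts/radvol.R`) exposes `simulate`, `fit`, `synth` and
`compare` workflows over CSV/YAML/JSON files.

`validation_cohort()` ships the reported per-patient summaries of the
nine-patient clinical validation cohort (initial volumes, halving times,
fitted factors and scores) for cohort-level arithmetic.

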