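---
title: "Modelling tumor volume changes during fractionated radiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tumor volume changes during fractionated radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radvol)
library(dplyr)
```

## The model

radvol models the volume of a tumor under a fractionated course of
radiotherapy with two coupled components.

**Cell survival.** The conventional linear-quadratic (LQ) law puts the mean
number of lethal events per cell at $N = \alpha D + \beta D^2$ for a
fraction of dose $D$ (Gy), giving a surviving fraction $S_0 = e^{-N}$. The
modified law adds two correction factors,

$$S = e^{-A(\alpha D + \beta D^2) + B},$$

where $A > 0$ rescales the double-strand-break term — absorbing hypoxia,
potentially lethal damage repair and microenvironment effects that modulate
the effective event count — and $B$ (any sign; clinically fitted values are
negative) absorbs kill through mechanisms outside the $\alpha/\beta$
bookkeeping, such as single-strand-break damage leading to reproductive
death. Setting $A = 1$, $B = 0$ recovers the conventional model exactly,
so the conventional model is nested in the modified one.

**Population kinetics.** The tumor is a two-compartment cell population:
viable cells $N_l$ and lethally damaged cells $N_d$. Each fraction $k$
instantaneously moves the killed complement into the damaged pool,

$$\bar N_{l,k} = N_{l,k-1}\,S, \qquad
  \bar N_{d,k} = N_{d,k-1} + N_{l,k-1}(1 - S),$$

conserving the total count at the instant of irradiation. Between events
the viable pool regrows and the damaged pool clears exponentially,

$$N_{l}(t + \Delta t) = N_l(t)\, e^{\lambda \Delta t}, \qquad
  N_{d}(t + \Delta t) = N_d(t)\, e^{-\mu \Delta t},$$

with $\lambda = \ln 2 / T_{pot}$ set by the potential doubling time and
$\mu = \ln 2 / T_{1/2}$ by the volume halving time of damaged-cell
clearance. Tumor volume is proportional to the total count; because the
per-cell volume and the absolute cell number are unobservable from volume
data, radvol normalizes the initial total count to 1 and carries the
initial measured volume $V_0$ as the scale: $V(t) = V_0\,(N_l + N_d)$.

This is a deliberate simplification of four-level population models with
explicit oxygenated/hypoxic compartments and a reoxygenation rate: those
quantities are rarely measurable in routine clinics, and their net effect
is folded into $A$ and $B$.

## Parameters and defaults

| Parameter | Meaning | Unit | Default |
|---|---|---|---|
| `alpha` | linear LQ sensitivity | Gy⁻¹ | 0.35 |
| `beta`  | quadratic LQ sensitivity | Gy⁻² | 0.035 ($\alpha/\beta = 10$ Gy) |
| `corr_a` | multiplicative correction $A$ | — | fitted; bounds [0.01, 3] |
| `corr_b` | additive correction $B$ | — | fitted; bounds [−5, 1] |
| `t_pot` | potential doubling time | d | 5.5 (lung), 4.5 (cervix) |
| `t_half` | damaged-cell halving time | d | patient-specific input |

$\alpha$ and $\beta$ are assumed, not fitted. Because $A$ multiplies
$\alpha D + \beta D^2$, a fitted $\hat A$ is only meaningful *relative to*
the assumed $\alpha, \beta$: halving $\alpha$ and $\beta$ doubles $\hat A$.
Any comparison of fitted correction factors across studies must state the
assumed radiosensitivity. $T_{1/2}$ and $T_{pot}$ are treated as fixed
per-patient inputs, never co-fitted.

## Conventions and numerical choices

* **Time axis.** Day 0 is the first volume measurement; fraction times
  live on the same axis, in days. All constants are per day.
* **Event ordering.** When a fraction time coincides with an evaluation
  time the fraction is applied first ("post-fraction" reporting). A
  consequence: the reported volume at a day-0 fraction equals $V_0$,
  because irradiation conserves the total count.
* **Between and after events.** Evaluation at arbitrary times uses the
  same exponential laws over the partial interval — the unique
  continuous-time extension of the per-interval update. After the final
  fraction, viable regrowth at rate $\lambda$ continues indefinitely; no
  plateau is imposed.
* **$S > 1$ is possible** when $B > 0$ outweighs the kill term. radvol
  computes the law as written and warns rather than clamping: silently
  capping at 1 would hide an ill-posed parameter region from the
  optimizer, which instead excludes it via bounds. The exponent is formed
  in log space; at extreme doses survival underflows to 0, which is
  accepted.
* **Degenerate inputs.** A constant measured series makes $R^2$ undefined
  (zero total sum of squares) and is a hard error, as are non-positive
  volumes, unsorted times, non-increasing fraction times and fewer than
  3 measured timepoints for the 2-parameter fit.

## Fitting and scoring

`fit_correction_factors()` minimizes the sum of squared volume residuals
between the forward simulation and the measurements, with $V_0$ taken from
the first measurement. The reported score is
$R^2 = 1 - \sum(y - \hat y)^2 / \sum(y - \bar y)^2$, computed on absolute
volumes; the conventional comparator $R_0^2$ scores the same dynamics with
$A = 1$, $B = 0$ and no free parameters.

The optimizer is deterministic by construction: a 21 × 21 grid over the
bound box seeds L-BFGS-B refinements from the 5 best cells, followed by an
iterated Nelder–Mead polish (relative tolerance $10^{-15}$, up to 4
restarts). The polish matters: the (A, B) sum-of-squares surface has a
long, curved, nearly degenerate valley (see the next section) in which
quasi-Newton steps stall short of the floor. The conventional point
$(1, 0)$ is always included as a start whenever it lies inside the bounds,
which guarantees $R^2 \ge R_0^2$ up to optimizer tolerance — the empirical
nesting property. Identical inputs yield bit-identical results. If every
local refinement fails, the best grid cell is returned with
`converged = FALSE` rather than an exception.

Residuals are minimized in absolute volume (cm³) by default; a
`residual_space = "relative"` switch normalizes by $V_0$. For a single
series the two objectives differ by a constant factor, so the fitted
parameters coincide; the switch exists because "least squares" on volume
data is ambiguous between the two readings, and the objective value is
reported in the chosen space.

Cohort summaries (`summarize_cohort()`) report both the plain arithmetic
mean and the mean over non-negative values only. The latter is reported
because published cohort means of comparator scores are consistent with
dropping negative $R_0^2$ entries; both are always labelled and neither is
silently preferred.

## Identifiability: why recovery studies use a designed probe schedule

A structural property of the model dictates the design of every
parameter-recovery experiment in this package. Under a **uniform-dose
schedule** — e.g. the conventional 2 Gy × 25 course — every fraction has
the same survival $S = e^{-A N(d) + B}$, and the entire volume trajectory
depends on $(A, B)$ only through that one scalar. Every pair on the line
$-A\,N(d) + B = \log S$ reproduces the data *exactly*: $A$ and $B$ are
structurally non-identifiable, and any least-squares point estimate from a
uniform course is an arbitrary point on a ridge. (The composite
$\log S$ — equivalently the per-fraction survival — *is* identifiable, and
fits to uniform-schedule data still achieve their $R^2$; only the split
into $A$ and $B$ is undetermined.)

Two distinct dose levels break the degeneracy in principle, but not in
practice if the second level arrives late: after a handful of fractions
the viable pool is depleted by orders of magnitude, and late fractions
leave numerically invisible signatures. radvol therefore exposes
`probe_schedule()`, a designed two-fraction experiment — 2 Gy at day 0 and
8 Gy at day 10 — in which both survival levels act on an appreciable
viable pool and are separately observable from a four-point series
(days 0, 14, 28, 42). Under this design the noiseless 3 × 3 truth grid
$A \in \{0.2, 0.5, 0.8\} \times B \in \{-3, -1.5, -0.5\}$ is recovered to
relative error below $10^{-9}$.

The practical implication for clinical fits is sobering and worth stating
plainly: correction factors fitted to a uniform-dose course should be
interpreted only through their composite per-fraction survival, not as
separately meaningful $A$ and $B$.

## The synthetic cohort generator

`generate_cohort()` emulates the validation setting: initial volumes drawn
uniformly from 7.6–375.2 cm³ and halving times from 13.9–90.6 days (the
reported nine-patient ranges), cohort-specific $T_{pot}$, ground-truth
$A \sim U(0.15, 0.9)$ and $B \sim U(-3, -0.4)$ (bracketing the reported
fits), the conventional 2 Gy × 25 regimen with weekend gaps, and four
samples at 14-day intervals — the coarser end of the reported one-to-two
week CT cadence. Measurement noise is multiplicative lognormal with
median 1 and a given coefficient of variation (default 5%), on the grounds
that CT contouring error scales with the volume being contoured. Noise is
seeded per patient; the noiseless trajectory is seed-independent, and
generation restores the global RNG state.

What the generator does **not** emulate: real contouring errors are
temporally correlated (the same oncologist contours consecutive scans),
schedules vary across and within patients (gaps, boosts, replans), volumes
can include non-tumor tissue, and $T_{1/2}$ is itself estimated from the
same scans rather than known. Passing recovery tests on synthetic data
therefore demonstrates the correctness and conditioning of the estimation
machinery, not the clinical accuracy of the model.

## Problem sizes in the test suite

The shipped tests exercise: conservation on $10^4$ random states;
closed-form agreement for 1–30 uniform fractions at relative tolerance
$10^{-10}$; the conventional-model identity on $10^3$ random draws at
machine precision; the noiseless 3 × 3 recovery grid at $10^{-4}$ relative
tolerance; model nesting on 100 synthetic patients; and a 200-replicate
Monte-Carlo recovery study at 5% noise (median absolute errors and the
$R^2$ distribution). The full suite completes in well under a minute on a
single CPU.

## Known limitations

* Per-patient reproduction of published clinical fits is impossible from
  public information: the measured trajectories and fraction schedules
  were not published. The package reproduces the cohort arithmetic and the
  model's property surface instead.
* The fitted $(A, B)$ from uniform-dose courses are ridge points (above);
  only their composite survival is interpretable.
* No uncertainty quantification beyond residuals — point fits only, as in
  the clinical analysis the model accompanies.
* No hypoxic compartment, reoxygenation, cell-cycle structure or
  stochastic birth–death dynamics; regrowth after the course is unbounded
  exponential.

## A worked example

```{r example}
sched <- probe_schedule()
kin <- kinetic_params(t_pot = 5.5, t_half = 40.5)
truth <- lq_params(corr_a = 0.6, corr_b = -1.5)

obs <- simulate_course(sched, c(0, 14, 28, 42), v0 = 80, truth, kin)
obs

cmp <- compare_models(obs[c("time_days", "volume_cm3")], sched, kin)
tidy(cmp)
glance(cmp)
```

```{r plot, fig.width = 6, fig.height = 4}
ggplot2::autoplot(cmp)
```
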