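---
title: "Methods: spatial adjustment and canopy phenomics for MAD trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial adjustment and canopy phenomics for MAD trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopytrial)
```

`canopytrial` analyses unreplicated field trials laid out as a Type-II
Modified Augmented Design (MAD) and the season-long canopy phenotypes
measured on them. This vignette is the package's account of the models it
implements, the choices made where the methods literature leaves the
design open, and what the synthetic-trial generator does and does not
emulate.

## The design and the spatial-adjustment model

A Type-II MAD arranges unreplicated test plots in rectangular blocks
(whole plots), 5 × 5 by default. One *primary check* genotype is planted
at the central cell of every block; two *secondary check* genotypes each
appear once per block at uniformly random non-central cells. The primary
check, being replicated at a known position in every block, carries the
information about smooth field trend; the secondary checks, replicated
across blocks but not within, measure how much plot-to-plot error remains
after any correction.

**Method I (adjustment by design structure).** The primary-check values
are modelled additively over the *whole-plot grid* — the rows and columns
of blocks, not of individual plots:

$$Y^{check1}_{ijk} = \mu + R_i + C_j + \varepsilon_{ijk},$$

and every plot in block-row $i$, block-column $j$ is corrected by

$$Y^{adj}_{ij} = Y_{ij} - R_i - C_j + 2\mu,$$

with $R_i$, $C_j$ the primary-check means of the plot's block-row and
block-column and $\mu$ the primary-check grand mean. Indexing at the
whole-plot grid is the construction under which the correction can cancel
an additive row/column gradient exactly: each block-row and block-column
contains one primary check per block, so the means are estimable
everywhere. (Indexing at the plot grid would leave most rows without any
check; the package falls back to $R_i = \mu$ for such rows, which defines
behaviour on sparse layouts but cannot remove a plot-level gradient.)
Exact cancellation additionally requires the blocks to tile a *complete*
rows × columns grid, so the row and column means weight the effects
evenly; the tests and verification studies use complete grids (3 × 3,
2 × 5, 5 × 2).

**Method III (adjustment by regression).** Per block, the primary-check
value is regressed (OLS across blocks) on the average of the two
secondary checks; plots are corrected by

$$Y^{adj}_{ij} = Y_{ij} - \beta\,(\mathrm{Check1}_{block} -
\overline{\mathrm{Check2}}) + \alpha.$$

The reference level $\overline{\mathrm{Check2}}$ is not subscripted in
the published formula; the package defaults to the grand mean of the
per-block secondary-check averages, with a per-block variant behind
`check2_reference = "block"`. $\alpha$ is added exactly as printed. If the
secondary-check averages are constant across blocks the slope is
undefined and Method III reports itself unavailable; selection then
considers Method I only.

**Deciding whether to adjust.** The intra-whole-plot error pools each
secondary check's squared deviations from its own across-block mean:

$$\mathrm{IWP} = \frac{SS_1 + SS_2}{2\,(n_1 + n_2 - 2)},$$

the pooled-variance form consistent with the printed divisor ("sums of
squared differences" is not defined more precisely in the design
literature as cited; the within-check deviation form is the reading whose
degrees of freedom match). Relative efficiency is
$RE = 100 \cdot \mathrm{IWP}_{raw} / \mathrm{IWP}_{adj}$, and the
three-rule criterion applies: both $RE < 100$ → no adjustment; one
$\ge 100$ → that method; both $\ge 100$ → the higher, with an exact tie
going to Method I because it uses the design structure (more plots inform
it). Strata (location × spacing) are adjusted independently. Edge
conventions: $RE$ with both errors zero is defined as 100 (no
information); a zero adjusted error with positive raw error reports
$+\infty$ with a warning.

## Time-course models and temporal parameters

Each plot × trait series is fit with three candidates:

* **LOWESS** — robust local quadratic regression (`stats::loess`,
  `family = "symmetric"`, three robustness iterations), span 0.5 by
  default. AIC/BIC for the smoother use a Gaussian likelihood with
  effective degrees of freedom equal to the trace of the smoother matrix,
  the standard construction when an information criterion is needed for a
  nonparametric fit.
* **Logistic** — $A/(1 + e^{-r(t - m)})$ fit by bounded
  Levenberg–Marquardt least squares with up to five data-driven starts.
  The rate is constrained positive (a growth model); an estimate pinned at
  its bound is reported as non-convergence rather than a fit, which is how
  monotone-decreasing or non-sigmoidal series surface.
* **Quadratic** — second-degree polynomial by OLS.

All models are scored by MAE, RSS, RMSE, $R^2$, AIC and BIC under the
same profiled-σ Gaussian likelihood (the AIC/BIC constants therefore
match `stats::AIC` on the equivalent `lm`). Selection takes the lowest
AIC among converged fits, breaking ties by BIC then RMSE.

Temporal parameters are read off the selected fit evaluated on a dense
0.1-day grid: the peak (argmax; flagged censored on the window boundary),
threshold crossings for percentage traits with linear interpolation
between grid points (full canopy closure operationalised as the 99.5%
crossing — a fitted asymptote never literally attains 100), and the
decline onset: the first day at or after the peak where the fit has
dropped below $(1-\delta)$ of the peak and stays below for at least three
consecutive grid days.

**Choice of $\delta$.** The default is $\delta = 0.03$. A smaller drop
(e.g. 1%) is below the smoother's own resolution: around a
plateau-to-decline corner a span-0.5 local fit sits 1–2% below the
plateau *before* the decline starts, so a 1% criterion dates the onset
systematically ~4 days early at seasonal sampling densities, while 3%
tracks the true onset nearly unbiasedly (97% within ±3 days at
twice-weekly sampling in the package's Monte-Carlo study). Both $\delta$
and the closure threshold are arguments.

## Image indices, segmentation, and digital biomass

Images are `(H, W, 4)` arrays, channels R, G, B, NIR in $[0, 1]$ — one
convention, stated once. Vegetation is separated from soil by thresholding
the Excess Green index $2G - (R + B)$; the thresholding method is not
fixed by the phenomics literature, so the default is Otsu's criterion
computed *exactly* (exhaustive minimisation of within-class variance over
candidate thresholds between consecutive distinct values) rather than on
a binned histogram, with a fixed threshold available. Canopy coverage is
the percentage of vegetation pixels inside a half-open rectangular plot
boundary; polygon zones are out of scope. NDVI is $(NIR - R)/(NIR + R)$,
masked where the denominator is zero, summarised by the zonal mean by
default (the mean and median are nearly interchangeable on real canopies;
the mean is the convention carried forward).

Digital biomass voxelises a plot's point cloud on a grid anchored at the
cloud's minimum corner: a voxel is occupied when at least one point falls
in it, volume is occupied-voxel count × voxel³, and digital biomass is
volume over footprint area (m³ m⁻²). The anchored one-point occupancy
rule is exactly testable: for a solid box the counted volume lies within
a one-voxel shell of the analytic volume and converges as the voxel
shrinks. The default voxel size is an argument (0.05 m in the examples);
no canonical value exists for gantry LiDAR.

## FvCB A–Ci fitting

Net assimilation is the minimum of the Rubisco-limited and
RuBP-regeneration-limited rates minus day respiration:

$$W_c = \frac{V_{cmax}(C_i - \Gamma^*)}{C_i + K_c(1 + O/K_o)}, \quad
W_j = \frac{J(C_i - \Gamma^*)}{4C_i + 8\Gamma^*}, \quad
A = \min(W_c, W_j) - R_d.$$

Mesophyll conductance is treated as infinite, so all parameters are
apparent, $C_i$-based values. Kinetic constants and their Arrhenius
activation energies are the Bernacchi in-vivo calibration
($K_{c,25} = 404.9$ µmol mol⁻¹, $H_a$ 79.43 kJ mol⁻¹;
$K_{o,25} = 278.4$ mmol mol⁻¹, 36.38; $\Gamma^*_{25} = 42.75$ µmol mol⁻¹,
37.83; $V_{cmax}$ 65.33; $R_d$ 46.39; $J$ 43.9 from the companion
calibration). Fitting minimises the residual sum of squares — the
maximum-likelihood estimate under Gaussian error — with a derivative-free
Nelder–Mead simplex on the log-parameter scale (positivity for free),
started from a coarse grid over $V_{cmax} \in [20, 250]$,
$J \in [40, 400]$, $R_d \in [0.1, 5]$, with optional seed-controlled
jitter. Estimates are normalised to 25 °C by dividing by the Arrhenius
factor at leaf temperature. A triose-phosphate-use limitation is not
fitted: the protocol truncates at $C_i$ = 1800 µmol mol⁻¹ where TPU
limitation is rarely expressed, and a 3-parameter fit is identifiable
from 14 points; repeated 400-ppm setpoints are retained as independent
observations. Non-convergence after all starts is reported
(`converged = FALSE`), not raised.

## LAI–yield optimum

Within each stratum, yield is regressed on peak LAI with linear and
quadratic OLS; both are scored by AIC, BIC, $R^2$ and RMSE (same
likelihood convention as above, with σ counted in the parameters). The
quadratic vertex $-b_1/(2 b_2)$ is reported as the yield-maximising LAI
only when $b_2 < 0$; a vertex outside the observed LAI range is flagged
extrapolated, and parsimony breaks exact AIC ties toward the linear
model. Strata are never pooled.

## What the generator emulates — and what it does not

The synthetic-trial generator reproduces the statistical structure the
analysis assumes, with defaults at the scale of a Midwest soybean NIL
trial: 25-plot blocks with the check geometry above; additive block-row/
block-column gradients plus independent Gaussian noise (the Method-I
model form), with an optional smooth plot-level polynomial trend for
robustness checks; a bimodal leaf-ratio mixture with component means 1.3
and 2.4 (broad vs narrow leaves, component sd 0.15); logistic, concave,
and rise–plateau–decline seasonal curves (plateau LAI ≈ 9–10, canopy
closure near day 38, NDVI decline near day 80); two-class plot images
with green-dominant, high-NIR vegetation pixels; box-shaped uniform point
clouds; and FvCB-generated A–Ci curves at the 14-step survey protocol.

The verification studies run at desk scale, and their conditions are:
LAI peak recovery on the concave family at 10 samples (days 25–95, noise
sd 0.15); CC50 and decline onset at the twice-weekly flight cadence
(days 21–99; CC noise 2 points, NDVI noise 0.01); gradient studies on
complete block grids with gradient sd twice the noise sd; FvCB recovery
at noise sd 0.5 µmol m⁻² s⁻¹ over 200 curves; optimum recovery at
n = 150 plots per stratum, yield noise 150 kg ha⁻¹. The demonstration
pipeline uses two strata of five blocks.

What passing these studies shows is that the implementations are correct
against their own model assumptions and known ground truth. What they do
not show: real fields have non-additive, patchy spatial structure;
real canopies mix soil shadow, specular leaves and mixed pixels that a
two-class image does not contain; real point clouds have occlusion and
ground returns; real A–Ci curves have operator truncation and stomatal
drift. Results on real data inherit those caveats.

## Numerical conventions and degenerate inputs

Randomness: every generator takes a `seed` and is bit-reproducible; the
pipeline derives named per-stage sub-seeds from one root seed, so stages
are individually reproducible and a run's JSON report is byte-identical
for the same configuration. Dense-grid resolution is 0.1 day and
extracted days are reported at that resolution. Degenerate inputs are
defined, not silent: even block dimensions (no unique centre), missing
genotype effects, non-increasing days, thresholds outside (0, 100],
empty boundaries, constant Otsu inputs, under-determined A–Ci curves and
constant LAI predictors all raise informative errors; an empty point
cloud has zero biomass by definition. Fits that merely fail to converge
(logistic, FvCB) are reported as such so downstream selection can route
around them, mirroring how non-sigmoidal traits surface in practice.
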