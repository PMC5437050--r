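---
title: "Models and methods: SpIDA, MEU calibration, and the companion kinetic analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: SpIDA, MEU calibration, and the companion kinetic analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spidar)
```

## The intensity model

SpIDA treats each pixel of an analog confocal image as a point sample of a
shot-noise field. Fluorescent entities (monomers, dimers, ...) of quantal
brightness $\varepsilon$ (intensity units contributed by one entity centred
on a pixel) are placed as a homogeneous spatial Poisson process of density
$\rho$ per µm². The microscope blurs each with a point spread function
normalized to peak 1, and the detector adds a baseline offset and Gaussian
read noise of SD $\sigma_0$. The marginal distribution of a pixel value is
then compound Poisson with log characteristic function

$$\log\varphi(\omega) = \rho \int \left(e^{i\omega\varepsilon\,
\mathrm{PSF}(r)} - 1\right)\mathrm{d}A \;-\; \tfrac{1}{2}\sigma_0^2\omega^2
\;+\; i\omega\,\mathrm{offset},$$

and `spida_pmf()` evaluates it by discretizing the PSF radially and
inverting with an FFT. Two integrals of the PSF summarize everything the
moments need: the beam area $A_1 = \int \mathrm{PSF}\,\mathrm{d}A$ and
$A_2 = \int \mathrm{PSF}^2\,\mathrm{d}A$, giving
$\mathrm{mean} = \mathrm{offset} + \rho\varepsilon A_1$ and
$\mathrm{var} = \sigma_0^2 + \rho\varepsilon^2 A_2$. A dimer contributes
$2\varepsilon$ at one point, which leaves the mean unchanged at fixed total
fluorophore density but inflates the variance — the super-Poissonian excess
that the histogram fit detects.

Assumptions worth stating plainly: entities are point-like and immobile
within one frame (no blinking or within-frame bleaching), the detector is
analog (continuous intensity, additive Gaussian noise) rather than
photon-counting, the PSF is a 2D Gaussian, and one brightness population per
RoI suffices. The fit is two-parameter $(\rho, \varepsilon)$; offset and
$\sigma_0$ are calibration inputs measured from blank/dark images in real
use and known exactly in simulation. Fixing them stabilizes the fit and
matches SpIDA practice. A two-population fit is deliberately out of scope:
the quaternary-structure pipeline asks only for the *apparent* brightness
per RoI, which the MEU threshold then dichotomizes.

## Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| PSF $e^{-2}$ radius | 0.25 | µm | typical 488 nm excitation with a high-NA oil objective |
| PSF truncation | 3 × radius | — | profile is $1.5\times10^{-8}$ of peak at the cut |
| pixel size | 0.05 | µm | Nyquist-comfortable sampling of the PSF |
| image/RoI | 256×256 / 64×64 | px | acquisition format vs. fit region; fits refuse < 32×32 px |
| detector offset | 10 | intensity units | small positive baseline |
| read-noise SD | 2 | intensity units | small relative to emitter variance at study densities |
| histogram bin width | 1 | intensity unit | resolves the model without empty-bin noise |

The defaults define the synthetic study conditions and were chosen once; the
imaging truth values exercised throughout (quantal brightness 11.01 units at
130 molecules/µm², and 24.31 units at 68 molecules/µm², for the 2% and 6%
laser-power conditions) are the calibration scales the pipeline is meant to
operate at. Emitters are sampled in a margin strip one truncation radius
wide beyond the image so edge pixels see unbiased statistics; the renderer
rejects margins smaller than the truncation radius.

## Numerical choices

*PSF discretization.* The radial integrals are computed by Gauss–Legendre
quadrature in the $u = r^2$ variable (64 nodes), where the area element is
flat and the Gaussian profile smooth; the discretized $A_1, A_2$ agree with
the closed forms to ~1e-14, so the pmf's analytic moment identities hold to
the 1e-6 level the tests assert.

*FFT grid.* The intensity grid is a power of two, spacing equal to the
histogram bin width, covering the model mean ± 8 SD and the observed range,
and snapped to the lattice of observed bin centres so model and data bins
coincide exactly. `spida_pmf()` rejects grids that truncate more than 1e-6
of the mass.

*Objective.* Weighted least squares between observed and expected counts
with weights $1/\max(\text{expected}, 1)$ — a chi-square-like objective in
which empty model bins get weight 1. Optimization is Nelder–Mead on
$(\log\varepsilon, \log\rho)$ started from the moment inversion
$\varepsilon_0 = \frac{\mathrm{var}-\sigma_0^2}{\mathrm{mean}-\mathrm{offset}}
\cdot \frac{A_1}{A_2}$, $\rho_0 = \frac{\mathrm{mean}-\mathrm{offset}}
{\varepsilon_0 A_1}$. Standard errors come from the curvature of the
chi-square surface (delta method back from the log scale) and should be
read as asymptotic.

*Degenerate inputs.* Images whose sample variance does not exceed the read
noise, or whose mean does not exceed the offset, are flagged degenerate
(density 0, brightness NA) rather than fitted; non-convergence is flagged,
never thrown.

*Density convention.* Because the PSF areas $a_k$ enter the characteristic
function in µm², the fitted $\rho$ is directly per µm². Some SpIDA
implementations report density per beam area instead; `surface_density()`
makes the convention explicit — it divides offset-corrected mean intensity
by (monomeric QB × $A_1$), or by QB alone if no PSF is supplied (the
per-beam-area convention collapsed to unit area).

*Classification tie-break.* RoIs exactly at the threshold are scored
monomeric ("less than or equal"). The threshold is mean + 2 SD of the
calibration MEUs — an upper one-sided cut. The 95.44% conventionally quoted
with it is the *two-sided* ±2σ Gaussian mass (`gaussian_central_mass(2)`);
about 97.7% of a Gaussian calibration population actually falls below the
cut. The package reproduces the conventional pairing without resolving the
inconsistency, which is one of nomenclature, not arithmetic.

## The MEU calibration

Monomeric QB per laser power is the mean of per-RoI fitted brightness on the
monomeric reference construct (median available as an option; the mean
matches how such calibrations are reported, as mean ± SEM over
experiments × RoIs). MEUs measured at different powers may be pooled only
*after* per-power normalization — brightness scales with excitation power,
so `qb_to_meu()` refuses unregistered powers outright rather than
extrapolate. Normality of the pooled calibration MEUs is assessed by the
D'Agostino–Pearson omnibus $K^2$ test (implemented here, with the
sign-preserving cube root in the kurtosis transform; verified against an
independent reference implementation), plus skewness/kurtosis reports. The
0.1-MEU binning in `fit_meu_distribution()` is for presentation; all
statistics use unbinned values.

## FRAP

The generator produces the bleached-spot (Fs), background (Fb) and
non-bleached-control (Fc) series: 5 pre-bleach + 44 recovery frames at
2.5 s, mono-exponential recovery
$F_s(t) = bg + [\mathrm{floor} + \tfrac{mf}{100}(\mathrm{pre}-\mathrm{floor})
(1-e^{-t\ln 2/t_{1/2}})]\,d(t)$, with $d(t)$ an exponential
acquisition-bleaching decay calibrated so the control ends at $r$ times its
start (default $r = 0.95$, a typical ~5% loss; pre-bleach 100, bleach depth
70, background 5). Correction follows the standard recipe: $r = F_{c,end} /
F_{c,0}$, $F = (F_s - F_b)/r$, then normalization mapping the pre-bleach
mean to 100 and the first post-bleach frame to 0; the one-phase fit
$F(t) = \mathrm{plateau}(1 - e^{-kt})$ gives $t_{1/2} = \ln 2 / k$ and the
plateau is the mobile fraction in percent.

A known limitation, inherited from the end-ratio correction itself: dividing
every frame by the single end-of-run ratio $r$ over-corrects early frames
when acquisition bleaching is ongoing, biasing $t_{1/2}$ low by several
percent at $r = 0.95$. The noiseless round-trip identity (exact recovery to
machine precision) therefore holds for $r = 1$, background 0 — the
configuration the round-trip tests use; noise-robustness tests add 5%
multiplicative (CV) noise to that same configuration so they measure noise,
not the correction's own bias. Flat post-bleach series return mobile
fraction equal to their level with an unidentifiable rate (NA) rather than
a spurious fit, and traces whose first post-bleach frame is not below the
pre-bleach mean are flagged.

## Radioligand analyses

Dissociation under infinite dilution: specific binding (total minus the
paired nonspecific series, subtracted pointwise before fitting) is fitted to
$B_0 e^{-k_{off} t}$ with no plateau term — after nonspecific subtraction
the asymptote is zero by construction; a floating plateau is available as an
option. The half-life is reported as the analytic $\ln 2 / k_{off}$ (for
$k_{off} = 0.014\ \mathrm{min}^{-1}$, 49.5 min; informal roundings of such
values to ~51 min trace to quoting, not arithmetic). Flat traces are
flagged as non-dissociating instead of returning a meaningless rate.

Competition: one-site curve with Hill slope fixed at 1 (the one-site model;
no slope information is available to justify freeing it), IC50 fitted on the
log10 scale, converted by Cheng–Prusoff $K_i = \mathrm{IC50}/(1 +
[L]/K_d)$. Fits whose IC50 falls outside the tested concentration range are
flagged (`in_range = FALSE`). The radioligand $K_d$ used in the conversion
is an explicit input (0.3 nM in the synthetic studies), not an estimate
from the same curve. Saturation: specific binding fitted to
$B_{max}[L]/(K_d + [L])$, with nonspecific modeled as linear in ligand
concentration in the generator, as is standard for filter-binding assays.

## Helix-distance summaries

`generate_helix_frames()` emulates trajectory snapshots at the level the
analysis consumes: one Cα per labelled Ballesteros–Weinstein position, pair
distances Gaussian about configured means (apo defaults 12.0, 10.0, 11.0 Å
for pairs 1.35–2.65, 3.40–6.44, 4.50–5.50; jitter 0.5 Å). It does not
emulate correlated helix motion, only marginal distance fluctuation — which
is exactly what the mean ± SEM summaries and the ANOVA + Tukey group
comparison in `distance_delta_summary()` consume. The BW-label-to-residue
mapping is an external CSV, so the module carries no receptor-specific
numbering; frames travel as multi-MODEL PDB read via bio3d.

## What the synthetic validation does and does not show

Passing parameter recovery on these generators demonstrates that the
estimators are correct *for the stated models*: Poisson-placed point
emitters with a Gaussian PSF and Gaussian analog noise, ideal
mono-exponential kinetics, one-site binding. Real membranes add
inhomogeneous receptor distribution, membrane topography, detector
nonlinearity and shot-noise scaling, photophysics (blinking, partial
maturation of the fluorophore), and cell-to-cell variability — none of which
the generators emulate. Quantities that depend on those real-data features
(clone-specific dimer percentages, drug-treatment effect sizes, affinities
from real membranes, distances from real trajectories) are therefore
validated here only at the level of the machinery that would compute them.

## Problem sizes

The test suite fits 88 synthetic RoIs per laser-power condition (shared
across tests via a fixture cache) plus smaller mixture sets; the
model-vs-Monte-Carlo total-variation checks use 10^6 independent pixels per
parameter combination. The acceptance script fits 4 × 44 RoIs per condition
and 20 noisy competition curves. These sizes give Monte-Carlo standard
errors of ~1% on the recovered means, an order of magnitude below the 10%
recovery tolerances asserted.
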