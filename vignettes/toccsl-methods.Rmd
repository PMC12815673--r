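---
title: "Brightness-distribution stoichiometry and transporter kinetics: models and methods"
author: "toccsl package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brightness-distribution stoichiometry and transporter kinetics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toccsl)
```

## The problem

Membrane transporters of the SLC6 family (the serotonin, dopamine and
norepinephrine transporters) form oligomers in the plasma membrane, and both
their oligomeric state and their lateral mobility respond to the lipid
environment. Quantifying the oligomer distribution of *mobile* transporters
at the single-molecule level relies on TOCCSL ("thinning out clusters while
conserving stoichiometry of labeling"): an aperture-confined region of the
membrane is photobleached, mobile unbleached molecules diffuse back in
during a recovery delay, and the now well-separated diffraction-limited
spots are imaged. Because every fluorophore inside such a spot belongs to
one diffusing entity, the spot's integrated brightness carries its subunit
count.

This package implements that analysis chain — photon calibration, spot
fitting, brightness-distribution deconvolution with bootstrap uncertainties
— together with the companion measurements that make the stoichiometry
interpretable: FRAP mobile-fraction fitting, sensitized-emission FRET with
bleed-through correction, and the uptake/binding/efflux/patch-clamp summary
fits. A synthetic-data generator produces every input with known ground
truth, so each stage is testable end to end without laboratory data.

## The stoichiometry model

Let $\rho_1(B)$ be the probability distribution of the integrated brightness
$B$ (in photons) of a single fluorophore-tagged monomer, estimated from
calibration frames in which essentially only monomers remain visible. An
n-mer with all fluorophores active emits the sum of $n$ independent monomer
brightnesses, so its brightness distribution is the n-fold autoconvolution
$\rho_n = \rho_1^{*n}$. The observed spot brightness distribution is the
mixture

$$\rho(B) = \sum_{n=1}^{n_{\max}} \alpha_n\, \rho_n(B), \qquad
  \sum_n \alpha_n = 1,\ \alpha_n \ge 0,$$

and the $\alpha_n$ — the fractions of mobile, fluorophore-carrying
molecules in each oligomeric state — are the quantity of interest.

### Numerical representation

`brightness_pdf` stores a distribution as a uniform-width histogram with an
explicit grid `offset`. The offset matters: summing $n$ bin-center values
lands on a grid shifted by $(n-1)w/2$ for bin width $w$, and recording that
shift (instead of rounding it into the nearest bin) keeps the convolution
mean identity $\mathrm{mean}(\rho_n) = n\,\mathrm{mean}(\rho_1)$ exact to
machine precision. Autoconvolution is a direct (FFT-free) discrete
self-convolution — exactness over speed at the problem sizes involved
(hundreds of bins). The default bin width is one fifth of the calibration
sample's standard deviation; the calibration grid extends to
$n_{\max}\cdot\max(B)$ so no autoconvolution mass is truncated (a guard
raises an error if more than $10^{-6}$ of mass would fall off the grid).

### Fit criterion

`fit_mixture` maximises the multinomial log-likelihood of the binned spot
brightnesses under the mixture, by expectation-maximisation on the weight
simplex. The likelihood is concave in $\alpha$, the EM update respects the
constraints exactly, and a fixed initialisation (uniform weights), iteration
cap and tolerance make the result deterministic. Maximum likelihood is
preferred over least squares because histogram counts are heteroscedastic;
an exact simplex-constrained least-squares mode (`method = "ls"`, solved by
active-set enumeration) is provided for sensitivity checks. Spots brighter
than the $n_{\max}$-mer envelope cannot be explained by any component; they
are excluded from the fit and counted in `n_excluded` rather than forced
into the largest class.

### Uncertainties

`bootstrap_fractions` refits the mixture on random 50% subsamples of the
spots, drawn without replacement, in 100 repetitions (both defaults
deliberately match the subsampling scheme customary for this analysis), and
reports the standard deviation of each $\alpha_n$ over repetitions.
Subsampling at half the data overestimates the full-sample standard error
by roughly $\sqrt{2}$, which makes the reported uncertainties conservative.

No fluorophore-maturation correction is applied: the fitted fractions
describe molecules *carrying an active fluorophore*, which is also what the
assay observes. The generator's `p_active` hook exists for studying the
effect, but it is 1 by default.

## The synthetic-data generator

The generator emulates the statistical structure the analysis consumes, not
the microscope:

* **Monomer brightness** is log-normal (positive support, right-skewed, the
  shape single-fluorophore brightness histograms actually have), default
  mean 400 photons with 35% coefficient of variation. These defaults are
  conventional for EMCCD single-fluorophore imaging; no published values
  constrain them, and the analysis calibrates $\rho_1$ from data anyway.
* **Molecule fields** are spatial Poisson processes (default 0.4
  molecules/µm² in a 16 µm field) with per-molecule oligomer order drawn
  from the ground-truth mixture and per-order mobility flags. Mobile
  molecules perform free 2-D Brownian motion (default D = 0.1 µm²/s,
  typical for SLC6 transporters in the plasma membrane) with reflecting
  field boundaries; there is no rebinding or confinement.
* **Imaging** deposits each molecule's flux — the sum of one independent
  monomer draw per active fluorophore — as an exactly pixel-integrated 2-D
  Gaussian (default σ = 1.1 px at 160 nm pixels), then applies Poisson shot
  noise, optional EM excess noise (variance doubling of the shot term), and
  Gaussian readout noise, and maps photons to camera counts through
  `offset + gain × photons`. Pixel counts are converted back to photons by
  offset subtraction and multiplication with the inverse gain, which is
  exactly invertible.
* **The TOCCSL protocol** uses a 2000 ms aperture-confined bleach and a
  15 s recovery delay; a prebleach frame serves density estimation and the
  post-bleach control frame verifies bleach completeness. The ledger emitted
  beside the frames records every molecule's positions, order, active
  fluorophores and analyzability, so tests never reverse-engineer truth from
  pixels.

What the generator does **not** emulate — blinking, incomplete bleaching at
the aperture edge, drift, uneven illumination, anomalous diffusion — bounds
what passing tests show about real data: they validate the estimator, not
the microscope. In particular, prebleach frames at realistic densities
contain overlapping spots; the density reported from spot detection is then
a lower bound on the true molecular density, which is the same limitation
the real assay has at high expression levels.

## The shipped scenarios and the mobility confound

TOCCSL reads out only molecules that diffused into the aperture, i.e. the
*mobile* subpopulation. The two shipped scenarios make this concrete. Both
share the total composition (55% monomers, 25% dimers, 15% trimers, 5%
tetramers — a plausible mixed population whose exact values are a modelling
choice, not a measurement):

* `control`: every order is mobile with probability 0.86, so the overall
  mobile fraction a FRAP experiment sees is 86%.
* `cholesterol_depleted`: trimers and tetramers are immobilised and
  monomers/dimers stay mobile with probability 0.9, giving an overall
  mobile fraction of $0.9 \times 0.8 = 72\%$.

These per-order mobilities were chosen so the scenarios' overall mobile
fractions equal the two mobile fractions the assays report under the
corresponding treatments, which makes the scenarios a faithful in-silico
restaging of the reconciliation between the three read-outs: immobilising
the higher-order oligomers lowers the FRAP mobile fraction and shifts the
fitted TOCCSL fractions toward monomers and dimers, while the total
(ledger) composition is unchanged — oligomers did not dissolve, they
stopped moving.

## Companion fits

**FRAP.** Recovery traces are normalized to the prebleach signal $I_0$
after aligning the first postbleach sample to zero, and fitted by the
one-phase association model $I(t)/I_0 = \mathrm{mf}\,(1 - e^{-Kt})$ with
the mobile fraction bounded to $[0,1]$ (bounds are physical, not cosmetic:
noisy plateaus otherwise exceed 1). Whether the original normalization used
the first postbleach point or an extrapolated bleach depth is not
documented; the first-postbleach-point convention is the default here and
the `baseline` argument exposes the alternative. Initialisation takes K
from a log-linear fit of the early points and mf from the last-quartile
mean; an unreached plateau ($K t_{\max} < 1$) is flagged.

**FRET.** Normalized FRET is
$(I_F - BT_D I_D - BT_A I_A)/\sqrt{I_D I_A}$ with bleed-through
coefficients measured from single-label controls (defaults 0.57 and 0.04
for the CFP/YFP pair). Negative values are retained — clipping would bias
condition means. Background subtraction happens upstream of the ROI table;
the background estimator is a configuration choice. The fused donor-acceptor
construct serves as a reference condition in summaries, not as a
normalizer, because the assay reports NFRET rather than FRET efficiency.

**Assays.** Uptake and binding use unweighted nonlinear least squares of
the rectangular hyperbola after subtracting the nonspecific arm
(per-concentration by default; a constant-level mode exists because the
original subtraction convention is not documented). The "one-site" binding
read-out is a saturation model fit — a literal linear regression cannot
produce $K_d$ and $B_{\max}$. Turnover is $V_{\max}/B_{\max}$ with
delta-method error propagation. Efflux plates are expressed as percent of
total well radioactivity and normalized to the basal condition, with the
per-condition totals reported so equal loading is checkable.
Electrophysiology summaries start from measured amplitudes and relaxation
rates (trace-level filtering belongs to the acquisition software): the
steady-state dose response is normalized per cell to the 10 µM reference
pulse before the hyperbola fit; $k_{on}$ is the ordinary least-squares
slope through the three lowest-concentration relaxation rates (with µM and
s⁻¹ inputs the slope is numerically on the 10⁶ M⁻¹s⁻¹ scale), which as a
secant systematically underestimates the true initial tangent
$k_{\max}/k_{0.5}$ — the tests assert exactly that inequality.

## Numerical choices and degenerate inputs

* Spot candidates closer than `min_separation` are discarded pairwise, not
  merged: stoichiometry is only valid for spots that are single diffusing
  entities. Ties between equal-valued neighbouring maxima (possible on
  noiseless symmetric data) are broken by raster order so a flat-topped
  maximum yields one candidate instead of a mutually-rejecting pair.
* The spot model is the pixel-integrated Gaussian with the integrated
  brightness B as a free parameter; fit windows clipped by the image edge
  are rejected, not padded. Acceptance requires σ within $[0.5, 2]\times$
  the expected PSF width and $B$ above a small floor (default 10 photons),
  which is what rejects structureless windows.
* Degenerate inputs resolve deterministically: an all-zero FRAP trace
  returns mf = 0 with the rate flagged unidentifiable; a flat relaxation
  curve is flagged `no_association`; a release well with zero total counts
  is excluded and logged; a fully nonspecific binding table is a fit error.
* Every stochastic operation takes an explicit integer seed and restores
  the caller's RNG state; scenario reruns under an identical configuration
  are byte-identical, and every artifact carries the md5 hash of its
  configuration.

## Problem sizes used in validation

The shipped validation exercises use 3000 spots for direct-sample weight
recovery (20 seeds, full 50%/100-rep bootstrap each), 120 simulated TOCCSL
runs (~500 analyzable spots) for the image-level pipeline, and 40 runs per
scenario for the mobility-confound comparison. These sizes put Monte-Carlo
error comfortably below the effects being asserted while keeping a full
validation run in the minutes range on a single core.

## Known limitations

* The fitted fractions describe the mobile, fluorophore-carrying
  subpopulation; immobile oligomers are invisible to TOCCSL by design and
  only the FRAP/FRET companions reveal them.
* Monomer calibration error propagates into all $\alpha_n$ but is not
  included in the bootstrap SDs (the bootstrap resamples spots, not
  calibration frames); with the conservative 50% subsampling this has not
  mattered in validation, but very small calibration sets will
  underestimate uncertainty.
* Density estimates from dense prebleach frames undercount overlapping
  molecules.
* The diffusion model is free Brownian motion; confined or hop diffusion
  would change re-entry statistics during recovery, though not the
  brightness model itself.

## A worked example

```{r example, eval = FALSE}
res <- run_scenario(list(seed = 1, n_runs = 40L,
                         n_calibration_frames = 20L))
res$stoichiometry          # fitted alpha_n with bootstrap SDs
res$results$ledger         # ground-truth composition for comparison
res$frap                   # fitted mobile fraction
```
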