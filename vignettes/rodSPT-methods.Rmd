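---
title: "rodSPT: models and methods for single-molecule tracking in rod-shaped bacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rodSPT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(rodSPT)
```

rodSPT analyzes stroboscopic single-molecule tracking experiments of small,
fast-diffusing fluorescent molecules (such as organic-dye-labelled tRNA)
inside live rod-shaped bacteria, and generates ground-truthed synthetic data
to validate every stage of that analysis. This vignette describes the models,
their assumptions, the tunable parameters, and the numerical choices that a
user should know before trusting the output.

## The physical model

A bacterium is modelled as a **spherocylinder**: a cylinder of radius $r$
(default 0.5 µm) with hemispherical caps, tip-to-tip length $L$ (default
3 µm). A molecule performs 3D Brownian motion with diffusion coefficient $D$
inside this volume. The boundary is **specular (reflecting)**: a substep that
leaves the volume is folded back across the nearest surface point. Reflection
preserves the uniform equilibrium distribution, which we verify by testing
the long-time transverse variance against the uniform-disc value $r^2/4$ per
axis.

Imaging is **stroboscopic**: a short excitation pulse (default 1 ms) at the
start of each camera frame (default 5 ms) limits motion blur of fast
molecules. The reported position of an emitter in a frame is the mean of its
Brownian substep positions inside the strobe window. For free diffusion this
averaging reduces the expected per-frame squared displacement by a factor
$1 - t_s/(3\Delta t)$ ($t_s$ = strobe length), about 7% at the defaults.

Brownian substeps default to 25 per frame (substep $\mathrm{d}t$ = 0.2 ms),
which puts 5 substeps inside a 1-ms strobe; at $D \le 12\ \mu m^2/s$ the
residual discretization error of the blur average is well below the
localization error.

The simulator is 3D but the camera sees a 2D projection; the whole $z$ range
projects into the image (**no focal sectioning and no $z$-dependent PSF**).
This is a deliberate simplification, with consequences discussed under
*Limitations*.

## Two synthetic-data fidelity levels

* **Geometric tracks** (`simulate_localized_tracks()`): true strobe-averaged
  positions plus independent Gaussian per-axis localization error
  $s$ (default 0.04 µm). Cheap; used for the calibration study. Emitters per
  cell are Poisson (mean 1.5); trajectories are simulated for a fixed
  number of frames (default 10).
* **Rendered movies** (`render_movie()`): every live emitter deposits an
  expected `photons_per_strobe` photons per frame, split over its strobe
  substep positions (so motion blur is rendered physically), integrated over
  pixels through a symmetric Gaussian PSF (sd 0.13 µm), with Poisson photon
  and background noise, EM gain, EMCCD excess noise (approximated by
  doubling the Poisson variance; only precision, not absolute counts,
  matters downstream), and Gaussian read noise, written as 16-bit TIFF.

The photon and noise defaults (120 photons/strobe, 2 background
photons/pixel/frame, gain 20, read noise 10) were calibrated once so that
the end-to-end movie pipeline applied to immobile emitters returns a mean
apparent diffusion coefficient of ≈ 0.33 µm²/s, i.e. a per-axis localization
error of ≈ 0.04 µm, matching the geometric path. The pixel size is fixed at
0.67/7 µm so that a 7-pixel linking window equals 0.67 µm.

## Localization and linking

Spots are detected by a difference-of-Gaussians bandpass followed by local
maxima above a fixed intensity threshold (minimum separation 2 px; the
brighter of two nearer candidates wins), then fitted with a 2D **elliptical
Gaussian** (free: position, widths, rotation, amplitude, background) on a
9×9-px window (≥ 6 PSF sd). Fitted localization precision scales as the
inverse square root of the photon count. For symmetric spots the rotation
angle is canonicalized to 0. Photons are estimated as
$2\pi A w_x w_y / (a^2 G)$ with pixel size $a$ and EM gain $G$.

Localizations in consecutive frames within **0.67 µm** are linked by optimal
bipartite assignment (maximum number of links, then minimum total squared
displacement; ties break toward lower localization index, making linking
deterministic and order-independent). A disappeared spot is remembered for
**one frame**; a gap-bridging displacement may use the window enlarged by
$\sqrt{2}$, since displacement variance grows with lag (the enlargement is
configurable; published descriptions of the window do not address gaps).
For a single species the probability that a step stays inside the window
is the Rayleigh expression
$1 - \exp(-W^2/(4 D_{app}\Delta t + 4 s^2))$ — 99.5% at
$D_{app} = 4\ \mu m^2/s$, $\Delta t = 5$ ms, $s = 0.04$ µm.

## Apparent diffusion coefficients and species decomposition

Each trajectory's **apparent diffusion coefficient** uses its first four
single-frame steps:
$D_{app} = \sum_{k=1}^{4} (\Delta x_k^2 + \Delta y_k^2) / (16\,\Delta t)$,
with gap-bridging steps excluded and shorter trajectories dropped (and
counted). For an immobile emitter this estimator's mean is $s^2/\Delta t$ =
0.32 µm²/s at the defaults, which is how a fixed-cell control measures the
localization precision: $\sigma = \sqrt{4 D_{app}^{fixed} \Delta t}$ =
0.08 µm, with the per-axis error $s = \sigma/2$. That convention makes the
fixed-cell estimator mean and the printed precision mutually consistent.

For one free species, $D_{app}$ follows a **gamma distribution** with shape
4 and mean $D + s^2/\Delta t$; a mixture of species is fitted by maximum
likelihood with EM (10 deterministic quantile-scaled restarts; histogram
least squares is only a diagnostic, as MLE is better behaved at these sample
sizes). Any species mean can be constrained, e.g. to ribosome-bound
diffusion (0.5 µm²/s), a fixed-cell control (0.32 µm²/s), or the ternary
complex (`ternary_complex_Dapp` = 2.4 µm²/s) for three-species fits.
When two free components converge to nearly coincident means their weight
split is unidentifiable (the likelihood is flat); among restarts whose
log-likelihoods differ by less than 2 units the fit therefore returns the
most parsimonious solution (largest dominant weight), so single-species
data never presents as two separated species.
Localization noise shared between consecutive steps introduces a small
negative correlation between steps; its effect on the gamma shape is
second order ($\propto (s^2/(D\Delta t))^2$) and undetectable at the sample
sizes used here.

The **CDF decomposition** (`fit_cdf()`) least-squares fits the empirical CDF
of single-frame squared displacements to
$1 - \sum_j A_j \exp(-u/(4 D_j \Delta t + 4 s^2))$, with softmax weights and
log-scale means for unconstrained optimization from three deterministic
starts. The $4s^2$ noise offset is subtracted from the fitted means. The
small-$D$ component is the statistically hardest quantity: the fitted mean
$\tau_1 = 4 D_1 \Delta t + 4 s^2$ is recovered to a few percent, but
subtracting the offset amplifies the relative error of $D_1$ by
$\tau_1/(\tau_1 - 4 s^2)$ (≈ 3.7 at $D_1 = 0.12$ µm²/s, $s = 0.04$ µm) —
an intrinsic property of measuring a diffusion coefficient close to the
noise floor, not of the fitting routine.

Trajectories are classified **slow** below 1 µm²/s; at the defaults ≥ 90% of
fixed-cell trajectories classify slow.

## Calibration of apparent to accurate D

`calibrate()` runs the full geometric pipeline
(simulate → add noise → link → estimate → average) for a grid of true $D$
values, fits a monotone Hyman spline through the mean apparent $D$, and
inverts it with `predict()`, propagating the replicate sd and the
measurement error in quadrature through the local slope (a symmetric
interval; asymmetric intervals are not reproduced analytically). Since the
simulated population holds a single mobile species, its mean apparent D is
the maximum-likelihood gamma mean, i.e. the sample mean. The default study
conditions are 500 cells, 1.5 emitters/cell, 10 frames/emitter and 2
replicates per grid point; one grid point takes a few seconds on one CPU.

At the defaults the forward map is strongly compressive
(confinement + blur + noise + window truncation): true 8.1 µm²/s yields an
apparent ≈ 5.2 µm²/s. Inverse∘forward is identity to within the replicate
scatter. See *Limitations* for why a finite depth of field would compress
further.

## The diffusion-budget arithmetic

`cycle_budget()` implements the bookkeeping for a diffusion-based tRNA
cycle: with 2 tRNA sites at each of 50 000 ribosomes and a pool of 375 000
tRNAs, 100 000 are bound and 275 000 searching (bound fraction ≈ 25%);
at 50 ms per amino acid the ribosome visit lasts 100 ms, the full cycle
100 ms / 0.25 = 400 ms, and the search time 300 ms. The cell-exploration
time uses $MSD(t) = 6Dt$ against a target MSD whose default is the numeric
value of the long cell axis (3 µm → 3 µm²), giving 62.5 ms at 8 µm²/s —
under the 70 ms bound quoted for this argument. We kept that target (rather
than the squared length, 9 µm²) because it is the convention this
back-of-the-envelope argument uses; both are crude summaries of "time to
span the cell".

## Molecule counting by photobleaching steps

Single-cell traces are baseline-subtracted using the post-bleach plateau
(last 10% of frames). Counting uses an HMM over molecule numbers
$k = 0..6$ with emissions $\mathcal{N}(k u, \sigma_n)$ and transitions
$k \to k$ or $k \to k-1$ only, parameterized by a single per-frame,
per-molecule bleaching probability (so $P(k \to k-1) = kp$ — independent
bleaching physics). The unitary intensity $u$, noise sd and $p$ maximize the
forward likelihood over a deterministic grid — 40 log-spaced $u$ candidates
around a robust guess (the smallest sustained intensity drop above the
noise), four noise scales around a MAD estimate, four bleaching
probabilities — and the state path is decoded by Viterbi, so the decoded
path can never increase. Decoding accuracy exceeds 90% at the
$u = 8.7$, $\sigma_n = 2.4$ operating point. Pooled step heights are
summarized by a single-Gaussian histogram fit whose center is the unitary
intensity; a large residual (e.g. bimodal heights) raises a poor-fit
diagnostic. Cell loading is called by the control mean + 3 sd rule, which
misclassifies ≈ 0.13% of the control population itself. The camera
a.u.→photons conversion is an external gain constant, never inferred.

## Unit-cell spatial statistics

Localizations are normalized to a **unit cell**: $x$ is the absolute
midline position (0 = mid-cell, 1 = pole), $y$ the absolute short-axis
distance divided by the local half-width — the radius on the cylindrical
part and the hemispherical profile $\sqrt{r^2 - (|x|-a)^2}$ in the caps
(the cap convention is ours; outlines near poles are rarely informative
either way). Out-of-outline points are dropped and counted.

The uniform reference along the short axis is the analytic projection of a
uniform cylinder, $pdf(\rho) = 4\sqrt{\max(1-\rho^2, 0)}/\pi$ (unit cell,
$r = 1$), which integrates to 1 and equals $4/\pi$ at the midline; endcap
contributions to the reference are ignored, consistent with that formula.
**Enrichment** splits the short axis at a configurable cutoff (default 0.5,
a declared choice — the shaded-region boundary behind published percentages
is not printed anywhere) and reports the percent deviation of the observed
occupancy from the uniform mass of each region
(periphery mass $\int_{0.5}^{1} pdf = 0.391$), with a seeded bootstrap CI.
Cells are optionally binned by length into short (1.7–2.9 µm, one nucleoid)
and long (3.1–4.3 µm, two nucleoids) classes; cells between bins are
excluded and counted.

## Determinism

Every stochastic function takes a `seed`; identical seed + configuration
gives bit-identical output. The pipeline driver (`run_pipeline()`) derives
per-stage seeds from the master seed, writes every table (CSV) and fit
(JSON) with the configuration hash, and emits a manifest with MD5 checksums,
stage timings and drop counts. EM restarts, the HMM grid and the CDF-fit
starts are deterministic by construction (no RNG).

## Problem sizes used in the test-suite

The packaged tests run the study conditions at desk scale: 500–700 cells for
pipeline-level checks, $10^4$ trajectories for distribution-law (KS) checks,
$10^5$ draws for window-probability checks, 200 photobleaching traces for
HMM accuracy, $2\times10^4$–$10^5$ points for spatial laws, and a 7-point
calibration grid with 2 replicates. These sizes keep each check's sampling
error several times smaller than its tolerance.

## What the synthetic data does and does not emulate

The generator reproduces: spherocylindrical confinement, stroboscopic blur,
localization error, Poisson cell loading, EMCCD counting statistics,
exponential photobleaching, quantized intensity decay, and uniform or
periphery-biased spatial patterns (radial weight $(\rho/r)^{bias}$). It does
**not** emulate: photoblinking beyond one-frame disappearances, z-dependent
PSF shape or focal sectioning, nucleoid-exclusion forces, cell-to-cell
parameter variability, or drift. Passing tests therefore validate the
estimators under these model assumptions, not the full physics of a
microscope.

## Limitations

* **No focal sectioning.** Because every molecule is detectable at any
  depth, fast molecules lose none of their frames and the apparent-D
  compression at high D is weaker than in experiments with a shallow depth
  of field, where defocused (fast, out-of-slab) molecules drop out of
  trajectories and bias the surviving steps slow. Calibrations built here
  are self-consistent but not transferable to instruments where focal
  selection is strong.
* The linking assignment is exact only per frame pair (no multi-frame
  global optimization), matching common practice at ~1.5 molecules/cell.
* The HMM assumes a constant unitary intensity within a trace; slow
  acquisition drift must be removed beforehand.
* Curved midlines are not modelled; cells are straight spherocylinders.
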