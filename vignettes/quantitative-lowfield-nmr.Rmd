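---
title: "Synthetic-spectrum calibration for quantitative low-field NMR"
author: "qNMRsynth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic-spectrum calibration for quantitative low-field NMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qNMRsynth)
```

## The problem

Benchtop NMR spectrometers (permanent magnets, ~43 MHz proton
frequency) are attractive for online reaction monitoring, but their
low field strength broadens lines and compresses chemical-shift
dispersion until the aromatic multiplets of a technical mixture
overlap beyond direct integration. NMR remains strictly linear —
signal area is proportional to the number of contributing nuclei and
hence to concentration — so quantification reduces to *deconvolving*
per-component areas from an overlapped spectrum.

`qNMRsynth` implements two deconvolution routes and the data
machinery around them:

* a transparent indirect-hard-modeling (IHM) style baseline that fits
  a parametric sum-of-peaks mixture model to each spectrum by bounded
  nonlinear least squares, and
* a compact 1-D convolutional network trained entirely on synthetic
  spectra sampled from that same parametric model (or from altered
  measured pure-component spectra), so that no large measured
  calibration set is ever needed.

## The spectral model

Each peak is a height-parameterised pseudo-Voigt

$$V(\nu) = \alpha\,[\beta L(\nu) + (1-\beta)G(\nu)],$$

where $L$ and $G$ are Lorentzian and Gaussian shapes of unit peak
height sharing the half width at half maximum $\gamma$ (ppm), so
$V(\omega) = \alpha$ exactly. Closed-form areas
($\pi\alpha\gamma$ for the Lorentzian part,
$\alpha\gamma\sqrt{\pi/\ln 2}$ for the Gaussian part) anchor several
tests. Two conventions deserve note because the parameter names alone
do not fix them:

* $\beta = 1$ is taken as **pure Lorentzian** — the natural dominant
  limit for liquid-state NMR lines. If your tables use the opposite
  convention, use $1-\beta$.
* $\gamma$ is a **half** width; divide by 2 when importing FWHM
  values.

A pure component $S_k$ is a sum of such peaks. Peaks are grouped by a
chaining rule: scanning positions in ascending order, a peak opens a
new group when it deviates by more than $\Delta\nu = 0.12$ ppm from
its predecessor, otherwise it joins the current group (a group can
therefore span more than $\Delta\nu$ in total; only adjacent gaps are
tested). The mixture model is

$$\chi(\nu, \mathbf{w}, \theta) = \sum_{k=1}^{K} w_k\,
S_k(\nu, \theta_{P,k}, \theta_{S,k}, \theta_{GS,k}, \theta_{PB,k}),$$

with per-component weight $w_k \ge 0$ and shift $\theta_{S,k}$, one
shift $\theta_{GS}$ per peak group, and a width multiplier
$\theta_{PB,k}$ applied to every $\gamma$ of the component. A
per-peak position jitter $\delta\omega$ completes the perturbations
used during simulation. All position terms are additive
($\omega + \delta\omega + \theta_{GS} + \theta_S$), so their
composition order is immaterial. The simulator evaluates peaks on an
ascending ppm grid; mass falling outside the grid is silently
truncated, with a warning when more than 1% of a component's
analytic area is lost.

## Synthetic training data

Two generators produce labelled datasets of mixture spectra; both are
pure functions of (inputs, config, seed), rebuilt bit-identically
from a single seeded RNG with a fixed draw order (documented in the
function help pages), and both label each spectrum with the
*noise-free* trapezoidal area of every component.

**From measured pure spectra** (`makeDatasetXi`): per spectrum and
component, draw a line-broadening factor uniformly from the discrete
set {0.2, 0.5, 0.8, 1.0, 1.5} Hz, a shift uniform on ±0.015 ppm, and
a target area uniform on 0–180 a.u.; broaden, shift, then rescale the
measured pure spectrum so its area equals the target, and sum the K
altered components. Because measured noise scales together with the
signal, label conservation holds only up to that noise (~1%).

**From the spectral model** (`makeDatasetXii`): per component draw
$\theta_S$ (±0.015 ppm), $\theta_{PB}$ (±15%), a target area
(0–180 a.u.); per group $\theta_{GS}$ (±0.01 ppm); per peak
$\delta\omega$ (±0.005 ppm). The weight is set to
$w_k = A_k^{\mathrm{target}} / \int S_k$, so the label *is* the
target area. Noise is then resampled point-wise with replacement from
an empirical pool harvested from baseline regions of a measured
spectrum, and scaled per spectrum by $1+u$, $u \sim U(-0.15, 0.15)$.
Labels are computed before noise; the noise draws are consumed even
in noise-free builds so that toggling noise cannot change anything
else.

Design choices made where the mechanism was genuinely open:

* The Hz-scale **line-broadening factor** is realised as convolution
  with a unit-area Lorentzian of FWHM = lb Hz — the frequency-domain
  equivalent of exponential FID apodization, the operation the factor
  names in NMR processing. The discrete kernel is truncated at ±60
  HWHM and renormalised to unit sum, so convolution redistributes
  each point's mass exactly and the window integral is conserved for
  interior peaks; the ~1% far-tail kernel mass is folded back by the
  renormalisation rather than leaking off-grid.
* The **noise factor** range ("±15%") is read as a multiplicative
  perturbation of the empirical noise amplitude. An additive reading
  (percentage of maximum signal) would couple noise level to the
  strongest component, which contradicts how baseline noise arises;
  the multiplicative reading is also the one the pool-resampling
  mechanism supports naturally.
* Per-peak jitter is sampled independently per peak (not per group);
  group-coherent movement is already carried by $\theta_{GS}$.

## The network

The regression network is deliberately minimal: one 1-D
convolutional layer with kernel 9, stride 9 and 4 filters —
**locally connected**, i.e. every output position owns its kernel and
bias, which suits spectra because a given ppm position always means
the same chemistry — with ELU activation, flattened into a K-node
dense layer with ReLU output (areas cannot be negative). With $P =
\lfloor(L-k)/s\rfloor + 1$ positions the parameter count is
$PF(k{+}1) + PFK + K$; the production geometry ($L = 1692$ points
over 5.6–9.0 ppm, $K = 4$) gives $P = 188$ and 10,532 parameters.
The 1692-point default is the grid length consistent with that count
and window; it is a configuration default, not a constraint.

Training: inputs and labels are normalised to $[0,1]$ by their
dataset maxima (both scalars are stored in the model and applied
inversely at prediction time); a seeded 95:5 split separates
training and validation rows; the loss is plain MSE under Adam
($\beta_1 = 0.9$, $\beta_2 = 0.999$, batch 1024) with a step
learning-rate schedule $10^{-4} \to 3\cdot10^{-5}$ (epoch 170)
$\to 10^{-5}$ (epoch 240) over 400 epochs. The printed three-step
schedule ends in a repeated $10^{-5}$, so the third step is a no-op
and is omitted from the default schedule table. Additive white
Gaussian noise of sd 0.04 (normalised units) is drawn freshly for
every minibatch and added to training inputs only — fresh-per-batch
is standard augmentation practice and matches the regularising role
the noise plays; evaluation always sees clean inputs, so prediction
is deterministic. Early stopping is deliberately **not** applied:
the validation-set minimum reflects only the narrow concentration
range a real campaign visits, while training to convergence keeps
the model accurate over the full 0–180 a.u. label space. When an
external reference set (spectra plus areas from a more accurate
analyzer) is supplied, the model is additionally scored against it
after every epoch in back-transformed units, giving a second
validation curve on real measurements.

One integer seed drives split, initialisation, epoch shuffles and
AWGN through a single RNG stream; with R's single-threaded BLAS the
whole training run is bit-reproducible.

The forward/backward pass and Adam are implemented directly in
vectorised R. The model is small (a few thousand parameters) and the
locally-connected layer reduces to $P$ independent
$\text{batch}\times k$ by $k\times F$ products, so this is fast
enough for the package's scale and keeps training exactly
reproducible and dependency-free. A `convType = "shared"` switch
provides an ordinary weight-shared convolution for ablation.

## The hard-model baseline

`fitMixture` minimises
$\sum_\nu (y(\nu) - \chi(\nu, \mathbf{w}, \theta))^2$ with box
constraints ($w \ge 0$; $\theta_S$ within ±0.015 ppm, $\theta_{GS}$
±0.01 ppm, $\theta_{PB}$ within ±15% by default — each block can be
pinned at identity). Numerical choices:

* Optimisation is bounded Levenberg–Marquardt (`minpack.lm::nls.lm`,
  ftol/ptol $10^{-10}$, 500-iteration cap), warm-started from a
  **non-negative linear least-squares** solution for $\mathbf{w}$
  with all perturbations at identity — a convex starting point.
* Parameters are released **progressively**: weights only, then
  $+\theta_S$, then $+\theta_{GS}$, then $+\theta_{PB}$, each stage
  starting at the previous stage's optimum. The width multipliers
  couple strongly with the weights (a broadened peak of equal area is
  lower and wider) and the component/group shifts are nearly
  degenerate, so releasing everything at once opens local minima
  that progressive release avoids; the stage objectives are
  non-increasing by construction and are recorded in
  `diagnostics$rssStages`.
* An all-zero spectrum short-circuits to $w = 0$ with zero residual.
* Non-convergence is reported in the `FitResult`, never thrown.

`fitPureComponent` estimates a pure component's peak table from a
measured spectrum (bounds $\alpha \ge 0$, $\gamma > 0$,
$0 \le \beta \le 1$, $\omega$ inside the grid), starting from a
user-supplied table or from local maxima above 5% of the spectrum
maximum; groups are assigned afterwards by the chaining rule.
Overlapping-peak ambiguity is left to the optimizer — no splitting
heuristics.

## Reference-data curation

Two time-stamped analyzer streams (a noisy online low-field series
and an accurate reference series) are merged and filtered:

1. each target timestamp is paired with the reference row of minimal
   absolute time difference (an exact midpoint tie goes to the
   earlier row);
2. a centred 11-point window slides over the online series; per
   component an ordinary least-squares line against the true
   timestamps (not sample indices) is fitted, and the window is
   steady iff $|$slope$| < 0.1$ mol/h **and** the residual standard
   deviation about the fitted line $< 0.01$ mol/L for *all*
   components. The mask marks window centres (`markAll` flags whole
   windows; `rawStd` switches the spread to the plain sd — the
   residual reading is the default because a window sliding onto a
   ramp has a large raw sd even when perfectly linear, which would
   conflate drift with scatter). Thresholds are strict inequalities.
3. pairs in which any component disagrees by more than 0.04 mol/L
   between the two analyzers are dropped (strictly greater than:
   exactly 0.04 is kept);
4. Kennard–Stone selects a uniformly covering subset: start with the
   two points at maximal Euclidean distance, then repeatedly add the
   candidate maximising the minimal distance to the selected set.
   Distances are Euclidean on unscaled component vectors (a min-max
   scaling flag exists); ties break to the lowest row index, making
   the selection deterministic and a prefix chain in $k$.

Transport-delay estimation is out of scope; measured delay constants
can be applied to the timestamps before pairing.

## The toy system, and what the tests do and do not show

`makeToyLibrary` builds a fixed 4-component system whose components
play the roles of the reaction species in an organolithium coupling
(a nitroaromatic reagent, a free and a lithiated amine, a lithiated
product): 3–7 pseudo-Voigt peaks per component with benchtop-typical
widths (HWHM 0.014–0.020 ppm), three spectral regions deliberately
shared between two components, rendered pure spectra with 0.5% white
measurement noise, a baseline noise pool, and a 200-point process
trajectory (four plateaus joined by ramps of 0.1–0.5 mol/L per hour,
online noise sd 0.003 mol/L, four reference-side outliers of
0.08 mol/L injected at known rows). The peak tables are fixed by
design; the seed drives only the stochastic parts, so the library
regenerates bit-identically.

The default toy grid has 423 points over 5.6–9.0 ppm — small enough
that dataset generation and a 50-epoch training run finish in well
under a minute, while keeping the production kernel geometry
($k = s = 9$, $P = 47$). The scaled-down training experiment used in
the tests (5,000 model-based spectra, batch 256, constant learning
rate $10^{-3}$, 50 epochs) was sized once as the smallest problem on
which learning dynamics are unambiguous; the production defaults in
`AnnConfig()` remain the full-size recipe.

What passing the toy-system tests shows: the mixture model, the
generators, the network and the curation chain are internally
consistent — labels are conserved, known parameters are recovered,
oracles agree, reruns are bit-identical. What it does **not** show:
performance on real measured spectra. The toy system has ideal
pseudo-Voigt line shapes, white noise, a perfectly linear baseline
and no unmodelled species; real benchtop data add phase and baseline
error, temperature-driven shift drift beyond the simulated ranges,
and chemistry the model does not contain. The package consumes
already baseline-corrected, phased and aligned spectra; those
preprocessing steps are outside its scope, as are vendor raw-data
formats and 2-D or time-domain modelling.

## Known limitations

* The pseudo-Voigt is an approximation to the true Voigt profile; no
  convolution-based Voigt evaluation is provided.
* `fitMixture` releases (w, θ_S, θ_GS, θ_PB) — hierarchical model
  maintenance (adding/removing peaks during a fit) as found in
  commercial hard-modeling suites is not implemented.
* Dataset bundles are plain-text directories (TSV matrices plus JSON
  metadata with seed and config hash): transparent and
  dependency-free, at the cost of file size for very large builds —
  full-size 300,000-spectrum datasets are better regenerated from
  their seed than stored.
* JCAMP-DX input is not implemented; spectra enter as two-column
  text (a descending ppm axis is accepted and flipped).
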