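---
title: "Acquisition speed, sample dimensionality and fit-quality control in localization microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acquisition speed, sample dimensionality and fit-quality control in localization microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Localization microscopy (PALM/STORM) builds a super-resolution image by
activating sparse random subsets of fluorophores, fitting each isolated
point-spread function (PSF), and accumulating fitted positions over many
camera frames. In live-cell work the binding constraint is time: the
experimenter controls the per-frame activation density $a$ (activations
per unit sample area per frame) and wants the target reconstruction
quality in as few frames as possible. Too low an $a$ wastes frames; too
high an $a$ overlaps the PSFs, and single-emitter fitters then either
reject the fits or — worse — fit the overlap as one molecule at a biased
position. The second failure mode is silent: it *sharpens* individual
structures while destroying the ability to separate nearby ones, and
resolution metrics computed from the data alone (Fourier ring
correlation, FRC) report an improvement.

`locspeed` packages three things around this problem:

1. a closed-form model of the frames-to-quality cost and its optimum,
   parameterized by the local dimensionality of the labelled structure;
2. a simulator (photoswitching Markov chain + pixel-integrated Gaussian
   PSF + EMCCD noise) and a reference localizer, so every claim can be
   exercised against ground truth;
3. a per-acquisition, user-trainable random-forest classifier that flags
   each localization as `good`, `background` or `too_dense`, plus FRC
   and density-based evaluation tools.

## The acquisition-time model

Activations are Poisson in space and time with density $a$. A fitted
activation at position $x$ is spoiled if any second activation falls in
its *exclusion area* $E(x)$ — the intersection of a disc of radius $r$
(the minimum separation the analysis algorithm tolerates, typically
400–600 nm for stock single-emitter fitters at $\lambda = 488$ nm,
NA 1.4) with the labelled structure. The expected number of frames to
reach a density $Q$ of successful localizations per unit area is

$$T(a) = \frac{Q}{a\,e^{-aE}},$$

with a unique interior minimum at $a^\* = 1/E$, where
$T_{\min} = e\,Q\,E$. Everything therefore hinges on $E$, which depends
on the structure's dimensionality $D$ at the scale of $r$:

| structure | $D$ | $E$ |
|---|---|---|
| point-like object ($w_1 \times w_2 \ll r$) | 0 | $w_1 w_2$ |
| strand of width $w$ | 1 | $2wr$ |
| extended patch | 2 | $\pi r^2$ |

Because $T_{\min} \propto E$, each integer step in dimensionality costs
roughly an order of magnitude in acquisition time: a 25 nm strand versus
an extended patch at $r = 600$ nm differ by $\pi\,600^2 / (2 \cdot 25
\cdot 600) \approx 38$; a 7 nm strand versus a patch at $r = 400$ nm by
almost a factor of 100. `exclusion_area()` implements the closed forms,
`intersection_area_numeric()` is the Monte-Carlo oracle for arbitrary
geometries, and `plan_acquisition()` wraps the whole calculation. The
default target is $Q = 1/25\ \mathrm{nm^{-2}}$ (one localization per
5 × 5 nm region). All internal lengths are nm and areas nm²; a single
canonical unit avoids silent factor-of-$10^6$ errors between nm² and
µm² quantities.

$E = 0$ (an idealized point with no spatial extent) makes $T = Q/a$
decrease without bound; `optimal_activation()` flags this degenerate
case instead of returning an infinite optimum.

## The simulator

`simulate_acquisition()` composes three stages.

**Emitters and photoswitching.** Emitters are seeded uniformly on the
structure at a tagging density (benchmark value 0.5 nm⁻²) and evolve
through a four-state per-frame Markov chain (inactive, active, dark,
bleached). The default regime is the live-cell *pool* model: a large
reservoir of inactive fluorophores of which a fraction `p_act` activates
each frame, active emitters return to the pool with probability 0.5 per
frame, dark and bleached transitions off. Throughout the package
"activation density" means the *observable* estimator — the mean number
of active emitters per frame divided by the tagged area — because that
is the only version measurable on real data. In the pool model an
activation stays on for $1/p_\mathrm{deact}$ frames on average, so the
stationary active density is (tagging density)
$\times\,p_\mathrm{act}/p_\mathrm{deact}$; `p_act_for_density()`
inverts this to configure a simulation for a target density. With bleaching
negligible and the pool much larger than the number of activations, the
per-frame active count is Poisson-like, which is exactly the assumption
of the closed-form model. An emitter switching on mid-frame contributes
a uniform random fraction of the frame's photon budget on its first
active frame, producing the dim partial events a classifier must cope
with. For large structures the default fixtures reduce the tagging
density (0.01 nm⁻² for the 3.5 µm plane, 0.1 nm⁻² for the strand); the
pool stays 50× larger than the number of activations in any simulated
sequence, so the pool approximation is unaffected while the emitter
state vector stays tractable.

**Optics.** The PSF is a pixel-integrated symmetric Gaussian with
$\sigma = 0.21\,\lambda/\mathrm{NA} \approx 73$ nm at the default
$\lambda = 488$ nm, NA 1.4 (the standard Airy-core approximation;
vectorial PSFs are out of scope). Pixel size 110 nm. Integration uses
the error-function mass per pixel, not point sampling, so the rendered
flux equals the photon budget (≈450 photons for a full-frame activation,
taken to be *detected* photoelectrons before gain) to machine precision
on an unclipped grid.

**Camera.** EMCCD: Poisson shot noise on photoelectrons
(QE 0.9), an electron-multiplying register modelled as
Gamma(shape = $n_{pe}$, scale = gain) — normalized by the gain so one
photoelectron is one count in expectation while the characteristic
excess-noise factor of 2 is preserved — then Gaussian read noise (1
count RMS) and a baseline offset of 100 counts, rounded to non-negative
integers. Gain 1 bypasses the EM register entirely, which is what the
noise-free flux tests use.

Coordinates: x along columns, y along rows, origin at the outer corner
of pixel (0, 0), pixel centres at $(i + 0.5) \times 110$ nm. Identical
seeds give bit-identical stacks.

## The reference localizer

The localizer is deliberately a documented stand-in, not a clone of any
published tool: per frame it band-pass filters (difference of
Gaussians), finds local maxima above a robust threshold with a 3-pixel
minimum separation (ties broken toward the lowest row, then column),
and least-squares fits an elliptical pixel-integrated Gaussian in an
11 × 11 window (Levenberg–Marquardt, analytic Jacobian, initial width =
optics sigma, initial position = candidate pixel centre). Precision is
reported with the Thompson-style estimate including the background term
and the EM excess-noise factor.

Two width-filtering policies are exposed. `reject_fits()` defaults to
the strict single-emitter bounds (fitted sigma within 0.7–1.5× the
optical sigma, x/y asymmetry below 1.5), which removes most merged
two-emitter fits — a 300 nm pair fits with sigma well above 1.5×
single-emitter width. `localize_stack()`'s *default* config, however,
applies no width filter at all (only degenerate fits — non-convergent,
runaway, or collapsed — are dropped): stock configurations of the
widely used single-emitter packages return unfiltered fits, and it is
precisely those accepted misfits that create the silent-failure regime
the classifier exists to catch. A strict table is one configuration
change away. This choice is what lets the package
reproduce the qualitative acquisition-speed phenomenology: counting
*all* returned localizations, frames-to-$Q$ keeps falling or plateaus
as the activation density grows (artificial sharpening), while counting
only truly good localizations recovers the interior optimum the theory
predicts.

`separation_sweep()` renders two equal emitters at decreasing
separations and classifies each separation as *accurate* (two fits
within a 25 nm inward-bias tolerance), *biased* (two fits, pulled toward
the midpoint) or *merged* (one fit). The three regimes partition the
separation axis; `estimate_exclusion_radius()` reports the
merge/accurate boundaries and recommends the conservative accurate
threshold as $r$. For this fitter at default optics the noise-free
boundaries are ≈250 nm (merge) and ≈350 nm (accurate) — tighter than
the 400–600 nm reported for the stock analysis packages, as expected
for a fitter whose detector merges candidates below 3 pixels; the
bracket is fitter-specific and the sweep is the instrument for
measuring it, not a constant.

## Patch features and PCA

For each localization a 21 × 21 pixel patch is cut from its frame,
resampled (one composed bilinear pass) so the localization sits at the
centre of the middle pixel, rotated so the Sobel gradient of the
σ = 1 px smoothed patch at the centre points vertically, and multiplied
by an axis-aligned Gaussian window (σ = 5 px, covering the PSF core
while down-weighting the rim). The same transform is applied to the
previous and next frames; a missing neighbour (first/last frame) is
replaced by a copy of the current patch and flagged. The raw feature is
the fixed-order concatenation `[current 441 | previous 441 | next 441 |
sigma, intensity, offset, bkgstd, uncertainty | has_prev, has_next]` —
1330 dimensions. Each element is replaced by the natural log of its
magnitude (a small epsilon keeps zeros finite), because pixel
intensities span orders of magnitude within one acquisition and PCA on
raw intensities would be dominated by a handful of bright patches; the
log-normal assumption is much milder. PCA (fitted on the covariance of
*this* acquisition's features, never reused across data sets) reduces
to 20 components; a basis fingerprint travels with the features and the
trained model so a forest can never silently be applied in the wrong
coordinate system. The Gaussian window is applied after the
shift+rotation, so it stays axis-aligned in the patch frame.

## The classifier

Labels are three-valued: `good` (a single fluorophore), `background`
(a noise fluctuation) and `too_dense` (a fit corrupted by overlapping
activations). ~300 localizations are chosen for labelling by
time-stratified sampling (equal counts per acquisition-time stratum) so
the training set spans the whole sequence. On simulated data
`oracle_label()` stands in for the human: `too_dense` if two or more
emitters were active within 500 nm of the localization in its frame,
else `good` if exactly one emitter lies within 250 nm and the error is
under 3× the reported uncertainty, else `background`.

The forest has 300 trees, each split drawn from
$\lceil\sqrt{20}\rceil = 5$ random components, unlimited depth, minimum
leaf 1, majority vote. One design choice departs from a plain forest:
each tree's bootstrap is drawn *class-balanced* (per-class sample count
equal to the rarest class). In the overlap-rich regime the labels are
80–95% `too_dense`; with plain bootstraps the majority vote simply
reproduces the majority class and the per-class recalls of the rare
classes — the quantities a user of a quality-control tool actually cares
about — are zero. Balanced bootstraps trade a few points of raw accuracy
for non-trivial minority recall. Per-class recall should always be
inspected alongside any single summary number.

Known limitation (reproduced deliberately): a classifier can only learn
what its labels encode. The oracle counts *active* emitters, including
ones whose sub-frame on-fraction contributed almost no photons, so in
the dense regime a sizeable share of `too_dense` labels are invisible in
the patch. Measured on the 2×-optimal-density plane benchmark, even a
generously trained 3-class forest tops out near 0.67 balanced accuracy
against the oracle; with the 300-label protocol it reaches ≈0.5. The
same mechanism, with human labels, is why vesicles 200 nm apart — below
what a labeller can distinguish by eye — retain misclassified bridge
localizations while 400 nm pairs are cleaned effectively.

## Evaluation

Reconstructions are 2D histograms at 10 nm pixels (floor-division
binning). `frc_resolution()` splits the localizations into random
halves, renders both on a common square grid, correlates per Fourier
ring (1-pixel rings, no curve smoothing), averages over 20 random
splits, and reads the resolution at the fixed 1/7 threshold with linear
interpolation between rings; a curve that never crosses is reported as
unresolved, not as a number. Sample area is estimated from a thresholded
(> 0 counts by default) reconstruction with 8-connected components
smaller than 10 pixels removed — a reproducible replacement for
hand-annotating the structure outline. `frames_to_quality()` extrapolates
linearly from the per-frame localization rate, which is how frame counts
far beyond any practical simulation length are estimated.
`subsample_frames()` trims the first and last 5% of frames (the
documented default; the head of a real acquisition is anomalously dense
and the tail motion-blurred) and samples uniformly at random so repeat
localizations of one emitter in consecutive frames cannot inflate
short-sequence FRC values.

The brightness-sum proxy (sum of fitted intensities over the median
single-fluorophore intensity) estimates the number of *activated*
fluorophores rather than the number of returned fits: a merged fit to
two overlapping emitters is still fitted, with roughly doubled
brightness, and the proxy counts it twice where the plain count sees
one.

## Problem sizes and what the tests do (and do not) show

The benchmark structures are the 8 × 8 nm point, the 8 × 3,520 nm
strand, the 3,520 × 3,520 nm plane and the four 30 nm vesicles at
(0,0), (200,200), (200,400), (400,600) nm. Stochastic benchmarks run at
200 frames per condition with 2–3 seeds per point of a five-point
activation-density ladder, and frames-to-quality is extrapolated from
the measured per-frame rate; these sizes are the package's test scale,
chosen so the full suite exercises every pipeline end-to-end while
remaining routine to run. The simulator reproduces Poisson activation,
realistic EMCCD noise and sub-frame blinking, but not drift, z-structure,
non-uniform labelling, varying background, or fluorophore heterogeneity
— so passing tests validate the method's internal logic and its
closed-form predictions, not performance on any particular real sample.
The live-cell factor-of-30 observation between microtubule and
focal-adhesion imaging speed is a property of the original experimental
data and is not reproducible from simulation; the package instead checks
the >10× ordering between its own simulated 1D and 2D structures.

## Numerical choices

* Monte-Carlo intersection areas: 10⁶ points by default (~0.1% relative
  error), fixed configurable seed.
* LM fitting: max 100 iterations, `ftol = ptol = 1e-8`; fits that run
  outside the window or collapse to non-positive width/amplitude are
  dropped with a reason rather than returned.
* Detection threshold: 4 robust SDs of the band-passed frame plus a 5%
  relative floor (the floor suppresses PSF side-lobes in noise-free
  images); detection ties broken toward the lowest (row, column).
* Patch extraction at image borders reflects the image and flags the
  record; gradient magnitudes below 1e-12 leave the patch unrotated.
* PCA: `prcomp` on mean-centred log-features; components ordered by
  decreasing eigenvalue; at least k+1 observations required.
* FRC rings: 1 Fourier pixel wide; resolution read by linear
  interpolation between the bracketing rings.
* All randomness flows from explicit integer seeds; stages re-run from
  the same seed are bit-identical.
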