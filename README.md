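# locspeed

Acquisition-speed planning and fit-quality classification for
single-molecule localization microscopy (PALM/STORM).

## The problem

In localization microscopy the resolution of the reconstruction is
limited by the density `Q` of successfully localized activations, and in
live-cell work the number of camera frames you can afford is the binding
constraint. The per-frame activation density `a` is the main control
knob: too low wastes frames, too high overlaps the PSFs and the
single-emitter fitter silently returns biased "merged" positions that
*look* sharper while destroying real structure.

`locspeed` implements the quantitative version of this trade-off. An
activation at `x` is spoiled if a second activation lands inside its
exclusion area `E(x)` — the intersection of a disc of radius `r` (the
minimum separation the analysis algorithm tolerates, 400–600 nm for
common single-emitter fitters at λ = 488 nm, NA 1.4) with the labelled
structure. With Poisson activations, the frames needed to reach a
reconstruction density `Q` are

    T(a) = Q / (a * exp(-a * E)),

minimized at `a* = 1/E` with `T_min = e * Q * E`. Since `E ≈ c(x) * r^D`
with the local dimensionality `D` of the structure (`E = w1*w2` for a
point, `2wr` for a strand of width `w`, `πr²` for an extended patch),
every integer step in dimensionality costs roughly an order of magnitude
in acquisition time. The package also ships a full simulator
(Markov-chain photoswitching, pixel-integrated Gaussian PSF, EMCCD
noise), a reference localizer with a two-emitter separation sweep that
measures `r`, per-localization patch features (21×21×3 aligned windows,
log transform, per-acquisition PCA to 20 components) and a 300-tree
random-forest classifier that labels each localization `good`,
`background` or `too_dense`, plus Fourier-ring-correlation resolution
over 20 random half-splits.

## Worked example

How much longer does an extended 2D structure (a focal adhesion) take to
image than a 25 nm microtubule, at the same target quality?

```r
library(locspeed)

fa <- make_structure("plane")                       # 3.52 x 3.52 um patch
mt <- make_structure("strand", size_nm = c(25, 20000))

plan_acquisition(mt, radius_nm = 600)
#> <acquisition_plan> r = 600 nm, Q = 0.04 nm^-2
#>   E      = 3e+04 nm^2 (0.03 um^2)
#>   a*     = 3.333e-05 nm^-2 per frame (33.33 um^-2)
#>   T_min  = 3262 frames

plan_acquisition(fa, radius_nm = 600)
#> <acquisition_plan> r = 600 nm, Q = 0.04 nm^-2
#>   E      = 1.131e+06 nm^2 (1.131 um^2)
#>   a*     = 8.842e-07 nm^-2 per frame (0.8842 um^-2)
#>   T_min  = 1.23e+05 frames

speed_ratio(fa, mt, radius_nm = 600)
#> [1] 37.69911
```

The strand's exclusion area is 0.03 µm², the patch's 1.13 µm², so the
patch needs ~38× more frames at each structure's own optimal activation
density — and its optimal density is ~38× lower.

The simulation side closes the loop end to end:

```r
fx  <- make_fixture("fig_strand", scale = "ci", seed = 1)   # 200 frames
tab <- localize_stack(fx$stack)           # detect + fit, unfiltered
lab <- oracle_label(tab, fx$sidecar)      # ground-truth labels
fm  <- build_feature_matrix(fx$stack, tab)
idx <- stratified_sample(tab, 300, seed = 1)
rf  <- train_forest(fm$reduced[idx, ], lab$label[idx], seed = 1,
                    fingerprint = fm$fingerprint)
pred <- classify_all(rf, fm)
split_reconstruction(tab, pred)           # good vs misfit tables
frc_resolution(tab, n_splits = 20, seed = 1)
```

A thin command-line front end over the same functions is installed at
`inst/cli/locspeed.R` (`plan`, `simulate`, `localize`, `sweep`,
`evaluate`, `classify`, `make-fixture`).

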