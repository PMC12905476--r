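# stemmorph

Quantitative morphometrics and visual-field reconstruction for larval
lacewings (Neuroptera) and other holometabolan larvae with simple eyes
(stemmata). The package is aimed at workers comparing digitized head
silhouettes of extant and fossil larvae — e.g. amber inclusions — and asking
two questions: *does a new specimen fall outside the known range of head
shapes?* and *could its eyes have supported binocular (stereoscopic)
vision over the prey-capture range of its stylets?*

## What it computes

**Outline morphometrics.** A closed head-plus-stylets outline is decomposed
by elliptical Fourier analysis. For a contour parameterized by arc length
*t* over perimeter *T*, each harmonic *n* contributes a quadruple
(*a<sub>n</sub>*, *b<sub>n</sub>*, *c<sub>n</sub>*, *d<sub>n</sub>*):

    x(t) = a0 + Σ_n [ a_n cos(2πnt/T) + b_n sin(2πnt/T) ]
    y(t) = c0 + Σ_n [ c_n cos(2πnt/T) + d_n sin(2πnt/T) ]

computed by the exact Kuhl–Giardina closed forms for piecewise-linear
contours. Harmonic power *P<sub>n</sub>* = (*a<sub>n</sub>*² + *b<sub>n</sub>*² +
*c<sub>n</sub>*² + *d<sub>n</sub>*²)/2 calibrates how many harmonics carry a
target fraction (default 99%) of shape variation. Normalized coefficients
feed a covariance PCA; group occupancy in the morphospace is measured with
convex hulls, pairwise hull overlap, and per-specimen outside-all-hulls
flags.

**Allometry.** Ordinary least squares (or major-axis) regression of
log₁₀(largest-lens diameter) on log₁₀(head length); specimens with residuals
above a cutoff are flagged as having disproportionately large eyes.

**Stemma optics.** A 2D dorsal-plane model of a flat-lensed simple eye:
a lens segment of aperture *A*, a retina of extent *E* at depth *D* behind
it. The limiting rays connect each retina edge to the opposite aperture
edge, giving internal half-angle arctan((*E*/2 + *A*/2)/*D*); at the flat
air–lens interface Snell's law maps internal angle θ to external angle
arcsin(*n* sin θ) (default *n* = 1.4). The left and right monocular fields
are intersected to obtain the binocular region, its onset distance along
the midline, and its relation to the stylet capture sector
(`between_stylets`, `beyond_stylets`, `none`). Four eye-geometry scenarios
(short flat baseline, long tapering, long protruding, tilted) are evaluated
in both geometric and refractive mode.

**Synthetic data.** Parametric generators produce head outlines with group
structure (tight extant cluster, dispersed fossils, a wide-headed
high-eye-protrusion outlier), power-law measurement tables with implanted
outliers, and preset head/eye layouts — so the full pipeline runs and is
tested without any specimen downloads.

## Worked example

```r
library(stemmorph)

set <- gen_population(population_spec(seed = 1))   # 20 extant + 20 fossil + 1 outlier
pca <- run_pca(build_matrix(set, n_harmonics = 14))
occ <- morphospace_occupancy(pca)
print(occ)
#> <occupancy_report> axes 1/2
#>   extant: area 0.006612
#>   fossil: area 0.04495
#>   new: area 0 (degenerate)
#>   specimens outside all hulls: 1
occ$outside_all["new_01"]
#> new_01
#>   TRUE
```

The extant hull is ~7× tighter than the fossil hull and the implanted
wide-headed specimen plots outside both occupied regions — the morphospace
signature of a genuinely novel head morphology.

```r
evaluate_scenarios(gen_layout("flat_short"))[, c(1:3, 6)]
#>        scenario       mode feasible        relation
#> 1    flat_short  geometric     TRUE between_stylets
#> 2    flat_short refractive     TRUE between_stylets
#> 3 tapering_long  geometric     TRUE  beyond_stylets
#> 4 tapering_long refractive     TRUE between_stylets
#> 5  long_clipped  geometric    FALSE  beyond_stylets
#> 6  long_clipped refractive    FALSE  beyond_stylets
#> 7        tilted  geometric     TRUE            none
#> 8        tilted refractive     TRUE            none
```

Only the short flat eye is both anatomically feasible and yields a
stereoscopic region between the stylets; making the eye longer pushes the
overlap beyond the prey-capture range unless refraction is invoked, and a
tilted inner axis destroys the overlap entirely.

The pipeline entry points `run_morphometrics()`, `run_allometry()` and
`run_vision()` wrap these steps behind a single config (YAML/JSON) and
write CSV/JSON reports plus SVG renderings; `inst/scripts/stemmorph-cli.R`
exposes them as shell subcommands.

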