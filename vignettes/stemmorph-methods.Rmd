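---
title: "Methods: outline morphometrics and stemma visual fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: outline morphometrics and stemma visual fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemmorph)
```

This vignette documents the models behind `stemmorph`, the assumptions they
make, the defaults and why they were chosen, and what the synthetic-data
generators do and do not emulate.

## The comparative problem

Predatory lacewing larvae catch prey with a pair of forward-projecting
stylets and, in several lineages, have evolved enlarged forward-facing
simple eyes (stemmata) whose left and right visual fields overlap, giving
binocular depth cues over the strike zone. Assessing whether a newly found
(often fossil) larva belongs to a known morphotype, and whether its eye
arrangement could have supported such vision, requires two quantitative
tools: a shape space in which head silhouettes can be compared at scale,
and a geometric-optics model of the eyes that can be evaluated under
alternative anatomical assumptions, since internal eye structure is rarely
preserved.

## Elliptical Fourier analysis

A digitized head outline is a closed planar loop. We store loops *open*
(the final point does not repeat the first) so that no boundary segment is
counted twice in the Fourier integrals, and we force counterclockwise
orientation before decomposition because reversing a contour flips the
signs of half the coefficients. The coordinate convention is y-up with the
anterior of the head toward +y; "forward" in the optics model means +y on
the midline.

The contour is parameterized by arc length. For a polygonal contour the
Fourier integrals have exact closed forms in the segment increments
(Kuhl–Giardina); `efa_decompose()` implements these sums directly, and the
test suite checks them against trapezoidal quadrature of the defining
integrals on a battery of circles, ellipses, squares, and random smooth
blobs (relative error < 1e-4). The DC terms are computed as the exact
arc-length centroid of the contour. One consequence of arc-length
parameterization worth noting: an ellipse traced uniformly in its polar
angle is *not* uniform in arc length, so its decomposition retains a small
amount of higher-harmonic power (about 1% for a 3:1 ellipse). This is a
property of the method, not an artifact.

Normalization follows the usual outline-analysis sequence:

* **centering** zeroes the DC terms (position);
* **scaling** divides all harmonic coefficients by the semi-major axis
  length of the first-harmonic ellipse (the largest singular value of the
  2×2 first-harmonic matrix), the standard size functional for outlines;
* **alignment** (off by default) standardizes start point and rotation via
  the first-harmonic ellipse. It is off by default because consistently
  digitized dorsal-view outlines share an orientation already, and
  alignment discards a real signal (head tilt relative to stylets) if the
  digitization was consistent. The residual half-period/semi-axis
  ambiguities of the phase normalization are resolved deterministically:
  the semi-major axis is preferred, and the first non-negligible trailing
  coefficient is made positive.

Harmonic power \(P_n = (a_n^2+b_n^2+c_n^2+d_n^2)/2\) excludes the DC terms,
which encode position rather than shape. `calibrate_harmonics()` finds the
smallest harmonic count whose *mean* cumulative power fraction across
specimens reaches a threshold (default 0.99). The mean-across-specimens
rule treats the threshold as a statement about the dataset; a
`per_specimen` mode (every specimen must reach the threshold) is available.
Cumulative fractions need a total-power reference that is *larger* than
the candidate range, otherwise the fraction at the maximum candidate is 1
by construction and the calibration could never fail; the reference is the
smaller of the set's Nyquist bound and `max(4 * max_harmonics, 32)`
harmonics.

## Morphospace

Normalized coefficients are flattened one specimen per row in the fixed
order a1, b1, c1, d1, ..., aN, bN, cN, dN. The PCA is a *covariance* PCA —
columns centered, never rescaled to unit variance — because after shape
scaling all coefficient columns share the same units, and per-column
rescaling would inflate the weight of high harmonics that carry mostly
digitization noise. Eigenvector signs are arbitrary, so each component is
flipped if needed to make its largest-magnitude loading positive; this
makes scores reproducible but means the sign of any axis is a convention,
not a finding.

Group occupancy is summarized with convex hulls in a chosen component
plane (PC1/PC2 by default): per-group hull areas, pairwise hull
intersection areas, and per-specimen flags. The hull boundary counts as
inside, which makes outlier calls conservative. Groups with fewer than
three distinct non-collinear points yield a *degenerate* hull of zero
area; degenerate hulls are reported but do not count as occupied regions
when deciding whether a specimen plots "outside all" groups — a
single-specimen group always contains itself and would otherwise make the
flag vacuous.

## Allometry

Eye size scales with body size roughly as a power law, so the trend of
largest-lens diameter against head length is fitted on log10–log10 axes by
OLS of log-lens on log-head, matching the orientation of the usual
scatterplot. Because both measurements are error-prone, major-axis
regression is available (`method = "ma"`); the above-line calls this
package makes are robust to the choice. "Above the trend line" is
operationalized as residual > threshold (default 0, i.e. any positive
residual), with a 1e-10 guard so exact-law data with floating-point-zero
residuals are never flagged. The trend can be fitted to a subset of groups
(e.g. extant only) while residuals are reported for everyone; the default
fits all records, since the source comparison plots all specimens around a
single line.

## Stemma optics

The visual-field model is two-dimensional, drawn in the dorsal plane, which
is where the reconstructions it supports are drawn; no 3D solid-angle
model is attempted. An eye is a flat lens segment (aperture \(A\)) with a
retina segment (extent \(E\)) at depth \(D\) behind it. The field is
bounded by *limiting rays* from each retina edge through the opposite
aperture edge — the wide-acceptance convention, which is the natural one
for a short eye with a large opening angle, giving internal half-angle
\(\arctan((E/2 + A/2)/D)\). The same-side ("narrow") pairing is available
as an option for sensitivity checks.

Refraction is applied once, at the single flat air–lens interface:
\(\theta_{air} = \arcsin(\min(1, n \sin\theta_{in}))\), saturating at
grazing beyond the critical angle. A flat lens has essentially no focusing
power, so the lens interior is treated as optically continuous with the
eye — no second interface is modeled. \(n = 1.4\) is the default, a
reasonable value for arthropod lens material; \(n = 1\) reduces exactly to
the geometric construction and is verified as an identity in the tests.

A tilted eye rotates the inner axis (lens center to retina center) away
from the lens normal while the lens stays in place; the retina stays
perpendicular to the tilted axis. This produces asymmetric boundary rays
and a field that swings opposite to the retina displacement.

Binocular overlap is the polygon intersection of the two monocular fields,
clipped to a finite window (default a square of 10 head lengths — fields
are unbounded cones and polygon arithmetic needs a window; the window is
large enough that it never truncates any overlap the stylets could reach).
The overlap *onset* is the distance from the anterior head margin to the
nearest overlap point along the midline. The stylet capture zone is a
circular sector (radius = stylet reach, angular width = stylet span,
discretized at 256 arc segments, which keeps sector areas accurate to well
under 0.5%). The classification is `between_stylets` when the overlap
intersects the zone with positive area, `beyond_stylets` when the overlap
exists but lies wholly outside it, `none` when there is no overlap.

### Scenarios

Internal eye anatomy is usually unknowable for fossils, so four eye
geometries are evaluated per head, in units of head length
(aperture/extent/depth/tilt): `flat_short` (0.30/0.30/0.35/0°), the
baseline consistent with a wide, short head; `tapering_long`
(0.30/0.24/0.90/0°), a longer eye that tapers posteriorly to fit;
`long_clipped` (0.30/0.30/1.30/0°), a longer untapered eye that protrudes
beyond the head capsule and is flagged anatomically infeasible;
`tilted` (0.30/0.24/0.90/25°), a long eye accommodated diagonally. The
depth values are fixed by the head geometry itself (a short head cannot
house a deep eye); the 25° tilt is the smallest round value at which both
boundary rays of each eye point laterally, which is the configuration the
tilted reconstruction depicts. On the default layout (eyes at ±0.7 head
lengths, stylet reach 1.5, span 60°) these yield: baseline overlap between
the stylets in both modes; tapering-long overlap beyond the stylets
geometrically, pulled within stylet range by refraction at n = 1.4;
long-clipped infeasible; tilted no overlap.

## Synthetic data

The generators exist so that every stage of the pipeline is exercised with
data whose ground truth is known.

`gen_head_outline()` builds a single closed loop — capsule, stylets with
teeth, eye bulges — from parametric pieces, mirrored exactly about the
midline, resampled to equal arc length, with optional smooth Gaussian-bump
noise along the outward normal. The default parameter values encode the
study conditions: capsule up to ~2× wider than long for the novel
morphotype, stylets 1.5× head length, two inner-margin teeth at about 1/3
and 2/3 of stylet length. `population_spec()` fixes the comparative
structure: 20 extant specimens with 4% relative parameter spread, 20
fossils with 12% (three times as dispersed), and one outlier with a 1.9
width ratio and an eye protrusion 4 fossil standard deviations above the
fossil mean. Parameters are drawn from gaussians truncated at physical
bounds by resampling. Seeding is hierarchical: specimen *i* uses
`(seed * 7919 + i) mod (2^31 - 1)`, so any subset regenerates identically.

What the generator does *not* emulate: digitization jitter correlated
along the outline, broken or occluded contours, asymmetric preservation,
and the fine setae of real silhouettes. Its shapes are smoother than real
digitized outlines — they concentrate spectral power in the first ~5
harmonics, whereas real head-plus-stylet outlines need on the order of 14
harmonics for 99% of their variation. For that reason the
population-recovery checks decompose at 14 harmonics (the registration
used for the real comparative dataset) rather than re-calibrating on each
smooth synthetic replicate, and a passing recovery test demonstrates
correctness of the pipeline machinery, not that 5 harmonics would suffice
for real material.

`gen_measurements()` draws head lengths log-uniformly over 0.3–10 length
units (about the span of real larval head lengths across instars) and
applies the power law with gaussian log-residuals; implanted outliers get
a +0.2 log10 offset (a ~1.6× lens enlargement, comfortably above the 0.05
residual spread but of the magnitude real above-line specimens show).

## Numerical choices and edge cases

* All polygon arithmetic (signed areas, convex clipping, point-in-polygon,
  ray entry) is done in double precision with relative tolerances of
  1e-9–1e-12; clipping uses Sutherland–Hodgman against convex clip
  polygons, which every clip region here is (rectangular windows, convex
  fields, sectors of span ≤ 180°, convex hulls).
* Zero-area outlines, zero first-harmonic magnitude (scale/align of a
  degenerate shape), harmonic counts beyond the Nyquist bound, and
  sub-3-point inputs raise immediate errors naming the specimen where
  possible.
* Layouts may deliberately violate eye-in-head containment
  (`long_clipped`); feasibility is a reported flag, not a constructor
  error.
* Reruns are bit-identical: generators are pure functions of their
  parameters and seed, pipeline outputs carry no timestamps, and PCA signs
  are fixed deterministically.

## Problem sizes

The shipped tests and the acceptance script use: outlines of 240–400
points (the pipeline default is 300), harmonic counts up to 64, populations
of 41 specimens, 100 seeded replicates for morphospace recovery (50 in the
acceptance script's reported rates), 200 replicates for slope recovery,
and rasterization steps of 1e-3 head lengths for the overlap-onset oracle.
These sizes were chosen so the full suite completes in a couple of minutes
while every statistical claim is still a ≥95%-of-replicates statement.

## Known limitations

* The optics model is planar; vertical (dorso-ventral) field extent and
  true solid angles are out of scope.
* No acuity or photoreceptor-sampling model: the binocular region says
  where depth cues were geometrically possible, not how well the animal
  resolved them.
* Morphospace comparisons are descriptive (hulls and flags); no
  significance tests of group separation are performed, mirroring standard
  practice for occupancy comparisons.
* Outline topology is a single closed loop; multi-part outlines (separate
  head and stylet contours) are not supported.
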