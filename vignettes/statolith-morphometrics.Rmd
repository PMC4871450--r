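---
title: "Statolith outline morphometrics: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statolith outline morphometrics: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cubozoan medusae are identified by soft characters that are easily
damaged; the statolith — the single hard calcium sulphate structure in
each rhopalium — is the only robust morphological record. This package
implements the full chain from silhouette photographs of a statolith's
three orthogonal faces (proximal, oral, lateral) to species- and
family-level classification, together with a synthetic statolith
generator that makes the whole chain testable without microscope data.

## From image to outline

Input images are near-binary silhouettes (black statolith on white).
They are binarized at a fixed threshold (default 0.5 of the intensity
range; the inputs are already bilevel, so an adaptive threshold would add
fragility without benefit), the largest 8-connected foreground component
is kept, interior holes are filled — the programmatic analogue of the
manual cleanup a microscopist performs on membrane fragments — and the
boundary is traced with Moore neighbour tracing, giving the outline as an
ordered list of boundary-pixel coordinates. Physical scale comes from the
manifest's `um_per_px` column rather than from scale-bar detection: scale
cancels in both L:W ratios and normalised Fourier coefficients, so
automated bar reading would add failure modes without changing any
result. Masks must not touch the image border (the outline would be
clipped); empty masks are errors, not warnings.

Outlines are oriented counterclockwise (signed area positive, y axis up).
Before Fourier decomposition they are smoothed by 300 iterations of the
cyclic (1/4, 1/2, 1/4) moving average — the conventional pre-smoothing of
outline morphometrics, which suppresses pixel-level jaggedness. L:W is
measured on the *unsmoothed* outline: smoothing contracts shapes slightly,
and the traditional measurement should reflect the traced silhouette. The
length definition is the maximum Feret diameter, width the maximum extent
perpendicular to the length axis; both are rotation invariant and
reproducible without human landmark clicks. For large convex hulls the
Feret pair is found by rotating calipers; small hulls use the exhaustive
pairwise scan (which also serves as the test oracle).

## Elliptical Fourier descriptors

Decomposition uses the exact piecewise-linear (chain-sum) Kuhl–Giardina
formulas over the closed polygon, parameterised by cumulative chord
length. This is exact for polygons and independent of sampling density —
no FFT, no resampling step. Twenty harmonics are computed per outline; on
the synthetic shapes three harmonics already carry over 99% of the
harmonic power, and real statoliths, with sharper ornament, need more —
the pipeline logs the per-specimen count as `harmonic_summary$n99` so the
adequacy of the harmonic budget is checkable on any data set.

One consequence of chord-length parameterisation deserves emphasis: an
exact ellipse is *not* a single harmonic under this convention, because
x(s) along an ellipse's arc is not sinusoidal. A 2:1 ellipse keeps about
0.6% of its power above harmonic 1; the "one harmonic describes an
ellipse" intuition is exact only near the circular limit. Tests of the
ellipse limit therefore use near-circular ellipses, and the coefficient
oracle (dense numerical integration of the Fourier integrals) is the
authority for eccentric shapes.

Normalisation to the first harmonic removes size, rotation, and
starting-point information: the start is rotated onto the first ellipse's
major axis, the shape rotated to put that axis horizontal, and all
coefficients divided by the semi-major axis. After normalisation A1 = 1,
B1 = C1 = 0 exactly; D1 (the first-ellipse aspect) is retained in the
coefficient object but excluded — with the whole first harmonic — from
feature vectors, since its sign and magnitude are sensitive to
orientation error. Reflection is deliberately *not* normalised away:
mirror-image statoliths are different objects. The starting-point phase
is defined modulo a half period, which flips the sign of every even
harmonic; we fix the representative by requiring the leading even-harmonic
coefficient to be positive. This makes normalisation a true invariant
(identical coefficients under 100 random similarity transforms and start
shifts, to 1e-6) at the cost of a discrete sensitivity: shapes whose
leading even coefficient sits near zero can flip representative under
tiny perturbations. The synthetic templates keep that coefficient safely
nonzero.

Feature vectors concatenate harmonics 2–20 (4 coefficients each: 76 per
face) in the fixed face order proximal, oral, lateral — 228 variables for
the three-face analysis.

## The statistical battery

* **L:W**: one-way ANOVA per face across species, Tukey–Kramer HSD post
  hoc pairs (studentized range with unequal-n standard errors), then a
  CDA on the three per-face ratios jointly.
* **PCA reduction**: per face, principal components of the correlation
  matrix with eigenvalue > 1 (Kaiser criterion) are retained. "Eigenvalue
  of a coefficient" is read as component retention — raw coefficients do
  not possess eigenvalues. On the default synthetic data this retains
  roughly 20–26 of the 76 coefficients per face.
* **CDA**: canonical variates solve the within⁻¹·between eigenproblem
  (via Cholesky whitening); scores are scaled to unit pooled within-group
  covariance. Wilks' Λ = Π 1/(1+λᵢ) is tested with Rao's F approximation;
  reported degrees of freedom are floored to integers, which reproduces
  the classical worked examples exactly (with 185 observations in 12
  groups: p = 3 gives F(33, 504); p = 83 gives F(913, 1033); six groups
  give F(415, 489); the ANOVA error df is 173). Classification assigns
  each observation to the nearest group centroid in canonical space with
  a −2 log(prior) offset; priors are equal by default, proportional on
  request. A singular pooled within-group matrix (unavoidable when
  retained dimensions approach N − k, as in small demonstration runs)
  triggers a tiny ridge (1e-8 of the mean diagonal) with a warning.
* **Jackknife**: each observation is classified by a CDA refitted on the
  other N − 1 observations. The PCA reduction is computed once on the
  full data set and held fixed across folds — the reduction is a
  separate, earlier step of the protocol, not part of the classifier;
  folding the PCA into each refit would be a different (also defensible)
  protocol and would slightly lower jackknife accuracy.
* **Allometry**: per species, ordinary least squares of the specimen's
  mean NEF coefficient (arithmetic mean of all feature-vector
  coefficients) on statolith length, with the slope t-test p-value.

## The synthetic generator

`default_templates()` encodes the study design the analysis assumes:
12 species nested in 6 families with species counts (1, 3, 2, 3, 1, 2)
and specimen counts 12, 20, 20, 11, 9, 17, 20, 12, 20, 20, 4, 20 (185
specimens, 555 images). Shapes are built in normalised-coefficient space:
a common egg-like base per face (proximal most elongate), family-level
offsets on harmonics 2–8 and on the first-ellipse aspect, and
species-level offsets of the same form at one third the family scale —
so species within a family are more alike than species across families,
which is the central structure the classifier must recover. All offsets
are drawn once from a fixed internal stream; candidates whose outline
self-intersects, or that fail to stay simple under noise probes, are
redrawn deterministically, so the default templates are a constant of the
package.

Each template's face carries two coefficient sets: the *generating*
coefficients (the recipe that specimen sampling perturbs and
reconstructs at 2048 points) and the *base* coefficients — the NEF of the
noise-free outline as the pipeline itself would measure it. Storing the
realized NEF makes ground truth exact: a noise-free specimen reproduces
its template's base coefficients to machine precision, and recovery tests
need no allowance for discretisation bias. (The reconstruct → decompose →
normalise map has no finite-resolution fixed point — at any sampling
density it drifts shapes very slowly toward roundness — so defining truth
as the realized NEF is both cheaper and more honest than chasing
self-consistency.)

Within-species variation adds independent Gaussian noise with standard
deviation `within_species_sd / h` (default 0.025) to each coefficient of
harmonic h: variation between conspecifics is a smooth deformation, and a
1/h profile keeps noisy outlines simple, whereas constant-amplitude noise
at harmonic 20 is boundary wiggle that readily self-intersects. Sizes are
Gaussian (per-species means 150–450 µm, CV 8%, truncated at 40% of the
mean). Exactly one species — the *Malo maxima* analogue — has allometric
drift: harmonics 3–8 shift by two noise units per standard deviation of
length (harmonic 2 is excluded so drift cannot push the sign-fixing
leading coefficient through zero). Faces of a specimen are sampled
independently given the template; cross-face correlation is not modelled,
matching an analysis that concatenates faces without modelling their
dependence.

Rendering centres the outline on a 512 px canvas scaled so the statolith
spans 80% of it, rasterises with a deterministic even-odd scanline fill
at pixel centres, and writes black-on-white PNGs. The NEF round trip
through render → load → trace → smooth → decompose agrees with the source
coefficients to about 2e-3 at 512 px (the tolerance budget is 2e-2), and
improves with resolution.

What passing tests on this generator do *not* show: real statolith
silhouettes have sharper ornament (higher harmonic content), correlated
faces, segmentation artefacts from manual cleanup, and measurement error
in mounting orientation. The generator validates the machinery and the
statistical battery, not the biological effect sizes.

## Numerical choices and degenerate inputs

Sample sizes in the test suite and acceptance script follow the default
design (185 specimens × 3 faces); the demonstration examples use 3
species × 8 specimens. Binarization threshold 0.5; mask components
8-connected; one-observation groups are accepted by the CDA (their
held-out classification can never be correct — warned, not refused);
all-identical ANOVA responses return F = 0, p = 1; outlines need at least
3 distinct points, positive perimeter and nonzero width, otherwise they
are rejected as degenerate with typed conditions. Determinism is treated
as a contract: identical inputs, configuration, and seed produce
byte-identical manifests, images and output CSVs (verified by MD5 in the
pipeline log).

## Known limitations

* Chord-length parameterisation attenuates the recovered spread of very
  high harmonics for wiggly outlines (by design of the method, not a
  bug); recovered noise scales are validated in aggregate.
* The even-harmonic sign canonicalisation is discontinuous for shapes
  whose leading even coefficient is near zero.
* The jackknife holds the PCA reduction fixed; a full two-stage refit
  per fold would be slightly more conservative.
* The generator's effect sizes are free parameters chosen to reproduce
  the qualitative classification structure (near-perfect resubstitution,
  substantially lower jackknife accuracy, within-family confusion
  dominating), not fitted to any real data set.
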