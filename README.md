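# statomorph

Outline-based morphometrics for cubozoan statoliths: discriminating box
jellyfish species and families from the shape of the only hard structure
their medusae possess.

Box jellyfish (Cubozoa) are soft, fragile, and often fatal to
misidentify — envenomation severity is family dependent — yet their
taxonomy rests on gelatinous characters that decompose, tear, and distort
in preservation. The statolith, a calcium sulphate crystal inside each
rhopalium, survives all of that. `statomorph` implements the complete
analysis that turns silhouette photographs of the three orthogonal
statolith faces (proximal, oral, lateral) into quantitative taxonomic
assignments, and ships a synthetic statolith generator so the entire
pipeline can be exercised, tested, and calibrated without microscope data.

## The methods in brief

**Traditional morphometrics.** For each face, length is the maximum Feret
diameter of the outline, width the maximum extent perpendicular to that
axis. L:W ratios are compared across species by one-way ANOVA with
Tukey–Kramer HSD post hoc tests, and the three per-face ratios jointly by
canonical discriminant analysis.

**Elliptical Fourier analysis.** Each closed outline, traced from the
binary silhouette by Moore neighbour tracing and smoothed by 300 cyclic
(¼, ½, ¼) iterations, is decomposed with the exact piecewise-linear
Kuhl–Giardina chain sums: with t the cumulative chord length over one
traversal of the outline and T its perimeter,

    A_n = T/(2 n² π²) · Σ_i (Δx_i/Δt_i) [cos(2πn t_i/T) − cos(2πn t_{i−1}/T)]

and analogously B_n (sin terms), C_n, D_n (y terms), for n = 1…20.
Coefficients are normalised to the first harmonic — rotation of the
starting point onto the first ellipse's major axis, rotation of that axis
to horizontal, division by the semi-major axis — making them invariant to
size, rotation, and trace starting point. Harmonic 1 (constant after
normalisation) is dropped, leaving 76 NEF coefficients per face, 228 for
three faces.

**Discrimination.** Per face, principal components of the correlation
matrix with eigenvalue > 1 (Kaiser criterion) are retained; the
concatenated scores enter canonical discriminant analysis. Group
separation is tested with Wilks' Λ = Π 1/(1+λᵢ) and Rao's F
approximation, F(df₁, df₂) with df₁ = p(k−1) and
df₂ = wt − p(k−1)/2 + 1, w = N−1−(p+k)/2,
t = √((p²(k−1)²−4)/(p²+(k−1)²−5)). Classification is by nearest group
centroid in canonical space (Mahalanobis, −2 log prior offset), reported
both as resubstitution and as leave-one-out jackknife (each observation
classified by a model refitted without it). Shape-on-size dependence
(allometry) is tested per species by least-squares regression of the mean
NEF coefficient on statolith length.

## Worked example

Simulate a small three-species study (one species from each of three
families, eight specimens each), run the pipeline on the proximal face,
and read the classification report:

```r
library(statomorph)

templates <- default_templates()[c("Carukia barnesi", "Copula sivickisi",
                                   "Chironex fleckeri")]
templates <- lapply(templates, function(tp) { tp$n <- 8L; tp })

ds  <- generate_dataset(templates, seed = 7, out_dir = "statolith-demo")
res <- run_pipeline(ds$manifest, pipeline_config(face_set = "proximal"),
                    out_dir = "demo-out")
res
```

```
statolith pipeline: 24 specimens, faces: proximal
species CDA: 100.0% resubstitution, 66.7% jackknifed
family CDA:  100.0% resubstitution, 66.7% jackknifed
```

Resubstitution is perfect — and misleading: with 76 Fourier coefficients
and 24 specimens, the honest leave-one-out estimate is 66.7%. That gap is
exactly why the jackknife is built into every classification here. The
L:W ANOVA on the same face,

```r
res$lw_anova$proximal
```

```
one-way ANOVA: F(2, 21) = 4.263, p = 0.0279
```

separates the species far more weakly than the Fourier description —
the traditional ratio sees "long vs round" but not curvature.
`report_tables(res)` prints the confusion tables with jackknifed row
percentages rounded to whole numbers:

```
                         family             group n pct_correct Carukia barnesi Chironex fleckeri Copula sivickisi
Carukia barnesi      Carukiidae   Carukia barnesi 8         100              88                12                0
Chironex fleckeri Chirodropidae Chironex fleckeri 8         100              12                62               25
Copula sivickisi  Tripedaliidae  Copula sivickisi 8         100              12                38               50
```

At full scale the picture sharpens: on the default design (12 species in
6 families, 185 specimens — group sizes 12, 20, 20, 11, 9, 17, 20, 12,
20, 20, 4, 20 — three faces each), species resubstitution is near-perfect,
jackknifed accuracy drops to roughly two thirds, and the errors
concentrate overwhelmingly within families — the signature of nested
taxonomic shape similarity.

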