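---
title: "Methods: arc geometry, section mechanics and phylogenetic regression for ever-growing incisors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: arc geometry, section mechanics and phylogenetic regression for ever-growing incisors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(incisorarc)
```

## The model

An ever-growing incisor curls through the jaw on a roughly helical
path. This package adopts the standard planar simplification: the
labial midline is treated as a **circular arc**, fully determined by
three landmarks — the tip, the point where the tooth emerges from the
bone (alveolar margin), and the base. Because every derived quantity is
a function of the three chord lengths alone, landmarks may be given in
2D or 3D and no best-fit-plane preprocessing is needed: three points
always span a plane, and Euclidean distances are invariant to the
embedding.

From chords $a$ (tip–margin), $b$ (margin–base), $c$ (tip–base):

* radius of curvature
  $r = abc/\sqrt{2a^2b^2 + 2b^2c^2 + 2a^2c^2 - a^4 - b^4 - c^4}$,
  the circumradius written in side lengths (the radicand is $16 \times$
  the squared Heron area);
* subtended angle $\theta = 2\sin^{-1}(c/2r)$, which is only valid up
  to $\pi$. The cosine-rule check $X = a^2 + b^2 - c^2$ detects an arc
  beyond a semicircle — $X > 0$ means the angle at the margin vertex is
  acute, which on a circle happens exactly when the tooth wraps past
  half the circumference — and the angle is then corrected to
  $2\pi - \theta$. $X = 0$ is the exact semicircle and returns $\pi$;
* arc lengths $\mathrm{TTL} = \theta r$, with the split at the margin
  computed from the **inscribed-angle identities**
  $\theta_{ext} = 2\angle(\text{base})$,
  $\theta_{int} = 2\angle(\text{tip})$. We use these rather than the
  chord-substitution form $2\sin^{-1}(a/2r)$, $2\sin^{-1}(b/2r)$
  because the triangle's angles sum to $\pi$, so
  $\theta_{ext} + \theta_{int} = 2(\pi - \angle(\text{margin})) =
  \theta_{total}$ holds *identically*, including for reflex arcs where
  a sub-arc can itself exceed $\pi$ and the substitution form would
  return the wrong branch. For arcs up to a semicircle the two forms
  agree, which the test suite verifies;
* fraction of circle $\theta/2\pi$, reported as a percentage.

The helix-to-circle simplification, and the treatment of the tooth as a
single homogeneous tissue in the section analyses, are modelling
choices inherited from the comparative literature; neither torsion nor
the enamel/dentine composite is represented.

## Cross-section geometry

The section at the alveolar margin arrives as a binary raster with an
isotropic pixel size in mm (anisotropic pixels are rejected rather than
silently averaged). Conventions are fixed and bit-exact: raster rows
are the image $y$ axis, the centre of the 1-based pixel $(i, j)$ sits
at $((j-\tfrac12)s, (i-\tfrac12)s)$, and greyscale input is binarized
at $> 0$ with no morphological cleaning.

Each occupied pixel is a **filled square**, not a point mass: its
contribution to a centroidal moment is $s^4/12$ (its own moment) plus
$d^2 s^2$ (parallel-axis term). This makes the small-mask limit correct
— a single pixel has CSA $s^2$ and moment $s^4/12$ — and makes an
exactly rasterized square hit $s^4/12$ with zero discretization error.
Principal moments are the eigenvalues of the $2\times2$ tensor of
$\int x^2$, $\int xy$, $\int y^2$; the reported `principal_angle` is
the axis of *minimal* second moment, i.e. the long axis of an elongate
section. The pipeline's default "SMA" is the moment about the
**mesio-distal centroidal axis**: gnawing loads the incisor
labio-lingually, so that axis moment is the relevant bending
resistance, and a section expanded labio-lingually (the aye-aye
pattern) scores high on it. All other axis choices (labio-lingual,
principal max/min, arbitrary direction) are exposed, since published
section analyses do not always state which moment they report.

Accuracy is resolution-limited: at 0.02 mm/px a 5 mm × 3 mm ellipse
reproduces $\pi ab$ to ≈0.002% and the axis moments
$\pi a b^3/4$, $\pi a^3 b/4$ to ≈0.02%, and the error falls
monotonically as pixels halve (tested). Square roots of CSA and fourth
roots of SMA have units of mm, which is what makes them linearizable
against arc lengths.

## Comparative statistics

`group_summary()` uses the $n-1$ standard deviation and
$CV = 100\,s/\bar x$. The t-test defaults to the pooled Student form
(df $= n_1+n_2-2$), the classical choice in this literature, with
Welch as an option. The variance ratio is reported
larger-over-smaller, so $F \ge 1$ with a two-tailed p; when the second
sample exists only as a published standard deviation the ratio is
still computable but p is `NA` without its sample size.

The Fligner–Killeen test is implemented from first principles:
absolute deviations from group medians, pooled midranks, normal scores
$a_i = \Phi^{-1}(\tfrac12 + r_i/(2(N+1)))$, statistic
$\sum_j n_j(\bar A_j - \bar a)^2 / V^2 \sim \chi^2_{k-1}$. Ties take
midranks and are not an error. Because FK is a *scale* test, testing
CV homogeneity requires making scale relative to location first:
`scaling = "cv"` divides each group by its own mean, which renders the
statistic invariant to independent positive rescaling of each group —
exactly the property a CV comparison needs (property-tested).
Unscaled and log10-scaled variants are also provided, since published
analyses rarely state which construction they used.

## Phylogenetic regression

Under Brownian motion the covariance of two tips is the depth of their
most recent common ancestor; `bm_covariance()` builds that matrix by
walking ancestor paths on the tree (ultrametricity is not assumed) and
is cross-checked in the tests against an independent implementation.
`pgls_fit()` is **closed-form GLS with the BM covariance fixed**: no
$\lambda$ or other covariance parameters are estimated, because the
analyses this package supports assume plain Brownian motion.
Numerically the fit whitens through the Cholesky factor of $C$ rather
than forming $C^{-1}$. Conventions that the GLS literature leaves
open, fixed here:

* $\hat\sigma^2 = \mathrm{RSS}_{GLS}/(n-2)$ (unbiased flavour);
* $R^2 = 1 - \mathrm{RSS}_{GLS}/\mathrm{TSS}_{GLS}$ with the total sum
  taken about the *GLS-weighted* mean of $y$ — the definition that
  reduces to the ordinary $R^2$ on a star phylogeny;
* the slope's $F(1, n-2)$ is exactly the squared t-ratio (tested to
  $10^{-12}$);
* a star phylogeny with equal depths reproduces OLS to $10^{-10}$, and
  rescaling all branch lengths leaves $\hat\beta$, $F$ and $R^2$
  unchanged (only $\hat\sigma^2$ rescales).

Transforms are applied per variable: `log10` (both sides, for the
log–log arc-length analysis), `sqrt`/`fourth_root` (response only in
the pipeline's CSA and SMA analyses, matching how areas and moments
are linearized against lengths), and `fraction_of_circle`, which
divides a length by the specimen's circumference $2\pi r$ — the
size-correction that turns ETL and ITL into dimensionless shape
variables. Whether published analyses logged every regression is
usually unstated, so the pipeline reports the raw, log–log and
fraction variants of the ETL–ITL relationship side by side rather than
guessing.

## The synthetic-specimen generator

No raw scan data ships with the package; the generator stands in for a
specimen collection, with ground truth attached to every object:

* **arcs** — exact on-circle landmark triplets for any radius, angle
  in $(0, 2\pi)$ and margin split, under any rigid 3D pose, with
  optional isotropic Gaussian landmark noise (default 0; the noisy
  tests use 0.01 mm, the order of a fine CT voxel);
* **sections** — centre-inclusion rasterized ellipses (no
  anti-aliasing, hence bit-reproducible) with closed-form CSA and
  moments;
* **trees** — seeded pure-birth (Yule) trees, ultrametric by
  construction;
* **traits** — $x$ as unit-rate Brownian motion, $y = \beta_0 +
  \beta_1 x + \varepsilon$ with $\varepsilon \sim N(0, \sigma^2 C)$,
  the exact generative model the GLS assumes.

The bundled `synthetic_study()` preset draws 30 specimens spanning
12–51% of a circle — the range observed across diprotodonts, hyraxes
to aye-aye — with radii, section sizes and hence arc lengths, CSA and
SMA co-varying with size, so the regression stage has a realistic
demonstration dataset. The recovery experiment in the acceptance suite
uses a generating slope of 0.43 (a value of the order reported for the
radius–length relationship in real incisors), 128-tip trees,
$\sigma^2 = 0.25$ and 200 replicates.

What passing these tests shows is that the estimators are correct
*under their own assumptions*: exact circular arcs, clean binary
sections, Brownian evolution on a known tree. Real incisors are
helical, landmarks carry observer error, segmentation is imperfect,
and trait evolution need not be Brownian — none of which the generator
emulates. The published per-species regression estimates additionally
depend on unpublished raw measurements, so they cannot be, and are
not, reproduced here; correctness is established against closed forms,
independent oracles and recovery of known ground truth instead.

## Numerical choices and degenerate inputs

* Collinear landmarks: circumradius radicand below
  $10^{-12}(abc)^{4/3}$ is treated as an infinite radius and rejected
  with an explicit error.
* `asin`/`acos` arguments within $10^{-9}$ of $\pm1$ are clamped;
  larger excess (a chord longer than the diameter) is an error.
* Sub-arc additivity violated beyond $10^{-6}$ relative signals
  landmarks inconsistent with a single circle.
* Empty masks, zero directions, anisotropic pixels, unknown axis
  labels: explicit errors, never silent coercion.
* Specimens with malformed landmark sets are rejected per specimen
  with a reason, and the pipeline continues with the rest; an analysis
  whose preconditions fail (no masks, fewer than 3 matched species,
  non-positive values under a log) is skipped with a message, not
  fabricated.
* Percentages are carried at full precision and rounded only for
  display.
* All generators save and restore the caller's RNG state.

## Problem sizes

The shipped test suite runs 1000-triangle and 1000-arc oracle sweeps,
ellipse rasters up to 500 × 300 px (0.02 mm/px), 100 random masks for
the moment invariants, and the 200-replicate slope-recovery experiment
on 128-tip trees — sizes chosen so the full suite completes in about a
minute while still exercising reflex arcs, rotated sections and
non-trivial tree shapes.

## Known limitations

Helical tooth paths, composite enamel/dentine stiffness, slice
extraction from 3D volumes, automatic landmarking, and non-Brownian
covariance models ($\lambda$, OU, early-burst) are out of scope. The
Fligner–Killeen CV construction and the GLS $R^2$ are reasonable but
not unique conventions; both are documented above so results are
interpretable, and alternatives (unscaled/log FK, OLS comparison fits)
are exposed where they exist.
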