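# incisorarc

Comparative biomechanics of ever-growing (diprotodont) lower incisors —
the enlarged, continuously erupting front teeth of rodents, lagomorphs,
hyraxes, the wombat and the aye-aye. The package is aimed at
morphologists who have landmarked incisors from CT reconstructions and
want the standard curvature, cross-section and phylogenetic-regression
analyses as a tested, scriptable pipeline.

## What it computes

**Arc geometry.** The lateral profile of an ever-growing incisor is
modelled as a circular arc through three landmarks on the labial
midline: the tip, the point at the alveolar margin, and the base. With
chord lengths *a* (tip–margin), *b* (margin–base) and *c* (tip–base),
the radius of curvature is the circumradius

r = abc / √(2a²b² + 2b²c² + 2a²c² − a⁴ − b⁴ − c⁴),

the subtended angle is θ = 2·sin⁻¹(c/2r), corrected by θ → 2π − θ when
the cosine-rule check X = a² + b² − c² is positive (the arc exceeds a
semicircle, as in the aye-aye). Total tooth length is TTL = θr, split
into external (ETL, tip to alveolar margin) and internal (ITL, within
the bone) arc lengths via the inscribed-angle identities so that
ETL + ITL = TTL holds for any arc, reflex included. θ/2π is the
fraction of a circle the tooth encompasses.

**Cross-section geometry.** From a binary raster of the section at the
alveolar margin: cross-sectional area (CSA), centroid, centroidal second
moments of area Ixx/Iyy/Ixy, principal moments, and the second moment
about any chosen loading axis (default: the mesio-distal axis, i.e.
resistance to labio-lingual bending during gnawing).

**Comparative statistics.** Group means, standard deviations and
coefficients of variation; pooled/Welch t-tests; a larger-over-smaller
variance-ratio F-test; and a from-scratch Fligner–Killeen scale test
with a mean-scaled variant that tests CV homogeneity.

**Phylogenetic regression.** Closed-form generalized least squares with
a Brownian-motion covariance (shared root-to-tip path lengths) built
from any rooted Newick tree, with log10, square-root, fourth-root and
fraction-of-circle (divide by 2πr) transforms, plus broom-style
`tidy()`/`glance()` and `autoplot()` methods.

**Synthetic specimens.** Generators for on-circle landmark triplets
(any rigid 3D pose, optional noise), rasterized elliptical sections,
pure-birth trees and Brownian trait tables — all seeded and all
returning their ground truth, so every stage of the pipeline has
end-to-end recovery tests.

## Worked example

```r
library(incisorarc)

# a synthetic incisor: radius 12 mm, 35% of a circle, 45% of the arc external
arc <- make_arc_landmarks(r = 12, theta_total = 0.35 * 2 * pi, margin_split = 0.45)
arc_metrics(arc$landmarks)
#>   specimen_id    a     b     c  r theta_total_rad theta_ext_rad theta_int_rad
#> 1   synthetic 11.4 13.65 21.38 12           2.199        0.9896          1.21
#>   pct_circle   TTL   ETL   ITL
#> 1         35 26.39 11.88 14.51
```

The recovered radius (12 mm), fraction of circle (35%) and arc lengths
(TTL = 26.39 mm = ETL + ITL) equal the generating values: the three
landmarks fully determine the arc.

The bundled species table of percent-of-circle values reproduces the
published lower-incisor summary row:

```r
tab <- table1_fixture()
group_summary(tab, pct_circle, by = is_rodent)
#>   is_rodent  n  mean     sd    cv
#> 1     FALSE  6 23.90 14.251 59.62
#> 2      TRUE 27 34.21  6.077 17.76

incisor_comparison(tab$pct_circle[tab$is_rodent])$variance_ratio
#>   statistic df1 df2 p_value
#> 1      1.06  26  NA      NA
```

Rodent lower incisors average 34.21% of a circle (CV 17.76%); the
variance ratio against the published upper-incisor standard deviation
(5.91) is F = 1.06, i.e. the two samples are about equally variable.

A full study — metrics, summaries, and the four bivariate PGLS analyses
(r ~ TTL; ETL ~ ITL raw, log–log and as fractions of a circle;
√CSA ~ ETL; SMA^¼ ~ ETL) — runs in one call:

```r
st <- synthetic_study(n = 30, seed = 1)
report <- run_study(st$landmarks, st$masks, st$tree)
report$fit_table
autoplot(report$fits$TTL_vs_r)
```

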