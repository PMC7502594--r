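---
title: "Quantifying the spatial influence of mosaic sectors on stomatal patterning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the spatial influence of mosaic sectors on stomatal patterning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stomaspace)
```

## The problem

Secreted peptides such as EPF1 (an inhibitor of stomatal differentiation) and
Stomagen (a promoter) act non-cell-autonomously on the leaf epidermis. When a
clonal mosaic sector overexpresses one of them, stomatal density changes not
only inside the sector but over some *effective range* around it. Classical
summary statistics — stomatal density and stomatal index — cannot resolve that
range, because they ignore two-dimensional position. This package works from
the 2D coordinates (µm) of every stoma on a cotyledon, together with the
cotyledon outline and the sector outlines, and quantifies how stomatal
positioning varies with distance from a sector.

Three complementary analyses are provided:

1. **Offset-band density accounting** (`partition_cotyledon()`,
   `density_table()`): stomatal density inside sectors, in successive
   distance bands around them, and over the rest of the cotyledon.
2. **Stomata–sector correlation** (`sector_correlation()`,
   `space_correlate()`): a bivariate two-point correlation function of
   stomatal positions relative to the sector boundary, evaluated against
   ensembles of uniform random points confined to the same cotyledon.
3. **Stomata–stomata autocorrelation** (`stomata_autocorrelation()`): a
   Landy–Szalay-type estimator of the pattern's correlation with itself.

## The estimators

### Stomata–sector correlation

For distance bins \(r_i\) (logarithmically spaced, default 24 bins over
5–2000 µm),

\[
\zeta(r_i) = \frac{S(r_i)}{\langle R(r_i)\rangle} - 1,
\]

where \(S(r_i)\) counts stomata whose nearest Euclidean distance to a sector
boundary falls in \([r_i, r_{i+1})\) and \(\langle R(r_i)\rangle\) is the mean
of the same count over an ensemble of uniform random point sets (default
1000), each of the same size as the observed stoma count and confined to the
cotyledon outline. \(\zeta > 0\) means stomata are enriched at that distance
relative to complete spatial randomness (CSR); \(\zeta < 0\) means depletion;
\(\zeta \ge -1\) always. This is the differential (binned) counterpart of
Ripley's K against an inhomogeneity-free null that conditions on the
cotyledon window, so no separate edge correction is required.

Stomata lying inside a sector are excluded from \(S\). Random points inside a
sector are excluded from \(R\) **symmetrically**; without that exclusion the
estimate would be biased negative near the boundary by construction, since
the data can never place points there. (The symmetric exclusion is a design
choice of this package; one could also leave random interior points in.)

### Stomata–stomata autocorrelation

With stoma–stoma (\(SS\)), random–random within one set (\(RR\)) and
stoma–random (\(SR\)) pair-distance counts per bin, each normalized by its
total number of pairs and with \(RR\), \(SR\) averaged over the ensemble,

\[
\zeta(r_i) = \frac{ss - 2\,sr + rr}{rr},
\]

the Landy–Szalay estimator from galaxy clustering statistics, chosen for its
low bias and variance at small counts. All stomata enter (no sector
involvement). One degeneracy convention is applied: coincident stoma–random
pairs (exactly zero distance) are dropped from the cross count and its
normalization. These pairs cannot occur for continuous data; the convention
guarantees the exact null identity \(\zeta \equiv 0\) when a random set
coincides with the data.

### Confidence bands

The 95% band is a percentile bootstrap over the observed stoma distance
list: distances are resampled with replacement (same \(N\)), \(\zeta\) is
recomputed against the *fixed* ensemble expectation, and the 2.5/97.5
percentiles are taken per bin (`bootstrap_ci()`, default 1000 resamples).
This measures the sampling noise of the observed pattern, not the Monte
Carlo noise of the null, which is already suppressed by the ensemble
average. Resampling distances rather than re-drawing ensembles is a design
choice; "resampling" admits several readings and this one isolates the
quantity of interest.

### Pooling

`pool_cotyledons()` sums \(S\) and \(\langle R\rangle\) across cotyledons
measured on identical bins before forming \(\zeta\), producing per-genotype
curves; the alternative (averaging per-cotyledon \(\zeta\)) weights
low-count cotyledons more heavily and is not used.

## Sector filtering

Sector size and mutual proximity influence the range and magnitude of the
correlation, so `filter_sectors()` retains only sectors with area in
15,000–40,000 µm² (the upper bound can be disabled with
`sector_filter(area_max = NULL)`) and removes **both** members of any pair of
retained sectors closer than 200 µm boundary-to-boundary. Distances to
multiple retained sectors are minimized over sectors.

## Geometry

All counting conventions are boundary-inclusive, with deterministic
tie-breaks:

* a point on an outline edge is *inside* (`point_in_polygon()`);
* a stoma on a shared region boundary is assigned to the innermost region
  (sector before ring \(k\) before ring \(k+1\) before "rest");
* distances are measured to boundary *segments*, never to sampled vertices,
  so they do not depend on digitization density;
* outlines are normalized counter-clockwise on construction and must be
  simple with positive area.

Offset bands are built by true Euclidean (Minkowski-disk) dilation of the
sector outline — every point of the band is within \(d\) of the sector —
rather than by radially displacing vertices from the centroid; the two
coincide for convex, roughly isotropic sectors but differ for concave ones,
and only the Euclidean construction matches the definition "within a
\(d\)-µm range of the sector". Boolean operations (clipping to the
cotyledon, subtracting sector interiors, uniting overlapping bands of
multiple sectors) use the Clipper engine via the `polyclip` package, the
same backend the `spatstat` family uses. Arcs are polygonized at 64 chords
per full circle by default (configurable via `segments`); on a
100 µm × 100 µm square dilated by 50 µm this leaves a 0.03% area deficit
against the closed form \(s^2 + 4sd + \pi d^2\). Clipper's integer scaling
is set to \(\mathrm{range}/2^{40}\), so boolean area accounting is exact to
about \(10^{-12}\) of the coordinate range and the partition areas sum to
the cotyledon area to well within \(10^{-6}\) relative.

Stomata, by contrast, are classified by *exact* Euclidean distance to the
sector union, not by membership in the polygonized bands; counts are
therefore conserved exactly (they always sum to the cotyledon total), at the
price of a sub-tolerance inconsistency with the polygonized band areas for
stomata within the arc sagitta (≲0.2 µm) of a band edge.

## Null ensembles

`generate_uniform_points()` mirrors the reference sampling scheme: draw five
times the requested count uniformly in the bounding rectangle, keep points
inside the outline, take the first \(N\); if the draw falls short (thin
outlines in large boxes), it is repeated until \(N\) interior points exist,
so the requested size is always met exactly. One master seed spawns per-set
child seeds (`generate_ensemble()`), making sets independently reproducible.

## Synthetic data

The generators exist so every stage is testable without real coordinate
exports, and their defaults are the reference conditions of the analyses
they exercise:

* `synth_cotyledon()` — a convex, slightly egg-tapered ellipse, default
  2000 µm × 1200 µm (a 7-day-old cotyledon blade at the scale the density
  and correlation analyses operate on).
* `synth_sector()` — an irregular low-order-harmonic blob, default 20,000
  µm², inside the 15,000–40,000 µm² filter window.
* `generate_pattern()` — reference patterns of `n = 500` points:
  * `uniform`: CSR over the cotyledon (the null);
  * `clustered`: CSR thinned to intensity \(\propto e^{-d/\ell}\) of
    boundary distance \(d\), default \(\ell = 50\) µm. The exponential form
    and scale are package choices — the reference figure shows a plotted
    density, not a formula — and are configurable;
  * `ringed`: equal point allocation over annuli at successive 200 µm
    multiples of boundary distance (3 rings, width 40 µm; the width is a
    package choice, rings in the reference rendering being visibly thin);
  * `spaced`: simple sequential inhibition with hard-core distance 40.9 µm,
    the measured mean one-cell spacing. This emulates the one-cell spacing
    rule's second-order signature; it is not a model of the developmental
    process.

What these patterns deliberately do *not* emulate: cell-size granularity
(stomata occupy ~20 µm cells, not points), the abaxial/adaxial distinction,
leaf curvature (coordinates are treated as flat 2D projections), and
intensity gradients along the proximodistal axis. Tests passing on them
validate the estimators' mathematics and conventions, not any biological
claim about real cotyledons.

The expected signatures, each verified by the test suite across replicate
seeds: uniform input drives both \(\zeta\) functions to zero within Monte
Carlo error; clustered input gives \(\zeta(r\to 0) > 0\); ringed input
oscillates between positive and negative with at least two sign changes
over 0–600 µm; hard-core input depresses the autocorrelation at short range.

## Hypothesis tests

`chi_square_2x2()` (stomatal index comparisons), `mann_whitney_u()`
(density comparisons; the populations are not assumed normal) and
`kruskal_wallis()` (density across ≥3 regions or genotypes) wrap the
standard base-R implementations. Two conventions are pinned down where the
reference analyses leave them open: the χ² test applies **no** continuity
correction (a test of independence on aggregated, large counts), and the
Mann–Whitney test is exact for combined \(n \le 20\) without ties (the
relevant regime for 6–10 cotyledons per genotype) and otherwise uses the
normal approximation with tie correction and no continuity correction.
Their empirical size is verified by simulation: under matched nulls
(binomial(200, 0.35) counts for χ²; standard normal samples of 20 and of
15 × 3 for the rank tests — designs chosen once, in the asymptotic regime
each test assumes), all three hold a type-I error within [0.04, 0.06] at
\(\alpha = 0.05\) over 10⁴ replicates.

## Geometric sectors

`transpose_outline()` implements the shape-matched control: a real sector
outline is rigidly translated (no rotation or scaling) to a uniformly random
position inside a wild-type cotyledon; placements extending beyond the
cotyledon are rejected and redrawn, and after 1000 failed attempts the
sector is reported unplaceable — mirroring the exclusion rule for transposed
sectors that fall outside the target cotyledon.

## Numerical choices and degenerate inputs

* Bins are half-open \([r_i, r_{i+1})\) with the top edge closed; distances
  outside the bin range are dropped (and `S` therefore sums to the stomata
  the bins span).
* Bins with \(\langle R\rangle = 0\) (or \(rr = 0\)) are reported as
  undefined (`NA`), never as ±∞, and serialize to empty CSV fields.
* Boundary tolerance for "on the outline" is 1 nm — far below segmentation
  precision.
* An empty region is valid with area 0; subtracting a region from itself
  yields it.
* The spaced generator fails loudly (packing error) when the hard-core
  distance cannot be honored at the requested \(n\), rather than silently
  under-filling; the same loud-failure policy applies to unplaceable
  sectors.

## Problem sizes

The test suite exercises the estimator nulls at \(n = 500\) stomata with
200-set ensembles over 50 replicate seeds, the pattern signatures over 20
seeds with 100-set ensembles, and the test calibration at 10⁴ null
replicates. The acceptance script (`scripts/acceptance.R`) reruns the same
pipeline at 12 CSR replicates, 10 signature seeds and 2×10³ calibration
replicates — sizes at which every reported quantity is stable to well
within its interpretation — and completes in a couple of minutes on one
CPU. Full-scale analyses of real cotyledons (1000-set ensembles, 1000
bootstrap resamples) run in seconds per cotyledon.

## Known limitations

* The correlation functions condition on the cotyledon outline but not on
  internal inhomogeneity (e.g. the midrib region); a strongly non-uniform
  baseline intensity would register as autocorrelation.
* Sector-interior exclusion makes \(\zeta(r)\) undefined *inside* sectors;
  the density table covers that region instead.
* The bootstrap band reflects stoma-sampling noise only; ensemble noise is
  controlled by making the ensemble large, not by the band.
* Cell-adjacency statistics ("one cell away", "two cells away") require
  cell outlines, which are not part of the coordinate interchange; such
  counts enter only as user-supplied contingency tables.
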