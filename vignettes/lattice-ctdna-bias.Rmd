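---
title: "Spatially biased ctDNA shedding from boundary-driven tumor growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially biased ctDNA shedding from boundary-driven tumor growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latticeshed)
```

## The model

`latticeshed` couples two models: a stochastic spatial model of clonal
tumor evolution, and a calibrated sampling model of the circulating tumor
DNA (ctDNA) that such a tumor releases into blood. The package's purpose is
to quantify how much a blood draw can *distort* the clonal picture of the
tissue when cell death — the dominant source of ctDNA — varies in space.

### Boundary-driven growth

Cells live on a 2D square lattice with Moore (8-neighbor) neighborhoods,
starting from a single founder voxel at the grid center. One *event* is:

1. choose an occupied voxel uniformly at random;
2. it attempts division with probability `b (1+s)^n` (clamped at 1), where
   `n` is its clone's driver count; if it has at least one empty Moore
   neighbor, a daughter occupies one of them, chosen uniformly;
3. the daughter draws `Pois(mu)` new driver mutations; one or more new
   drivers found a new clone (clone identity = driver genotype) under an
   infinite-sites assumption — every mutation id is globally unique;
4. the *same chosen cell* then dies with its regional death probability.
   The daughter placed in step 2 is not a death candidate in this event.

Division requires an empty neighbor, so proliferation concentrates on the
rim (Eden growth); interior turnover happens only where deaths open holes.
Time is measured in *sweeps*: one sweep equals as many events as there are
occupied voxels when the sweep starts. The model has no physical clock —
normalized time (sweep / final sweep) is used for cross-run comparison.

Death rates are spatially structured after clinical *detection*, which
triggers when the population reaches the area of a disc of the detection
radius (`ceiling(pi r^2)` voxels; 25,447 at the default `r = 90`). We use
a population-size trigger rather than a geometric radius estimate because
it is robust to ragged growth fronts, and we latch it: once detected,
always detected. Pre-detection every cell dies at `d1`; afterwards cells
within Euclidean distance `R` of the founder (ties inclusive) keep `d1`
(the sanctuary, e.g. poor drug penetration) while the rest die at `d2`.

Two regimes follow from the ordering of rates. With `d1 < b < d2`
(*driver-dependent* invasion) a wild-type clone has negative net growth on
the edge; expansion beyond the sanctuary waits for a lineage with
`b (1+s)^n > d2` (three drivers at the reference values, since
`0.7 * 1.1^3 = 0.932 > 0.9`). With `d1 < d2 < b` (*driver-independent*,
`d2 = 0.69`) every clone can expand, just more slowly. Two orthogonal
variants complete the grid of scenarios: *quiescent* growth, in which a
fully surrounded cell neither divides nor dies (only the rim turns over),
and *death-rate selection*, in which drivers do not raise the birth rate
but lower death multiplicatively, `d (1-s)^n`. The death-variant
compounding mirrors the birth-rate form; a single driver reproduces the
plain `d (1-s)` reduction.

Whether a surrounded proliferative cell can still die is a genuinely open
modeling choice; we make death independent of division success, which is
the literal reading of the event loop above, and test that choice
explicitly (a surrounded cell with `d = 1` always dies in the
proliferative variant, never in the quiescent one).

### Reference parameters

| parameter | default | meaning |
|---|---|---|
| `b` | 0.7 | baseline division probability per event |
| `s` | 0.1 | multiplicative advantage per driver |
| `mu` | 0.001 | Poisson driver rate per division (~100x the empirical 1e-5) |
| `d1` | 0.1 | core/sanctuary death probability |
| `d2` | 0.9 or 0.69 | edge death probability after detection |
| `R` | 20–60 voxels | sanctuary radius (0.4–1.2 cm) |
| `detection_radius` | 90 voxels | detection size (~3e9 cells) |
| `max_voxels` | 60,000 | terminal size (~1e10 cells) |

The inflated `mu` buys speed: each voxel then stands for
`mu / mu_real = 100` identical cells, a voxel edge for 10 cell diameters
(200 µm at 20 µm cells). Reading the 2D simulation as a cross-section of a
3D tumor of equal cross-sectional cell area gives
`N = (4/3) pi (sqrt(100 m / pi))^3` cells for `m` voxels — 25,447 voxels
(disc of radius 90) maps to 3.05e9 cells, 60,000 voxels to 1.1e10.

The lattice is sized from `max_voxels` with a generous margin
(half-width `4 sqrt(max_voxels / pi)`), and a run that nonetheless touches
the boundary aborts with a diagnostic rather than silently wrapping or
clipping.

### The shedding and VAF model

Circulating fragments decay fast (half-life 30 min, `eps = 48 ln 2 ≈ 33.3`
per day) relative to tumor growth, so fragment counts sit at their
quasi-steady state `C = N d q / eps` (the growth correction `r` is
negligible and fixed at 0). The chain is anchored to plasma measurements:
29 ng/mL cell-free DNA and 0.0033 ng per haploid genome give 8788 genome
equivalents per mL; 5 L of blood at 55% plasma and a 1% tumor fraction at
detection give `C = 5000 * 0.55 * 8788 * 0.01 = 241,670` circulating tumor
fragments. Solving at the detection-size tumor (3e9 cells, death rate 0.1)
calibrates the shedding probability per cell death,
`q = C eps / (3e9 * 0.1) = 0.0268` (conventionally quoted as 0.026). A
15 mL draw is 0.3% of supply; we thin the *means* by 0.003, which by
Poisson thinning is distributionally identical to thinning the draws.

For a blood sample at any time point, with `m` voxels alive and converted
population `N`:

* total tumor fragments: `Ct = N q d̄ / eps * 0.003`, with `d̄` the
  cell-weighted mean death rate of the whole tumor;
* healthy background: `Ch = 0.99 * Ctot0`, held constant over time, with
  `Ctot0 = 5000 * 0.55 * 8800 * 0.003 = 72,600`. The deliberately rounded
  8800 (vs the derived 8788) is kept as its own constant so the published
  totals are reproduced exactly; both are configurable;
* a mutation with tissue frequency `f_m` and carrier mean death rate
  `d̄_m` contributes `Cm = f_m N d̄_m q / eps * 0.003` mutant fragments.
  Cells are diploid with one mutated copy and no copy-number change or
  recurrent mutation, so the sampled VAF is
  `Pois(Cm / 2) / Pois(Ct + Ch)`, numerator and denominator independent.

The *unbiased* (spatially uniform shedding) null model substitutes the
tumor-wide `d̄` for `d̄_m`. Clonal mutations (`f_m = 1`) have
`d̄_m = d̄` identically, so their VAFs are distributionally invariant to
spatial bias — the package's per-mutation tables make that an exact
identity, not an approximation.

Numerical conventions: a denominator draw of 0 recovers no fragments and
yields `NA`, which downstream detection counts treat as undetected (a draw
that recovers nothing detects nothing). Within one blood sample the healthy
background is drawn once and shared across mutations; each mutation adds an
independent `Pois(Ct)` tumor draw, so the marginal denominator law is
exactly `Pois(Ct + Ch)` while mutations within a sample are realistically
correlated through the background.

### Distortion metrics

Blood clone fractions weight each clone's regional counts by the regional
death rates, `sum_j d_j N_ij / sum_ij d_j N_ij`; with `d1 = d2` this
collapses algebraically to the tissue fractions (tested on 1000 random
censuses). Distortion is summarized by per-clone differences
`delta_i = blood_i - tissue_i` (averaged separately over positive and
negative clones comprising at least 10% of the tissue), the inverse Simpson
index `D = 1 / sum f_i^2` in blood versus tissue, detectable driver counts
at VAF limits 1e-3 and 1e-2, and the percent change in detectable drivers
between the biased and unbiased models (undefined, not an error, when the
unbiased count is 0).

For the limiting case of a single invasive subclone of size `x` growing
against a constant resident population `S`, the expected difference is

```
f(x) = d2 x / (d2 x + d1 S) - x / (x + S)
```

We find its maximum numerically — `optimize()` over `log(x/S)`, which makes
the search scale-free — rather than trusting a closed form, because two
algebraic candidates circulate: `(d2-d1)/(d2+d1)` and the radical form
`(sqrt(d2)-sqrt(d1))/(sqrt(d2)+sqrt(d1))` at `x* = S sqrt(d1/d2)`. The
numeric maximum at `d1 = 0.1, d2 = 0.9` is 0.5, matching the radical form
(the plain ratio gives 0.8); the tests document both candidates and assert
which one the optimizer selects. The maximum is independent of `S`, a
property the acceptance suite checks across three orders of magnitude.

## Synthetic fixtures

`make_fixture()` builds deterministic lattice states from discs and annuli
of labeled clones with specified driver sets, chained through the same
clone ledger the simulator uses. These fixtures emulate the *geometry* the
shedding stage cares about — who sits inside the sanctuary, who on the
edge, with which drivers — and make every downstream quantity computable by
hand (the two-clone disc/annulus fixture reproduces the weighted-fraction
arithmetic exactly). They do not emulate ragged Eden fronts, interleaved
clone boundaries, or genealogies deeper than their region list, so tests of
the census and shedding stages on fixtures say nothing about growth
dynamics; those are exercised on small simulated tumors against per-cell
enumeration oracles.

## Reproducibility and run sizes

All randomness — engine events, mutation draws, VAF sampling — flows from
R's global RNG, so a seed makes a full run bit-reproducible; the test suite
asserts identical trajectories, ledgers and grids for repeated seeds. The
compiled event loop uses R's own generator (no hidden entropy), and
neighbor enumeration uses a fixed row-major offset order so ties break
reproducibly.

The package's own quantitative checks run at desk scale: detection radius
45 voxels (6362-voxel detection size, ~3.8e8 cells) and terminal size
15,000 voxels for the headline driver-dependent analyses, with smaller
tumors in unit tests. When scaling down, the shedding calibration must be
rescaled consistently — `shedding_calibration(n_cells_at_detection =
voxels_to_3d_population(detection_threshold(r)))` — so that the tumor
fraction at detection stays at its calibrated 1%; otherwise scaled tumors
would be absurdly under- or over-detectable. Replicate analyses condition
on establishment (a founder lineage that survives to the terminal size),
discarding early-extinct runs, as any study of grown tumors implicitly
does.

## Limitations

The model deliberately omits vasculature, hypoxia fields, immune agents,
explicit chemotherapy pharmacokinetics, 3D growth, passenger mutations,
sequencing error, copy-number change, germline and hematopoietic
confounders, and any treatment-induced shrinkage at detection (the
environment switch alone is modeled; no shrinkage procedure is specified).
Clone fractions in blood depend on death rates only through the two-region
weighting — any mechanism that weights clones differently in blood than in
tissue (vessel proximity, active secretion) would distort similarly, but is
not modeled here.
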