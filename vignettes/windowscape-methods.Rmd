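---
title: "windowscape: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{windowscape: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(windowscape)
```

# The problem

Landscape genetics infers which environmental features facilitate or hinder
gene flow by correlating genetic distances with landscape-aware movement
costs. Run in a single study area, the inference is hostage to two unknowns:
the spatial scale at which the organism responds to the landscape, and local
confounders (evolutionary history, recent landscape change) specific to the
chosen location. windowscape operationalizes the resampling answer: generate
circular study areas of every diameter in a range, centered on every
sampling location, run the identical analysis inside each, and read the
aggregate — support frequency by scale, support geography by individual.

# Models and statistics

## Genetic distances

Diploid microsatellite genotypes are coded per allele: 0 absent, 1 present
once, 2 homozygous. Each individual becomes a vector over the union of
alleles seen in the dataset; each non-missing locus contributes exactly 2.
Pairwise dissimilarity is Bray–Curtis,
$d(x,y) = 1 - 2\sum_a \min(x_a,y_a) / (\sum_a x_a + \sum_a y_a) \in [0,1]$.

*Missing data.* A missing locus masks that locus for that individual only;
pairs are compared over the loci typed in **both** members (pairwise
deletion). With the 0/1/2 coding this reduces to
$d = \sum|x-y| / (4\,L_{shared})$. Pairwise deletion keeps all filtered
individuals without imputation bias; individuals missing more than 2 loci
are removed up front (the `filter_individuals` default).

## Resistance distances

Environmental rasters are used directly as conductance after a min–max
rescale to $[\varepsilon, 1]$, $\varepsilon = 10^{-3}$:

* **T** — warm cells conduct (cold resists); **Pc** — dense pine conducts.
* **E** — high elevation resists; **Pr** — dense pine resists. These use the
  complementary transform $(1+\varepsilon) - v$, so Pr + Pc is constant
  cell-wise.

A literal "negative values" treatment of the corridors scenario is not
computable (conductances must be positive for a random walk), hence the
complementary-transform construction; it preserves each hypothesis's
direction exactly. The floor $\varepsilon$ keeps every cell traversable so
the lattice graph stays connected wherever the raster is valid.

The raster lattice (8-neighbor by default; diagonal edges divided by
$\sqrt 2$; edge weight = mean of the two cells' conductances) defines a
weighted graph. The IBR distance is the commute time
$C(i,j) = \mathrm{vol}(G)\,(L^+_{ii} + L^+_{jj} - 2L^+_{ij})$, computed
exactly per connected component by a grounded sparse Cholesky solve (no
dense pseudo-inverse); cross-component pairs are `Inf` and flagged.
Distances are computed **once** on the full raster extent and subset per
window — recomputing per window would change the hypothesis being tested,
not just the sample.

Distance matrices are min–max normalized to [0, 1] before analysis. This is
cosmetic for the Mantel machinery (Pearson r is affine-invariant) but makes
matrices comparable in output files. Collinearity among predictors is
diagnosed with VIF = 1/(1 − R²) on the lower-triangle vectors (> 10 flags
trouble).

## Tests and the support criterion

Mantel statistics are Pearson correlations of lower-triangle vectors;
significance comes from jointly permuting rows and columns of one matrix
(for partial tests, the response G, residualizing on the covariate inside
every permutation). Tests are **one-tailed for positive association**: the
hypotheses are directional (resistance should increase genetic distance),
and a negative correlation is non-support, not reversed support. The
p-value uses the add-one estimator $(1 + \#\{r^\ast \ge r\})/(1 + n_{perm})$
so p is never 0 and is exact under full enumeration.

A hypothesis is supported in a window iff IBR explains G beyond geography
(`p(G ~ IBR | IBD) < α`) **and** geography adds nothing beyond IBR
(`p(G ~ IBD | IBR) ≥ α`). Both legs are kept in the output.

Commonality analysis decomposes the OLS R² of G on all predictors into
$2^p - 1$ subset coefficients. We obtain them as the exact solution of the
linear system $R^2(A) = \sum_{S \cap A \neq \emptyset} C_S$ over all
non-empty subsets — algebraically equivalent to the classical
inclusion–exclusion formulas but immune to sign bookkeeping errors, and it
guarantees $\sum_S C_S = R^2_{full}$ to solver precision. Subsets are
emitted by order, lexicographic within order. (The reference table this
package ships for its bookkeeping check prints second-order terms in colex
order; comparisons are by subset name.)

## Variogram

The empirical semivariogram of a spatial variable (typically PCA axis-1
scores of the allele matrix) uses half-open bins $[kw, (k+1)w)$ of width
50 km by default; $\hat\gamma(h)$ is half the mean squared difference over
pairs in the bin. An optional exponential model
$\gamma(h) = n + s(1 - e^{-h/r})$ is fitted by weighted least squares
(weights = pair counts). `nls` flags exact zero-residual fits as "singular
convergence", so convergence is judged by the achieved weighted residuals,
not the flag. Plateau reading remains interpretive; the package reports
fitted parameters only.

## Windows and aggregation

Windows are circles of diameter 220–1,000 km (step 20 km) centered on each
sampling location; membership is great-circle distance ≤ radius. Windows
with fewer than 3 distinct demes are dropped (`min_demes`, configurable):
below that, distance matrices are dominated by within-deme pairs and the
permutation tests degenerate. Candidate count is always
`n_locations × n_diameters` before filtering.

Per-scale summaries report the support percentage over *testable* windows
and the mean partial Mantel r over *supported* windows only. The
per-individual support surface divides the number of supported windows
containing an individual by the number of testable windows containing it,
within a scale band (default 220–600 km, where support geography varies
most). The source method names an "overlap correction" without defining
it; this ratio is our construction — it normalizes exactly the exposure
imbalance produced by overlapping circles, is bounded in [0, 1], and gives
identical values to individuals with identical window sets. IDW
interpolation (power 2, 12 nearest neighbors — the common GIS defaults)
maps it.

Per-window randomness is reproducible: window i uses seed
`(7919·seed + 104729·i) mod (2^31 − 1)` derived from the run seed.

# The synthetic world

The generator exists so that every stage is testable without external data.
It emulates: demes scattered over a rectangular landscape; smooth
environmental rasters (Gaussian-filtered noise, optional shared component
for inter-raster correlation, a latitudinal warm-south trend on
temperature, an optional cold barrier strip); and forward-time
Wright–Fisher demes whose per-copy migration probability is
$\propto e^{-C_{ij}/\theta}$ with $C$ the commute matrix of the driving
scenario, total emigration 0.25/generation, stepwise (±1 repeat) mutation
at $10^{-3}$, 200 generations. Defaults: 20 demes × 10 diploids × 10 loci
on a 25 × 25 grid — minutes-scale end-to-end runs. $\theta$ is set to the
lower quartile of the commute distribution: migration is effectively local
but the graph remains demographically connected on each side of a barrier.

What it does **not** emulate: linkage, null alleles, selection, uneven
sampling effort, coordinate error, and real rasters' long-range
autocorrelation structure. A green end-to-end test therefore establishes
that the pipeline recovers a known driver under idealized stepping-stone
gene flow — not that any particular empirical inference is correct.

Two theory checks calibrate the simulator: near-panmixia at high migration
(mean pairwise Fst < 0.02), and the two-deme island model, which
equilibrates near the **finite-island** expectation
$F_{st} \approx 1/(1 + 4Nm\,(d/(d-1))^2) = 1/(1+16Nm)$ at $d = 2$ — the
infinite-island shorthand $1/(1+4Nm)$ is off by the squared correction
factor at two demes and is not the oracle used.

# Numerical choices

* Great-circle distances everywhere (haversine, R = 6371 km); the source
  method's projection is unstated, and a projection-free choice is exactly
  reproducible.
* Allele identifiers are integers (fragment sizes), never strings.
* Missing genotype markers: empty cell (CSV), `0000`/`000000` (GenePop),
  `NA` in memory.
* Sampling points snap to the nearest valid raster cell within one cell
  diagonal; farther points are an error, not silently moved.
* Matrix normalization refuses constant matrices; Mantel tests refuse
  zero-variance matrices; windows hitting either are flagged "untestable"
  and excluded from denominators rather than failing the run.
* Permutation tests with an explicit permutation matrix reproduce exact
  enumeration; with a seed they are bit-reproducible.

# Known limitations

* **Deep vicariance defeats the support criterion at large scales.** In the
  default barrier world the two sides diverge strongly (cross-barrier Fst
  0.5–0.7). Bray–Curtis saturates across the split while each side keeps
  internal geography-aligned structure, so the *linear* partial Mantel
  leaves IBD significant in a substantial minority of replicates and the
  two-leg criterion withholds support for the true driver. Consequently the
  driving scenario ranks first at the largest scale in ~85% of replicates,
  not the ≥95% the package's strictest end-to-end check demands; the
  matrix-level positive control (G = commute + noise), which matches the
  criterion's linear assumptions, passes at 100%. This mirrors the
  empirical observation that study areas overlapping differentiated genetic
  clusters blur landscape inference — it is a property of the support
  criterion, documented rather than tuned away.
* Mantel-family tests have known inflation/deflation pathologies under
  spatial autocorrelation; commonality analysis is the built-in complement,
  not a cure.
* No least-cost paths, no MLPE/dbRDA, no HWE/LD testing, no null-allele
  estimation (loci to drop are user input), no GeoTIFF reader, no projected
  CRS support.
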