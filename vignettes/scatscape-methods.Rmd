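---
title: "Methods: from scat metabarcoding reads to conflict-hotspot maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from scat metabarcoding reads to conflict-hotspot maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scatscape)
```

`scatscape` analyses the diet of carnivores from scat DNA metabarcoding and
relates it to the landscape around the scat locations. This vignette is the
package's own account of the methods: the models and rules, the parameters
that matter, the choices made where the method itself leaves room, and what
the synthetic-data validation does and does not demonstrate.

## 1. From count tables to presence/absence

The pipeline ingests a denoised scat-by-OTU read count table (read-level
processing — trimming, denoising, chimera removal — is a sequencing-pipeline
concern and is out of scope). Three rules turn counts into the
presence/absence matrix on which every diet statistic is computed, applied in
a fixed order:

1. **Consensus taxonomy** (`consensus_assign()`). Reference hits failing
   97 % nucleotide identity or 85 % query coverage are discarded; among the
   top 50 surviving hits per OTU, the OTU is assigned to the deepest rank at
   which one taxon reaches at least 51 % agreement, descending species →
   genus → family. "At least 51 %" is taken literally as a fraction
   ≥ 0.51, so 26 of 50 hits pass and 25 of 50 do not — the tightest reading
   that keeps a strict majority with a one-hit margin at the 50-hit cap.
2. **Negative-control threshold** (`control_threshold_filter()`). The
   minimum-read threshold T is the largest per-OTU count observed in the
   flagged negative control; every table entry ≤ T is zeroed and the control
   removed. A per-OTU maximum is the most conservative statistic that still
   uses the control, and the most common practice; a per-OTU or mean variant
   would be laxer. Missing controls degrade to T = 0 with a warning rather
   than an error, since reruns without a control are common in practice.
3. **Presence rule** (`to_presence()`). OTU counts are pooled to their
   assigned taxon *first* (genus-level prey such as *Mus* spp. aggregate all
   member OTUs), then a taxon is present in a scat iff its relative
   abundance over the retained reads is strictly greater than 1 %. Pooling
   before thresholding is required for genus-level prey to be judged at the
   rank at which diets are reported. Relative abundance is computed over
   retained (post-taxonomy, post-host-exclusion) reads; computing it over
   all reads is the plausible alternative, but host read depth varies wildly
   between scats (blocking oligos are imperfect), which would make the
   effective presence threshold scat-dependent.

Between steps 2 and 3, OTUs that are unassigned or resolved only to family
level, OTUs outside the vertebrate classes, and the predator's own reads
inside its scats are removed (`drop_coarse_and_offtarget()`).

Properties enforced by tests: presence is invariant to uniform scaling of a
scat's counts; the chain reproduces the generating truth exactly on
noise-free synthetic data, and in ≥ 95 % of 200 seeded replicates with
sub-threshold noise; 50-table equivalence with an independent brute-force
filter.

## 2. Diet statistics

With `s_t` the number of scats containing taxon `t` and `N = Σ s_t` the
total number of prey items:

* percent occurrence `PO_t = 100 · s_t / N`;
* frequency of occurrence `FO_t = 100 · s_t / n_scats`;
* standardized Levins niche breadth `Bsta = (B − 1)/(N − 1)` with
  `B = 1/Σ p_i²`, `p_i = s_i/N`.

A "prey item" is one taxon present in one scat — multiplicity within a scat
is not counted, which is what makes `Σ s_t = N` an identity. The
standardization denominator is the **total number of prey items** `N`, not
the number of taxa: both published niche-breadth values (0.18 for the
leopard with N = 37, 0.07 for the leopard cat with N = 76) are reproduced
only under this reading, which also matches the verbal definition of the
index as used in this literature. The textbook variant that standardizes by
the taxon count is available via `levins_standardized(n = "taxa")` but is
off by default.

Table output rounds half-up to two decimals (the convention of printed diet
tables; R's default round-half-even would print 0.175 → 0.17), while full
precision is kept internally.

The bundled fixtures rebuild the two published diet tables:
`round_half_up(%PO × N / 100)` gives integer occurrence counts that re-sum
exactly to N for both predators (verified at load time and aborting
otherwise), and equal the counts implied by the %FO column. One documented
discrepancy is retained rather than reconciled: the prose accompanying the
original tables reports rodents at 17 % of the leopard diet while the table
itself sums to 16.22 % (6/37); the table is treated as authoritative.

## 3. Synthetic data: what it emulates, what it does not

`diet_fixture()` knows per-taxon totals but not which scats co-contained
which taxa (the per-scat matrix was never published), so each taxon's
occurrences are assigned to distinct scats uniformly at random under a seed,
with one constraint: no scat may end up empty, since every analysed scat by
construction contained at least one identified prey item. Column sums always
match the published counts; **row-level co-occurrence is randomized and any
scat-level aggregate (e.g. how many scats contain a domestic taxon) is
fixture-dependent** and flagged as such.

`simulate_scat_counts()` draws, per scat, a multinomial over the scat's true
prey taxa (equal shares of the prey budget), a host OTU (default 10 % of
reads — blocking oligos suppress, not eliminate, host DNA), and `noise_taxa`
contaminant taxa sharing `noise_fraction` of reads (default 0.5 % in the
pipeline, deliberately below the 1 % presence rule so noise is removable in
expectation). Noise lineages are synthetic vertebrates from an invented
family, so they can never collide with a real prey name yet still exercise
the abundance filter rather than the taxonomy filter. The negative control
carries only uniform leaked reads of at most `control_contamination` per
OTU. The generator does **not** emulate read-level errors, chimeras, tag
jumps, or taxon-specific amplification bias; passing recovery tests
therefore show the filter logic is correct, not that real libraries are this
clean.

`simulate_hit_table()` produces per-query hits of which a chosen fraction
carry a sibling species in the true genus, with identities/coverages drawn
above or below the cutoffs as configured — enough to drive every consensus
branch (species, genus ascent, unassigned).

`simulate_landscape()` paints rectangles and ellipses onto a background
grid, later placements overwriting earlier ones, and returns a ground-truth
inventory (cells, area, perimeter per visible patch) computed by direct
counting, independent of the metric code, for oracle tests.

## 4. Landscape fragmentation metrics

Patches are maximal 8-connected components of a class (two cells touching
only at a corner belong to one patch). Six class-level metrics are computed
per analysis unit:

| metric | definition | units | fragmentation direction |
|---|---|---|---|
| PD | patches per 100 ha | /100 ha | higher = more fragmented |
| ED | Σ perimeter / area | m/ha | higher |
| MPA | mean patch area | ha | **lower** = more fragmented |
| MSI | mean of 0.25·perimeter/√area | — | higher |
| MCA | mean core area at edge depth | ha | **lower** |
| ENN | mean nearest same-class patch distance | m | higher |

Numerical choices, each exposed as an argument:

* **Perimeter** counts cell faces adjacent to a different class, nodata, or
  the raster boundary. Clipped analysis units (forest-area masks, point
  buffers) need closed perimeters, so the boundary-as-edge convention is the
  only consistent one across scales; it can diverge from tools that offer a
  "border" option.
* **Core area** (default edge depth 100 m): a cell is core when its centre
  lies more than the edge depth from every cell centre outside its patch.
  Cell centres that do not exist (off the raster) impose no constraint.
  Centre-to-centre distance is exactly brute-forceable, which is what the
  oracle tests exploit; cell-edge variants differ by sub-cell amounts.
  Depth 0 makes MCA = MPA identically.
* **ENN** uses boundary-cell centre distances to the nearest other patch of
  the same class and is reported missing (NA) with fewer than two patches —
  a zero would fake contiguity.
* MSI equals 1 exactly for squares and exceeds 1 otherwise
  (property-tested); doubling the cell size multiplies areas ×4 and
  perimeters ×2 and leaves MSI unchanged.

`metrics_at_scales()` evaluates the metrics over the whole raster, over
named masks, or over circular point buffers (cell-centre membership,
default radius 1000 m), with the landscape area taken as the unit's
non-nodata area.

### Median-rank fragmentation classes

`classify_fragmentation()` ranks each metric across units in its
fragmentation direction (ties averaged, missing metrics excluded from that
unit's median), takes each unit's median rank, and splits units into
low/moderate/high by equal-count tertiles. The inversions for MPA and MCA
and the "farther apart = more isolated = more fragmented" reading of ENN are
the directions under which archetypal geometries sort correctly — a unit of
many small dispersed fragments classifies high, one large compact block low
(asserted on synthetic rasters). Tied medians stay together and a tie group
takes the tertile of its mean sorted position; a fully tied set of units is
uniformly "moderate", which is the only self-consistent label when no
ordering information exists.

## 5. Spatial context and interface rasters

Buffer composition counts cells whose centres fall inside the circle
(exactly brute-forceable; truncated with a warning at the raster edge), at
the five home-range-scale radii 1000/1500/2000/3500/4500 m by default.
Distance to the forest edge is the Euclidean distance from the point to the
nearest cell face separating forest from any other non-nodata class, signed
positive inside forest.

Interface rasters use a focal **presence** statistic (class occurs at any
cell centre within the 150 m circular neighbourhood): the layers are then
{0,1} and the cellwise products FA = forest×agriculture, FB =
forest×built-up, FAB = FA×FB are well-defined intersections. A focal mean
with threshold is available as an option, but presence is the only focal
statistic under which binary multiplication is meaningful. FAB ⊆ FA ∩ FB
holds identically and focal layers are monotone in radius (both
property-tested). The published landscape shares of these interfaces (41 %,
48 %, 39 %) depend on the original regional rasters and are not reproduction
targets; the operators are validated by oracles instead.

## 6. Reliance scores and models

Presence is collapsed to origin×group indicators (domestic ungulate, wild
rodent, ...) — the closest reconstruction of "grouped into various taxa,
mostly by order and class" that also carries the domestic/wild axis the
analysis is about. PCA runs on the covariance matrix (the indicators share
the 0/1 scale; correlation is an option), and PC1 is sign-oriented so that
scats containing a domestic taxon score at least as high on average as scats
with none. The orientation rule is the package's own, chosen to make
"positive = domestic-reliant" hold by construction rather than by luck of
the eigendecomposition.

The two model contracts are ordinary least squares: `pc1 ~ patch * predator`
with a two-way ANOVA including the interaction, and `pc1 ~ forest_prop +
edge_dist + frag_class`. The published fits (R² = 0.80 and 0.32) require the
unpublished per-scat matrix and are **not** reproducible; the statistical
layer is validated by parameter recovery (a simulated predator effect falls
inside its 95 % CI in ≥ 93 % of 200 runs) and by the F-test's type-I error
(0.05 ± 0.02 over 2000 null simulations at n = 46 scats, the study's sample
size).

## 7. Pipeline, problem sizes, limitations

`run_pipeline()` chains every stage under one YAML-round-trippable config
whose defaults are exactly the protocol parameters above, hashes every
output into a manifest, and is byte-deterministic under a fixed seed (every
stage seeds its own RNG stream derived from the master seed and restores the
caller's RNG state afterwards).

Problem sizes were chosen so the full validation suite runs comfortably on a
laptop: the demonstration landscape is 200×200 cells at 30 m (6 km × 6 km,
six named forest areas), oracle equivalence for the six metrics runs on 200
random rasters up to 20×20 cells (the brute-force oracle is quadratic in
cell count), focal oracles up to 30×30, and the statistical calibrations use
200–2000 simulations.

Known limitations: no biomass-corrected diet models (PO over-weights small
prey; mass is carried as metadata only); no CRS handling — rasters and
points are assumed planar metres; no spatial autocorrelation correction or
mixed models in the statistical layer; ESRI ASCII grid is the only raster
file format; and everything scat-level about the bundled fixtures reflects a
seeded randomization, not the original field data.
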