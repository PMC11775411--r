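# scatscape

Diet analysis of carnivores from scat DNA metabarcoding, combined with the
landscape context of the scat locations.

Non-invasive scat surveys plus 12S vertebrate metabarcoding are now the
standard way to ask what urban and peri-urban carnivores actually eat — and,
when a predator such as the leopard (*Panthera pardus*) turns out to rely on
cattle, goats and poultry, where in a fragmenting landscape human–carnivore
conflict is most likely. `scatscape` implements that whole analysis chain as
tested, reusable R functions:

* **Taxonomy and filtering** — consensus BLAST-style taxonomy assignment for
  OTUs (top ≤ 50 hits at ≥ 97 % identity and ≥ 85 % coverage, deepest rank
  with ≥ 51 % agreement), a negative-control minimum-read threshold, removal
  of off-target / family-level / host OTUs, and a strict > 1 % relative
  abundance presence rule.
* **Diet statistics** — percent occurrence `PO = s/N` (occurrences of a prey
  taxon over all prey occurrences), frequency of occurrence `FO` (share of
  scats containing the taxon), group and domestic/wild aggregates, and the
  standardized Levins niche breadth

  `Bsta = (B − 1) / (N − 1)`, with `B = 1 / Σ pᵢ²`, `pᵢ = sᵢ / N`,

  where `N` is the total number of prey items ingested (0 = specialist,
  1 = generalist).
* **Landscape fragmentation** — patch delineation on categorical rasters
  under the 8-neighbourhood rule and the six FRAGSTATS-style class metrics
  (patch density, edge density, mean patch area, mean shape index, mean core
  area at 100 m edge depth, mean Euclidean nearest-neighbour distance), at
  any analysis scale (whole raster, named masks, 1000 m point buffers), plus
  a median-rank classifier labelling units low / moderate / high
  fragmentation.
* **Spatial context** — land-cover composition in buffers
  (1000/1500/2000/3500/4500 m) around scat points, signed distance to the
  nearest forest edge, wildland–urban interface rasters (150 m focal
  presence of forest × agriculture × built-up), and a Welch comparison of
  habitat around cattle-positive vs cattle-negative scats.
* **Reliance statistics** — PCA of group×origin presence indicators giving a
  per-scat domestic-prey reliance score (PC1, oriented so higher = more
  domestic-reliant), with the two standard linear-model contracts
  (`PC1 ~ patch * predator` with two-way ANOVA; `PC1 ~ forest proportion +
  edge distance + fragmentation class`).
* **Synthetic data** — seeded generators for scat×OTU count tables
  (multinomial reads with host and contaminant noise plus a negative
  control), BLAST-style hit tables with controllable discordance, and
  land-cover rasters with known patch geometry, so the full pipeline runs
  and is validated without any external download.

Reconstructions of the two published diet-composition tables (20 leopard
scats, 37 prey items; 26 leopard-cat scats, 76 prey items) ship as plain-TSV
fixtures and drive the exact checks.

## Worked example

```r
library(scatscape)

fx <- diet_fixture("leopard", seed = 1)   # rebuild Table-style ground truth
diet_profile(fx$pm, fx$catalog)
```

```
Diet profile: 13 prey taxa, N = 37 items over 20 scats
                                 taxon     group   origin s po_pct fo_pct mass_kg
                   Cattle (Bos taurus)  ungulate domestic 9  24.32     45  167.00
                   Goat (Capra hircus)  ungulate domestic 3   8.11     15   26.00
                   ...
                      Mouse (Mus spp.)    rodent     wild 5  13.51     25    0.50
              Porcupine (Hystrix spp.)    rodent     wild 1   2.70      5    1.50

Standardized Levins niche breadth: 0.18
PO by origin: domestic 51.4%, wild 48.6%
PO by group: bird 18.9%, carnivore 2.7%, primate 2.7%, rodent 16.2%, ungulate 59.5%
```

Cattle alone account for 24.32 % of all leopard prey occurrences and occur in
45 % of scats; domestic animals make up 51.4 % of the diet, and the niche
breadth of 0.18 marks a fairly specialised predator despite 13 prey taxa.

The full pipeline — simulate reads, assign taxonomy, filter, diet stats,
fragmentation metrics, buffers, interfaces, reliance models — runs from one
seeded config and writes a hashed manifest:

```r
manifest <- run_pipeline(default_config(seed = 1), outdir = "run1")
```

Rerunning with the same config reproduces every file hash.

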