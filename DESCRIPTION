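Package: scatscape
Title: Carnivore Diet Metabarcoding and Landscape Fragmentation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the diet of carnivores from scat DNA
    metabarcoding together with the landscape context of the scat locations.
    Implements consensus taxonomy assignment from BLAST-style hit tables,
    negative-control and relative-abundance filtering of OTU count tables,
    dietary composition statistics (percent occurrence, frequency of
    occurrence, standardized Levins niche breadth), class-level forest
    fragmentation metrics with a median-rank fragmentation classifier,
    buffer-based habitat context around sample points, wildland-urban
    interface rasters, and PCA-based domestic-prey reliance models. A
    seeded synthetic-data module generates count tables, hit tables and
    categorical land-cover rasters with known ground truth so the whole
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
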