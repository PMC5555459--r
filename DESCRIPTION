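Package: chromomorph
Title: Morphometry and QTL Mapping of Nucleus and Chromocenter Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Image-based morphometric quantification of DAPI-stained
    interphase nuclei and their chromocenters (area, intensity, perimeter,
    roundness, heterogeneity, relative heterochromatin fraction), population
    statistics for recombinant inbred line panels (outlier filtering,
    broad-sense heritability from one-way variance components, trait
    correlation networks, transgression ratios), composite interval mapping
    with forward-backward cofactor selection and permutation-derived
    genome-wide LOD thresholds, and confirmation of detected loci against
    near-isogenic line introgression panels. A synthetic-data generator
    renders nucleus images with ground-truth masks and simulates selfed RIL
    populations with planted additive QTL so the whole pipeline is testable
    end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
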