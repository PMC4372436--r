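Package: bioregdiv
Title: Phylogenetic Diversity Assessment of Bioregional Plant Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Community phylogenetics toolkit for bioregional biodiversity
    assessment: Faith's phylogenetic diversity, MPD/MNTD with standardized
    effect sizes under the sample-pool randomization null (NRI/NTI),
    phylogenetic beta diversity (Dpw, Dnn, unweighted UniFrac), Bray-Curtis
    compositional dissimilarity, non-metric multidimensional scaling,
    Mantel-type matrix correlation, species accumulation curves, and
    conservation-priority summaries. Includes a mean-path-length tree dating
    routine, a synthetic-data generator (birth-death chronograms, community
    assembly scenarios, attribute tables with controlled rank correlation to
    diversity), and a config-driven pipeline that runs the full assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    picante,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
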