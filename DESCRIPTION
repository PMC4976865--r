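Package: betataxa
Title: Partitioning Species and Taxonomic Beta Diversity Among Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify compositional dissimilarity among sites from
    incidence (presence/absence) data, partitioning total Jaccard-family
    dissimilarity (beta-cc) into a species-replacement (turnover, beta-3)
    component and a richness-difference (beta-rich) component, both pairwise
    and across multiple sites.  The same partition is computed over the pooled
    set of Linnaean taxa at all ranks (species, genus, family, ...) to give a
    taxonomic dissimilarity (beta-ccT) that acts as a surrogate for
    phylogenetic beta diversity.  Also included: abundance-based sample
    coverage for inventory-completeness assessment, non-metric
    multidimensional scaling of dissimilarity matrices, correlations between
    species-level and taxonomic dissimilarity, a synthetic multi-site
    community generator with known compositional structure, and an
    end-to-end pipeline that writes tabular summaries of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
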