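Package: repomod
Title: Drug Repositioning from Side-Effect and Symptom Similarity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts new drug indications from clinical surface data alone.
    Drugs are embedded in a TF-IDF weighted side-effect space and linked by
    cosine similarity; diseases enter through a symptom-based similarity
    network. Both networks are clustered into overlapping dense modules by a
    greedy cohesiveness search, drug and disease modules are connected
    through curated chemical-disease associations, and individual
    drug-disease pairs inside a linked module pair are scored by propagating
    within-module path similarities across the known cross-module links.
    Includes strict readers and writers for the tabular interchange formats,
    a seeded synthetic-corpus generator with planted module structure for
    end-to-end testing, and precision-at-k evaluation against curation
    marks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    methods,
    pROC,
    stats,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
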