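Package: dermvis
Title: Visual-Element Decomposition of Dermoscopic Pattern Terminology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An executable knowledge model for the metaphoric terminology of
    dermoscopy. Metaphoric pattern terms ("pseudopods", "pigment network",
    "rosettes") are decomposed into typed visual elements (shapes, colors,
    textures, strokes, sizes, spatial patterns and positions) held in a
    validity-checked S4 object model with a two-layer vocabulary (a generic
    visuals layer and a dermoscopy extension layer). The package provides a
    four-flag interior/boundary spatial-relationship calculus evaluated by
    deterministic grid sampling with analytic shortcuts, a machine-readable
    catalog of pattern definitions with group structure and coverage audits,
    OWL2 serialization (RDF/XML and Turtle) with SKOS preferred/alternative
    labels, deterministic axiom verbalization with rater-agreement
    statistics, semiotic ontology-quality scoring with cross-ontology
    z-scores, a conjunctive feature-query engine over the catalog, and a
    seeded synthetic scene generator that instantiates pattern definitions
    as SVG geometry for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    xml2,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'catalog.R'
    'catalog-io.R'
    'core-model.R'
    'geometry.R'
    'owl.R'
    'ontology-build.R'
    'vocab.R'
    'query.R'
    'scenes.R'
    'semiotics.R'
    'utils.R'
    'verbalizer.R'
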