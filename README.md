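# dermvis

Visual-element decomposition of dermoscopic pattern terminology, as an
executable R toolkit.

## The problem

Dermoscopy — non-invasive, in-vivo imaging of skin lesions — names its
features with metaphors: *pseudopods*, *pigment network*, *rosettes*,
*blue white veil*. The metaphors are memorable but ambiguous, which is a
real obstacle for training, for standardization, and for any machine that
should reason about lesion features. The remedy modeled here is
decomposition: every metaphoric term is expressed as a composite of typed
**visual elements** — shapes (circle, line, polygon, structureless area)
with color fill, stroke, texture and size, arranged by spatial patterns,
spatial relationships, relative position and body position. A *dot* is a
small circle; a *pseudopod* is a peripheral circle meeting a radial line;
*rosettes* are bright white circles whose centers form a square.

dermvis implements that knowledge model end to end, for ontology
engineers and dermoscopy informatics researchers:

* a validity-checked S4 domain model with a two-layer vocabulary (a
  generic visuals core and a dermoscopy extension; core mode rejects
  dermoscopy-only values);
* a spatial-relationship calculus over the four interior/boundary
  intersection flags (bb, ii, bi, ib) of the dimensionally extended
  intersection model, evaluated by deterministic grid sampling with an
  exact analytic shortcut for circle pairs, exposing the nine predicates
  `spatialDisjoint`, `spatialMeet`, `spatialEqual`, `spatialOverlap`,
  `spatialInside`/`spatialContains`, `spatialCoveredBy`/`spatialCovers`
  and `spatialSurround`;
* a machine-readable catalog of pattern definitions with higher-level
  groups, alias resolution, schema-checked JSON/YAML files and a
  category-coverage audit;
* OWL2 serialization (Turtle and RDF/XML) with SKOS labels, canonical
  byte-stable exports, entity counting and diffing;
* deterministic axiom verbalization ("every ellipse is a shape") with
  Y/N/X review recoding (Y→1, N/X→0), per-rater and mean agreement, and
  pairwise percent agreement;
* semiotic quality scoring (richness, lawfulness, comprehensiveness
  computed; clarity/consistency/interpretability accepted as supplied
  leaves), uniform-mean aggregation into syntactic/semantic/pragmatic/
  overall composites, and cross-ontology z-scores;
* a conjunctive feature-query engine ("dark circles", "white lines")
  checked against a brute-force oracle;
* a seeded synthetic scene generator that renders pattern terms as SVG
  geometry satisfying their own clauses.

## A worked example

```r
library(dermvis)

# decompose a metaphoric term into its visual-element clauses
cat <- dermoscopyCatalog()
for (cl in decomposeTerm(cat, "Pseudopods")) show(cl)
#> <shape-requirement> Circle, Periphery
#> <shape-requirement> Line, Radial
#> <relation-assertion> Circle spatialMeet Line

# render a seeded geometric instantiation and check its own clause
sc <- renderScene(cat, "Pseudopods", seed = 7)
cfg <- spatialConfig(0.005, 0.01)
spatialPredicate("spatialMeet", sc@geometries[[2]], sc@geometries[[1]], cfg)
#> [1] TRUE

# rater agreement: per-rater proportions of recoded Y answers and their mean
m <- ratingMatrixFromProportions(c(0.90, 0.63, 0.92), 100)
st <- agreementStats(m)
st$perRater
#>   R1   R2   R3
#> 0.90 0.63 0.92
round(st$meanAgreement, 2)
#> [1] 0.82

# semiotic composites for a published four-ontology comparison
leaves <- readLeafScores()
aggregateScores(unlist(leaves["DEVO", ]))
#> syntactic  semantic pragmatic   overall
#> 0.7820000 0.9840000 0.0200000 0.5953333

# query the catalog for dark circles
findPatterns(cat, parseFeatureQuery("dark circles"))$term
#> [1] "Annular Granular Pattern" "Rim of Brown Globules"
```

The mean agreement of 0.82 is the unweighted mean of the three per-rater
proportions; the syntactic composite 0.782 is the uniform mean of
richness (0.564) and lawfulness (1); the query walks the color
subsumption table, so "dark" covers gray brown and brown circle clauses.

A thin command-line front end over the same functions ships at
`inst/scripts/dermvis-cli.R` (subcommands `classify`, `catalog`, `owl`,
`verbalize`, `agreement`, `score`, `render`, `query`).

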