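---
title: "Decomposing dermoscopic pattern terminology into visual elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing dermoscopic pattern terminology into visual elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermvis)
```

## The modeling problem

Dermoscopy describes sub-macroscopic features of skin lesions with a
metaphoric vocabulary — "pseudopods", "pigment network", "rosettes",
"leaf-like areas" — that is memorable but ambiguous, and with a
descriptive vocabulary of basic elements (lines, circles, dots, clods,
pseudopods, structureless areas) that is precise but verbose. dermvis
makes the bridge executable: every metaphoric pattern term is decomposed
into typed *visual elements* — shapes with fills, strokes, textures and
sizes, arranged under spatial patterns, spatial relationships and
relative/body positions — and the decomposition is machine-checkable,
serializable as OWL2, verbalizable for expert review, scoreable, and
queryable.

The model is layered. A generic *core* layer defines the vocabulary any
visualization needs (shape taxonomy, colors with RGB/hex encodings,
stroke, texture, size, points, spatial patterns and the pairwise spatial
predicates). A *dermoscopy* layer extends it with what the lesion
vocabulary demands: pigmentation-relative colors (hypopigmented,
pigmented, dark...), shiny texture, uniform/variable stroke widths and
sizes, styled lines (sharp, curved, serpiginous, wavy, dotted, double),
relative position (center, off-center, periphery) and body position
(face, volar). Constructors take a `mode` argument, and `"core"` mode
rejects dermoscopy-only values, preserving the two-layer architecture.

Three modeling conventions are worth calling out:

* **Circles are loose.** Real lesion elements are never perfect circles,
  so `Circle` means a rounded shape that need not have uniform radius;
  geometric realizations may perturb the radius up to a configurable
  eccentricity bound (default 0.3). "Dot", "clod", "globule" and
  "ellipse" are therefore *aliases*, not classes: a dot is a small
  circle, a clod or globule a circle, an ellipse a circle of long size
  (`shapeAlias()`, recorded as SKOS alternative labels in the export).
* **Named polygons carry exact point cardinalities.** A triangle has
  exactly 3 points and a decagon exactly 10 — the restriction is
  "exactly", not "at most"; `makeShape("Decagon", points = <9 points>)`
  is a cardinality error, and the OWL export uses exact qualified
  cardinality.
* **Pattern containment is not functional.** A pattern is a non-empty
  composite of shapes and/or sub-patterns, may contain several
  sub-patterns, and the containment graph must be acyclic (checked at
  construction).

## The spatial calculus

Spatial adjacency between elements uses a four-flag abstraction of the
dimensionally extended intersection model: for a pair of plane objects we
record whether boundary meets boundary (`bb`), interior meets interior
(`ii`), the first boundary meets the second interior (`bi`), and
conversely (`ib`). Predicates are fixed truth-table functions of the
flags:

| predicate        | condition              |
|------------------|------------------------|
| spatialDisjoint  | ¬bb ∧ ¬ii ∧ ¬bi ∧ ¬ib  |
| spatialMeet      | bb ∧ ¬ii ∧ ¬bi ∧ ¬ib   |
| spatialEqual     | bb ∧ ii ∧ ¬bi ∧ ¬ib    |
| spatialOverlap   | bb ∧ ii ∧ bi ∧ ib      |
| spatialInside    | ii ∧ bi ∧ ¬bb          |
| spatialContains  | ii ∧ ib ∧ ¬bb          |
| spatialCoveredBy | bb ∧ ii ∧ bi           |
| spatialCovers    | bb ∧ ii ∧ ib           |

Two design decisions sit behind this table. First, the source
vocabulary's prose description of *contains* ("the interior is part of
the boundary") conflicts with the standard point-set reading; we follow
the converse-pair structure the vocabulary clearly intends —
inside/contains and coveredBy/covers are mutual converses, which the test
suite verifies on randomized scenes — and additionally offer a strict
point-set mode (`spatialConfig(strict = TRUE)`) that uses
exterior-intersection flags. Second, the *overlap* definition requires
all four flag combinations, which is stronger than common usage (it
excludes, e.g., a lens-shaped overlap in which one boundary never enters
the other's interior); we adopt it verbatim and flag it here.

### Evaluation by grid sampling

The reference evaluation is deterministic exhaustive sampling: the joint
bounding box, expanded by twice the boundary tolerance, is covered by a
row-major lattice of step `resolution`; every lattice point is classified
against each geometry as interior, boundary (within `eps` of the
boundary) or exterior; a flag is set when its combination is realized at
any point. There is no randomness. Defaults are `resolution = 0.01` and
`eps = 2 * resolution` in canvas units. Consequences a user should know:

* **Tangency is `eps`-dependent.** "Meet" means the boundaries come
  within the tolerance while no interior mixing is detected. The scene
  generator places meeting pairs at exactly the configured `eps` gap.
* **1-D geometries get tube semantics.** A polyline's point set is its
  `eps`-tube; points near the endpoints are its boundary, other on-curve
  points its interior. External circle–line tangency at *zero* gap
  produces a thin boundary-interior crescent under these semantics, which
  is why meeting constructions stand off by `eps`.
* **Degenerate geometry errors.** A geometry smaller than twice the grid
  step raises an error instead of silently sampling nothing, forcing the
  caller to refine the resolution.
* **Numerical hygiene.** The lattice origin is offset by an irrational
  fraction of the step so lattice points never sit exactly on
  round-number boundaries, and the circle-pair analytic shortcut (which
  reduces each grid column to closed-form y-intervals and is exact on the
  lattice) shrinks open interior/exterior intervals by a 1e-9 hair so
  ties resolve to the boundary band exactly as the grid classifier
  resolves them. The shortcut-vs-grid equivalence is asserted over 200
  seeded circle/polygon pairs.

`spatialSurround` has no stated definition beyond its name, so the
package defines it: a (possibly composite) geometry A surrounds B when B
lies inside the convex hull of A's components and no component's interior
overlaps B's. This makes "interconnecting lines surrounding large
hypopigmented circles" checkable against a rendered mesh scene.

## The pattern catalog

`dermoscopyCatalog()` ships the pattern definitions whose decompositions
are attested in the consensus-derived vocabulary, organized under six
higher-level groups (Blotch ×2, Globules ×4, Dots ×2, Streaks ×3, Shiny
White Structures ×3, Network ×2) plus ungrouped terms (milia-like cyst,
starburst, annular granular, rainbow, ridge, blue white veil). Where only
the term name and its group are attested, clauses follow the group's
stated structure and the definition is marked `provisional`. The full
48-term inventory can be supplied as a user catalog file (JSON or YAML,
one document per term with keys
`term/alt_labels/group/clauses/body_position/annotations`); the loader is
format-complete and schema-strict, reporting the offending document and
clause on error (documents are addressed by index and term rather than
raw line number, which the YAML/JSON parsers do not reliably expose).

Clauses are role-typed (`shape-requirement`, `relation-assertion`,
`subpattern-reference`, `spatial-pattern`, `body-position`,
`annotation`), and validity checking rejects fields a role does not
license. Non-visual information — the polarized-light requirement of
shiny white structures and the rainbow pattern, the cloudy/starry
appearance of milia-like cysts — lives in annotations only, never in
visual clauses; a test enforces this. Stroke is deliberately rare in the
shipped definitions (expert annotators found "stroke" a poor fit for
lesion borders); it survives only as the uniform-width qualifier of the
typical pigment network lines.

```{r catalog}
cat <- dermoscopyCatalog()
for (cl in decomposeTerm(cat, "Pseudopods")) show(cl)
```

`auditCategoryCoverage()` implements the reviewers' consistency rule —
once any term defines a category (color, size, ...), every term should —
and reports, deterministically, which terms lack which used categories.
The shipped catalog intentionally fails this audit (e.g. texture is only
attested for milia-like cysts); the audit is a to-do list, not a
validity gate.

## Scenes: executable instantiations

`renderScene(catalog, term, seed)` draws a seeded geometric instantiation
of a term on the unit canvas (x rightward, y downward, SVG convention)
such that the term's clauses hold under the calculus: pseudopod scenes
place five peripheral circles each meeting its radial line, rosette
scenes place four bright white circles whose centers form an exact
square, network scenes surround hypopigmented circles with a line mesh.
Conventions: "periphery" means centroid > 0.35 from the canvas center,
"center" < 0.15; randomness comes only from the seed (global RNG state is
saved and restored), and identical (term, seed) pairs give byte-identical
SVG. Terms whose clauses need unbounded or structureless areas (blotches,
veils, rainbow) are honestly not realizable and raise an explicit error.

The generator emulates geometry and topology only: it does not emulate
color gradients, texture, lighting, skin-tone context or the irregular
outlines of real lesions. Passing scene-based tests therefore shows that
the calculus and the clause semantics cohere — not that the definitions
segment real dermoscopic images.

## OWL2 serialization

`buildCoreOntology()` and `buildDermoscopyOntology()` assemble the two
layers as ontology models (the dermoscopy layer imports the core by IRI),
and `exportOWL()`/`importOWL()` serialize them as Turtle or RDF/XML with
SKOS preferred/alternative labels. Choices:

* **IRIs** are `<base>#CamelCaseLabel`; the source publishes no IRIs, so
  a single package namespace is used and kept stable across exports.
* **Canonical order.** Entities and axioms are emitted in lexicographic
  order, so export → import → export is byte-identical (tested for both
  dialects), and cross-dialect imports are axiom-equivalent.
* **No bundled reasoner.** `structuralViolations()` checks what a
  modeler wants before invoking an external DL reasoner: conflicting
  exact cardinalities, subclassing under disjoint classes, dangling
  references. Data-property ranges are typed (`xsd:integer` for stroke
  width and RGB components), never plain literals.

The built dermoscopy layer is far smaller than a full released ontology
(the ~1000-class scale comes from an imported color inventory and the
complete 48-term catalog); `entityCounts()` reports whatever model it is
given, with and without the import closure.

## Verbalization and rater agreement

`verbalize()` maps axioms to review sentences through fixed templates
with lower-cased labels — `Ellipse ⊑ Shape` becomes "every ellipse is a
shape", an exact cardinality becomes "every decagon is something that has
exactly 10 points" — deterministically, so review sheets are stable
across runs. Review answers are Y (agree), N (disagree) and X (unsure);
recoding maps Y→1 and both N and X→0, on the premise that an unclear
axiom counts against the model. `agreementStats()` then gives per-rater
proportions of 1s, their unweighted mean, and pairwise percent agreement
(simple percent agreement over rater pairs, not a chance-corrected
kappa, matching how such reviews are reported). Whether pairwise
agreement should compare raw Y/N/X or recoded values is ambiguous in the
source; both are offered and recoded is the default. Reconstructing a
matrix from reported per-rater proportions (0.90, 0.63, 0.92 over
100-statement columns) reproduces the reported mean of 0.82.

## Semiotic quality scores

Leaf metrics: `richness` (fraction of a fixed 16-kind OWL2 construct
inventory used), `lawfulness` (1 − violations/statements), and
`comprehensiveness` (element count normalized by the corpus maximum) are
computed; `clarity`, `consistency` and `interpretability` require an
external word-sense inventory and are accepted as supplied leaves (the
shipped `semiotic_leaf_scores.csv` carries the published four-ontology
dermatology comparison: DEVO, DL, HDDO, SPO). Aggregation is uniform-mean
by default — syntactic = mean(richness, lawfulness), semantic =
mean(clarity, consistency, interpretability), pragmatic =
comprehensiveness, overall = mean of the three — with configurable
non-negative weights. The published syntactic composites reproduce
exactly under uniform means (0.782, 0.417, 0.577, 0.692 with half-even
display rounding at 3 dp, for which `roundHalfEven()` performs decimal
tie detection); the published semantic and overall composites deviate
from uniform means by a few thousandths (0.986 vs 0.984; 0.597 vs
0.596), so their reproduction is documented as approximate and the
cross-ontology z-scores (`zScores()`, sample standard deviation) are
computed on the published composite rows, where they match the reported
1.17, −0.589, 1.22 and 1.45 within ±0.005.

## The query engine

`findPatterns()` answers conjunctive feature queries over the catalog. A
term matches when its expanded clause set satisfies every constraint, and
the shape-attribute constraints (shape, color, size, texture,
relationship, relative position) must hold jointly on a *single* clause:
"dark circles" requires a dark-colored circle clause, not a dark line
plus a white circle. `subsumes` mode (default) walks the color
subsumption table (Dark covers black, brown, gray brown, blue gray,
indigo, violet; pigmented covers the melanin colors; white covers bright
white) and lets the generic polygon cover named subkinds. Result order is
matched-clause count descending, then term ascending. Free-text queries
are parsed by a fixed color-adjective + shape-noun grammar with plural
folding — deliberately not natural-language processing; anything else
asks for a structured query. Disease-association queries are out of
scope: the model links no diseases. An independent brute-force clause
scan (`bruteForceFind()`) must agree with the engine on every
single-constraint query over every vocabulary value; this runs in the
test suite and the acceptance script.

## Problem sizes and numerical defaults

The shipped checks use: grid resolution 0.01 with eps 0.02 for
predicate-level work and 0.005/0.01 for scene-level work (scene
geometries are smaller); 200 seeded pairs for the shortcut/oracle
equivalence; 20 seeds per relation for generator–checker closure; 100
statements per rater column when reconstructing agreement arithmetic.
These sizes were chosen so the full property suite exercises every
branch while remaining comfortably interactive.

## Known limitations

* The shipped catalog covers the terms whose decompositions are attested
  in the consensus vocabulary's published materials, not all 48; the
  rest load from a user catalog file. Vessel patterns (arborizing,
  glomerular, ...) are absent entirely.
* Skin-tone context (e.g. a Fitzpatrick scale) is unmodeled, although
  pigmentation colors are defined relative to the individual's skin.
* The geometric calculus is 2-D and topological only; no raster-image
  segmentation, no full nine-cell intersection matrix with dimension
  values (the four-flag abstraction plus the optional strict mode).
* "Uniform color"/"variable color" are modeled as symbolic colors with a
  qualifier flag; the source lists them under Color but they behave as
  collection qualifiers — the ambiguity is preserved, not resolved.
* Whether a medium stroke width exists in the dermoscopy layer is
  unclear in the source; it is accepted in both modes here.
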