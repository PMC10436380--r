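# shared fixtures built in code

black <- makeColor("Black", c(0, 0, 0), "#000000")
white <- makeColor("White", c(255, 255, 255), "#FFFFFF")
blue <- makeColor("Blue", c(0, 0, 255), "#0000FF")
gray <- makeColor("Gray", c(128, 128, 128), "#808080")

# a tiny two-term catalog: one term with a color clause, one without
toyCatalog <- function() {
  cg <- emptyCatalog()
  cg <- registerPattern(cg, patternDefinition(
    "Toy Colored", clauses = list(shapeClause("Circle", color = "Black"))))
  registerPattern(cg, patternDefinition(
    "Toy Plain", clauses = list(shapeClause("Line"))))
}

# a three-class toy ontology with one object property
toyOntology <- function() {
  m <- ontologyModel("http://example.org/toy", "toy")
  m <- addEntity(m, "Shape")
  m <- addEntity(m, "Circle")
  m <- addEntity(m, "Ellipse")
  m <- addAxiom(m, "SubClassOf", "Circle", object = "Shape")
  m <- addAxiom(m, "SubClassOf", "Ellipse", object = "Shape")
  m <- addEntity(m, "hasShape", "objectProperty")
  m
}

# random simple scene pairs for property tests (circle/polygon mix)
randomGeometryPair <- function(allowPolygons = TRUE) {
  mk <- function() {
    if (allowPolygons && stats::runif(1) < 0.3) {
      regularPolygonGeom(stats::runif(2, 0.3, 0.7),
                         stats::runif(1, 0.08, 0.2),
                         sample(3:6, 1), rotate = stats::runif(1, 0, pi))
    } else {
      circleGeom(stats::runif(2, 0.3, 0.7), stats::runif(1, 0.08, 0.2))
    }
  }
  list(a = mk(), b = mk())
}

stateFlags <- function(st) c(bb = st@bb, ii = st@ii, bi = st@bi, ib = st@ib)
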