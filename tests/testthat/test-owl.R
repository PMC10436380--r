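test_that("entity counts cover toys, the empty model and imports", {
  toy <- toyOntology()
  expect_identical(entityCounts(toy),
                   c(classes = 3L, objectProperties = 1L,
                     dataProperties = 0L))
  expect_identical(unname(entityCounts(ontologyModel())), c(0L, 0L, 0L))
  # additivity over the import closure, shared declarations counted once
  derm <- buildDermoscopyOntology()
  core <- derm@imports[[1]]
  shared <- sum(derm@entities$label %in% core@entities$label)
  expect_identical(
    sum(entityCounts(derm, includeImports = TRUE)),
    sum(entityCounts(derm)) + sum(entityCounts(core)) - shared)
})

test_that("export produces re-parseable documents with stable IRIs", {
  core <- buildCoreOntology()
  ttl <- exportOWL(core, "turtle")
  expect_match(ttl, "Circle rdf:type owl:Class", fixed = TRUE)
  expect_match(ttl, "skos:prefLabel", fixed = TRUE)
  expect_identical(exportOWL(core, "turtle"), ttl)   # stable across exports
  derm <- buildDermoscopyOntology()
  ttl2 <- exportOWL(derm, "turtle")
  expect_match(ttl2, "owl:imports", fixed = TRUE)
  expect_match(ttl2, core@iri, fixed = TRUE)
})

test_that("export-import-export is byte-identical in both dialects", {
  for (m in list(toyOntology(), buildCoreOntology(),
                 buildDermoscopyOntology())) {
    for (dialect in c("turtle", "rdfxml")) {
      one <- exportOWL(m, dialect)
      back <- importOWL(one)
      expect_true(axiomEquivalent(m, back))
      expect_identical(exportOWL(back, dialect), one)
    }
  }
})

test_that("the two dialects are axiom-equivalent", {
  for (m in list(toyOntology(), buildCoreOntology())) {
    fromTTL <- importOWL(exportOWL(m, "turtle"))
    fromXML <- importOWL(exportOWL(m, "rdfxml"))
    expect_true(axiomEquivalent(fromTTL, fromXML))
  }
})

test_that("polygon point counts are exact cardinality restrictions", {
  core <- buildCoreOntology()
  ax <- core@axioms
  dec <- ax[ax$kind == "ObjectExactCardinality" & ax$subject == "Decagon", ]
  expect_identical(dec$value, 10L)
  expect_identical(dec$property, "hasPoints")
  # and data properties have typed (numeric) ranges, not plain literals
  rng <- ax[ax$kind == "DataPropertyRange" & ax$subject == "strokeWidth", ]
  expect_identical(rng$object, "integer")
  ttl <- exportOWL(core, "turtle")
  expect_match(ttl, "owl:qualifiedCardinality \"10\"", fixed = TRUE)
  expect_false(grepl("maxQualifiedCardinality", ttl))
})

test_that("malformed documents raise located parse errors", {
  expect_error(importOWL("<rdf:RDF><broken", dialect = "rdfxml"),
               class = "parseError")
  expect_error(importOWL(":A rdf:type owl:Class", dialect = "turtle"),
               class = "parseError")
})

test_that("unnamed entities cannot be exported", {
  expect_error(addEntity(ontologyModel(), ""),
               class = "unnamedEntityError")
})

test_that("structural checks catch cardinality conflicts and disjointness
          clashes", {
  m <- toyOntology()
  expect_identical(structuralViolations(m), character(0))
  m <- addEntity(m, "hasPoints", "objectProperty")
  m <- addEntity(m, "Point")
  m <- addAxiom(m, "ObjectExactCardinality", "Circle", "hasPoints",
                "Point", 3L)
  m <- addAxiom(m, "ObjectExactCardinality", "Circle", "hasPoints",
                "Point", 4L)
  expect_match(structuralViolations(m), "conflicting", all = FALSE)
  d <- toyOntology()
  d <- addEntity(d, "Color")
  d <- addAxiom(d, "DisjointClasses", "Shape", object = "Color")
  d <- addAxiom(d, "SubClassOf", "Circle", object = "Color")
  expect_match(structuralViolations(d), "disjoint", all = FALSE)
  expect_lt(lawfulness(d), 1)
})

test_that("owlDiff reports axiom and entity asymmetries", {
  a <- toyOntology()
  b <- addAxiom(a, "SubClassOf", "Ellipse", object = "Circle")
  d <- owlDiff(a, b)
  expect_identical(nrow(d$axiomsOnlyInA), 0L)
  expect_identical(d$axiomsOnlyInB$subject, "Ellipse")
})
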