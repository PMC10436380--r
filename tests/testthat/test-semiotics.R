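leaves <- readLeafScores()

test_that("richness is the used fraction of the construct inventory", {
  inv <- owlConstructInventory()
  expect_length(inv, 16)
  empty <- ontologyModel()
  expect_equal(richness(empty), 0)
  # a toy exercising 4 of the 16 kinds (annotation labels count as one)
  m <- toyOntology()
  m <- addAxiom(m, "DisjointClasses", "Circle", object = "Ellipse")
  m <- addAxiom(m, "ObjectPropertyDomain", "hasShape", object = "Shape")
  expect_equal(richness(m), 4 / 16)
  full <- Reduce(function(mm, k) addAxiom(mm, k, "Shape", "p", "Shape", 1L),
                 setdiff(owlConstructInventory(), "AnnotationAssertion"),
                 toyOntology())
  expect_equal(richness(full), 1)
})

test_that("lawfulness is one minus the violation rate", {
  expect_equal(lawfulness(toyOntology()), 1)
  expect_equal(lawfulness(ontologyModel()), 1)   # empty: no violations
  m <- toyOntology()   # 4 entities + 2 axioms = 6 statements
  expect_equal(lawfulness(m, violations = 3), 0.5)
  expect_equal(lawfulness(buildDermoscopyOntology()), 1)
})

test_that("comprehensiveness normalizes by the corpus maximum", {
  expect_equal(comprehensiveness(50, list(500, 100)), 0.1)
  expect_equal(comprehensiveness(500, list(500, 100)), 1)
  toy <- toyOntology()
  expect_equal(comprehensiveness(toy, list(toy)), 1)
})

test_that("uniform-mean aggregation reproduces the published syntactic
          composites", {
  expected <- c(DEVO = 0.782, DL = 0.417, HDDO = 0.577, SPO = 0.692)
  for (o in names(expected)) {
    syn <- aggregateScores(unlist(leaves[o, ]))[["syntactic"]]
    expect_equal(roundHalfEven(syn, 3), unname(expected[o]), info = o)
  }
})

test_that("aggregation handles extremes and names missing leaves", {
  ones <- stats::setNames(rep(1, 6), names(leaves))
  expect_equal(unname(aggregateScores(ones)), rep(1, 4))
  err <- expect_error(aggregateScores(c(richness = 0.5, lawfulness = 1)),
                      class = "missingLeafError")
  expect_match(conditionMessage(err), "clarity")
  # weights must be non-negative and renormalize
  w <- list(syntactic = c(2, 2))
  expect_equal(aggregateScores(unlist(leaves["DEVO", ]), w)[["syntactic"]],
               0.782)
  expect_error(aggregateScores(ones, list(syntactic = c(-1, 1))),
               class = "weightError")
})

test_that("sample-sd z-scores reproduce the published standardizations", {
  comp <- readCompositeScores()
  zOverall <- zScores(unlist(comp["overall", ]))
  expect_equal(unname(zOverall["DEVO"]), 1.17, tolerance = 0.005)
  zPrag <- zScores(unlist(comp["pragmatic", ]))
  expect_equal(unname(zPrag["DEVO"]), -0.589, tolerance = 0.005)
  expect_equal(unname(zPrag["DL"]), 1.45, tolerance = 0.005)
  zRich <- zScores(stats::setNames(leaves$richness, rownames(leaves)))
  expect_equal(unname(zRich["DEVO"]), 1.22, tolerance = 0.005)
  # z-scores always sum to zero
  for (z in list(zOverall, zPrag, zRich))
    expect_lt(abs(sum(z)), 1e-9)
  expect_error(zScores(c(1, 1, 1)), class = "zscoreError")
  expect_error(zScores(0.5), class = "zscoreError")
})

test_that("display rounding is half-to-even on decimal ties", {
  expect_equal(roundHalfEven((0.385 + 1) / 2, 3), 0.692)
  expect_equal(roundHalfEven(0.6935, 3), 0.694)
  expect_equal(roundHalfEven(2.5, 0), 2)
  expect_equal(roundHalfEven(3.5, 0), 4)
})

test_that("the score report carries raw scores, z-scores and display", {
  rep <- scoreReport(leaves)
  expect_identical(colnames(rep$scores), rownames(leaves))
  expect_equal(rep$scores["syntactic", "DEVO"], 0.782)
  expect_identical(rep$display["syntactic", "SPO"], "0.692")
  expect_equal(unname(rep$z["richness", "DEVO"]), 1.215, tolerance = 1e-3)
  # all scores are proportions
  expect_true(all(rep$scores >= 0 & rep$scores <= 1))
})

test_that("computed metrics for the built ontology stay in range", {
  derm <- buildDermoscopyOntology()
  r <- richness(derm)
  expect_true(r > 0 && r <= 1)
  leaf <- c(richness = r, lawfulness = lawfulness(derm),
            clarity = 1, consistency = 1, interpretability = 1,
            comprehensiveness = comprehensiveness(derm, list(derm)))
  agg <- aggregateScores(leaf)
  expect_true(all(agg >= 0 & agg <= 1))
})
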