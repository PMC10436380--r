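shipped <- dermoscopyCatalog()
cfg <- spatialConfig(0.005, 0.01)

test_that("identical (term, seed) pairs give identical scenes and SVG
          bytes", {
  s1 <- renderScene(shipped, "Pseudopods", 7)
  s2 <- renderScene(shipped, "Pseudopods", 7)
  expect_identical(sceneToSVG(s1), sceneToSVG(s2))
  s3 <- renderScene(shipped, "Pseudopods", 8)
  expect_false(identical(sceneToSVG(s1), sceneToSVG(s3)))
})

test_that("pseudopod scenes satisfy the meet clause they encode", {
  sc <- renderScene(shipped, "Pseudopods", 7, cfg)
  circles <- which(grepl("circle", sc@ids))
  for (i in circles) {
    line <- sc@geometries[[i - 1]]
    circ <- sc@geometries[[i]]
    expect_true(spatialPredicate("spatialMeet", circ, line, cfg))
    # peripheral placement per the canvas convention
    ctr <- circ@center
    expect_gt(sqrt(sum((ctr - c(0.5, 0.5))^2)), 0.35)
  }
})

test_that("rosette scenes place four circles in a square formation", {
  sc <- renderScene(shipped, "Rosettes", 1)
  expect_length(sc@geometries, 4)
  ctrs <- t(vapply(sc@geometries, function(g) g@center, numeric(2)))
  d <- sort(as.matrix(dist(ctrs))[upper.tri(diag(4))])
  expect_equal(d[1], d[4], tolerance = 1e-9)          # four equal sides
  expect_equal(d[5] / d[1], sqrt(2), tolerance = 1e-9)  # diagonals
})

test_that("network scenes surround their circles with the line mesh", {
  sc <- renderScene(shipped, "Pigment Network", 3, cfg)
  lines <- sc@geometries[grepl("line", sc@ids)]
  for (i in which(grepl("circle", sc@ids))) {
    expect_true(spatialSurrounds(lines, sc@geometries[[i]], cfg))
  }
})

test_that("every supported relation generates a pair its checker accepts", {
  for (rel in spatialPredicates()) {
    for (seed in c(1, 5, 9)) {
      pr <- sampleRelationPair(rel, seed)
      if (rel == "spatialSurround") {
        expect_true(spatialSurrounds(pr$a, pr$b, cfg), info = rel)
      } else {
        expect_true(rel %in% classifyRelations(pr$a, pr$b, cfg),
                    info = paste(rel, seed))
      }
    }
  }
  expect_error(sampleRelationPair("touches"), class = "vocabularyError")
})

test_that("scenes stay within the unit canvas", {
  for (term in c("Pseudopods", "Rosettes", "Dots Regular",
                 "Cobblestones", "Ridge Pattern")) {
    sc <- renderScene(shipped, term, 4)
    for (g in sc@geometries) {
      bb <- geomBBox(g)
      expect_true(all(c(bb$xlim, bb$ylim) >= -1e-9) &&
                    all(c(bb$xlim, bb$ylim) <= 1 + 1e-9), info = term)
    }
  }
})

test_that("unrealizable terms raise an explicit error", {
  expect_error(renderScene(shipped, "Rainbow Pattern", 1),
               class = "notRealizableError")
  expect_error(renderScene(shipped, "Blue White Veil", 1),
               class = "notRealizableError")
})

test_that("SVG round trip reproduces the geometry within 1e-6", {
  for (term in c("Pseudopods", "Rosettes", "Cobblestones")) {
    sc <- renderScene(shipped, term, 11)
    back <- readSceneSVG(sceneToSVG(sc))
    expect_identical(back@ids, sc@ids)
    expect_identical(back@provenance, sc@provenance)
    for (i in seq_along(sc@geometries)) {
      g1 <- sc@geometries[[i]]; g2 <- back@geometries[[i]]
      if (is(g1, "CircleGeom")) {
        expect_lt(max(abs(c(g1@center - g2@center, g1@radius - g2@radius))),
                  1e-6)
      } else {
        expect_lt(max(abs(g1@vertices - g2@vertices)), 1e-6)
      }
    }
  }
})

test_that("scene JSON round trips exactly", {
  sc <- renderScene(shipped, "Branched Streaks", 2)
  path <- withr::local_tempfile(fileext = ".json")
  writeSceneJSON(sc, path)
  back <- readSceneJSON(path)
  expect_identical(back@ids, sc@ids)
  expect_identical(back@seed, sc@seed)
  for (i in seq_along(sc@geometries))
    expect_equal(sc@geometries[[i]]@vertices, back@geometries[[i]]@vertices)
})

test_that("unsupported SVG elements are rejected", {
  svg <- paste0('<svg xmlns="http://www.w3.org/2000/svg">',
                '<ellipse cx="1" cy="1" rx="2" ry="1"/></svg>')
  expect_error(readSceneSVG(svg), class = "svgError")
})
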