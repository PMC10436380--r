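cfg <- spatialConfig(0.01, 0.02)

test_that("intersection flags reproduce canonical configurations", {
  far <- intersectionState(circleGeom(c(0, 0), 1), circleGeom(c(5, 0), 1),
                           cfg)
  expect_identical(unname(stateFlags(far)), rep(FALSE, 4))
  same <- intersectionState(circleGeom(c(0, 0), 1), circleGeom(c(0, 0), 1),
                            cfg)
  expect_identical(unname(stateFlags(same)), c(TRUE, TRUE, FALSE, FALSE))
  nested <- intersectionState(circleGeom(c(0.5, 0), 1),
                              circleGeom(c(0, 0), 3), cfg)
  expect_identical(unname(stateFlags(nested)),
                   c(FALSE, TRUE, TRUE, FALSE))
})

test_that("predicates follow the truth table on canonical pairs", {
  expect_true(spatialPredicate("spatialDisjoint", circleGeom(c(0, 0), 1),
                               circleGeom(c(5, 0), 1), cfg))
  expect_true(spatialPredicate("spatialMeet", circleGeom(c(0, 0), 1),
                               circleGeom(c(2, 0), 1), cfg))
  expect_true(spatialPredicate("spatialInside", circleGeom(c(0.5, 0), 1),
                               circleGeom(c(0, 0), 3), cfg))
  expect_identical(classifyRelations(circleGeom(c(0, 0), 1),
                                     circleGeom(c(0, 0), 1), cfg),
                   "spatialEqual")
  # the adopted overlap convention requires all four flags
  expect_true("spatialOverlap" %in%
                classifyRelations(circleGeom(c(0, 0), 1),
                                  circleGeom(c(1, 0), 1), cfg))
  expect_identical(classifyRelations(circleGeom(c(0, 0), 1),
                                     circleGeom(c(5, 0), 1), cfg),
                   "spatialDisjoint")
})

test_that("unknown predicates list the vocabulary", {
  err <- expect_error(
    spatialPredicate("touches", circleGeom(c(0, 0), 1),
                     circleGeom(c(0, 0), 1), cfg),
    class = "vocabularyError")
  expect_match(conditionMessage(err), "spatialDisjoint")
})

test_that("degenerate geometry forces grid refinement", {
  expect_error(intersectionState(circleGeom(c(0, 0), 0.005),
                                 circleGeom(c(0, 0), 1), cfg),
               class = "degenerateGeometryError")
})

test_that("flags are symmetric under the bb/ii swap and bi<->ib exchange", {
  withr::with_seed(101, {
    for (i in 1:20) {
      pr <- randomGeometryPair()
      ab <- intersectionState(pr$a, pr$b, cfg)
      ba <- intersectionState(pr$b, pr$a, cfg)
      expect_identical(ab@bb, ba@bb)
      expect_identical(ab@ii, ba@ii)
      expect_identical(ab@bi, ba@ib)
      expect_identical(ab@ib, ba@bi)
    }
  })
})

test_that("symmetric predicates and converse pairs hold on random scenes", {
  symmetric <- c("spatialDisjoint", "spatialMeet", "spatialEqual",
                 "spatialOverlap")
  withr::with_seed(202, {
    for (i in 1:15) {
      pr <- randomGeometryPair()
      for (p in symmetric)
        expect_identical(spatialPredicate(p, pr$a, pr$b, cfg),
                         spatialPredicate(p, pr$b, pr$a, cfg))
      expect_identical(
        spatialPredicate("spatialInside", pr$a, pr$b, cfg),
        spatialPredicate("spatialContains", pr$b, pr$a, cfg))
      expect_identical(
        spatialPredicate("spatialCoveredBy", pr$a, pr$b, cfg),
        spatialPredicate("spatialCovers", pr$b, pr$a, cfg))
    }
  })
})

test_that("the circle shortcut agrees with the grid oracle", {
  withr::with_seed(303, {
    for (i in 1:40) {
      a <- circleGeom(stats::runif(2, 0.3, 0.7), stats::runif(1, 0.08, 0.3))
      b <- circleGeom(stats::runif(2, 0.3, 0.7), stats::runif(1, 0.08, 0.3))
      expect_identical(stateFlags(intersectionState(a, b, cfg)),
                       stateFlags(gridIntersectionState(a, b, cfg)))
    }
  })
})

test_that("halving the resolution preserves flags of fat regions", {
  fine <- spatialConfig(0.005, 0.02)
  pairs <- list(
    list(circleGeom(c(0.4, 0.5), 0.2), circleGeom(c(0.6, 0.5), 0.2)),
    list(circleGeom(c(0.5, 0.5), 0.1), circleGeom(c(0.5, 0.5), 0.3)),
    list(circleGeom(c(0.3, 0.3), 0.1), circleGeom(c(0.7, 0.7), 0.1)))
  for (pr in pairs) {
    expect_identical(stateFlags(intersectionState(pr[[1]], pr[[2]], cfg)),
                     stateFlags(intersectionState(pr[[1]], pr[[2]], fine)))
  }
})

test_that("surround holds for a mesh around a circle and fails otherwise", {
  ring <- lapply(seq(0, 2 * pi, length.out = 9)[-9], function(t) {
    circleGeom(c(0.5, 0.5) + 0.3 * c(cos(t), sin(t)), 0.07)
  })
  inner <- circleGeom(c(0.5, 0.5), 0.08)
  expect_true(spatialSurrounds(ring, inner, cfg))
  outside <- circleGeom(c(0.05, 0.05), 0.04)
  expect_false(spatialSurrounds(ring, outside, cfg))
  # a disk cannot surround what overlaps its interior
  expect_false(spatialSurrounds(circleGeom(c(0.5, 0.5), 0.3), inner, cfg))
})

test_that("strict mode uses standard point-set definitions", {
  strict <- spatialConfig(0.01, 0.02, strict = TRUE)
  # proper overlap without boundary crossing subtleties
  expect_true(spatialPredicate("spatialOverlap", circleGeom(c(0, 0), 1),
                               circleGeom(c(1, 0), 1), strict))
  expect_true(spatialPredicate("spatialInside", circleGeom(c(0.5, 0), 1),
                               circleGeom(c(0, 0), 3), strict))
  expect_false(spatialPredicate("spatialOverlap", circleGeom(c(0.5, 0), 1),
                                circleGeom(c(0, 0), 3), strict))
})

test_that("polygon geometries must be simple", {
  bow <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(polygonGeom(bow))
  expect_s4_class(polygonGeom(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))),
                  "PolygonGeom")
})
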