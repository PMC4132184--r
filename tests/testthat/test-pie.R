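test_that("reference degrees are full-network degrees, not induced ones", {
  refn <- net(c("A", "B"), c("B", "C"), c("A", "C"), c("C", "D"))
  expect_equal(unname(degreesInReference(c("A", "C"), refn)), c(2L, 3L))
  expect_equal(unname(degreesInReference("D", refn)), 1L)
  iso <- referenceNetwork(data.frame(a = "A", b = "B"),
                          nodes = c("x", "y"))
  expect_equal(unname(degreesInReference(c("x", "y"), iso)), c(0L, 0L))
  ## star K1,5 hub
  star <- net(c("h", "l1"), c("h", "l2"), c("h", "l3"), c("h", "l4"),
              c("h", "l5"))
  expect_equal(unname(degreesInReference("h", star)), 5L)
  expect_error(degreesInReference("nope", refn), "absent")
})

test_that("induced edge counts match closed forms and the all-pairs oracle", {
  k4 <- net(c("a", "b"), c("a", "c"), c("a", "d"), c("b", "c"),
            c("b", "d"), c("c", "d"))
  expect_equal(countInducedEdges(k4, c("a", "b", "c")), 3L)  # C(3,2)
  expect_equal(countInducedEdges(k4, "a"), 0L)
  for (s in 1:10) {
    refn <- makeReference(nNodes = 10, nEdges = 18, seed = s)
    sub <- sample(networkNodes(refn), 4)
    expect_equal(countInducedEdges(refn, sub),
                 bruteInducedEdges(refn, sub))
  }
})

test_that("degree-matched draws honour the contract on every draw and select uniformly within classes", {
  refn <- twoTriangleFixture()
  target <- degreesInReference(c("n01", "n02", "n07"), refn)
  set.seed(99)
  nDraw <- 10000L
  appear <- integer(12)
  names(appear) <- networkNodes(refn)
  deg0 <- nodeDegrees(refn)
  want <- sort(unname(target))
  violations <- 0L
  for (i in seq_len(nDraw)) {
    s <- sampleDegreeMatched(refn, target)
    ## contract, asserted per draw: 3 distinct nodes, degree multiset equal
    if (length(s) != 3L || anyDuplicated(s) ||
        !identical(sort(unname(deg0[s])), want))
      violations <- violations + 1L
    appear[s] <- appear[s] + 1L
  }
  expect_identical(violations, 0L)
  deg <- nodeDegrees(refn)
  ## each degree-2 node appears with prob 2/6, degree-1 with 1/6
  for (nd in names(appear)) {
    p <- if (deg[nd] == 2) 2 / 6 else 1 / 6
    se <- sqrt(nDraw * p * (1 - p))
    expect_lt(abs(appear[nd] - nDraw * p), 3 * se + 1e-9)
  }
})

test_that("thin exact degree classes fall back to binned matching with a warning", {
  ## hub degree 5 is unique -> exact matching impossible for it
  star <- net(c("h", "l1"), c("h", "l2"), c("h", "l3"), c("h", "l4"),
              c("h", "l5"), c("l1", "l2"))
  expect_warning(s <- sampleDegreeMatched(star, c(5L, 1L)),
                 "falling back to binned")
  expect_length(s, 2L)
  ## structurally infeasible request errors with the deficient bin named
  expect_error(
    sampleDegreeMatched(star, c(5L, 5L),
                        degreeMatchPolicy(mode = "binned")),
    "degree bin")
})

test_that("pie analysis is bit-reproducible under a fixed seed", {
  refn <- makeReference(nNodes = 80, nEdges = 160, seed = 11)
  sub <- networkNodes(refn)[1:9]
  r1 <- pieAnalysis(refn, sub, nRand = 400, seed = 123)
  r2 <- pieAnalysis(refn, sub, nRand = 400, seed = 123)
  expect_identical(nullEdgeCounts(r1), nullEdgeCounts(r2))
  expect_identical(pieScore(r1), pieScore(r2))
  expect_identical(empiricalP(r1), empiricalP(r2))
})

test_that("empirical p respects the add-one floor and (0,1] range", {
  refn <- makeReference(nNodes = 100, nEdges = 150, seed = 5)
  for (k in c(3, 6, 10)) {
    sub <- sample(networkNodes(refn), k)
    r <- pieAnalysis(refn, sub, nRand = 200, seed = k)
    expect_gt(empiricalP(r), 0)
    expect_lte(empiricalP(r), 1)
    expect_gte(empiricalP(r), 1 / 201)
  }
})

test_that("undefined score is flagged when the null mean is zero", {
  ## two far-apart edges plus many isolated nodes: a degree-0 query set
  refn <- referenceNetwork(data.frame(a = c("a", "c"), b = c("b", "d")),
                           nodes = sprintf("i%02d", 1:10))
  r <- pieAnalysis(refn, c("i01", "i02"), nRand = 50, seed = 1)
  expect_identical(observedEdges(r), 0L)
  expect_true(is.na(pieScore(r)))
  expect_identical(empiricalP(r), 1)
})

test_that("null histogram export tabulates the draw distribution", {
  refn <- twoTriangleFixture()
  r <- pieAnalysis(refn, c("n01", "n02", "n03"), nRand = 300, seed = 4)
  f <- tempfile()
  writePieHistogram(r, f)
  h <- read.delim(f)
  expect_equal(sum(h$count), 300L)
  expect_equal(sum(h$edges * h$count) / 300, r@nullMean)
})
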