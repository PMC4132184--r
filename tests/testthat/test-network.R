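test_that("seed graph is the exact induced subgraph and unknown seeds drop with a warning", {
  refn <- net(c("A", "B"), c("B", "D"))
  sg <- buildSeedGraph(c("A", "B", "D"), refn)
  expect_equal(nrow(networkEdges(sg)), 2L)

  sg2 <- buildSeedGraph(c("A", "B"), refn)
  e <- networkEdges(sg2)
  expect_equal(paste(e$a, e$b), "A B")

  expect_warning(sg3 <- buildSeedGraph(c("A", "B", "ZZZ"), refn), "absent")
  expect_equal(droppedSeeds(sg3), "ZZZ")
  expect_error(buildSeedGraph(character(0), refn), "empty seed")
  expect_error(suppressWarnings(buildSeedGraph("ZZZ", refn)), "no seed")

  ## seeds with no mutual edges: zero edges, all isolated
  sg4 <- buildSeedGraph(c("A", "D"), refn)
  expect_equal(numEdges(sg4), 0L)
})

test_that("parsimony expansion admits neighbours at the seed-link threshold only", {
  refn <- net(c("E", "A"), c("E", "B"), c("F", "A"), c("A", "B"))
  en <- expandParsimony(buildSeedGraph(c("A", "B"), refn), refn, minLinks = 2)
  expect_equal(addedNodes(en), "E")   # two seed links
  expect_false("F" %in% addedNodes(en))  # only one seed link
  prov <- nodeProvenance(en)
  expect_equal(prov$seed_links[prov$node == "E"], 2L)
  ## induced edges include seed-seed and seed-added
  expect_equal(numEdges(en), 3L)
})

test_that("expansion is single-pass: added nodes never qualify further nodes", {
  ## chain where v qualifies from seeds and w only via v
  refn <- net(c("s1", "v"), c("s2", "v"), c("v", "w"), c("s1", "w"),
              nodes = "s3")
  en <- expandParsimony(buildSeedGraph(c("s1", "s2", "s3"), refn), refn, 2)
  expect_equal(addedNodes(en), "v")
  expect_false("w" %in% addedNodes(en))  # w has 1 seed link + 1 added link

  ## matches the single-pass oracle on random fixtures; the iterated
  ## (cascading) variant is a superset whenever they differ
  for (s in 1:15) {
    refn <- makeReference(nNodes = 60, nEdges = 120, seed = s)
    seeds <- networkNodes(refn)[1:8]
    en <- expandParsimony(buildSeedGraph(seeds, refn), refn, 2)
    sp <- singlePassExpansion(refn, sort(seeds), 2)
    it <- iteratedExpansion(refn, sort(seeds), 2)
    expect_equal(addedNodes(en), sp)
    expect_true(all(sp %in% it))
  }
})

test_that("added set shrinks in minLinks; minLinks=1 is the full first-order neighbourhood", {
  for (s in 1:10) {
    refn <- makeReference(nNodes = 50, nEdges = 100, seed = s)
    seeds <- networkNodes(refn)[1:6]
    sg <- buildSeedGraph(seeds, refn)
    a1 <- addedNodes(expandParsimony(sg, refn, 1))
    a2 <- addedNodes(expandParsimony(sg, refn, 2))
    a3 <- addedNodes(expandParsimony(sg, refn, 3))
    expect_true(all(a3 %in% a2) && all(a2 %in% a1))
    e <- networkEdges(refn)
    nbr <- setdiff(unique(c(e$b[e$a %in% seeds], e$a[e$b %in% seeds])), seeds)
    expect_setequal(a1, nbr)
  }
  expect_error(expandParsimony(buildSeedGraph("A", net(c("A", "B"))),
                               net(c("A", "B")), 0), ">= 1")
})

test_that("node-role export reports both edge tallies for the twenty-edge ambiguity", {
  refn <- net(c("s1", "s2"), c("s1", "v"), c("s2", "v"), c("v", "w"),
              c("s1", "w"), c("s2", "w"))
  en <- expandParsimony(buildSeedGraph(c("s1", "s2"), refn), refn, 2)
  ep <- tempfile(); rp <- tempfile()
  writeExtendedNetwork(en, ep, rp)
  hdr <- readLines(rp, n = 1)
  expect_match(hdr, "edges_total=6")
  expect_match(hdr, "edges_seed_seed=1")
  expect_match(hdr, "edges_touching_added=5")
  roles <- read.delim(rp, comment.char = "#")
  expect_setequal(roles$node[roles$role == "added"], c("v", "w"))
})
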