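## Independent oracles and fixture builders shared across the suite.
## Every oracle here is written against first principles (set algebra,
## all-pairs scans, full enumeration) and never calls the code path it
## checks.

## quick network builder from a two-column matrix/vector of endpoint pairs
net <- function(..., nodes = character(0)) {
  pairs <- list(...)
  if (length(pairs) == 1L && is.data.frame(pairs[[1]])) {
    df <- pairs[[1]]
  } else {
    m <- do.call(rbind, pairs)
    df <- data.frame(a = m[, 1], b = m[, 2], stringsAsFactors = FALSE)
  }
  referenceNetwork(df, nodes = nodes)
}

## 12-node fixture: two triangles plus three disjoint degree-1 pairs;
## degree classes of size 6 (degree 2) and 6 (degree 1)
twoTriangleFixture <- function() {
  net(c("n01", "n02"), c("n02", "n03"), c("n01", "n03"),
      c("n04", "n05"), c("n05", "n06"), c("n04", "n06"),
      c("n07", "n08"), c("n09", "n10"), c("n11", "n12"))
}

## all-pairs brute force for induced edge counting
bruteInducedEdges <- function(network, nodeSet) {
  e <- networkEdges(network)
  cnt <- 0L
  for (k in seq_len(nrow(e)))
    if (e$a[k] %in% nodeSet && e$b[k] %in% nodeSet) cnt <- cnt + 1L
  cnt
}

## exhaustive enumeration of ALL exactly-degree-matched node sets and
## their induced edge counts (small references only)
exhaustNullCounts <- function(network, nodeSet) {
  deg <- nodeDegrees(network)
  target <- deg[nodeSet]
  tt <- table(target)
  classes <- lapply(names(tt), function(d)
    names(deg)[deg == as.integer(d)])
  ks <- as.integer(tt)
  combosPerClass <- lapply(seq_along(classes), function(i)
    utils::combn(classes[[i]], ks[i], simplify = FALSE))
  grid <- expand.grid(lapply(combosPerClass, seq_along))
  vapply(seq_len(nrow(grid)), function(r) {
    set <- unlist(lapply(seq_along(combosPerClass), function(i)
      combosPerClass[[i]][[grid[r, i]]]))
    bruteInducedEdges(network, set)
  }, 0L)
}

## brute-force two-sided Fisher p: full hypergeometric enumeration over
## the support, summing probabilities <= observed (with the customary
## relative tolerance for ties)
bruteFisherP <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(ks, r1, r2, c1)
  pObs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

## set-algebra oracle for candidate filtering
setAlgebraFilter <- function(baitSets, controlSets, minReplicates,
                             blocklists = list()) {
  all <- unique(unlist(baitSets))
  reps <- vapply(all, function(p)
    sum(vapply(baitSets, function(s) p %in% s, TRUE)), 0L)
  inCtrl <- vapply(all, function(p)
    any(vapply(controlSets, function(s) p %in% s, TRUE)), TRUE)
  if (!length(controlSets)) inCtrl <- rep(FALSE, length(all))
  inBlock <- vapply(all, function(p)
    any(vapply(blocklists, function(s) p %in% s, TRUE)), TRUE)
  if (!length(blocklists)) inBlock <- rep(FALSE, length(all))
  sort(all[reps >= minReplicates & !inCtrl & !inBlock])
}

## hit tables from plain protein sets, one replicate each
hitsFromSets <- function(sets, condition, peptides = 5L) {
  lapply(seq_along(sets), function(i) {
    prot <- sets[[i]]
    hitTable(data.frame(
      protein = prot,
      unique_peptides = rep(peptides, length(prot)),
      replicate = sprintf("%s%d", substr(condition, 1, 1), i),
      condition = rep(condition, length(prot)),
      stringsAsFactors = FALSE))
  })
}

## single-pass parsimony oracle: neighbours of the seed set with >=
## minLinks seed links, computed naively from the edge table
singlePassExpansion <- function(reference, seeds, minLinks) {
  e <- networkEdges(reference)
  others <- setdiff(networkNodes(reference), seeds)
  links <- vapply(others, function(v)
    sum((e$a == v & e$b %in% seeds) | (e$b == v & e$a %in% seeds)), 0L)
  sort(others[links >= minLinks])
}

## iterated (cascading) variant: keep admitting nodes against the growing
## member set until a fixed point -- deliberately NOT the implemented rule
iteratedExpansion <- function(reference, seeds, minLinks) {
  members <- seeds
  repeat {
    extra <- singlePassExpansion(reference, members, minLinks)
    extra <- setdiff(extra, members)
    if (!length(extra)) break
    members <- union(members, extra)
  }
  sort(setdiff(members, seeds))
}

## does any legal planting swap remain? (a,x),(b,y) -> (a,b),(x,y) with
## a,b nonadjacent members, x,y distinct nonadjacent non-members
legalSwapExists <- function(network, members) {
  e <- networkEdges(network)
  key <- paste(pmin(e$a, e$b), pmax(e$a, e$b))
  hasEdge <- function(i, j) paste(min(i, j), max(i, j)) %in% key
  nbrs <- function(v) c(e$b[e$a == v], e$a[e$b == v])
  for (a in members) {
    xs <- setdiff(nbrs(a), members)
    if (!length(xs)) next
    for (b in setdiff(members, a)) {
      if (hasEdge(a, b)) next
      ys <- setdiff(nbrs(b), members)
      for (x in xs) for (y in setdiff(ys, x))
        if (!hasEdge(x, y)) return(TRUE)
    }
  }
  FALSE
}

tmpTsv <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

screenFixturePath <- function() {
  system.file("extdata", "dtc_screen_percent.tsv",
              package = "cohesionScreen")
}
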