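## Synthetic-data generators: reference interactomes (uniform or exact
## degree sequence), planted cohesive modules via degree-preserving edge
## swaps, simulated TAP-MS hit tables, and multinomial phenotype screens.
## All generators are bit-reproducible under a fixed seed.

#' Erdos-Gallai feasibility of a degree sequence
#'
#' @param degrees non-negative integer vector.
#' @return TRUE when a simple undirected graph with this degree sequence
#'   exists.
#' @export
erdosGallaiFeasible <- function(degrees) {
  d <- sort(as.integer(degrees), decreasing = TRUE)
  if (any(d < 0) || sum(d) %% 2L != 0L) return(FALSE)
  if (!length(d) || d[1] == 0L) return(TRUE)
  if (d[1] > length(d) - 1L) return(FALSE)
  cs <- cumsum(d)
  for (k in seq_along(d)) {
    rhs <- k * (k - 1) + sum(pmin(d[-seq_len(k)], k))
    if (cs[k] > rhs) return(FALSE)
  }
  TRUE
}

## configuration-model pairing with rejection until the realization is
## simple (no self-loops, no multi-edges)
.configModel <- function(degrees, attemptLimit = 1000L) {
  stubs <- rep(seq_along(degrees), degrees)
  if (!length(stubs)) return(cbind(integer(0), integer(0)))
  for (attempt in seq_len(attemptLimit)) {
    p <- sample(stubs)
    a <- p[seq(1, length(p), by = 2)]
    b <- p[seq(2, length(p), by = 2)]
    lo <- pmin(a, b); hi <- pmax(a, b)
    if (all(lo != hi) && !anyDuplicated(lo * (length(degrees) + 1) + hi))
      return(cbind(lo, hi))
  }
  stop("configuration model: no simple realization found in ",
       attemptLimit, " attempts")
}

#' Generate a synthetic reference interactome
#'
#' Either a uniform random simple graph with \code{nEdges} edges on
#' \code{nNodes} nodes, or — when \code{degreeSequence} is supplied — a
#' graph realizing that degree sequence exactly, via configuration-model
#' stub pairing with rejection of self-loops and multi-edges. The default
#' desk scale (2,000 nodes, 2,800 edges) keeps the edge-to-node sparsity
#' of genome-scale interactomes (roughly 1.4 interactions per
#' protein-coding gene) so permutation-null edge counts behave
#' comparably to the full-scale setting.
#'
#' @param nNodes,nEdges size of the uniform random graph (ignored when a
#'   degree sequence is given).
#' @param degreeSequence optional non-negative integer vector; its sum
#'   must be even and Erdos-Gallai feasible.
#' @param seed integer seed, or \code{NULL}.
#' @param attemptLimit rejection limit for the configuration model.
#' @return A [ReferenceNetwork-class] with nodes named \code{g0001, ...}.
#' @export
makeReference <- function(nNodes = 2000L, nEdges = 2800L,
                          degreeSequence = NULL, seed = NULL,
                          attemptLimit = 1000L) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (!is.null(degreeSequence)) {
    degreeSequence <- as.integer(degreeSequence)
    if (!erdosGallaiFeasible(degreeSequence))
      stop("degree sequence is not realizable as a simple graph")
    nNodes <- length(degreeSequence)
    em <- .configModel(degreeSequence, attemptLimit)
  } else {
    nNodes <- as.integer(nNodes)
    nEdges <- as.integer(nEdges)
    if (nEdges > choose(nNodes, 2))
      stop("nEdges exceeds the number of possible pairs")
    g <- igraph::sample_gnm(nNodes, nEdges)
    em <- igraph::as_edgelist(g, names = FALSE)
    if (nEdges > 0L) {
      lo <- pmin(em[, 1], em[, 2]); hi <- pmax(em[, 1], em[, 2])
      em <- cbind(lo, hi)
    }
  }
  width <- max(4L, nchar(as.character(nNodes)))
  ids <- sprintf("g%0*d", width, seq_len(nNodes))
  edges <- if (nrow(em)) data.frame(a = ids[em[, 1]], b = ids[em[, 2]],
                                    evidence = "known",
                                    source = "synthetic",
                                    stringsAsFactors = FALSE)
           else NULL
  referenceNetwork(edges, nodes = ids)
}

## adjacency list (integer indices) from an index view
.adjList <- function(idx) {
  adj <- vector("list", idx$n)
  for (i in seq_len(idx$n)) adj[[i]] <- integer(0)
  if (length(idx$ia)) {
    adj <- lapply(split(c(idx$ib, idx$ia), c(idx$ia, idx$ib)), as.integer)
    out <- vector("list", idx$n)
    for (i in seq_len(idx$n)) out[[i]] <- integer(0)
    out[as.integer(names(adj))] <- adj
    adj <- out
  }
  adj
}

#' Select members for a planted cohesive module
#'
#' Snowball (breadth-like) sampling: a start node is drawn with
#' probability proportional to its degree, then nodes are added one at a
#' time uniformly from the current neighbourhood frontier until
#' \code{size} members are collected (jumping to a fresh degree-biased
#' start if a component is exhausted). The resulting member set is a
#' connected, hub-enriched subgraph — the topology functional modules
#' (protein complexes) actually have in curated interactomes, as opposed
#' to a uniform random node set, which in a sparse genome-scale network
#' is almost surely edgeless.
#'
#' @param network a [ReferenceNetwork-class].
#' @param size number of members.
#' @param seed integer seed, or \code{NULL}.
#' @return Character vector of member node ids.
#' @export
selectModuleMembers <- function(network, size, seed = NULL) {
  stopifnot(is(network, "ReferenceNetwork"))
  size <- as.integer(size)
  if (!is.null(seed)) set.seed(as.integer(seed))
  idx <- .netIndex(network)
  if (size < 1L || size > idx$n) stop("invalid module size")
  adj <- .adjList(idx)
  deg <- idx$deg
  selected <- integer(0)
  inSet <- logical(idx$n)
  frontier <- integer(0)
  while (length(selected) < size) {
    if (!length(frontier)) {
      cand <- which(!inSet & deg > 0)
      if (!length(cand)) cand <- which(!inSet)
      if (!length(cand)) stop("not enough nodes to fill the module")
      nxt <- cand[sample.int(length(cand), 1,
                             prob = pmax(deg[cand], 0.5))]
    } else {
      nxt <- frontier[sample.int(length(frontier), 1)]
    }
    selected <- c(selected, nxt)
    inSet[nxt] <- TRUE
    frontier <- setdiff(unique(c(frontier, adj[[nxt]])), selected)
  }
  idx$nodes[sort(selected)]
}

#' Plant a cohesive module by degree-preserving edge swaps
#'
#' Densifies the induced subgraph on \code{members} without touching any
#' node's degree: repeated double-edge swaps
#' \eqn{(a,x), (b,y) \to (a,b), (x,y)} with \eqn{a, b} members and
#' \eqn{x, y} non-members, each moving exactly one edge inside the member
#' set, are applied until the induced member edge count reaches
#' \code{multiplier} times its initial value or no legal swap remains
#' (swaps creating self-loops or duplicate edges are never applied).
#' Degree preservation is what keeps the degree-matched permutation null
#' honest: a module planted by \emph{adding} edges would change member
#' degrees and contaminate the null.
#'
#' @param network a [ReferenceNetwork-class].
#' @param members character vector of at least 2 member node ids.
#' @param multiplier target induced-edge count as a multiple of the
#'   initial count (>= 1; 1 leaves the network unchanged).
#' @param seed integer seed, or \code{NULL}.
#' @return A [ReferenceNetwork-class] with identical degree multiset.
#' @export
plantCohesiveModule <- function(network, members, multiplier = 1,
                                seed = NULL) {
  stopifnot(is(network, "ReferenceNetwork"))
  if (multiplier < 1) stop("multiplier must be >= 1")
  members <- unique(as.character(members))
  if (length(members) < 2L) stop("member set must have at least 2 nodes")
  if (!is.null(seed)) set.seed(as.integer(seed))
  idx <- .netIndex(network)
  mpos <- match(members, idx$nodes)
  if (anyNA(mpos)) stop("member absent from network")
  isMember <- logical(idx$n)
  isMember[mpos] <- TRUE

  ea <- idx$ia; eb <- idx$ib
  ev <- networkEdges(network)$evidence
  src <- networkEdges(network)$source
  nbase <- idx$n + 1
  keyOf <- function(i, j) pmin(i, j) * nbase + pmax(i, j)
  keys <- new.env(hash = TRUE, parent = emptyenv())
  for (k in seq_along(ea)) assign(as.character(keyOf(ea[k], eb[k])), k,
                                  envir = keys)
  hasEdge <- function(i, j) !is.null(get0(as.character(keyOf(i, j)),
                                          envir = keys))
  adj <- .adjList(idx)

  inside <- sum(isMember[ea] & isMember[eb])
  target <- ceiling(multiplier * inside)

  dropEdge <- function(i, j) {
    k <- get(as.character(keyOf(i, j)), envir = keys)
    rm(list = as.character(keyOf(i, j)), envir = keys)
    adj[[i]] <<- setdiff(adj[[i]], j)
    adj[[j]] <<- setdiff(adj[[j]], i)
    k
  }
  addEdge <- function(i, j, k) {
    ea[k] <<- min(i, j); eb[k] <<- max(i, j)
    assign(as.character(keyOf(i, j)), k, envir = keys)
    adj[[i]] <<- c(adj[[i]], j)
    adj[[j]] <<- c(adj[[j]], i)
  }
  doSwap <- function(a, b, x, y) {
    k1 <- dropEdge(a, x)
    k2 <- dropEdge(b, y)
    addEdge(a, b, k1)
    addEdge(x, y, k2)
    inside <<- inside + 1L
  }
  legalPick <- function(a, b) {
    xs <- adj[[a]][!isMember[adj[[a]]]]
    ys <- adj[[b]][!isMember[adj[[b]]]]
    if (!length(xs) || !length(ys)) return(NULL)
    x <- xs[sample.int(length(xs), 1)]
    ycand <- ys[ys != x]
    if (!length(ycand)) return(NULL)
    y <- ycand[sample.int(length(ycand), 1)]
    if (hasEdge(x, y)) return(NULL)
    c(x, y)
  }

  while (inside < target) {
    found <- FALSE
    for (attempt in seq_len(200L)) {
      ab <- mpos[sample.int(length(mpos), 2)]
      if (hasEdge(ab[1], ab[2])) next
      xy <- legalPick(ab[1], ab[2])
      if (is.null(xy)) next
      doSwap(ab[1], ab[2], xy[1], xy[2])
      found <- TRUE
      break
    }
    if (!found) {
      ## deterministic exhaustive scan before concluding no swap exists
      for (ii in seq_along(mpos)) {
        a <- mpos[ii]
        xs <- adj[[a]][!isMember[adj[[a]]]]
        if (!length(xs)) next
        for (jj in seq_along(mpos)) {
          if (jj == ii) next
          b <- mpos[jj]
          if (hasEdge(a, b)) next
          ys <- adj[[b]][!isMember[adj[[b]]]]
          if (!length(ys)) next
          for (x in xs) {
            ycand <- ys[ys != x]
            ycand <- ycand[!vapply(ycand, function(y) hasEdge(x, y), TRUE)]
            if (length(ycand)) {
              doSwap(a, b, x, ycand[1])
              found <- TRUE
              break
            }
          }
          if (found) break
        }
        if (found) break
      }
      if (!found) break  # no legal swap exists; stop at what was achieved
    }
  }

  referenceNetwork(
    data.frame(a = idx$nodes[ea], b = idx$nodes[eb], evidence = ev,
               source = src, stringsAsFactors = FALSE),
    nodes = idx$nodes)
}

#' Generate a desk-scale reference with a planted cohesive module
#'
#' Convenience composition of [makeReference()], [selectModuleMembers()]
#' and [plantCohesiveModule()] under a single seed.
#'
#' @param nNodes,nEdges reference size (defaults: desk scale).
#' @param plantedSize module size (default 27, the size of an extended
#'   candidate-interactor network).
#' @param plantedMultiplier induced-edge multiplier for the planting
#'   swaps.
#' @param seed integer seed.
#' @return List with elements \code{network} (a
#'   [ReferenceNetwork-class]) and \code{members} (character).
#' @export
makePlantedReference <- function(nNodes = 2000L, nEdges = 2800L,
                                 plantedSize = 27L, plantedMultiplier = 3,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  net <- makeReference(nNodes, nEdges)
  members <- selectModuleMembers(net, plantedSize)
  list(network = plantCohesiveModule(net, members, plantedMultiplier),
       members = members)
}

#' Simulate TAP-MS bait and control hit tables
#'
#' Emulates a replicated tandem-affinity-purification design: every true
#' interactor appears in each bait replicate independently with
#' probability \code{pTrue} and never in the control; every background
#' protein appears in any run — bait replicate or control — independently
#' with probability \code{pBg}. Unique-peptide counts are drawn uniformly
#' from 1 to 30.
#'
#' @param trueSet character, the true interactors.
#' @param backgroundPool character, candidate contaminants; disjoint from
#'   \code{trueSet}.
#' @param pTrue,pBg detection probabilities in [0, 1].
#' @param nReps number of bait replicates (default 2).
#' @param seed integer seed, or \code{NULL}.
#' @return List with \code{bait} (list of \code{nReps}
#'   [HitTable-class]s) and \code{control} (one [HitTable-class], possibly
#'   empty).
#' @export
makeTapmsTables <- function(trueSet, backgroundPool, pTrue = 0.9,
                            pBg = 0.05, nReps = 2L, seed = NULL) {
  trueSet <- as.character(trueSet)
  backgroundPool <- as.character(backgroundPool)
  if (length(intersect(trueSet, backgroundPool)))
    stop("trueSet and backgroundPool must be disjoint")
  if (pTrue < 0 || pTrue > 1 || pBg < 0 || pBg > 1)
    stop("probabilities must lie in [0, 1]")
  nReps <- as.integer(nReps)
  if (!is.null(seed)) set.seed(as.integer(seed))
  oneRun <- function(replicate, condition) {
    prot <- character(0)
    if (condition == "bait" && length(trueSet))
      prot <- trueSet[stats::runif(length(trueSet)) < pTrue]
    if (length(backgroundPool))
      prot <- c(prot, backgroundPool[stats::runif(length(backgroundPool)) < pBg])
    hitTable(data.frame(
      protein = prot,
      unique_peptides = if (length(prot)) sample.int(30L, length(prot),
                                                     replace = TRUE)
                        else integer(0),
      replicate = rep(replicate, length(prot)),
      condition = rep(condition, length(prot)),
      stringsAsFactors = FALSE))
  }
  bait <- lapply(seq_len(nReps), function(r) oneRun(sprintf("rep%d", r),
                                                    "bait"))
  control <- oneRun("ctrl1", "control")
  list(bait = bait, control = control)
}

#' Simulate a categorical RNAi phenotype screen
#'
#' Control and non-hit treatments draw their five-category outcome counts
#' from a multinomial with \code{controlProbs}; hit treatments use
#' \code{hitProbs}. The defaults are the regime of a distal-tip-cell
#' migration screen: a control with 99\% normal gonad arms, and hits with
#' a severe overshoot-dominated defect spectrum.
#'
#' @param nTreatments number of screened treatments (default 20).
#' @param nHits number of true hits among them (default 9).
#' @param animalsPerTreatment gonad arms scored per treatment
#'   (default 100).
#' @param controlProbs,hitProbs probability vectors over the categories
#'   (normal, extra_turn, wandering, overshoot, other); must sum to 1.
#' @param seed integer seed, or \code{NULL}.
#' @return List with \code{counts} (phenotype count data.frame: a
#'   \code{"control"} row plus one row per treatment) and \code{hitIds}
#'   (character).
#' @export
makeScreen <- function(nTreatments = 20L, nHits = 9L,
                       animalsPerTreatment = 100L,
                       controlProbs = c(0.99, 0, 0.01, 0, 0),
                       hitProbs = c(0.25, 0.13, 0.11, 0.46, 0.05),
                       seed = NULL) {
  nTreatments <- as.integer(nTreatments)
  nHits <- as.integer(nHits)
  if (nHits > nTreatments) stop("nHits cannot exceed nTreatments")
  for (p in list(controlProbs, hitProbs))
    if (length(p) != 5L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("probability vectors must be length 5 and sum to 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  ids <- sprintf("t%02d", seq_len(nTreatments))
  hitIds <- if (nHits > 0L) sort(sample(ids, nHits)) else character(0)
  drawRow <- function(probs)
    as.integer(stats::rmultinom(1, animalsPerTreatment, probs))
  rows <- lapply(ids, function(id)
    drawRow(if (id %in% hitIds) hitProbs else controlProbs))
  ctrl <- drawRow(controlProbs)
  tab <- do.call(rbind, c(list(ctrl), rows))
  counts <- data.frame(treatment = c("control", ids), tab,
                       stringsAsFactors = FALSE)
  names(counts)[2:6] <- PHENOTYPE_CATEGORIES
  counts$n <- rowSums(tab)
  list(counts = validatePhenotypeCounts(counts), hitIds = hitIds)
}
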