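## Seed-graph construction and parsimony expansion.

.inducedEdges <- function(reference, nodes) {
  e <- networkEdges(reference)
  e[e$a %in% nodes & e$b %in% nodes, , drop = FALSE]
}

#' Build the induced subgraph on a set of seed proteins
#'
#' Extracts the reference edges whose both endpoints are seed proteins.
#' Seeds absent from the reference are dropped with a warning and recorded
#' in the result (interactome snapshots vary, so an unknown id is not
#' fatal); an empty surviving seed set is an error.
#'
#' @param seeds character vector of seed protein ids (e.g. the retained
#'   candidates of [filterCandidates()]).
#' @param reference a [ReferenceNetwork-class].
#' @return An [ExtendedNetwork-class] with an empty added-node set.
#' @export
buildSeedGraph <- function(seeds, reference) {
  stopifnot(is(reference, "ReferenceNetwork"))
  seeds <- unique(as.character(seeds))
  if (!length(seeds)) stop("empty seed set")
  known <- seeds %in% networkNodes(reference)
  dropped <- seeds[!known]
  if (length(dropped))
    warning(sprintf("%d seed(s) absent from reference, dropped: %s",
                    length(dropped),
                    paste(utils::head(dropped, 5), collapse = ", ")))
  seeds <- seeds[known]
  if (!length(seeds)) stop("no seed is present in the reference")
  e <- .inducedEdges(reference, seeds)
  new("ExtendedNetwork", seedNodes = sort(seeds),
      addedNodes = character(0), droppedSeeds = dropped,
      edges = e,
      provenance = data.frame(node = character(0), seed_links = integer(0),
                              stringsAsFactors = FALSE))
}

#' Expand a seed graph by the two-or-more-links parsimony rule
#'
#' Adds to the seed graph every reference node (outside the seed set) that
#' interacts with at least \code{minLinks} \emph{seed} proteins, then takes
#' the reference-induced subgraph on seeds plus added nodes. Qualification
#' is evaluated in a single pass against the original seed set only: an
#' added node never helps another node qualify, and edges among added
#' nodes, while present in the induced subgraph, do not count towards the
#' threshold. With \code{minLinks = 1} this is the full first-order
#' neighbourhood.
#'
#' @param seedGraph an [ExtendedNetwork-class] from [buildSeedGraph()].
#' @param reference the [ReferenceNetwork-class] the seed graph was built
#'   from.
#' @param minLinks minimum number of seed interactions a neighbour needs to
#'   be retained (default 2, the parsimony setting).
#' @return An [ExtendedNetwork-class]; \code{nodeProvenance()} gives each
#'   added node's seed-link count.
#' @examples
#' ref <- referenceNetwork(data.frame(a = c("s1", "s2", "s1"),
#'                                    b = c("v", "v", "w")))
#' net <- expandParsimony(buildSeedGraph(c("s1", "s2"), ref), ref)
#' addedNodes(net)  # "v" (two seed links); "w" has only one
#' @export
expandParsimony <- function(seedGraph, reference, minLinks = 2L) {
  stopifnot(is(seedGraph, "ExtendedNetwork"),
            is(reference, "ReferenceNetwork"))
  minLinks <- as.integer(minLinks)
  if (minLinks < 1L) stop("minLinks must be >= 1")
  seeds <- seedNodes(seedGraph)
  e <- networkEdges(reference)
  aSeed <- e$a %in% seeds
  bSeed <- e$b %in% seeds
  ## edges with exactly one endpoint in the seed set; tally the other end
  outA <- e$b[aSeed & !bSeed]
  outB <- e$a[bSeed & !aSeed]
  linkCounts <- table(c(outA, outB))
  added <- sort(names(linkCounts)[linkCounts >= minLinks])
  keep <- union(seeds, added)
  new("ExtendedNetwork", seedNodes = seeds, addedNodes = added,
      droppedSeeds = droppedSeeds(seedGraph),
      edges = .inducedEdges(reference, keep),
      provenance = data.frame(
        node = added,
        seed_links = as.integer(linkCounts[added]),
        stringsAsFactors = FALSE))
}

#' Write an extended network as edge-list plus node-role tables
#'
#' Writes the induced edges as a 3-column TSV and a node-role table with
#' one row per member node: role (\code{seed}/\code{added}), seed-link
#' count for added nodes, and the two edge tallies whose distinction
#' matters when counting what an expansion "added" — edges incident to
#' added nodes versus all induced edges beyond the seed-only subgraph.
#'
#' @param net an [ExtendedNetwork-class].
#' @param edgePath,rolePath output TSV paths.
#' @return \code{edgePath}, invisibly.
#' @export
writeExtendedNetwork <- function(net, edgePath, rolePath) {
  stopifnot(is(net, "ExtendedNetwork"))
  e <- networkEdges(net)
  utils::write.table(e[c("a", "b", "evidence")], edgePath, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE,
                     fileEncoding = "UTF-8")
  prov <- nodeProvenance(net)
  roles <- data.frame(
    node = c(seedNodes(net), addedNodes(net)),
    role = c(rep("seed", length(seedNodes(net))),
             rep("added", length(addedNodes(net)))),
    seed_links = c(rep(NA_integer_, length(seedNodes(net))),
                   prov$seed_links[match(addedNodes(net), prov$node)]),
    stringsAsFactors = FALSE)
  touchAdded <- e$a %in% addedNodes(net) | e$b %in% addedNodes(net)
  seedOnly <- sum(e$a %in% seedNodes(net) & e$b %in% seedNodes(net))
  attrLine <- sprintf(
    "# edges_total=%d edges_seed_seed=%d edges_touching_added=%d",
    nrow(e), seedOnly, sum(touchAdded))
  con <- file(rolePath, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(attrLine, con)
  utils::write.table(roles, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(edgePath)
}
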