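#' @import methods
NULL

EVIDENCE_LEVELS <- c("known", "predicted")

## canonical unordered-pair key; edges are stored with a <= b lexicographically
.pairKey <- function(a, b) {
  swap <- a > b
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  paste(lo, hi, sep = "\r")
}

.checkGeneIds <- function(ids, what = "gene identifier") {
  ids <- as.character(ids)
  bad <- is.na(ids) | !nzchar(ids) | grepl("[[:space:]]", ids)
  if (any(bad)) {
    return(sprintf("invalid %s(s): %s", what,
                   paste(utils::head(ids[bad], 5), collapse = ", ")))
  }
  NULL
}

#' ReferenceNetwork: an undirected simple interactome
#'
#' Container for a reference protein-protein interaction network: a set of
#' gene/protein identifiers (nodes) and a set of unordered, evidence-typed
#' interaction edges. The graph is simple by construction: self-interactions
#' and duplicate unordered pairs are rejected by the validity method. Nodes
#' with no interactions (degree zero) are first-class citizens, because the
#' degree-matched permutation null must be able to sample from all
#' protein-coding genes, most of which have no catalogued interaction.
#'
#' @slot nodes character vector of unique gene identifiers.
#' @slot edges data.frame with columns \code{a}, \code{b} (endpoints,
#'   stored with \code{a <= b}), \code{evidence} (\code{"known"} or
#'   \code{"predicted"}) and \code{source} (free-text provenance tag).
#'
#' @seealso [referenceNetwork()] for the user-facing constructor,
#'   [readEdgeList()] to parse one from disk.
#' @export
setClass("ReferenceNetwork",
  representation(nodes = "character", edges = "data.frame"),
  prototype(nodes = character(0),
            edges = data.frame(a = character(0), b = character(0),
                               evidence = character(0), source = character(0),
                               stringsAsFactors = FALSE)))

setValidity("ReferenceNetwork", function(object) {
  e <- object@edges
  need <- c("a", "b", "evidence", "source")
  if (!all(need %in% names(e)))
    return(sprintf("edges must have columns %s", paste(need, collapse = ", ")))
  msg <- .checkGeneIds(object@nodes, "node id")
  if (!is.null(msg)) return(msg)
  if (anyDuplicated(object@nodes)) return("duplicated node identifiers")
  if (nrow(e)) {
    if (any(e$a == e$b)) return("self-interactions are not allowed")
    if (!all(e$evidence %in% EVIDENCE_LEVELS))
      return("edge evidence must be 'known' or 'predicted'")
    if (!all(c(e$a, e$b) %in% object@nodes))
      return("edge endpoint not present in node set")
    if (any(e$a > e$b)) return("edges must be stored with a <= b")
    if (anyDuplicated(.pairKey(e$a, e$b)))
      return("duplicate unordered edge pair")
  }
  TRUE
})

#' Construct a ReferenceNetwork from an edge table
#'
#' Normalises the input: endpoints of each edge are put in lexicographic
#' order, duplicate unordered pairs are collapsed (evidence \code{"known"}
#' takes precedence over \code{"predicted"}), and self-loops raise an error
#' (use [readEdgeList()] if you want them dropped with a warning instead).
#'
#' @param edges data.frame with at least columns \code{a} and \code{b};
#'   optional \code{evidence} and \code{source} columns.
#' @param nodes optional character vector of node ids; the union of edge
#'   endpoints is always included, so this is the way to declare isolated
#'   (degree-zero) nodes.
#' @param defaultEvidence evidence assigned to edges lacking one.
#' @return A [ReferenceNetwork-class] object.
#' @examples
#' net <- referenceNetwork(data.frame(a = c("x", "y"), b = c("y", "z")),
#'                         nodes = "lonely")
#' numNodes(net)  # 4
#' numEdges(net)  # 2
#' @export
referenceNetwork <- function(edges = NULL, nodes = character(0),
                             defaultEvidence = c("known", "predicted")) {
  defaultEvidence <- match.arg(defaultEvidence)
  if (is.null(edges) || nrow(edges) == 0L) {
    e <- data.frame(a = character(0), b = character(0),
                    evidence = character(0), source = character(0),
                    stringsAsFactors = FALSE)
  } else {
    a <- as.character(edges$a)
    b <- as.character(edges$b)
    if (any(a == b)) stop("self-interaction in edge table")
    ev <- if ("evidence" %in% names(edges)) as.character(edges$evidence)
          else rep(defaultEvidence, length(a))
    src <- if ("source" %in% names(edges)) as.character(edges$source)
           else rep("", length(a))
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    key <- .pairKey(a, b)
    ## 'known' wins over 'predicted' on duplicate pairs
    ord <- order(key, match(ev, EVIDENCE_LEVELS))
    keep <- ord[!duplicated(key[ord])]
    keep <- sort(keep)
    e <- data.frame(a = a[keep], b = b[keep], evidence = ev[keep],
                    source = src[keep], stringsAsFactors = FALSE)
  }
  nodes <- sort(unique(c(as.character(nodes), e$a, e$b)))
  new("ReferenceNetwork", nodes = nodes, edges = e)
}

#' HitTable: protein identifications from one or more TAP-MS runs
#'
#' One row per identified protein per run: protein id, number of unique
#' peptides supporting the identification, replicate label and condition
#' (\code{"bait"} for tagged-bait purifications, \code{"control"} for the
#' untagged negative control). The (protein, replicate, condition) triple
#' must be unique.
#'
#' @slot hits data.frame with columns \code{protein}, \code{unique_peptides},
#'   \code{replicate}, \code{condition}.
#' @export
setClass("HitTable", representation(hits = "data.frame"),
  prototype(hits = data.frame(protein = character(0),
                              unique_peptides = integer(0),
                              replicate = character(0),
                              condition = character(0),
                              stringsAsFactors = FALSE)))

setValidity("HitTable", function(object) {
  h <- object@hits
  need <- c("protein", "unique_peptides", "replicate", "condition")
  if (!all(need %in% names(h)))
    return(sprintf("hit table needs columns %s", paste(need, collapse = ", ")))
  if (!nrow(h)) return(TRUE)
  msg <- .checkGeneIds(h$protein, "protein id")
  if (!is.null(msg)) return(msg)
  up <- h$unique_peptides
  if (any(is.na(up)) || any(up < 1) || any(up != as.integer(up)))
    return("unique_peptides must be integers >= 1")
  if (!all(h$condition %in% c("bait", "control")))
    return("condition must be 'bait' or 'control'")
  if (anyDuplicated(paste(h$protein, h$replicate, h$condition, sep = "\r")))
    return("duplicated (protein, replicate, condition) triple")
  TRUE
})

#' @rdname HitTable-class
#' @param hits data.frame of hit records (see slot description).
#' @return A [HitTable-class] object.
#' @export
hitTable <- function(hits) {
  hits <- as.data.frame(hits, stringsAsFactors = FALSE)
  if (nrow(hits)) {
    hits$protein <- as.character(hits$protein)
    hits$unique_peptides <- as.integer(hits$unique_peptides)
    hits$replicate <- as.character(hits$replicate)
    hits$condition <- as.character(hits$condition)
  }
  new("HitTable", hits = hits)
}

#' CandidateSet: the outcome of TAP-MS candidate filtering
#'
#' Retained high-confidence interactors plus a per-protein audit trail
#' recording, for every protein seen in any bait run, either
#' \code{"retained"} or the first filtering rule that removed it
#' (rule order: replicate reproducibility, then control subtraction, then
#' blocklists).
#'
#' @slot retained character vector of retained protein ids.
#' @slot audit data.frame with columns \code{protein}, \code{status},
#'   \code{n_replicates}, \code{max_unique_peptides}.
#' @export
setClass("CandidateSet",
  representation(retained = "character", audit = "data.frame"))

setValidity("CandidateSet", function(object) {
  a <- object@audit
  if (!all(c("protein", "status") %in% names(a)))
    return("audit needs 'protein' and 'status' columns")
  if (anyDuplicated(a$protein)) return("protein appears twice in audit")
  if (!setequal(object@retained, a$protein[a$status == "retained"]))
    return("retained set inconsistent with audit trail")
  TRUE
})

#' ExtendedNetwork: seed interactors plus parsimony-added neighbours
#'
#' The induced subgraph of a reference interactome on a set of seed
#' proteins, optionally extended by first-order neighbours connected to at
#' least \code{minLinks} seeds (see [expandParsimony()]). Seed and added
#' node sets are disjoint; \code{provenance} records, for each added node,
#' how many seed interactors it touches in the reference.
#'
#' @slot seedNodes character, the seed protein ids present in the reference.
#' @slot addedNodes character, neighbours added by the parsimony rule.
#' @slot droppedSeeds character, requested seeds absent from the reference.
#' @slot edges data.frame, reference edges induced on seed + added nodes.
#' @slot provenance data.frame with columns \code{node}, \code{seed_links}.
#' @export
setClass("ExtendedNetwork",
  representation(seedNodes = "character", addedNodes = "character",
                 droppedSeeds = "character", edges = "data.frame",
                 provenance = "data.frame"))

setValidity("ExtendedNetwork", function(object) {
  if (length(intersect(object@seedNodes, object@addedNodes)))
    return("seed and added node sets overlap")
  keep <- union(object@seedNodes, object@addedNodes)
  e <- object@edges
  if (nrow(e) && !all(c(e$a, e$b) %in% keep))
    return("induced edge with endpoint outside the network")
  p <- object@provenance
  if (!all(c("node", "seed_links") %in% names(p)))
    return("provenance needs 'node' and 'seed_links' columns")
  if (!setequal(p$node, object@addedNodes))
    return("provenance rows must match added nodes")
  TRUE
})

#' DegreeMatchPolicy: how the permutation null matches node degrees
#'
#' \code{"exact"} mode samples, for every degree represented in the query
#' set, the required number of nodes from the reference nodes of exactly
#' that degree. When some degree class is too thin to sample from (fewer
#' than two candidates), the sampler falls back to \code{"binned"} mode
#' with a warning: degrees are grouped into bins (default
#' 0, 1, 2, 3-4, 5-8, 9-16, 17+) and per-bin counts are matched instead.
#'
#' @slot mode \code{"exact"} or \code{"binned"}.
#' @slot binEdges numeric, ascending lower bounds of the degree bins
#'   (binned mode).
#' @slot maxAttempts integer, attempt limit for rejection steps.
#' @export
setClass("DegreeMatchPolicy",
  representation(mode = "character", binEdges = "numeric",
                 maxAttempts = "integer"))

setValidity("DegreeMatchPolicy", function(object) {
  if (!object@mode %in% c("exact", "binned"))
    return("mode must be 'exact' or 'binned'")
  be <- object@binEdges
  if (length(be) < 1L || is.unsorted(be, strictly = TRUE) || be[1] != 0)
    return("binEdges must be strictly ascending and start at 0")
  if (object@maxAttempts < 1L) return("maxAttempts must be >= 1")
  TRUE
})

#' @rdname DegreeMatchPolicy-class
#' @param mode matching granularity, \code{"exact"} (default) or
#'   \code{"binned"}.
#' @param binEdges ascending lower bounds of degree bins; the last bin is
#'   open-ended.
#' @param maxAttempts attempt limit for rejection sampling.
#' @return A [DegreeMatchPolicy-class] object.
#' @export
degreeMatchPolicy <- function(mode = c("exact", "binned"),
                              binEdges = c(0, 1, 2, 3, 5, 9, 17),
                              maxAttempts = 100L) {
  new("DegreeMatchPolicy", mode = match.arg(mode),
      binEdges = as.numeric(binEdges), maxAttempts = as.integer(maxAttempts))
}

#' PieResult: physical interaction enrichment of a node set
#'
#' Result of [pieAnalysis()]: the observed number of reference edges induced
#' by the query node set, the permutation null distribution of that count
#' over degree-matched random node sets, the PIE score (observed / null
#' mean) and the add-one empirical p-value
#' \eqn{(1 + \#\{null \ge observed\}) / (1 + n_{rand})}.
#'
#' @slot observedEdges integer, induced edge count of the query set.
#' @slot nullEdgeCounts integer vector of length \code{nRand}.
#' @slot nullMean,nullSd numeric summaries of the null distribution.
#' @slot pieScore numeric; \code{NA} (flagged undefined) when the null mean
#'   is zero.
#' @slot empiricalP numeric in \code{(0, 1]}.
#' @slot nRand integer, number of permutation draws.
#' @slot seed integer seed used (NA when none was supplied).
#' @slot policy the [DegreeMatchPolicy-class] requested.
#' @slot resolvedMode character, matching mode actually used after any
#'   exact-to-binned fallback.
#' @export
setClass("PieResult",
  representation(observedEdges = "integer", nullEdgeCounts = "integer",
                 nullMean = "numeric", nullSd = "numeric",
                 pieScore = "numeric", empiricalP = "numeric",
                 nRand = "integer", seed = "integer",
                 policy = "DegreeMatchPolicy", resolvedMode = "character"))

setValidity("PieResult", function(object) {
  if (length(object@nullEdgeCounts) != object@nRand)
    return("null distribution length disagrees with nRand")
  p <- object@empiricalP
  if (p <= 0 || p > 1) return("empirical p must lie in (0, 1]")
  if (p < 1 / (1 + object@nRand) - 1e-12)
    return("empirical p below the add-one estimator floor")
  TRUE
})

#' ScreenSummary: Fisher-exact scoring of an RNAi phenotype screen
#'
#' Per-treatment two-sided Fisher's exact tests of the proportion of normal
#' outcomes against the control, with significance tiers
#' (\code{"four_star"} for p < 0.0005, \code{"star"} for p < 0.05,
#' \code{"ns"} otherwise) and a Benjamini-Hochberg adjusted column for
#' modern use (the tiers themselves are per-comparison, uncorrected).
#'
#' @slot results data.frame, one row per scored treatment.
#' @slot nSignificant integer, significant treatments among the declared
#'   interactor ids (all scored treatments when no ids were declared).
#' @slot nSignificantOther integer, significant treatments outside the
#'   interactor id set.
#' @slot totalScreened integer, number of scored (non-arrested) treatments.
#' @slot interactorIds character, the declared interactor id set.
#' @export
setClass("ScreenSummary",
  representation(results = "data.frame", nSignificant = "integer",
                 nSignificantOther = "integer", totalScreened = "integer",
                 interactorIds = "character"))

setValidity("ScreenSummary", function(object) {
  r <- object@results
  need <- c("treatment", "p_two_sided", "tier")
  if (!all(need %in% names(r)))
    return(sprintf("results needs columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(r$treatment)) return("duplicated treatment id")
  TRUE
})
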