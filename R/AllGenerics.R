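#' Accessors for network containers
#'
#' @param x a [ReferenceNetwork-class] or [ExtendedNetwork-class] object.
#' @return \code{networkNodes} and \code{networkEdges} return the node
#'   character vector and the edge data.frame; \code{numNodes} and
#'   \code{numEdges} their lengths; \code{nodeDegrees} a named integer
#'   vector of degrees over all nodes (zero for isolated nodes).
#' @examples
#' net <- referenceNetwork(data.frame(a = "u", b = "v"))
#' nodeDegrees(net)
#' @name network-accessors
NULL

#' @rdname network-accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname network-accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname network-accessors
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))
#' @rdname network-accessors
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))
#' @rdname network-accessors
#' @export
setGeneric("nodeDegrees", function(x) standardGeneric("nodeDegrees"))

#' @rdname network-accessors
#' @export
setMethod("networkNodes", "ReferenceNetwork", function(x) x@nodes)
#' @rdname network-accessors
#' @export
setMethod("networkEdges", "ReferenceNetwork", function(x) x@edges)
#' @rdname network-accessors
#' @export
setMethod("numNodes", "ReferenceNetwork", function(x) length(x@nodes))
#' @rdname network-accessors
#' @export
setMethod("numEdges", "ReferenceNetwork", function(x) nrow(x@edges))
#' @rdname network-accessors
#' @export
setMethod("nodeDegrees", "ReferenceNetwork", function(x) {
  d <- integer(length(x@nodes))
  names(d) <- x@nodes
  if (nrow(x@edges)) {
    tab <- table(c(x@edges$a, x@edges$b))
    d[names(tab)] <- as.integer(tab)
  }
  d
})

#' Accessors for ExtendedNetwork
#'
#' @param x an [ExtendedNetwork-class] object.
#' @return \code{seedNodes} / \code{addedNodes} / \code{droppedSeeds} return
#'   the respective id vectors; \code{nodeProvenance} the per-added-node
#'   seed-link counts; \code{networkNodes} all member ids.
#' @name extended-accessors
NULL

#' @rdname extended-accessors
#' @export
setGeneric("seedNodes", function(x) standardGeneric("seedNodes"))
#' @rdname extended-accessors
#' @export
setGeneric("addedNodes", function(x) standardGeneric("addedNodes"))
#' @rdname extended-accessors
#' @export
setGeneric("droppedSeeds", function(x) standardGeneric("droppedSeeds"))
#' @rdname extended-accessors
#' @export
setGeneric("nodeProvenance", function(x) standardGeneric("nodeProvenance"))

#' @rdname extended-accessors
#' @export
setMethod("seedNodes", "ExtendedNetwork", function(x) x@seedNodes)
#' @rdname extended-accessors
#' @export
setMethod("addedNodes", "ExtendedNetwork", function(x) x@addedNodes)
#' @rdname extended-accessors
#' @export
setMethod("droppedSeeds", "ExtendedNetwork", function(x) x@droppedSeeds)
#' @rdname extended-accessors
#' @export
setMethod("nodeProvenance", "ExtendedNetwork", function(x) x@provenance)
#' @rdname extended-accessors
#' @export
setMethod("networkNodes", "ExtendedNetwork",
          function(x) union(x@seedNodes, x@addedNodes))
#' @rdname extended-accessors
#' @export
setMethod("networkEdges", "ExtendedNetwork", function(x) x@edges)
#' @rdname extended-accessors
#' @export
setMethod("numNodes", "ExtendedNetwork",
          function(x) length(x@seedNodes) + length(x@addedNodes))
#' @rdname extended-accessors
#' @export
setMethod("numEdges", "ExtendedNetwork", function(x) nrow(x@edges))

#' Accessors for HitTable and CandidateSet
#'
#' @param x a [HitTable-class] or [CandidateSet-class] object.
#' @return \code{hitRecords} returns the hit data.frame; \code{retained}
#'   the retained protein ids; \code{auditTrail} the per-protein filtering
#'   audit.
#' @name hit-accessors
NULL

#' @rdname hit-accessors
#' @export
setGeneric("hitRecords", function(x) standardGeneric("hitRecords"))
#' @rdname hit-accessors
#' @export
setGeneric("retained", function(x) standardGeneric("retained"))
#' @rdname hit-accessors
#' @export
setGeneric("auditTrail", function(x) standardGeneric("auditTrail"))

#' @rdname hit-accessors
#' @export
setMethod("hitRecords", "HitTable", function(x) x@hits)
#' @rdname hit-accessors
#' @export
setMethod("retained", "CandidateSet", function(x) x@retained)
#' @rdname hit-accessors
#' @export
setMethod("auditTrail", "CandidateSet", function(x) x@audit)

#' Accessors for PieResult
#'
#' @param x a [PieResult-class] object.
#' @return \code{pieScore} the PIE score (NA when the null mean is zero),
#'   \code{empiricalP} the add-one permutation p-value,
#'   \code{observedEdges} the induced edge count of the query set,
#'   \code{nullEdgeCounts} the integer null distribution.
#' @name pie-accessors
NULL

#' @rdname pie-accessors
#' @export
setGeneric("pieScore", function(x) standardGeneric("pieScore"))
#' @rdname pie-accessors
#' @export
setGeneric("empiricalP", function(x) standardGeneric("empiricalP"))
#' @rdname pie-accessors
#' @export
setGeneric("observedEdges", function(x) standardGeneric("observedEdges"))
#' @rdname pie-accessors
#' @export
setGeneric("nullEdgeCounts", function(x) standardGeneric("nullEdgeCounts"))

#' @rdname pie-accessors
#' @export
setMethod("pieScore", "PieResult", function(x) x@pieScore)
#' @rdname pie-accessors
#' @export
setMethod("empiricalP", "PieResult", function(x) x@empiricalP)
#' @rdname pie-accessors
#' @export
setMethod("observedEdges", "PieResult", function(x) x@observedEdges)
#' @rdname pie-accessors
#' @export
setMethod("nullEdgeCounts", "PieResult", function(x) x@nullEdgeCounts)

#' Accessors for ScreenSummary
#'
#' @param x a [ScreenSummary-class] object.
#' @return \code{screenResults} the per-treatment result table;
#'   \code{nSignificant} the number of significant treatments among the
#'   declared interactors.
#' @name screen-accessors
NULL

#' @rdname screen-accessors
#' @export
setGeneric("screenResults", function(x) standardGeneric("screenResults"))
#' @rdname screen-accessors
#' @export
setGeneric("nSignificant", function(x) standardGeneric("nSignificant"))

#' @rdname screen-accessors
#' @export
setMethod("screenResults", "ScreenSummary", function(x) x@results)
#' @rdname screen-accessors
#' @export
setMethod("nSignificant", "ScreenSummary", function(x) x@nSignificant)

setMethod("show", "ReferenceNetwork", function(object) {
  cat(sprintf("ReferenceNetwork: %d nodes, %d edges (%d known, %d predicted)\n",
              numNodes(object), numEdges(object),
              sum(object@edges$evidence == "known"),
              sum(object@edges$evidence == "predicted")))
})

setMethod("show", "ExtendedNetwork", function(object) {
  cat(sprintf(
    "ExtendedNetwork: %d seed + %d added nodes, %d induced edges\n",
    length(object@seedNodes), length(object@addedNodes), numEdges(object)))
  if (length(object@droppedSeeds))
    cat(sprintf("  (%d requested seeds absent from reference)\n",
                length(object@droppedSeeds)))
})

setMethod("show", "HitTable", function(object) {
  h <- object@hits
  cat(sprintf("HitTable: %d records, %d proteins, replicates: %s\n",
              nrow(h), length(unique(h$protein)),
              paste(unique(h$replicate), collapse = ", ")))
})

setMethod("show", "CandidateSet", function(object) {
  cat(sprintf("CandidateSet: %d retained of %d audited proteins\n",
              length(object@retained), nrow(object@audit)))
})

setMethod("show", "DegreeMatchPolicy", function(object) {
  cat(sprintf("DegreeMatchPolicy: mode=%s, bins=[%s], maxAttempts=%d\n",
              object@mode, paste(object@binEdges, collapse = ","),
              object@maxAttempts))
})

setMethod("show", "PieResult", function(object) {
  cat(sprintf(
    paste0("PieResult: observed=%d edges, null mean=%.2f (sd %.2f), ",
           "PIE=%s, p=%.4g [%d draws, %s matching]\n"),
    object@observedEdges, object@nullMean, object@nullSd,
    if (is.na(object@pieScore)) "undefined"
    else sprintf("%.3f", object@pieScore),
    object@empiricalP, object@nRand, object@resolvedMode))
})

setMethod("show", "ScreenSummary", function(object) {
  cat(sprintf(
    "ScreenSummary: %d scored treatments, %d significant interactors\n",
    object@totalScreened, object@nSignificant))
  if (length(object@interactorIds) && object@nSignificantOther > 0)
    cat(sprintf("  plus %d significant non-interactor treatments\n",
                object@nSignificantOther))
})
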