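#' Filter TAP-MS hits to high-confidence candidate interactors
#'
#' Reduces raw bait-purification identifications to a candidate interactor
#' set using three rules applied in fixed order:
#' \enumerate{
#'   \item \emph{replicate reproducibility} — the protein must appear in at
#'     least \code{minReplicates} distinct bait replicates;
#'   \item \emph{control subtraction} — any appearance in a negative-control
#'     run excludes the protein (the strictest reading of control
#'     filtering);
#'   \item \emph{blocklists} — membership in any supplied contaminant list
#'     (e.g. heat-shock proteins, organellar proteins) excludes it.
#' }
#' The audit trail records, per protein, \code{"retained"} or the first
#' failing rule. Unique-peptide counts are carried through for reporting
#' but are never a filter criterion.
#'
#' @param baitRuns a [HitTable-class] (with a replicate column
#'   distinguishing runs) or a list of them; all records must have
#'   condition \code{"bait"}.
#' @param controlRuns like \code{baitRuns} but for negative-control
#'   purifications (condition \code{"control"}); may be empty.
#' @param minReplicates minimum number of distinct bait replicates a
#'   protein must appear in (default 2, i.e. both of a two-replicate
#'   design).
#' @param blocklists named list of character vectors of protein ids to
#'   exclude (names identify the list in the audit trail).
#' @return A [CandidateSet-class].
#' @examples
#' bait <- hitTable(data.frame(
#'   protein = c("A", "B", "A", "C"), unique_peptides = c(5, 3, 8, 2),
#'   replicate = c("r1", "r1", "r2", "r2"), condition = "bait"))
#' retained(filterCandidates(bait))  # only "A" survives two replicates
#' @export
filterCandidates <- function(baitRuns, controlRuns = NULL,
                             minReplicates = 2L, blocklists = list()) {
  minReplicates <- as.integer(minReplicates)
  if (minReplicates < 1L) stop("minReplicates must be >= 1")
  bait <- .bindHits(baitRuns, "bait")
  if (!nrow(bait)) stop("no bait replicates supplied")
  ctrl <- if (is.null(controlRuns)) bait[0, ] else .bindHits(controlRuns, "control")
  if (length(blocklists)) {
    if (is.null(names(blocklists)) || any(!nzchar(names(blocklists))) ||
        anyDuplicated(names(blocklists)))
      stop("blocklists must be uniquely named")
  }

  nRep <- tapply(bait$replicate, bait$protein,
                 function(r) length(unique(r)))
  maxPep <- tapply(bait$unique_peptides, bait$protein, max)
  proteins <- sort(names(nRep))
  inControl <- proteins %in% ctrl$protein

  status <- rep("retained", length(proteins))
  failRep <- nRep[proteins] < minReplicates
  status[failRep] <- "replicate"
  still <- status == "retained"
  status[still & inControl] <- "control"
  for (bn in names(blocklists)) {
    still <- status == "retained"
    hit <- still & proteins %in% as.character(blocklists[[bn]])
    status[hit] <- paste0("blocklist:", bn)
  }

  audit <- data.frame(protein = proteins, status = status,
                      n_replicates = as.integer(nRep[proteins]),
                      max_unique_peptides = as.integer(maxPep[proteins]),
                      stringsAsFactors = FALSE)
  new("CandidateSet", retained = proteins[status == "retained"],
      audit = audit)
}

.bindHits <- function(runs, expectCondition) {
  if (is(runs, "HitTable")) runs <- list(runs)
  if (!is.list(runs) || !all(vapply(runs, is, TRUE, "HitTable")))
    stop("expected a HitTable or list of HitTables")
  df <- do.call(rbind, lapply(runs, hitRecords))
  if (is.null(df))
    df <- data.frame(protein = character(0), unique_peptides = integer(0),
                     replicate = character(0), condition = character(0),
                     stringsAsFactors = FALSE)
  if (nrow(df) && !all(df$condition == expectCondition))
    stop("all records must have condition '", expectCondition, "'")
  df
}

#' Write a candidate set with its audit trail
#'
#' @param candidates a [CandidateSet-class].
#' @param path output TSV file.
#' @return \code{path}, invisibly.
#' @export
writeCandidateSet <- function(candidates, path) {
  stopifnot(is(candidates, "CandidateSet"))
  utils::write.table(auditTrail(candidates), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
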