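## Tabular I/O: edge lists, hit tables, phenotype tables. All files are
## UTF-8 TSV; lines starting with '#' are comments.

.readTsvLines <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^[[:space:]]*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Read an undirected edge list
#'
#' Parses a 2-3 column TSV of interactions into a [ReferenceNetwork-class].
#' Column 1 and 2 are the endpoints; an optional column 3 gives the
#' evidence class (\code{known} or \code{predicted}; anything else is a
#' parse error). Self-loops are dropped with a warning; duplicate unordered
#' pairs are collapsed, \code{known} taking precedence over
#' \code{predicted}. Because a reference interactome must also carry the
#' genes with no catalogued interaction (the permutation null samples from
#' all of them), degree-zero nodes can be declared through a one-column
#' companion file.
#'
#' @param path TSV edge list file.
#' @param defaultEvidence evidence assigned to 2-column rows.
#' @param nodesPath optional one-column file of node ids to add (isolated
#'   nodes; ids already present are ignored).
#' @return A [ReferenceNetwork-class].
#' @seealso [writeEdgeList()] for the inverse.
#' @export
readEdgeList <- function(path, defaultEvidence = c("known", "predicted"),
                         nodesPath = NULL) {
  defaultEvidence <- match.arg(defaultEvidence)
  tsv <- .readTsvLines(path)
  if (!length(tsv$lines)) stop("empty network: no edges in '", path, "'")
  fields <- strsplit(tsv$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad))
    stop(sprintf("malformed row at line %d of '%s': expected 2-3 columns, got %d",
                 tsv$lineno[bad[1]], path, nf[bad[1]]))
  a <- trimws(vapply(fields, `[`, "", 1L))
  b <- trimws(vapply(fields, `[`, "", 2L))
  ev <- vapply(fields, function(f)
    if (length(f) >= 3L) trimws(f[3]) else defaultEvidence, "")
  badEv <- which(!ev %in% EVIDENCE_LEVELS)
  if (length(badEv))
    stop(sprintf("line %d of '%s': evidence must be 'known' or 'predicted', got '%s'",
                 tsv$lineno[badEv[1]], path, ev[badEv[1]]))
  self <- a == b
  if (any(self)) {
    warning(sprintf("dropped %d self-loop(s) (first at line %d)",
                    sum(self), tsv$lineno[which(self)[1]]))
    a <- a[!self]; b <- b[!self]; ev <- ev[!self]
  }
  if (!length(a)) stop("empty network: only self-loops in '", path, "'")
  extra <- character(0)
  if (!is.null(nodesPath)) {
    ntsv <- .readTsvLines(nodesPath)
    extra <- trimws(ntsv$lines)
  }
  referenceNetwork(
    data.frame(a = a, b = b, evidence = ev,
               source = basename(path), stringsAsFactors = FALSE),
    nodes = extra)
}

#' Write a network as a TSV edge list
#'
#' Inverse of [readEdgeList()]: writes the edge table (endpoints and
#' evidence) and, when \code{nodesPath} is given, the isolated nodes to a
#' one-column companion file so that the round trip preserves node and edge
#' sets exactly.
#'
#' @param net a [ReferenceNetwork-class].
#' @param path output TSV file.
#' @param nodesPath optional companion file for degree-zero nodes; required
#'   for a lossless round trip when the network has any.
#' @return \code{path}, invisibly.
#' @export
writeEdgeList <- function(net, path, nodesPath = NULL) {
  stopifnot(is(net, "ReferenceNetwork"))
  e <- networkEdges(net)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(e$a, e$b, e$evidence, sep = "\t"), con)
  iso <- setdiff(networkNodes(net), c(e$a, e$b))
  if (!is.null(nodesPath)) {
    writeLines(iso, nodesPath, useBytes = TRUE)
  } else if (length(iso)) {
    warning(length(iso), " isolated node(s) not written; supply nodesPath")
  }
  invisible(path)
}

.readHeaderTsv <- function(path) {
  tsv <- .readTsvLines(path)
  if (!length(tsv$lines)) stop("no header row in '", path, "'")
  ## sentinel keeps strsplit from swallowing trailing empty fields
  fields <- strsplit(paste0(tsv$lines, "\x01"), "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) {
    f[length(f)] <- sub("\x01$", "", f[length(f)])
    f
  })
  header <- trimws(fields[[1]])
  rows <- fields[-1]
  lineno <- tsv$lineno[-1]
  bad <- which(lengths(rows) != length(header))
  if (length(bad))
    stop(sprintf("malformed row at line %d of '%s': expected %d columns",
                 lineno[bad[1]], path, length(header)))
  df <- as.data.frame(do.call(rbind, lapply(rows, trimws)),
                      stringsAsFactors = FALSE)
  if (!length(rows))
    df <- as.data.frame(matrix(character(0), 0, length(header)),
                        stringsAsFactors = FALSE)
  names(df) <- header
  df
}

#' Read a TAP-MS hit table
#'
#' TSV with header columns \code{protein}, \code{unique_peptides},
#' \code{replicate}, \code{condition}. Validation enforces peptide counts
#' of at least one and uniqueness of (protein, replicate, condition).
#'
#' @param path TSV file.
#' @return A [HitTable-class] (possibly with zero records).
#' @export
readHitTable <- function(path) {
  df <- .readHeaderTsv(path)
  need <- c("protein", "unique_peptides", "replicate", "condition")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("hit table '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(df)) {
    up <- suppressWarnings(as.numeric(df$unique_peptides))
    if (any(is.na(up)))
      stop("non-numeric unique_peptides in '", path, "'")
    df$unique_peptides <- up
  }
  hitTable(df[need])
}

#' @rdname readHitTable
#' @param hits a [HitTable-class] to write.
#' @export
writeHitTable <- function(hits, path) {
  stopifnot(is(hits, "HitTable"))
  utils::write.table(hitRecords(hits), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

PHENOTYPE_CATEGORIES <- c("normal", "extra_turn", "wandering", "overshoot",
                          "other")

#' Validate a phenotype count table
#'
#' A phenotype count table is a data.frame with a \code{treatment} column,
#' the five outcome-category count columns (\code{normal},
#' \code{extra_turn}, \code{wandering}, \code{overshoot}, \code{other})
#' and the per-treatment total \code{n}. Unscored treatments (e.g. RNAi
#' knockdowns arresting before the phenotype can be read) are represented
#' by \code{NA} in \code{n} and the categories. For scored rows the
#' categories must be non-negative integers summing exactly to \code{n},
#' and \code{n >= 1}.
#'
#' @param counts data.frame as described.
#' @return The validated data.frame (categories coerced to integer),
#'   invisibly usable downstream.
#' @export
validatePhenotypeCounts <- function(counts) {
  need <- c("treatment", PHENOTYPE_CATEGORIES, "n")
  miss <- setdiff(need, names(counts))
  if (length(miss))
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(counts$treatment))
    stop("duplicated treatment id in phenotype table")
  scored <- !is.na(counts$n)
  for (cl in c(PHENOTYPE_CATEGORIES, "n")) {
    v <- counts[[cl]]
    if (any(scored & (is.na(v) | v < 0 | v != round(v))))
      stop("phenotype column '", cl,
           "' must hold non-negative integers for scored treatments")
    counts[[cl]] <- ifelse(is.na(v), NA_integer_, as.integer(round(v)))
  }
  if (any(counts$n[scored] < 1L))
    stop("scored treatments need n >= 1")
  sums <- rowSums(counts[scored, PHENOTYPE_CATEGORIES, drop = FALSE])
  off <- which(sums != counts$n[scored])
  if (length(off))
    stop(sprintf("category sum != n for treatment '%s' (%d vs %d)",
                 counts$treatment[scored][off[1]], sums[off[1]],
                 counts$n[scored][off[1]]))
  counts
}

#' Read a phenotype table (counts or percentages)
#'
#' Reads a TSV with columns \code{treatment}, the five outcome categories
#' and \code{n}. The category columns may hold either raw counts or
#' percentages of \code{n} (as printed in screen summary tables); with
#' \code{mode = "auto"} the file is treated as counts when every scored
#' row's categories sum exactly to its \code{n}, and as percentages
#' otherwise, in which case counts are reconstructed per row with
#' [countsFromPercent()]. Rows with an empty / \code{NA} total are kept as
#' unscored treatments. Extra columns (e.g. a locus or role annotation)
#' are preserved.
#'
#' @param path TSV file.
#' @param mode \code{"auto"}, \code{"counts"} or \code{"percent"}.
#' @return A validated phenotype count data.frame (see
#'   [validatePhenotypeCounts()]).
#' @export
readPhenotypeTable <- function(path, mode = c("auto", "counts", "percent")) {
  mode <- match.arg(mode)
  df <- .readHeaderTsv(path)
  need <- c("treatment", PHENOTYPE_CATEGORIES, "n")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenotype table '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  for (cl in c(PHENOTYPE_CATEGORIES, "n"))
    df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  scored <- !is.na(df$n)
  if (mode == "auto") {
    sums <- rowSums(df[scored, PHENOTYPE_CATEGORIES, drop = FALSE])
    mode <- if (all(!is.na(sums)) && all(sums == df$n[scored])) "counts"
            else "percent"
  }
  if (mode == "percent") {
    for (i in which(scored)) {
      cts <- countsFromPercent(as.numeric(df[i, PHENOTYPE_CATEGORIES]),
                               df$n[i])
      df[i, PHENOTYPE_CATEGORIES] <- as.list(cts)
    }
  }
  validatePhenotypeCounts(df)
}

#' @rdname readPhenotypeTable
#' @param counts validated phenotype count data.frame to write.
#' @export
writePhenotypeTable <- function(counts, path) {
  counts <- validatePhenotypeCounts(counts)
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}
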