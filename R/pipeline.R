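## End-to-end orchestration: filtering -> seed graph -> parsimony
## expansion -> PIE -> screen summary, with per-stage derived seeds and a
## machine-readable JSON report.

.stageSeed <- function(seed, offset)
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)

## small deterministic string fingerprint (djb2-style) for provenance
.configFingerprint <- function(txt) {
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 33 + b) %% 2147483647
  sprintf("%010d", as.integer(h))
}

#' Run the full screen-analysis pipeline
#'
#' Executes the four analysis stages in order — candidate filtering,
#' seed-graph construction, parsimony expansion, PIE cohesiveness
#' analysis and phenotype screen summary — writing every intermediate
#' artifact and a JSON report to \code{outputDir}. A single master seed
#' drives the run; each stochastic stage uses a fixed-offset derived seed
#' so stages are independently reproducible. A failed stage aborts with
#' the stage name; artifacts already written are retained.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{reference}{path to the reference edge list (TSV); optional
#'       \code{referenceNodes} companion file of isolated nodes.}
#'     \item{bait}{character vector of bait hit-table paths.}
#'     \item{control}{optional character vector of control hit-table
#'       paths.}
#'     \item{blocklists}{optional named list of one-column blocklist file
#'       paths.}
#'     \item{phenotypes}{optional path to a phenotype table (counts or
#'       percentages); its control row is identified by
#'       \code{controlLabel} (default \code{"control"}).}
#'     \item{minReplicates, minLinks, nRand}{stage parameters (defaults
#'       2, 2, 10000).}
#'     \item{seed}{master seed (default 1).}
#'     \item{outputDir}{output directory, created if absent.}
#'   }
#' @return Invisibly, the report as a named list (also written to
#'   \code{report.json}).
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$reference),
            !is.null(config$bait), !is.null(config$outputDir))
  minReplicates <- config$minReplicates %||% 2L
  minLinks <- config$minLinks %||% 2L
  nRand <- config$nRand %||% 10000L
  seed <- as.integer(config$seed %||% 1L)
  out <- config$outputDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))

  reference <- stage("read-reference",
    readEdgeList(config$reference,
                 nodesPath = config$referenceNodes %||% NULL))

  candidates <- stage("filter", {
    bait <- lapply(config$bait, readHitTable)
    ctrl <- if (length(config$control %||% character(0)))
      lapply(config$control, readHitTable) else NULL
    bl <- lapply(config$blocklists %||% list(),
                 function(p) .readTsvLines(p)$lines)
    cs <- filterCandidates(bait, ctrl, minReplicates = minReplicates,
                           blocklists = bl)
    writeCandidateSet(cs, file.path(out, "candidates.tsv"))
    cs
  })

  extended <- stage("build-network", {
    sg <- buildSeedGraph(retained(candidates), reference)
    en <- expandParsimony(sg, reference, minLinks = minLinks)
    writeExtendedNetwork(en, file.path(out, "network_edges.tsv"),
                         file.path(out, "node_roles.tsv"))
    en
  })

  pie <- stage("pie", {
    pr <- pieAnalysis(reference, networkNodes(extended), nRand = nRand,
                      seed = .stageSeed(seed, 3L))
    writePieHistogram(pr, file.path(out, "pie_null_histogram.tsv"))
    pr
  })

  screen <- NULL
  if (!is.null(config$phenotypes)) {
    screen <- stage("screen", {
      tab <- readPhenotypeTable(config$phenotypes)
      lab <- config$controlLabel %||% "control"
      ctrlRow <- tab[tab$treatment == lab, , drop = FALSE]
      if (nrow(ctrlRow) != 1L)
        stop("phenotype table needs exactly one '", lab, "' row")
      trt <- tab[tab$treatment != lab, , drop = FALSE]
      ss <- screenSummary(trt, ctrlRow,
                          interactorIds = retained(candidates))
      utils::write.table(screenResults(ss),
                         file.path(out, "screen_results.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         fileEncoding = "UTF-8")
      ss
    })
  }

  cfgJson <- jsonlite::toJSON(config, auto_unbox = TRUE)
  report <- list(
    candidates = list(retained = length(retained(candidates)),
                      audited = nrow(auditTrail(candidates))),
    network = list(seedNodes = length(seedNodes(extended)),
                   addedNodes = length(addedNodes(extended)),
                   inducedEdges = numEdges(extended)),
    pie = list(observedEdges = observedEdges(pie),
               nullMean = pie@nullMean, nullSd = pie@nullSd,
               pieScore = pieScore(pie), empiricalP = empiricalP(pie),
               nRand = pie@nRand, resolvedMode = pie@resolvedMode),
    screen = if (is.null(screen)) NULL else list(
      totalScreened = screen@totalScreened,
      nSignificant = nSignificant(screen),
      nSignificantOther = screen@nSignificantOther),
    provenance = list(
      seed = seed,
      configFingerprint = .configFingerprint(as.character(cfgJson)),
      package = as.character(utils::packageVersion("cohesionScreen")),
      rVersion = paste(R.version$major, R.version$minor, sep = ".")))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(report)
}
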