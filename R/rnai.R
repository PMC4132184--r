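## RNAi phenotype screen statistics: count reconstruction from printed
## percentages, Fisher's exact tests of %-normal against control,
## significance tiers, screen summary.

.roundHalfUp <- function(x) floor(x + 0.5)

#' Reconstruct category counts from printed percentages
#'
#' Screen summary tables usually print per-category percentages plus the
#' number of animals scored. This reconstructs integer counts: provisional
#' counts are \code{round-half-up(p/100 * n)}; any residual between their
#' sum and \code{n} (a few units at most, from independent rounding) is
#' repaired by adding or removing single counts in a deterministic order —
#' largest fractional part of \code{p/100 * n} first, ties broken by
#' column order (normal, extra_turn, wandering, overshoot, other). A
#' residual larger than the number of categories means the percentages are
#' inconsistent with \code{n} and is an error.
#'
#' @param percents numeric vector of 5 percentages (normal, extra_turn,
#'   wandering, overshoot, other), each >= 0.
#' @param n integer, number of animals scored (>= 1).
#' @return Named integer vector of 5 counts summing to \code{n}.
#' @examples
#' countsFromPercent(c(99, 0, 1, 0, 0), 102)   # 101 0 1 0 0
#' countsFromPercent(c(25, 13, 11, 46, 4), 114)  # sums to 114
#' @export
countsFromPercent <- function(percents, n) {
  if (length(percents) != 5L || any(is.na(percents)) || any(percents < 0))
    stop("percents must be 5 non-negative values")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be an integer >= 1")
  raw <- percents / 100 * n
  counts <- .roundHalfUp(raw)
  resid <- n - sum(counts)
  if (abs(resid) > 5L)
    stop(sprintf("percentages inconsistent with n = %d (residual %d counts)",
                 n, as.integer(resid)))
  if (resid != 0) {
    frac <- raw - floor(raw)
    ord <- order(-frac, seq_along(frac))
    step <- sign(resid)
    i <- 1L
    while (resid != 0 && i <= 5L) {
      j <- ord[i]
      if (counts[j] + step >= 0) {
        counts[j] <- counts[j] + step
        resid <- resid - step
      }
      i <- i + 1L
    }
    if (resid != 0)
      stop("could not repair rounding residual without negative counts")
  }
  if (any(counts < 0)) stop("negative reconstructed count")
  stats::setNames(as.integer(counts), PHENOTYPE_CATEGORIES)
}

#' Category percentages of a count vector
#'
#' The inverse-direction helper of [countsFromPercent()]: integer
#' percentages (round half up) of each category.
#'
#' @param counts numeric vector of 5 category counts.
#' @return Named integer vector of percentages.
#' @export
percentsFromCounts <- function(counts) {
  n <- sum(counts)
  if (n < 1) stop("counts must sum to >= 1")
  stats::setNames(as.integer(.roundHalfUp(100 * counts / n)),
                  PHENOTYPE_CATEGORIES)
}

.tierOf <- function(p, tiers) {
  if (p < tiers[["four_star"]]) "four_star"
  else if (p < tiers[["star"]]) "star"
  else "ns"
}

DEFAULT_TIERS <- c(four_star = 5e-4, star = 0.05)

.normalPair <- function(row) {
  if (is.data.frame(row)) {
    stopifnot(nrow(row) == 1L)
    c(normal = as.integer(row$normal), n = as.integer(row$n))
  } else {
    c(normal = as.integer(row[["normal"]]), n = as.integer(row[["n"]]))
  }
}

#' Fisher's exact test of normal outcomes versus control
#'
#' Collapses the five outcome categories to normal vs defective and runs a
#' two-sided Fisher's exact test of the 2x2 table
#' \code{[normal, n - normal]} for treatment and control (the two-sided
#' p-value is the sum of all hypergeometric table probabilities no larger
#' than the observed table's, the standard convention). Significance
#' tiers: \code{"four_star"} for p < 0.0005, \code{"star"} for p < 0.05,
#' \code{"ns"} otherwise.
#'
#' @param treatment,control one-row phenotype count data.frames (or named
#'   vectors with \code{normal} and \code{n}).
#' @param tiers named numeric vector with thresholds \code{four_star} and
#'   \code{star}.
#' @return List with elements \code{p_two_sided}, \code{table} (the 2x2
#'   matrix, rows = treatment/control, cols = normal/defective) and
#'   \code{tier}.
#' @export
fisherNormalVsControl <- function(treatment, control,
                                  tiers = DEFAULT_TIERS) {
  tr <- .normalPair(treatment)
  ct <- .normalPair(control)
  if (any(is.na(c(tr, ct))) || tr[["n"]] < 1L || ct[["n"]] < 1L)
    stop("degenerate margin: both groups need n >= 1 (unscored treatment?)")
  if (tr[["normal"]] > tr[["n"]] || ct[["normal"]] > ct[["n"]])
    stop("normal count exceeds group total")
  tab <- matrix(c(tr[["normal"]], tr[["n"]] - tr[["normal"]],
                  ct[["normal"]], ct[["n"]] - ct[["normal"]]),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("treatment", "control"),
                                c("normal", "defective")))
  p <- stats::fisher.test(tab)$p.value
  p <- min(p, 1)
  list(p_two_sided = p, table = tab, tier = .tierOf(p, tiers))
}

#' Summarise an RNAi phenotype screen
#'
#' Runs [fisherNormalVsControl()] for every scored treatment against the
#' control row, assigns significance tiers, adds a Benjamini-Hochberg
#' adjusted p-value column (reporting aid only; tiers are
#' per-comparison), and counts significant treatments. When
#' \code{interactorIds} is given, significance is tallied separately for
#' treatments inside that set (\code{nSignificant}) and outside it
#' (\code{nSignificantOther}) — e.g. primary screen interactors versus
#' network-expansion additions. Unscored treatments (\code{NA} totals,
#' e.g. larval-arrest knockdowns) are excluded from testing and are not
#' counted as hits.
#'
#' @param treatments phenotype count data.frame (multi-row, see
#'   [validatePhenotypeCounts()]); must not contain the control.
#' @param control one-row phenotype count data.frame.
#' @param interactorIds optional character vector of treatment ids forming
#'   the primary interactor set.
#' @param tiers significance thresholds, see [fisherNormalVsControl()].
#' @return A [ScreenSummary-class].
#' @export
screenSummary <- function(treatments, control, interactorIds = NULL,
                          tiers = DEFAULT_TIERS) {
  treatments <- validatePhenotypeCounts(treatments)
  if (!nrow(treatments)) stop("no treatments supplied")
  ctrl <- .normalPair(control)
  scored <- !is.na(treatments$n)
  res <- data.frame(treatment = treatments$treatment,
                    normal = treatments$normal,
                    n = treatments$n,
                    percent_normal = NA_real_,
                    p_two_sided = NA_real_,
                    p_adj_bh = NA_real_,
                    tier = "unscored",
                    stringsAsFactors = FALSE)
  for (i in which(scored)) {
    ft <- fisherNormalVsControl(treatments[i, ], control, tiers = tiers)
    res$p_two_sided[i] <- ft$p_two_sided
    res$tier[i] <- ft$tier
    res$percent_normal[i] <- round(100 * res$normal[i] / res$n[i], 1)
  }
  res$p_adj_bh[scored] <- stats::p.adjust(res$p_two_sided[scored],
                                          method = "BH")
  sig <- scored & res$tier != "ns" & res$tier != "unscored"
  if (is.null(interactorIds)) {
    nSig <- sum(sig)
    nOther <- 0L
  } else {
    inSet <- res$treatment %in% interactorIds
    nSig <- sum(sig & inSet)
    nOther <- sum(sig & !inSet)
  }
  new("ScreenSummary", results = res, nSignificant = as.integer(nSig),
      nSignificantOther = as.integer(nOther),
      totalScreened = as.integer(sum(scored)),
      interactorIds = as.character(interactorIds %||% character(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
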