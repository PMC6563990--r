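# Screening calls and prevalence summaries.

#' Binary screening calls from a measure
#'
#' A probe/sample entry is called positive — flagged hydroxymethylated —
#' iff its unmasked measure value is strictly greater than \code{threshold}.
#' Exact zeros are non-positive, matching the partition of the similarity
#' statistics into \eqn{x > 0} and \eqn{x \le 0}. The default threshold is 0;
#' a stricter published convention uses 0.3 on the beta-difference scale.
#'
#' @param measure a \linkS4class{MeasureMatrix}.
#' @param threshold single finite decision cut; default 0.
#' @return a \linkS4class{CallMatrix}.
#' @export
callPositive <- function(measure, threshold = 0) {
  stopifnot(is(measure, "MeasureMatrix"),
            length(threshold) == 1L, is.finite(threshold))
  cc <- measure@values > threshold
  cc[measure@mask] <- FALSE
  new("CallMatrix", measure = measure@measure, threshold = threshold,
      calls = cc, mask = measure@mask)
}

.axisSums <- function(m, axis) {
  if (axis == "per_sample") colSums(m) else rowSums(m)
}

#' Prevalence of positive screening calls
#'
#' Per sample (fraction of unmasked CpGs called positive within the sample)
#' or per probe (fraction of samples positive at the CpG, i.e. the CpG's
#' hydroxymethylation level). Units with no unmasked call are omitted with a
#' warning.
#'
#' @param calls a \linkS4class{CallMatrix}.
#' @param axis \code{"per_sample"} or \code{"per_probe"}.
#' @return a \linkS4class{PrevalenceSummary}.
#' @export
prevalence <- function(calls, axis = c("per_sample", "per_probe")) {
  axis <- match.arg(axis)
  ok <- !calls@mask
  num <- .axisSums(calls@calls & ok, axis)
  den <- .axisSums(ok, axis)
  if (any(den == 0L))
    warning(sprintf("%d unit(s) with no unmasked calls omitted", sum(den == 0L)))
  keep <- den > 0L
  den_i <- as.integer(den[keep]); names(den_i) <- names(den)[keep]
  new("PrevalenceSummary", axis = axis, measure = calls@measure,
      proportions = (num / den)[keep], denominators = den_i)
}

#' Joint prevalence of positive calls under two measures
#'
#' Per unit, the fraction of jointly-unmasked entries where both call
#' matrices are positive; by construction it never exceeds either marginal
#' prevalence computed on the same jointly-unmasked denominator.
#'
#' @param calls1,calls2 aligned \linkS4class{CallMatrix} objects.
#' @param axis \code{"per_sample"} or \code{"per_probe"}.
#' @return a \linkS4class{PrevalenceSummary} whose measure name is the pair.
#' @export
jointPrevalence <- function(calls1, calls2,
                            axis = c("per_sample", "per_probe")) {
  axis <- match.arg(axis)
  if (!identical(dim(calls1@calls), dim(calls2@calls)))
    stop("call matrices are not aligned")
  ok <- !calls1@mask & !calls2@mask
  num <- .axisSums(calls1@calls & calls2@calls & ok, axis)
  den <- .axisSums(ok, axis)
  if (any(den == 0L))
    warning(sprintf("%d unit(s) with no jointly-unmasked calls omitted",
                    sum(den == 0L)))
  keep <- den > 0L
  den_i <- as.integer(den[keep]); names(den_i) <- names(den)[keep]
  new("PrevalenceSummary", axis = axis,
      measure = paste(calls1@measure, calls2@measure, sep = "+"),
      proportions = (num / den)[keep], denominators = den_i)
}

#' Substantially hydroxymethylated CpGs
#'
#' Probes whose per-probe prevalence of positive calls (across samples) is at
#' least \code{minFraction}; the canonical rule calls a CpG substantially
#' hydroxymethylated when at least 75\% of its values across samples are
#' positive. The boundary is inclusive.
#'
#' @param calls a \linkS4class{CallMatrix}.
#' @param minFraction required fraction in (0, 1]; default 0.75.
#' @return character vector of probe ids.
#' @export
substantialCpGs <- function(calls, minFraction = 0.75) {
  stopifnot(minFraction > 0, minFraction <= 1)
  ok <- !calls@mask
  num <- rowSums(calls@calls & ok)
  den <- rowSums(ok)
  ids <- rownames(calls@calls)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(calls@calls)))
  ids[den > 0L & num / den >= minFraction]
}

#' Compare prevalence between two tissues
#'
#' Two-sided rank test of prevalence vectors from two tissues: Wilcoxon
#' signed-rank on matched units when \code{paired = TRUE} (the design of a
#' matched healthy/cancer cohort), Mann-Whitney otherwise. Reports the test
#' statistic, p value, median difference (a - b for paired data, difference
#' of medians otherwise) and its direction. With fewer than 3 informative
#' pairs the p value is \code{NA} and a warning is raised.
#'
#' @param summary_a,summary_b \linkS4class{PrevalenceSummary} objects (e.g.
#'   healthy and cancer); for paired tests units must match.
#' @param paired logical; default \code{TRUE}.
#' @return a one-row \code{data.frame} with columns \code{statistic},
#'   \code{p_value}, \code{median_diff}, \code{direction} (\code{"a>b"},
#'   \code{"a<b"} or \code{"none"}), \code{n_informative}.
#' @export
compareTissues <- function(summary_a, summary_b, paired = TRUE) {
  a <- proportions(summary_a)
  b <- proportions(summary_b)
  if (paired) {
    if (length(a) != length(b))
      stop("paired comparison requires equal-length, matched summaries")
    if (!is.null(names(a)) && !is.null(names(b)) &&
        !identical(names(a), names(b)))
      stop("paired comparison requires matched units")
    d <- a - b
    n_inf <- sum(d != 0)
    md <- stats::median(d)
  } else {
    n_inf <- min(length(a), length(b))
    md <- stats::median(a) - stats::median(b)
  }
  direction <- if (md > 0) "a>b" else if (md < 0) "a<b" else "none"
  if (n_inf < 3) {
    warning("fewer than 3 informative pairs; p value not reported")
    stat <- NA_real_; pv <- NA_real_
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, paired = paired, exact = FALSE))
    stat <- unname(ht$statistic); pv <- ht$p.value
  }
  data.frame(statistic = stat, p_value = pv, median_diff = md,
             direction = direction, n_informative = n_inf)
}

#' Benjamini-Hochberg adjustment across a family of comparisons
#'
#' Convenience wrapper adjusting the p values of several
#' \code{\link{compareTissues}} reports (one per measure/axis combination)
#' for multiplicity.
#'
#' @param reports list of one-row data.frames from \code{compareTissues}.
#' @return single \code{data.frame} with an added \code{p_adjusted} column.
#' @export
adjustComparisons <- function(reports) {
  out <- do.call(rbind, reports)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- names(reports)
  out
}
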