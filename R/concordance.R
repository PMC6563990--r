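# Gold-standard-free concordance of two screening measures.
#
# With no biochemical criterion for "hydroxymethylated" available, two
# measures are compared through their binary calls: the simple matching
# coefficient S (fraction of concordant calls), its mismatch-corrected
# Hamann transform SH = 2S - 1, and the conditional relative accuracies
# SE_r (co-positivity), SP_r (co-negativity) and the relative false
# discovery rate FDR_r(x1|x2) = 1 - SE_r(x2|x1).

.CONC_AXES <- c("per_probe_across_samples", "per_sample_across_probes")

# per-unit call vectors along the chosen axis; units with no jointly
# unmasked entry are dropped with a warning by callers
.unitCounts <- function(calls1, calls2, axis) {
  if (!identical(dim(calls1@calls), dim(calls2@calls)))
    stop("call matrices are not aligned")
  ok <- !calls1@mask & !calls2@mask
  c1 <- calls1@calls & ok
  c2 <- calls2@calls & ok
  f <- if (axis == "per_probe_across_samples") rowSums else colSums
  list(n = f(ok),
       pp = f(c1 & c2),              # both positive
       a = f(c1), b = f(c2),         # marginal positives
       nn = f(ok & !c1 & !c2))       # both non-positive
}

.unitNames <- function(calls1, axis) {
  nm <- if (axis == "per_probe_across_samples") rownames(calls1@calls)
        else colnames(calls1@calls)
  if (is.null(nm)) {
    k <- if (axis == "per_probe_across_samples") nrow(calls1@calls)
         else ncol(calls1@calls)
    nm <- as.character(seq_len(k))
  }
  nm
}

.concordance <- function(calls1, calls2, axis, statistic, values, degenerate,
                         method = "empirical_mean") {
  keep <- !is.na(values)
  expec <- if (any(keep)) mean(values[keep]) else NA_real_
  new("ConcordanceTable", pair = c(calls1@measure, calls2@measure),
      tissue = "unspecified", axis = axis, statistic = statistic,
      values = values, expectation = expec, expectationMethod = method,
      degenerate = degenerate)
}

#' Simple matching coefficient between two call matrices
#'
#' Per unit (probe across samples, or sample across probes), the fraction of
#' jointly-unmasked entries on which the two measures agree — concordant
#' positives plus concordant non-positives over the unit size n. S ranges in
#' [0, 1]: 1 is complete similarity, 0 complete dissimilarity. Units with no
#' jointly-positive entry but S > 0 are flagged degenerate: there S is driven
#' entirely by concordant negatives and can mislead; consult the Hamann
#' coefficient for those units.
#'
#' @param calls1,calls2 aligned \linkS4class{CallMatrix} objects.
#' @param axis \code{"per_probe_across_samples"} (the canonical definition)
#'   or \code{"per_sample_across_probes"}.
#' @return a \linkS4class{ConcordanceTable} with statistic \code{"S"}; its
#'   expectation is the empirical mean over units.
#' @export
simpleMatching <- function(calls1, calls2, axis = .CONC_AXES) {
  axis <- match.arg(axis)
  u <- .unitCounts(calls1, calls2, axis)
  if (any(u$n == 0))
    warning(sprintf("%d empty unit(s) omitted", sum(u$n == 0)))
  s <- ifelse(u$n > 0, (u$pp + u$nn) / u$n, NA_real_)
  names(s) <- .unitNames(calls1, axis)
  degen <- !is.na(s) & u$pp == 0 & s > 0
  .concordance(calls1, calls2, axis, "S", s, degen)
}

#' Hamann similarity coefficient between two call matrices
#'
#' Per unit, (matches - mismatches) / n; the mismatch-corrected transform of
#' the simple matching coefficient, satisfying SH = 2 S - 1 exactly and hence
#' SH <= S. Ranges in [-1, 1], with -1 complete dissimilarity and 1 complete
#' similarity. Preferred over S for units where agreement consists only of
#' concordant negatives.
#'
#' @inheritParams simpleMatching
#' @return a \linkS4class{ConcordanceTable} with statistic \code{"SH"}.
#' @export
hamann <- function(calls1, calls2, axis = .CONC_AXES) {
  axis <- match.arg(axis)
  s <- simpleMatching(calls1, calls2, axis)
  new("ConcordanceTable", pair = s@pair, tissue = s@tissue, axis = axis,
      statistic = "SH", values = 2 * s@values - 1,
      expectation = 2 * s@expectation - 1,
      expectationMethod = s@expectationMethod, degenerate = s@degenerate)
}

#' Hamann expectation from a matching expectation
#'
#' The exact identity \eqn{E[SH] = 2 E[S] - 1} linking the expected Hamann
#' coefficient to the expected simple matching coefficient; holds unit-wise
#' and for any expectation construction, so published E[S] values determine
#' the corresponding E[SH] values.
#'
#' @param es numeric vector/matrix of E[S] values in [0, 1].
#' @return E[SH] values of the same shape.
#' @export
hamannFromMatching <- function(es) 2 * es - 1

#' Expected similarity between two call matrices
#'
#' A single expectation for S or SH per measure pair. Two constructions are
#' provided: \code{"empirical_mean"}, the mean of the unit-wise coefficients;
#' and \code{"independence_null"}, the expectation under random placement of
#' the observed marginal positive counts a and b within each unit,
#' \eqn{E[S] = (ab + (n-a)(n-b)) / n^2}, averaged over units. Under either
#' method \eqn{E[SH] = 2E[S] - 1} exactly.
#'
#' @inheritParams simpleMatching
#' @param statistic \code{"S"} or \code{"SH"}.
#' @param method \code{"empirical_mean"} or \code{"independence_null"}.
#' @return single numeric expectation.
#' @export
expectedSimilarity <- function(calls1, calls2, axis = .CONC_AXES,
                               statistic = c("S", "SH"),
                               method = c("empirical_mean",
                                          "independence_null")) {
  axis <- match.arg(axis)
  statistic <- match.arg(statistic)
  method <- match.arg(method)
  if (method == "empirical_mean") {
    es <- simpleMatching(calls1, calls2, axis)@expectation
  } else {
    u <- .unitCounts(calls1, calls2, axis)
    keep <- u$n > 0
    es <- mean((u$a * u$b + (u$n - u$a) * (u$n - u$b))[keep] / u$n[keep]^2)
  }
  if (statistic == "SH") hamannFromMatching(es) else es
}

#' Relative accuracy of two measures against each other
#'
#' Conditional concordance without a gold standard. For measures x1, x2 and
#' per unit: relative sensitivity (co-positivity)
#' \eqn{SE_r(x_1|x_2) = P(x_1 > 0 \mid x_2 > 0)}, relative specificity
#' (co-negativity) \eqn{SP_r(x_1|x_2) = P(x_1 \le 0 \mid x_2 \le 0)}, and the
#' relative false discovery rate
#' \eqn{FDR_r(x_1|x_2) = 1 - P(x_1>0, x_2>0)/P(x_1>0) = 1 - SE_r(x_2|x_1)}.
#' Probabilities are empirical proportions over jointly-unmasked entries.
#' Units with an empty conditioning set get \code{NA} and are logged.
#'
#' Both orderings are returned: element \code{"x1|x2"} conditions on
#' \code{calls2}, element \code{"x2|x1"} on \code{calls1}.
#'
#' @inheritParams simpleMatching
#' @return named list of six \linkS4class{ConcordanceTable}s:
#'   \code{SE_r}, \code{SP_r}, \code{FDR_r}, each in both orderings.
#' @export
relativeAccuracy <- function(calls1, calls2, axis = .CONC_AXES) {
  axis <- match.arg(axis)
  u <- .unitCounts(calls1, calls2, axis)
  nm <- .unitNames(calls1, axis)
  rat <- function(num, den) {
    out <- ifelse(den > 0, num / den, NA_real_); names(out) <- nm; out
  }
  n_empty <- sum(u$b == 0) + sum(u$a == 0)
  if (n_empty > 0)
    message(sprintf("relativeAccuracy: %d unit/ordering(s) with empty conditioning set",
                    n_empty))
  se12 <- rat(u$pp, u$b)                 # P(x1>0 | x2>0)
  se21 <- rat(u$pp, u$a)                 # P(x2>0 | x1>0)
  sp12 <- rat(u$nn, u$n - u$b)           # P(x1<=0 | x2<=0)
  sp21 <- rat(u$nn, u$n - u$a)
  no_deg <- rep(FALSE, length(nm))
  ct <- function(stat, v, flip = FALSE) {
    c1 <- if (flip) calls2 else calls1
    c2 <- if (flip) calls1 else calls2
    .concordance(c1, c2, axis, stat, v, no_deg)
  }
  list("SE_r(x1|x2)" = ct("SE_r", se12),
       "SE_r(x2|x1)" = ct("SE_r", se21, flip = TRUE),
       "SP_r(x1|x2)" = ct("SP_r", sp12),
       "SP_r(x2|x1)" = ct("SP_r", sp21, flip = TRUE),
       "FDR_r(x1|x2)" = ct("FDR_r", 1 - se21),
       "FDR_r(x2|x1)" = ct("FDR_r", 1 - se12, flip = TRUE))
}

#' Relative FDR table from a relative sensitivity table
#'
#' Applies the exact identity \eqn{FDR_r(x_1|x_2) = 1 - SE_r(x_2|x_1)} to a
#' square matrix of (expected) relative sensitivities with conditioned
#' measure in rows and conditioning measure in columns, yielding the
#' corresponding (expected) relative FDR matrix in the same orientation.
#' Diagonal entries map 1 to 0.
#'
#' @param se square numeric matrix of SE_r (or E[SE_r]) values.
#' @return matrix of FDR_r (or E[FDR_r]) values, same dimnames.
#' @export
fdrFromSensitivity <- function(se) {
  se <- as.matrix(se)
  stopifnot(nrow(se) == ncol(se))
  1 - t(se)
}

#' Set the tissue label of a ConcordanceTable
#'
#' @param x a \linkS4class{ConcordanceTable}.
#' @param tissue one of \code{"healthy"}, \code{"cancer"},
#'   \code{"unspecified"}.
#' @return the relabelled object.
#' @export
setTissue <- function(x, tissue = c("unspecified", "healthy", "cancer")) {
  x@tissue <- match.arg(tissue)
  x
}
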