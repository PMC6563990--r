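# The three screening measures and their building blocks. All operate
# entrywise on the four intensity matrices and propagate masks by union.

.panelParts <- function(panel) {
  list(M_bs = assay(panel, "M_bs"), U_bs = assay(panel, "U_bs"),
       M_oxbs = assay(panel, "M_oxbs"), U_oxbs = assay(panel, "U_oxbs"),
       mask = assay(panel, "mask"))
}

#' Methylation proportion (beta value)
#'
#' Computes the offset-corrected methylation proportion
#' \eqn{\beta(\alpha) = M / (M + U + \alpha)} from methylated and unmethylated
#' allele intensities. The conventional offset is \code{alpha = 100};
#' \code{alpha = 0} is admitted (needed for the naive 5hmC surrogate), in
#' which case entries with \eqn{M + U = 0} are undefined and returned as
#' \code{NA}.
#'
#' @param M,U non-negative intensity vectors or matrices (recycled as usual).
#' @param alpha single non-negative offset; default 100.
#' @return numeric object of the common shape, values in [0, 1], \code{NA}
#'   where \eqn{M + U + \alpha = 0}.
#' @examples
#' betaValue(100, 100)        # 1/3
#' betaValue(50, 0, alpha = 0)  # 1
#' @export
betaValue <- function(M, U, alpha = 100) {
  stopifnot(length(alpha) == 1L, is.finite(alpha), alpha >= 0)
  den <- M + U + alpha
  out <- M / den
  out[den == 0] <- NA_real_
  out
}

.measureFromPanel <- function(panel, measure, values, extraMask = NULL,
                              alpha = numeric(0), noise = NULL) {
  mask <- assay(panel, "mask")
  if (!is.null(extraMask)) {
    n_new <- sum(extraMask & !mask)
    if (n_new > 0)
      message(sprintf("%s: %d additional entr%s masked (undefined)",
                      measure, n_new, if (n_new == 1L) "y" else "ies"))
    mask <- mask | extraMask
  }
  dimnames(values) <- dimnames(mask)
  .MeasureMatrix(measure, values, mask, alpha = alpha, noise = noise)
}

#' Difference of methylation proportions between BS and oxBS
#'
#' The classical screening measure for 5hmC: the entrywise difference
#' \eqn{\Delta\beta(\alpha) = \beta_{BS}(\alpha) - \beta_{oxBS}(\alpha)}
#' of the BS and oxBS methylation proportions. Positive values flag a CpG as
#' hydroxymethylated in the screening step; the conventional offset is
#' \code{alpha = 100}. Values lie in [-1, 1]. Note that the sign of
#' \eqn{\Delta\beta(\alpha)} can depend on \code{alpha} — see
#' \code{\link{criticalAlpha}}.
#'
#' @param panel an \linkS4class{HmcPanel}.
#' @param alpha single non-negative offset; default 100.
#' @return a \linkS4class{MeasureMatrix} named \code{"delta_beta"}.
#' @export
deltaBeta <- function(panel, alpha = 100) {
  p <- .panelParts(panel)
  den_bs <- p$M_bs + p$U_bs + alpha
  den_ox <- p$M_oxbs + p$U_oxbs + alpha
  vals <- p$M_bs / den_bs - p$M_oxbs / den_ox
  undef <- den_bs == 0 | den_ox == 0
  .measureFromPanel(panel, "delta_beta", vals, extraMask = undef,
                    alpha = alpha)
}

#' Difference of M-values between BS and oxBS
#'
#' The log-ratio analogue of \code{\link{deltaBeta}}:
#' \eqn{\Delta m(\alpha) = \log_2(M_{BS}/(U_{BS}+\alpha)) -
#' \log_2(M_{oxBS}/(U_{oxBS}+\alpha))}. The offset is applied to the
#' unmethylated intensity only; under this convention
#' \eqn{\Delta m(\alpha) \to \log_2(M_{BS}/M_{oxBS})} as \eqn{\alpha} grows
#' (see \code{\link{deltaMInf}}) and \eqn{\Delta m(\alpha)} has the same sign
#' as \eqn{\Delta\beta(\alpha)} wherever both are defined.
#'
#' Entries with a non-positive methylated intensity, or with
#' \eqn{U + \alpha = 0}, are masked.
#'
#' @inheritParams deltaBeta
#' @return a \linkS4class{MeasureMatrix} named \code{"delta_m"}.
#' @export
deltaM <- function(panel, alpha = 100) {
  p <- .panelParts(panel)
  undef <- p$M_bs <= 0 | p$M_oxbs <= 0 |
    (p$U_bs + alpha) <= 0 | (p$U_oxbs + alpha) <= 0
  vals <- suppressWarnings(
    log2(p$M_bs / (p$U_bs + alpha)) - log2(p$M_oxbs / (p$U_oxbs + alpha)))
  .measureFromPanel(panel, "delta_m", vals, extraMask = undef, alpha = alpha)
}

#' Methylated-intensity log-ratio (offset-free 5hmC measure)
#'
#' \eqn{\Delta m^\infty = \log_2(M_{BS}/M_{oxBS})}, the large-offset limit of
#' \code{\link{deltaM}}. Independent of the offset, and positive exactly when
#' the BS methylated intensity exceeds the oxBS one; zero means no 5hmC
#' signal at that CpG. Defined only where both methylated intensities are
#' strictly positive; other entries are masked and counted in a message.
#'
#' @inheritParams deltaBeta
#' @return a \linkS4class{MeasureMatrix} named \code{"delta_m_inf"}.
#' @export
deltaMInf <- function(panel) {
  p <- .panelParts(panel)
  undef <- p$M_bs <= 0 | p$M_oxbs <= 0
  vals <- suppressWarnings(log2(p$M_bs / p$M_oxbs))
  .measureFromPanel(panel, "delta_m_inf", vals, extraMask = undef)
}

#' Relative loss of total intensity under oxBS
#'
#' \eqn{\Delta h = 1 - (M_{oxBS}+U_{oxBS})/(M_{BS}+U_{BS})}, interpretable as
#' the proportion of 5hmC in the global methylation under the assumption that
#' a substantial 5hmC level depresses the overall oxBS intensity. Values lie
#' in (0, 1] exactly when the BS total exceeds the oxBS total. Negative
#' values are retained but flagged as noise in \code{\link{noiseFlag}}
#' (treated as measurement error); entries with zero BS total intensity are
#' masked.
#'
#' @inheritParams deltaBeta
#' @return a \linkS4class{MeasureMatrix} named \code{"delta_h"}.
#' @export
deltaH <- function(panel) {
  p <- .panelParts(panel)
  tot_bs <- p$M_bs + p$U_bs
  tot_ox <- p$M_oxbs + p$U_oxbs
  undef <- tot_bs == 0
  vals <- 1 - tot_ox / tot_bs
  noise <- !undef & !p$mask & !is.na(vals) & vals < 0
  .measureFromPanel(panel, "delta_h", vals, extraMask = undef, noise = noise)
}

#' Naive non-negative 5hmC estimate
#'
#' The zero-offset difference of proportions clamped at zero:
#' \eqn{\max(0, \Delta\beta(0))}. This is the screening surrogate for the
#' constrained maximum-likelihood 5hmC estimators (oxBS-MLE / OxyBS): in a
#' screening step those procedures flag exactly the CpGs with
#' \eqn{\Delta\beta(0) > 0}, which are exactly the entries where this
#' estimate is strictly positive.
#'
#' @inheritParams deltaBeta
#' @return a \linkS4class{MeasureMatrix} named \code{"naive_5hmc"}.
#' @export
naive5hmC <- function(panel) {
  db <- deltaBeta(panel, alpha = 0)
  vals <- pmax(0, db@values)
  dim(vals) <- dim(db@values); dimnames(vals) <- dimnames(db@values)
  .MeasureMatrix("naive_5hmc", vals, db@mask)
}

#' Compute a named 5hmC measure from a panel
#'
#' Dispatch helper mapping a measure name to its computing function; used by
#' the command-line interface and convenient for programmatic loops over
#' measures.
#'
#' @inheritParams deltaBeta
#' @param measure one of \code{"delta_beta"}, \code{"delta_m"},
#'   \code{"delta_m_inf"}, \code{"delta_h"}, \code{"naive_5hmc"}.
#' @param alpha offset for the offset-dependent measures; ignored otherwise.
#' @return a \linkS4class{MeasureMatrix}.
#' @export
computeMeasure <- function(panel, measure = c("delta_beta", "delta_m",
                                              "delta_m_inf", "delta_h",
                                              "naive_5hmc"),
                           alpha = 100) {
  measure <- match.arg(measure)
  switch(measure,
         delta_beta = deltaBeta(panel, alpha),
         delta_m = deltaM(panel, alpha),
         delta_m_inf = deltaMInf(panel),
         delta_h = deltaH(panel),
         naive_5hmc = naive5hmC(panel))
}
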