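# Offset-sensitivity analysis of the difference-of-proportions measure.
#
# Writing T = M + U for the total intensity of each treatment, the zero
# condition of delta-beta(alpha) is linear in alpha:
#   M_bs (T_ox + alpha) = M_ox (T_bs + alpha)
# so each probe/sample has at most one sign change on alpha in (0, Inf),
# located at alpha* = (M_ox T_bs - M_bs T_ox) / (M_bs - M_ox).

#' Closed-form sign-change offset of delta-beta
#'
#' For intensities \code{(M_bs, U_bs, M_oxbs, U_oxbs)} returns the unique
#' offset \eqn{\alpha^* > 0} at which \eqn{\Delta\beta(\alpha)} changes sign,
#' or \code{NA} when no sign change exists on \eqn{(0, \infty)} (including
#' the case \eqn{M_{BS} = M_{oxBS}}, where the sign of \eqn{\Delta\beta} is
#' the same for every \eqn{\alpha}). All arguments are vectorised.
#'
#' Entries with identical methylated intensities and identical totals have
#' \eqn{\Delta\beta(\alpha) \equiv 0} (in particular all-zero intensities
#' carry no information); they return \code{NA} and are marked in the
#' \code{"degenerate"} attribute.
#'
#' @param M_bs,U_bs,M_oxbs,U_oxbs non-negative intensities (vectors).
#' @return numeric vector of critical offsets (\code{NA} = absent), with a
#'   logical attribute \code{"degenerate"}.
#' @examples
#' criticalAlpha(110, 1000, 100, 100)  # 8900
#' @export
criticalAlpha <- function(M_bs, U_bs, M_oxbs, U_oxbs) {
  t_bs <- M_bs + U_bs
  t_ox <- M_oxbs + U_oxbs
  astar <- (M_oxbs * t_bs - M_bs * t_ox) / (M_bs - M_oxbs)
  astar[M_bs == M_oxbs] <- NA_real_
  astar[!is.na(astar) & astar <= 0] <- NA_real_
  degen <- M_bs == M_oxbs & t_bs == t_ox
  astar[degen] <- NA_real_
  attr(astar, "degenerate") <- degen
  astar
}

.criticalAlphaMatrix <- function(panel) {
  p <- .panelParts(panel)
  ca <- criticalAlpha(p$M_bs, p$U_bs, p$M_oxbs, p$U_oxbs)
  attr(ca, "degenerate") <- NULL
  ca[p$mask] <- NA_real_
  dim(ca) <- dim(p$mask); dimnames(ca) <- dimnames(p$mask)
  ca
}

#' Per-sample fraction of probes whose delta-beta sign can change
#'
#' For each sample, the fraction of unmasked probes possessing a finite
#' sign-change offset \eqn{\alpha^*} in \code{(0, alphaMax]}. Probes masked
#' for any required intensity are excluded from numerator and denominator.
#' \code{alphaMax} operationalises "may change its sign" and is a required,
#' reported parameter; pass \code{Inf} to count existence of any finite
#' crossing.
#'
#' @param panel an \linkS4class{HmcPanel}.
#' @param alphaMax positive upper bound on the offsets considered.
#' @return named numeric vector of per-sample proportions in [0, 1].
#' @export
signChangeFraction <- function(panel, alphaMax) {
  stopifnot(length(alphaMax) == 1L, alphaMax > 0)
  ca <- .criticalAlphaMatrix(panel)
  mask <- assay(panel, "mask")
  hit <- !is.na(ca) & ca <= alphaMax
  num <- colSums(hit & !mask)
  den <- colSums(!mask)
  out <- ifelse(den > 0, num / den, NA_real_)
  names(out) <- colnames(panel)
  out
}

#' Default offset grid for alpha scans
#'
#' The canonical displayed offsets \{0, 100, 500, 2000\} extended
#' log-uniformly up to \code{alphaMax}.
#'
#' @param alphaMax positive upper end of the grid.
#' @param nExtra number of log-uniform points added above 2000.
#' @return strictly increasing non-negative numeric vector.
#' @export
defaultAlphaGrid <- function(alphaMax, nExtra = 6) {
  base <- c(0, 100, 500, 2000)
  g <- base[base <= alphaMax]
  if (alphaMax > 2000 && nExtra > 0)
    g <- c(g, exp(seq(log(2000), log(alphaMax), length.out = nExtra + 1))[-1])
  sort(unique(c(g, alphaMax)))
}

#' Limit diagnostics of delta-beta and delta-m over an offset grid
#'
#' Quantifies the large-offset behaviour of the offset-dependent measures on
#' a panel: \eqn{\Delta\beta(\alpha)} vanishes as \eqn{\alpha} grows (like
#' \eqn{(M_{BS}-M_{oxBS})/\alpha}), \eqn{\Delta m(\alpha)} converges to the
#' offset-free log-ratio, and the positive-call set
#' \eqn{\{\Delta\beta(\alpha) > 0\}} converges to \eqn{\{M_{BS} > M_{oxBS}\}}
#' once \eqn{\alpha} exceeds every finite sign-change offset in the panel.
#'
#' @param panel an \linkS4class{HmcPanel}.
#' @param alphaGrid strictly increasing non-negative offsets; default
#'   \code{defaultAlphaGrid(alphaMax)}.
#' @param alphaMax upper bound used for the sign-change fractions.
#' @return an \linkS4class{AlphaScan}.
#' @export
limitDiagnostics <- function(panel, alphaGrid = NULL, alphaMax = 10000) {
  if (is.null(alphaGrid)) alphaGrid <- defaultAlphaGrid(alphaMax)
  stopifnot(all(alphaGrid >= 0), !is.unsorted(alphaGrid, strictly = TRUE))
  p <- .panelParts(panel)
  mask <- p$mask
  dmi <- deltaMInf(panel)
  maxAbs <- numeric(length(alphaGrid))
  disc <- integer(length(alphaGrid))
  gap <- numeric(length(alphaGrid))
  mref <- p$M_bs > p$M_oxbs
  for (i in seq_along(alphaGrid)) {
    a <- alphaGrid[i]
    db <- deltaBeta(panel, a)
    v <- db@values[!db@mask]
    maxAbs[i] <- if (length(v)) max(abs(v)) else NA_real_
    disc[i] <- sum(((db@values > 0) != mref)[!db@mask])
    dm <- deltaM(panel, a)
    both <- !dm@mask & !dmi@mask
    gap[i] <- if (any(both)) max(abs(dm@values[both] - dmi@values[both]))
              else NA_real_
  }
  new("AlphaScan", alphaGrid = as.numeric(alphaGrid), alphaMax = alphaMax,
      signChangeFraction = signChangeFraction(panel, alphaMax),
      criticalAlpha = .criticalAlphaMatrix(panel),
      maxAbsDeltaBeta = maxAbs, limitDiscordance = disc, maxDeltaMGap = gap)
}

#' @rdname AlphaScan-class
#' @param x an \code{AlphaScan}.
#' @return \code{alphaGrid}: the offset grid; \code{criticalAlphaMatrix}: the
#'   probe-by-sample sign-change offsets; \code{scanSignChangeFraction}: the
#'   per-sample fractions; \code{limitDiscordance}: per-alpha counts of
#'   disagreement between the positive set and \{M_BS > M_oxBS\};
#'   \code{maxAbsDeltaBeta} and \code{maxDeltaMGap}: per-alpha suprema
#'   tracking the two convergence laws.
#' @export
alphaGrid <- function(x) x@alphaGrid

#' @rdname AlphaScan-class
#' @export
criticalAlphaMatrix <- function(x) x@criticalAlpha

#' @rdname AlphaScan-class
#' @export
scanSignChangeFraction <- function(x) x@signChangeFraction

#' @rdname AlphaScan-class
#' @export
limitDiscordance <- function(x) x@limitDiscordance

#' @rdname AlphaScan-class
#' @export
maxAbsDeltaBeta <- function(x) x@maxAbsDeltaBeta

#' @rdname AlphaScan-class
#' @export
maxDeltaMGap <- function(x) x@maxDeltaMGap
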