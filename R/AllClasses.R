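#' @import methods
#' @importFrom stats rbeta rlnorm runif wilcox.test median p.adjust
#' @importFrom utils read.delim write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames
#' @importFrom S4Vectors metadata metadata<- SimpleList
NULL

.MEASURE_NAMES <- c("beta", "m", "delta_beta", "delta_m",
                    "delta_m_inf", "delta_h", "naive_5hmc")
# measures parameterised by the beta-value offset alpha
.ALPHA_MEASURES <- c("beta", "m", "delta_beta", "delta_m")
.TISSUES <- c("healthy", "cancer", "unspecified")

# ---------------------------------------------------------------------------
# HmcPanel: paired BS/oxBS intensity container
# ---------------------------------------------------------------------------

#' Paired BS/oxBS intensity panel
#'
#' An \code{HmcPanel} holds the four probe-by-sample intensity matrices of a
#' paired bisulfite (BS) / oxidative-bisulfite (oxBS) 450k experiment:
#' methylated and unmethylated allele intensities under each treatment.
#' It extends \linkS4class{SummarizedExperiment} with assays
#' \code{M_bs}, \code{U_bs}, \code{M_oxbs}, \code{U_oxbs} and a logical
#' \code{mask} assay marking invalid entries (\code{TRUE} = masked).
#' The tissue label is kept in \code{metadata(x)$tissue}.
#'
#' Unmasked intensities must be finite and non-negative; probe and sample
#' identifiers must be unique. Masks are propagated by union through every
#' downstream measure, so masked entries never enter any denominator.
#'
#' @slot .Data inherited \code{SummarizedExperiment} structure.
#' @seealso \code{\link{HmcPanel}}, \code{\link{readPanel}}
#' @export
setClass("HmcPanel", contains = "SummarizedExperiment")

.validHmcPanel <- function(object) {
  msg <- character()
  need <- c("M_bs", "U_bs", "M_oxbs", "U_oxbs", "mask")
  if (!all(need %in% assayNames(object)))
    return(paste("missing assays:",
                 paste(setdiff(need, assayNames(object)), collapse = ", ")))
  msk <- assay(object, "mask")
  if (!is.logical(msk))
    msg <- c(msg, "'mask' assay must be logical")
  for (nm in need[1:4]) {
    a <- assay(object, nm)
    ok <- msk | (is.finite(a) & a >= 0)
    if (!all(ok, na.rm = FALSE) || anyNA(ok))
      msg <- c(msg, sprintf("assay '%s' has non-finite or negative unmasked entries", nm))
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated probe ids")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicated sample ids")
  tis <- metadata(object)$tissue
  if (is.null(tis) || !tis %in% .TISSUES)
    msg <- c(msg, "metadata(x)$tissue must be one of 'healthy', 'cancer', 'unspecified'")
  if (length(msg)) msg else TRUE
}
setValidity("HmcPanel", .validHmcPanel)

#' Construct an HmcPanel
#'
#' @param M_bs,U_bs,M_oxbs,U_oxbs numeric probe-by-sample matrices of
#'   methylated/unmethylated allele intensities under BS and oxBS treatment,
#'   in arbitrary fluorescence units. All four must share dimensions and
#'   dimnames.
#' @param tissue tissue label, one of \code{"healthy"}, \code{"cancer"},
#'   \code{"unspecified"}.
#' @param mask optional logical matrix; \code{TRUE} marks an invalid entry.
#'   Defaults to all-\code{FALSE}.
#' @return an \linkS4class{HmcPanel}.
#' @examples
#' m <- matrix(100, 2, 2, dimnames = list(c("cg1","cg2"), c("s1","s2")))
#' p <- HmcPanel(m, m, m, m, tissue = "healthy")
#' dim(p)
#' @export
HmcPanel <- function(M_bs, U_bs, M_oxbs, U_oxbs,
                     tissue = c("unspecified", "healthy", "cancer"),
                     mask = NULL) {
  tissue <- match.arg(tissue)
  M_bs <- as.matrix(M_bs); U_bs <- as.matrix(U_bs)
  M_oxbs <- as.matrix(M_oxbs); U_oxbs <- as.matrix(U_oxbs)
  dims <- list(dim(M_bs), dim(U_bs), dim(M_oxbs), dim(U_oxbs))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("the four intensity matrices must share dimensions")
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow(M_bs), ncol(M_bs), dimnames = dimnames(M_bs))
  } else {
    mask <- as.matrix(mask)
    storage.mode(mask) <- "logical"
  }
  # any non-finite or negative raw cell is masked rather than rejected
  bad <- !(is.finite(M_bs) & M_bs >= 0) | !(is.finite(U_bs) & U_bs >= 0) |
         !(is.finite(M_oxbs) & M_oxbs >= 0) | !(is.finite(U_oxbs) & U_oxbs >= 0)
  mask <- mask | bad
  zero <- function(a) { a[!is.finite(a) | a < 0] <- 0; a }
  se <- SummarizedExperiment(
    assays = SimpleList(M_bs = zero(M_bs), U_bs = zero(U_bs),
                        M_oxbs = zero(M_oxbs), U_oxbs = zero(U_oxbs),
                        mask = mask))
  metadata(se)$tissue <- tissue
  new("HmcPanel", se)
}

setMethod("show", "HmcPanel", function(object) {
  cat(sprintf("HmcPanel: %d probes x %d samples, tissue = %s\n",
              nrow(object), ncol(object), metadata(object)$tissue))
  cat(sprintf("  masked entries: %d of %d\n",
              sum(assay(object, "mask")), length(assay(object, "mask"))))
})

# ---------------------------------------------------------------------------
# MeasureMatrix
# ---------------------------------------------------------------------------

#' Probe-by-sample matrix of one 5hmC measure
#'
#' Holds the values of a named hydroxymethylation measure together with the
#' offset alpha used (when the measure depends on one) and a logical mask of
#' undefined entries. For the total-intensity loss measure (\code{delta_h}),
#' the \code{noise} slot flags negative values, which are retained but treated
#' as measurement noise.
#'
#' @slot measure measure name, one of \code{beta}, \code{m}, \code{delta_beta},
#'   \code{delta_m}, \code{delta_m_inf}, \code{delta_h}, \code{naive_5hmc}.
#' @slot alpha the beta-value offset used; \code{numeric(0)} for offset-free
#'   measures.
#' @slot values numeric probe-by-sample matrix.
#' @slot mask logical matrix, \code{TRUE} where the measure is undefined.
#' @slot noise logical matrix flagging noise entries (negative \code{delta_h}).
#' @export
setClass("MeasureMatrix",
  representation(measure = "character", alpha = "numeric",
                 values = "matrix", mask = "matrix", noise = "matrix"))

.validMeasureMatrix <- function(object) {
  msg <- character()
  if (length(object@measure) != 1L || !object@measure %in% .MEASURE_NAMES)
    msg <- c(msg, "unknown measure name")
  has_alpha <- length(object@alpha) == 1L
  if (object@measure %in% .ALPHA_MEASURES) {
    if (!has_alpha || !is.finite(object@alpha) || object@alpha < 0)
      msg <- c(msg, "alpha must be a single non-negative number for this measure")
  } else if (has_alpha) {
    msg <- c(msg, "alpha must be absent for offset-free measures")
  }
  if (!identical(dim(object@values), dim(object@mask)))
    msg <- c(msg, "values and mask dimensions differ")
  if (!identical(dim(object@values), dim(object@noise)))
    msg <- c(msg, "values and noise dimensions differ")
  v <- object@values[!object@mask]
  if (length(v)) {
    if (object@measure == "delta_beta" && any(v < -1 | v > 1))
      msg <- c(msg, "delta_beta values outside [-1, 1]")
    if (object@measure == "beta" && any(v < 0 | v > 1))
      msg <- c(msg, "beta values outside [0, 1]")
    if (object@measure == "delta_h" && any(v > 1))
      msg <- c(msg, "delta_h values above 1")
    if (any(!is.finite(v)))
      msg <- c(msg, "non-finite unmasked values")
  }
  if (length(msg)) msg else TRUE
}
setValidity("MeasureMatrix", .validMeasureMatrix)

.MeasureMatrix <- function(measure, values, mask, alpha = numeric(0),
                           noise = NULL) {
  storage.mode(mask) <- "logical"
  values[mask] <- NA_real_
  if (is.null(noise))
    noise <- matrix(FALSE, nrow(values), ncol(values), dimnames = dimnames(values))
  storage.mode(noise) <- "logical"
  new("MeasureMatrix", measure = measure, alpha = alpha,
      values = values, mask = mask, noise = noise)
}

setMethod("show", "MeasureMatrix", function(object) {
  al <- if (length(object@alpha)) sprintf(", alpha = %g", object@alpha) else ""
  cat(sprintf("MeasureMatrix '%s'%s: %d probes x %d samples (%d masked)\n",
              object@measure, al, nrow(object@values), ncol(object@values),
              sum(object@mask)))
})

#' @rdname MeasureMatrix-class
#' @param x a \code{MeasureMatrix}.
#' @return \code{measureValues}: the numeric matrix with masked entries
#'   \code{NA}; \code{measureMask}: the logical mask; \code{measureName}: the
#'   measure name; \code{alphaOffset}: the offset or \code{numeric(0)};
#'   \code{noiseFlag}: logical matrix of noise-flagged entries.
#' @export
measureValues <- function(x) { v <- x@values; v[x@mask] <- NA_real_; v }

#' @rdname MeasureMatrix-class
#' @export
measureMask <- function(x) x@mask

#' @rdname MeasureMatrix-class
#' @export
measureName <- function(x) x@measure

#' @rdname MeasureMatrix-class
#' @export
alphaOffset <- function(x) x@alpha

#' @rdname MeasureMatrix-class
#' @export
noiseFlag <- function(x) x@noise

# ---------------------------------------------------------------------------
# CallMatrix
# ---------------------------------------------------------------------------

#' Binary screening calls
#'
#' Probe-by-sample logical calls derived from one 5hmC measure: a probe/sample
#' entry is called positive (flagged hydroxymethylated) iff its unmasked
#' measure value is strictly greater than the threshold.
#'
#' @slot measure the measure the calls derive from.
#' @slot threshold the decision cut (default 0 upstream).
#' @slot calls logical matrix of positive calls.
#' @slot mask logical matrix of undefined entries.
#' @export
setClass("CallMatrix",
  representation(measure = "character", threshold = "numeric",
                 calls = "matrix", mask = "matrix"))

setValidity("CallMatrix", function(object) {
  msg <- character()
  if (!is.logical(object@calls)) msg <- c(msg, "calls must be logical")
  if (!identical(dim(object@calls), dim(object@mask)))
    msg <- c(msg, "calls and mask dimensions differ")
  if (length(object@threshold) != 1L || !is.finite(object@threshold))
    msg <- c(msg, "threshold must be a single finite number")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CallMatrix", function(object) {
  cat(sprintf("CallMatrix (%s > %g): %d probes x %d samples, %d positive (%d masked)\n",
              object@measure, object@threshold, nrow(object@calls),
              ncol(object@calls), sum(object@calls & !object@mask),
              sum(object@mask)))
})

#' @rdname CallMatrix-class
#' @param x a \code{CallMatrix}.
#' @return \code{calls}: logical matrix (masked entries \code{NA});
#'   \code{callMask}: the mask; \code{callThreshold}: the threshold.
#' @export
calls <- function(x) { cc <- x@calls; cc[x@mask] <- NA; cc }

#' @rdname CallMatrix-class
#' @export
callMask <- function(x) x@mask

#' @rdname CallMatrix-class
#' @export
callThreshold <- function(x) x@threshold

# ---------------------------------------------------------------------------
# PrevalenceSummary
# ---------------------------------------------------------------------------

#' Prevalence of positive screening calls
#'
#' Per-sample (fraction of CpGs positive within a sample) or per-probe
#' (fraction of samples positive at a CpG; the hydroxymethylation level of
#' that CpG) prevalence of positive calls, with the number of unmasked calls
#' entering each denominator.
#'
#' @slot axis \code{"per_sample"} or \code{"per_probe"}.
#' @slot measure name of the underlying measure (or pair, for joint prevalence).
#' @slot proportions named numeric vector in [0, 1].
#' @slot denominators named integer vector of unmasked-call counts.
#' @export
setClass("PrevalenceSummary",
  representation(axis = "character", measure = "character",
                 proportions = "numeric", denominators = "integer"))

setValidity("PrevalenceSummary", function(object) {
  msg <- character()
  if (!object@axis %in% c("per_sample", "per_probe"))
    msg <- c(msg, "axis must be 'per_sample' or 'per_probe'")
  p <- object@proportions
  if (any(!is.finite(p) | p < 0 | p > 1))
    msg <- c(msg, "proportions must lie in [0, 1]")
  if (length(p) != length(object@denominators))
    msg <- c(msg, "proportions/denominators length mismatch")
  if (any(object@denominators <= 0L))
    msg <- c(msg, "denominators must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PrevalenceSummary", function(object) {
  cat(sprintf("PrevalenceSummary [%s, %s]: %d units, median %.3f\n",
              object@measure, object@axis, length(object@proportions),
              stats::median(object@proportions)))
})

#' @rdname PrevalenceSummary-class
#' @param x a \code{PrevalenceSummary}.
#' @return \code{proportions}: named numeric vector; \code{denominators}:
#'   named integer vector; \code{prevalenceAxis}: the axis.
#' @export
proportions <- function(x) x@proportions

#' @rdname PrevalenceSummary-class
#' @export
denominators <- function(x) x@denominators

#' @rdname PrevalenceSummary-class
#' @export
prevalenceAxis <- function(x) x@axis

# ---------------------------------------------------------------------------
# ConcordanceTable
# ---------------------------------------------------------------------------

#' Pairwise concordance of two 5hmC measures
#'
#' Unit-wise values of one concordance statistic between the binary calls of
#' two measures, with an overall expectation estimate. Units are either
#' probes (statistic computed across samples) or samples (across probes).
#' Statistics: simple matching coefficient \code{S}, Hamann coefficient
#' \code{SH}, relative sensitivity \code{SE_r}, relative specificity
#' \code{SP_r}, relative false discovery rate \code{FDR_r}.
#'
#' For \code{SE_r}/\code{SP_r}/\code{FDR_r} the pair is ordered: the statistic
#' refers to \code{pair[1]} conditioned on (or relative to) \code{pair[2]}.
#'
#' @slot pair character(2): the two measure names.
#' @slot tissue tissue label.
#' @slot axis \code{"per_probe_across_samples"} or
#'   \code{"per_sample_across_probes"}.
#' @slot statistic one of \code{S}, \code{SH}, \code{SE_r}, \code{SP_r},
#'   \code{FDR_r}.
#' @slot values named numeric vector, one value per unit (\code{NA} where the
#'   unit is undefined, e.g. an empty conditioning set).
#' @slot expectation overall expectation estimate.
#' @slot expectationMethod \code{"empirical_mean"} or \code{"independence_null"}.
#' @slot degenerate logical per-unit flag: \code{TRUE} where the unit has no
#'   jointly-positive call yet a positive similarity (the degenerate-matching
#'   caveat; consult \code{SH} there).
#' @export
setClass("ConcordanceTable",
  representation(pair = "character", tissue = "character", axis = "character",
                 statistic = "character", values = "numeric",
                 expectation = "numeric", expectationMethod = "character",
                 degenerate = "logical"))

setValidity("ConcordanceTable", function(object) {
  msg <- character()
  if (length(object@pair) != 2L) msg <- c(msg, "pair must have length 2")
  if (!object@statistic %in% c("S", "SH", "SE_r", "SP_r", "FDR_r"))
    msg <- c(msg, "unknown statistic")
  if (!object@axis %in% c("per_probe_across_samples", "per_sample_across_probes"))
    msg <- c(msg, "unknown axis")
  v <- object@values[!is.na(object@values)]
  rng <- switch(object@statistic, SH = c(-1, 1), c(0, 1))
  if (length(v) && any(v < rng[1] - 1e-12 | v > rng[2] + 1e-12))
    msg <- c(msg, sprintf("%s values outside [%g, %g]", object@statistic,
                          rng[1], rng[2]))
  if (length(object@degenerate) != length(object@values))
    msg <- c(msg, "degenerate flag length mismatch")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ConcordanceTable", function(object) {
  cat(sprintf("ConcordanceTable %s(%s, %s) [%s, %s]: %d units, E = %.4f (%s)\n",
              object@statistic, object@pair[1], object@pair[2], object@tissue,
              object@axis, length(object@values), object@expectation,
              object@expectationMethod))
  if (any(object@degenerate, na.rm = TRUE))
    cat(sprintf("  %d degenerate unit(s): no joint positives yet S > 0\n",
                sum(object@degenerate, na.rm = TRUE)))
})

#' @rdname ConcordanceTable-class
#' @param x a \code{ConcordanceTable}.
#' @return \code{concordanceValues}: named numeric per-unit values;
#'   \code{expectation}: the overall expectation; \code{degenerateUnits}:
#'   logical per-unit degeneracy flags.
#' @export
concordanceValues <- function(x) x@values

#' @rdname ConcordanceTable-class
#' @export
expectation <- function(x) x@expectation

#' @rdname ConcordanceTable-class
#' @export
degenerateUnits <- function(x) x@degenerate

# ---------------------------------------------------------------------------
# AlphaScan
# ---------------------------------------------------------------------------

#' Result of an alpha-sensitivity scan
#'
#' Characterises the offset dependence of the difference-of-proportions
#' measure on a panel: per-probe/sample closed-form sign-change points, the
#' per-sample fraction of probes whose sign can change below \code{alphaMax},
#' and per-grid-alpha diagnostics of the large-alpha limit behaviour.
#'
#' @slot alphaGrid increasing non-negative grid of offsets.
#' @slot alphaMax upper bound used for the sign-change fractions.
#' @slot signChangeFraction named per-sample proportions in [0, 1].
#' @slot criticalAlpha probe-by-sample matrix of sign-change offsets
#'   (\code{NA} where none exists in (0, Inf)).
#' @slot maxAbsDeltaBeta per-grid-alpha maximum |delta-beta(alpha)| over
#'   unmasked entries.
#' @slot limitDiscordance per-grid-alpha count of unmasked entries where
#'   the positive-call set {delta-beta(alpha) > 0} disagrees with
#'   {M_BS > M_oxBS}.
#' @slot maxDeltaMGap per-grid-alpha maximum |delta-m(alpha) - delta-m-inf|
#'   over entries where both are defined.
#' @export
setClass("AlphaScan",
  representation(alphaGrid = "numeric", alphaMax = "numeric",
                 signChangeFraction = "numeric", criticalAlpha = "matrix",
                 maxAbsDeltaBeta = "numeric", limitDiscordance = "integer",
                 maxDeltaMGap = "numeric"))

setValidity("AlphaScan", function(object) {
  msg <- character()
  g <- object@alphaGrid
  if (length(g) && (any(g < 0) || is.unsorted(g, strictly = TRUE)))
    msg <- c(msg, "alphaGrid must be strictly increasing and non-negative")
  f <- object@signChangeFraction
  if (any(!is.finite(f) | f < 0 | f > 1))
    msg <- c(msg, "signChangeFraction outside [0, 1]")
  ca <- object@criticalAlpha[!is.na(object@criticalAlpha)]
  if (length(ca) && any(ca <= 0 | !is.finite(ca)))
    msg <- c(msg, "criticalAlpha entries must be strictly positive and finite")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AlphaScan", function(object) {
  cat(sprintf("AlphaScan: grid of %d alphas (max %g), alphaMax = %g\n",
              length(object@alphaGrid), max(object@alphaGrid), object@alphaMax))
  cat(sprintf("  sign-change fraction: median %.4f over %d samples\n",
              stats::median(object@signChangeFraction),
              length(object@signChangeFraction)))
})

# ---------------------------------------------------------------------------
# SimulationConfig
# ---------------------------------------------------------------------------

#' Configuration of the paired BS/oxBS intensity simulator
#'
#' Full parameterisation of the synthetic paired-intensity generator,
#' including the seed; identical configurations produce identical panels.
#' See \code{\link{simulatePanels}} for the generative model.
#'
#' @slot nProbes,nSamples panel dimensions.
#' @slot seed RNG seed (mandatory).
#' @slot p5mcShape1,p5mcShape2 Beta parameters of the per-probe 5mC proportion.
#' @slot p5hmcShape1,p5hmcShape2 Beta parameters of the per-probe 5hmC
#'   proportion (truncated so that p5mC + p5hmC <= 1).
#' @slot p5hmcFixed optional fixed 5hmC proportion overriding the Beta draw.
#' @slot depthMeanLog,depthSdLog log-normal parameters of the per-probe/sample
#'   total-intensity scale.
#' @slot background additive non-negative intensity offset.
#' @slot attenuationGamma in [0, 1]: oxBS total-intensity loss per unit of
#'   5hmC proportion.
#' @slot cancerDepletion in [0, 1]: multiplicative 5hmC depletion in the
#'   cancer arm.
#' @slot noiseCV coefficient of variation of multiplicative log-normal noise.
#' @slot maxTries bound on Beta truncation resampling.
#' @export
setClass("SimulationConfig",
  representation(nProbes = "integer", nSamples = "integer", seed = "integer",
                 p5mcShape1 = "numeric", p5mcShape2 = "numeric",
                 p5hmcShape1 = "numeric", p5hmcShape2 = "numeric",
                 p5hmcFixed = "numeric",
                 depthMeanLog = "numeric", depthSdLog = "numeric",
                 background = "numeric", attenuationGamma = "numeric",
                 cancerDepletion = "numeric", noiseCV = "numeric",
                 maxTries = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nProbes < 1L || object@nSamples < 1L)
    msg <- c(msg, "nProbes and nSamples must be positive")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed is mandatory")
  if (any(c(object@p5mcShape1, object@p5mcShape2,
            object@p5hmcShape1, object@p5hmcShape2) <= 0))
    msg <- c(msg, "Beta shape parameters must be positive")
  if (length(object@p5hmcFixed) == 1L &&
      (object@p5hmcFixed < 0 || object@p5hmcFixed > 1))
    msg <- c(msg, "p5hmcFixed must lie in [0, 1]")
  if (object@background < 0) msg <- c(msg, "background must be >= 0")
  if (object@attenuationGamma < 0 || object@attenuationGamma > 1)
    msg <- c(msg, "attenuationGamma must lie in [0, 1]")
  if (object@cancerDepletion < 0 || object@cancerDepletion > 1)
    msg <- c(msg, "cancerDepletion must lie in [0, 1]")
  if (object@noiseCV < 0) msg <- c(msg, "noiseCV must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: %d probes x %d samples, seed %d\n",
                     "  gamma = %g, cancerDepletion = %g, noiseCV = %g, ",
                     "background = %g\n"),
              object@nProbes, object@nSamples, object@seed,
              object@attenuationGamma, object@cancerDepletion,
              object@noiseCV, object@background))
})
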