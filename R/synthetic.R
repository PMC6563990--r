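# Paired BS/oxBS intensity simulator with known per-probe 5mC/5hmC ground
# truth, plus deterministic counterexample constructions for the
# interpretation pitfalls of the difference-of-proportions measure.

#' Construct a SimulationConfig
#'
#' Parameters of the paired-intensity generator. Defaults emulate raw 450k
#' colorectal data: a roughly bimodal per-probe 5mC proportion
#' (Beta(0.4, 0.4)), a low 5hmC proportion (Beta(1, 40), mean 0.024),
#' fluorescence totals in the low thousands (log-normal, median ~3000),
#' a small additive background, oxBS total-intensity attenuation
#' proportional to the 5hmC level (gamma = 0.5), two-fold 5hmC depletion in
#' the cancer arm, and 10\% multiplicative measurement noise.
#'
#' @param nProbes,nSamples panel dimensions.
#' @param seed RNG seed (mandatory; identical configs give identical panels).
#' @param p5mcShape1,p5mcShape2 Beta parameters of the 5mC proportion.
#' @param p5hmcShape1,p5hmcShape2 Beta parameters of the 5hmC proportion.
#' @param p5hmcFixed optional single value in [0, 1] fixing the 5hmC
#'   proportion of every probe (overrides the Beta draw).
#' @param depthMeanLog,depthSdLog log-normal depth-scale parameters.
#' @param background additive non-negative intensity offset.
#' @param attenuationGamma oxBS total-intensity loss per unit 5hmC, in [0, 1].
#' @param cancerDepletion multiplicative 5hmC depletion in the cancer arm.
#' @param noiseCV coefficient of variation of multiplicative noise.
#' @param maxTries bound on truncation resampling for p5mC + p5hmC <= 1.
#' @return a \linkS4class{SimulationConfig}.
#' @export
SimulationConfig <- function(nProbes, nSamples, seed,
                             p5mcShape1 = 0.4, p5mcShape2 = 0.4,
                             p5hmcShape1 = 1, p5hmcShape2 = 40,
                             p5hmcFixed = numeric(0),
                             depthMeanLog = log(3000), depthSdLog = 0.4,
                             background = 50, attenuationGamma = 0.5,
                             cancerDepletion = 0.5, noiseCV = 0.1,
                             maxTries = 100L) {
  new("SimulationConfig",
      nProbes = as.integer(nProbes), nSamples = as.integer(nSamples),
      seed = as.integer(seed),
      p5mcShape1 = p5mcShape1, p5mcShape2 = p5mcShape2,
      p5hmcShape1 = p5hmcShape1, p5hmcShape2 = p5hmcShape2,
      p5hmcFixed = as.numeric(p5hmcFixed),
      depthMeanLog = depthMeanLog, depthSdLog = depthSdLog,
      background = background, attenuationGamma = attenuationGamma,
      cancerDepletion = cancerDepletion, noiseCV = noiseCV,
      maxTries = as.integer(maxTries))
}

# multiplicative log-normal noise with mean 1 and coefficient of variation cv
.noiseFactor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdl <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
}

.drawProportions <- function(config) {
  np <- config@nProbes
  p5mc <- stats::rbeta(np, config@p5mcShape1, config@p5mcShape2)
  if (length(config@p5hmcFixed) == 1L) {
    p5hmc <- rep(config@p5hmcFixed, np)
    bad <- p5mc + p5hmc > 1
    tries <- 0L
    while (any(bad)) {   # resample 5mC under a fixed 5hmC level
      tries <- tries + 1L
      if (tries > config@maxTries)
        stop("truncation p5mC + p5hmC <= 1 infeasible after maxTries resamples")
      p5mc[bad] <- stats::rbeta(sum(bad), config@p5mcShape1, config@p5mcShape2)
      bad <- p5mc + p5hmc > 1
    }
  } else {
    p5hmc <- stats::rbeta(np, config@p5hmcShape1, config@p5hmcShape2)
    bad <- p5mc + p5hmc > 1
    tries <- 0L
    while (any(bad)) {   # resample the pair jointly, keeping marginals Beta
      tries <- tries + 1L
      if (tries > config@maxTries)
        stop("truncation p5mC + p5hmC <= 1 infeasible after maxTries resamples")
      p5mc[bad] <- stats::rbeta(sum(bad), config@p5mcShape1, config@p5mcShape2)
      p5hmc[bad] <- stats::rbeta(sum(bad), config@p5hmcShape1,
                                 config@p5hmcShape2)
      bad <- p5mc + p5hmc > 1
    }
  }
  list(p5mc = p5mc, p5hmc = p5hmc)
}

.simulateArm <- function(config, p5mc, p5hmc, sample_ids, probe_ids) {
  np <- config@nProbes; ns <- config@nSamples
  n <- np * ns
  cv <- config@noiseCV; bg <- config@background; g <- config@attenuationGamma
  depth <- matrix(stats::rlnorm(n, config@depthMeanLog, config@depthSdLog),
                  np, ns)
  P5 <- matrix(p5mc, np, ns); H5 <- matrix(p5hmc, np, ns)
  e1 <- matrix(.noiseFactor(n, cv), np, ns)
  e2 <- matrix(.noiseFactor(n, cv), np, ns)
  e3 <- matrix(.noiseFactor(n, cv), np, ns)
  e4 <- matrix(.noiseFactor(n, cv), np, ns)
  att <- 1 - g * H5
  M_bs <- depth * (P5 + H5) * e1 + bg
  U_bs <- depth * (1 - P5 - H5) * e2 + bg
  M_ox <- depth * att * P5 * e3 + bg
  U_ox <- depth * att * (1 - P5) * e4 + bg
  dn <- list(probe_ids, sample_ids)
  dimnames(M_bs) <- dimnames(U_bs) <- dimnames(M_ox) <- dimnames(U_ox) <- dn
  list(M_bs = M_bs, U_bs = U_bs, M_oxbs = M_ox, U_oxbs = U_ox)
}

#' Simulate paired healthy/cancer BS/oxBS intensity panels
#'
#' Generates matched healthy and cancer panels from latent per-probe 5mC and
#' 5hmC proportions. For probe i and sample j, with depth D drawn log-normal
#' and epsilon multiplicative noise of coefficient of variation
#' \code{noiseCV}:
#' \deqn{M_{BS} = D (p_{5mC}+p_{5hmC}) \epsilon + bg, \quad
#'       U_{BS} = D (1-p_{5mC}-p_{5hmC}) \epsilon' + bg}
#' \deqn{M_{oxBS} = D (1-\gamma p_{5hmC}) p_{5mC} \epsilon'' + bg, \quad
#'       U_{oxBS} = D (1-\gamma p_{5hmC}) (1-p_{5mC}) \epsilon''' + bg}
#' The attenuation \eqn{\gamma} encodes the assumption that a substantial
#' 5hmC level depresses the overall oxBS intensity (so the total-intensity
#' measure carries signal; \eqn{\gamma = 0} gives a world where it carries
#' none). The cancer arm shares each probe's 5mC proportion and depletes its
#' 5hmC proportion by \code{cancerDepletion}; depths and noise are drawn
#' independently per arm. Identical configs (seed included) give identical
#' output.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with elements \code{healthy} and \code{cancer}
#'   (\linkS4class{HmcPanel}s) and \code{truth}, a data.frame of per-probe
#'   \code{p5mc}, \code{p5hmc_healthy}, \code{p5hmc_cancer}.
#' @examples
#' sim <- simulatePanels(SimulationConfig(50, 4, seed = 1))
#' sim$healthy
#' @export
simulatePanels <- function(config) {
  validObject(config)
  set.seed(config@seed)
  probe_ids <- sprintf("cg%07d", seq_len(config@nProbes))
  sample_ids <- sprintf("s%02d", seq_len(config@nSamples))
  pr <- .drawProportions(config)
  p5hmc_cancer <- pr$p5hmc * config@cancerDepletion
  h <- .simulateArm(config, pr$p5mc, pr$p5hmc, sample_ids, probe_ids)
  k <- .simulateArm(config, pr$p5mc, p5hmc_cancer, sample_ids, probe_ids)
  list(healthy = HmcPanel(h$M_bs, h$U_bs, h$M_oxbs, h$U_oxbs,
                          tissue = "healthy"),
       cancer = HmcPanel(k$M_bs, k$U_bs, k$M_oxbs, k$U_oxbs,
                         tissue = "cancer"),
       truth = data.frame(probe_id = probe_ids, p5mc = pr$p5mc,
                          p5hmc_healthy = pr$p5hmc,
                          p5hmc_cancer = p5hmc_cancer))
}

# Exact-zero construction: with integer intensities and an integer scale
# factor k > 1, M_ox = k * M_bs and U_ox = k * (U_bs + 100) - 100 give
# beta_bs(100) = M / (T + 100) and beta_ox(100) = k M / (k (T + 100)),
# whose IEEE quotients are identical, so delta-beta(100) is exactly 0.
.zeroBase <- function(n, seed) {
  set.seed(seed)
  M_bs <- sample(50:500, n, replace = TRUE)
  U_bs <- sample(50:1000, n, replace = TRUE)
  k <- sample(2:4, n, replace = TRUE)
  list(M_bs = as.numeric(M_bs), U_bs = as.numeric(U_bs),
       M_ox = as.numeric(k * M_bs),
       U_ox = as.numeric(k * (U_bs + 100) - 100), k = k)
}

#' Counterexample intensity points for the difference-of-proportions measure
#'
#' Deterministically constructs single-sample panels of points exposing the
#' interpretation pitfalls of the conventional screening measure at offset
#' 100:
#' \describe{
#'   \item{\code{spurious_positive}}{both BS intensities lie below their
#'     oxBS counterparts (no 5hmC signal by intensity comparison), yet
#'     \eqn{\Delta\beta(100) > 0}: the measure flags them.}
#'   \item{\code{spurious_negative}}{both BS intensities exceed their oxBS
#'     counterparts (a clear 5hmC signal), yet \eqn{\Delta\beta(100) < 0}:
#'     the measure rejects them.}
#'   \item{\code{ambiguous_zero}}{BS intensities below oxBS with
#'     \eqn{\Delta\beta(100) = 0} exactly, built from the proportionality
#'     condition \eqn{M_{BS}/M_{oxBS} = (U_{BS}+100)/(U_{oxBS}+100}).}
#' }
#' Every generated point is verified against its defining inequalities
#' before return; a construction failure is an error (it cannot occur with
#' the documented construction).
#'
#' @param kind which pitfall to construct.
#' @param nPoints number of points (probes); default 10.
#' @param seed RNG seed for the randomised base intensities.
#' @return a single-sample \linkS4class{HmcPanel}.
#' @export
demoPoints <- function(kind = c("spurious_positive", "spurious_negative",
                                "ambiguous_zero"),
                       nPoints = 10, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(nPoints >= 1)
  z <- .zeroBase(nPoints, seed)
  if (kind == "ambiguous_zero") {
    M_bs <- z$M_bs; U_bs <- z$U_bs; M_ox <- z$M_ox; U_ox <- z$U_ox
  } else if (kind == "spurious_positive") {
    # push U_ox above the exact-zero value: beta_ox drops, delta-beta > 0,
    # and both BS intensities stay below their oxBS counterparts
    delta <- sample(50:500, nPoints, replace = TRUE)
    M_bs <- z$M_bs; U_bs <- z$U_bs; M_ox <- z$M_ox; U_ox <- z$U_ox + delta
  } else {
    # mirror construction: scale the BS side up and inflate U_bs
    M_ox <- z$M_bs; U_ox <- z$U_bs
    M_bs <- z$M_ox; U_bs <- z$U_ox + sample(50:500, nPoints, replace = TRUE)
  }
  db <- betaValue(M_bs, U_bs, 100) - betaValue(M_ox, U_ox, 100)
  ok <- switch(kind,
    spurious_positive = all(M_bs < M_ox & U_bs < U_ox & db > 0),
    spurious_negative = all(M_bs > M_ox & U_bs > U_ox & db < 0),
    ambiguous_zero = all(M_bs < M_ox & U_bs < U_ox & db == 0))
  if (!ok) stop("counterexample construction failed verification")
  ids <- sprintf("s_%d", seq_len(nPoints))
  one <- function(v) matrix(v, ncol = 1, dimnames = list(ids, "sample1"))
  HmcPanel(one(M_bs), one(U_bs), one(M_ox), one(U_ox))
}
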