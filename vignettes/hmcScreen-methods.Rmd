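---
title: "Screening for hydroxymethylated CpGs from paired BS/oxBS intensities"
author: "hmcScreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for hydroxymethylated CpGs from paired BS/oxBS intensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmcScreen)
```

## The measurement problem

Bisulfite (BS) conversion reads 5-methylcytosine (5mC) and
5-hydroxymethylcytosine (5hmC) jointly as "methylated", while oxidative
bisulfite (oxBS) conversion first oxidises 5hmC so that only 5mC survives as
a methylated readout. On an Infinium 450k array each treatment yields, per
CpG probe and sample, a methylated and an unmethylated fluorescence
intensity, $M$ and $U$. The 5hmC level at a CpG is therefore only available
as a *contrast* between the two treatments, and screening for
hydroxymethylated CpGs amounts to deciding, per probe and sample, whether
that contrast is convincingly positive.

`hmcScreen` implements three screening measures on a paired intensity panel
(`HmcPanel`, a `SummarizedExperiment` with assays `M_bs`, `U_bs`, `M_oxbs`,
`U_oxbs` and a validity mask):

* the classical difference of methylation proportions
  $\Delta\beta(\alpha) = \frac{M_{BS}}{M_{BS}+U_{BS}+\alpha} -
  \frac{M_{oxBS}}{M_{oxBS}+U_{oxBS}+\alpha}$, conventionally at
  $\alpha = 100$ (`deltaBeta`);
* the offset-free methylated-intensity log-ratio
  $\Delta m^\infty = \log_2 (M_{BS}/M_{oxBS})$ (`deltaMInf`);
* the relative loss of total intensity under oxBS,
  $\Delta h = 1 - \frac{M_{oxBS}+U_{oxBS}}{M_{BS}+U_{BS}}$ (`deltaH`).

A CpG/sample entry is *called* hydroxymethylated when the measure value is
strictly greater than a threshold (default 0; `callPositive`). Exact zeros
are non-positive: this keeps the binary partition used by the similarity
statistics unambiguous.

## Why the offset matters, and what we do about it

The offset $\alpha$ in the $\beta$-value denominator is harmless for
describing methylation proportions but not for *signing* their difference.
Writing $T = M + U$, the zero condition of $\Delta\beta(\alpha)$ is linear
in $\alpha$, so each probe/sample pair has at most one sign change on
$(0, \infty)$, at

$$\alpha^* = \frac{M_{oxBS} T_{BS} - M_{BS} T_{oxBS}}{M_{BS} - M_{oxBS}}.$$

`criticalAlpha` evaluates this closed form (validated in the test suite
against an independent bisection root-finder to 1e-8 relative tolerance);
`signChangeFraction` reports, per sample, the fraction of probes whose sign
can change below a stated `alphaMax`. Because the counting rule for "can
change sign" depends on the range of offsets one is willing to consider,
`alphaMax` is an explicit, logged parameter rather than a constant; the
default grid `defaultAlphaGrid` carries the canonical displayed offsets
{0, 100, 500, 2000} extended log-uniformly.

Three limit facts anchor the analysis (`limitDiagnostics`):
$\Delta\beta(\alpha) \approx (M_{BS}-M_{oxBS})/\alpha \to 0$;
$\Delta m(\alpha) \to \Delta m^\infty$; and the positive-call set
$\{\Delta\beta(\alpha) > 0\}$ stabilises to $\{M_{BS} > M_{oxBS}\}$ once
$\alpha$ exceeds every finite $\alpha^*$ in the panel.

**The m-value convention.** We define
$m(\alpha) = \log_2(M/(U+\alpha))$, i.e. the offset corrects the
unmethylated intensity only. This is the unique convention under which the
limit $\Delta m(\alpha) \to \log_2(M_{BS}/M_{oxBS})$ holds and under which
$\mathrm{sign}\,\Delta m(\alpha) = \mathrm{sign}\,\Delta\beta(\alpha)$ is an
algebraic identity (both reduce to the sign of
$M_{BS}(U_{oxBS}+\alpha) - M_{oxBS}(U_{BS}+\alpha)$). The more common
convention with the offset in numerator and denominator satisfies neither.
The sign equivalence is enforced as a property test over random panels and
the canonical offsets.

**Counterexamples.** `demoPoints` constructs the three classes of points
that make the naive interpretation of $\Delta\beta$ fail: both BS
intensities strictly below their oxBS counterparts yet
$\Delta\beta(100) > 0$ (`spurious_positive`); both strictly above yet
$\Delta\beta(100) < 0$ (`spurious_negative`); and `ambiguous_zero`, points
with $\Delta\beta(100) = 0$ *exactly* despite depressed BS intensities. The
zero construction uses integer intensities with
$M_{oxBS} = k M_{BS}$, $U_{oxBS} = k(U_{BS}+100)-100$ for integer
$k \in \{2,3,4\}$, which makes both $\beta$ quotients the correctly rounded
value of the same rational number, so the difference is an exact floating
point zero. The other two kinds perturb the oxBS (resp. BS) unmethylated
intensity upward from that line. Every generated point is re-verified
against its defining inequalities before return.

## Measure domains, masks, and edge cases

All operations propagate the panel mask by union and exclude masked entries
from every denominator. In addition:

* $\Delta m^\infty$ and $\Delta m(\alpha)$ require strictly positive
  methylated intensities; offending entries are masked and counted in a
  message.
* $\Delta h$ requires $M_{BS}+U_{BS} > 0$; negative values (oxBS total above
  BS total) are *retained* but flagged in `noiseFlag` as measurement noise,
  so prevalence denominators match the full set of defined entries.
* $\alpha = 0$ is admitted although the proportion definition nominally
  requires $\alpha > 0$: the zero-offset measure is needed because the
  constrained maximum-likelihood 5hmC estimators (oxBS-MLE/OxyBS), used as
  a screening device, flag exactly the CpGs with $\Delta\beta(0) > 0$.
  `naive5hmC` exposes this surrogate as $\max(0, \Delta\beta(0))$; the
  degenerate $0/0$ entries at $\alpha = 0$ are masked.

## Screening summaries

`prevalence` reports the fraction of positive calls per sample (across
CpGs) or per CpG (across samples; the CpG's *hydroxymethylation level*);
`jointPrevalence` does the same for the conjunction of two measures on
jointly-unmasked entries, which makes joint and marginal prevalences
directly comparable. `substantialCpGs` implements the inclusive
"at least 75% of values positive across samples" rule.

For matched healthy/cancer designs `compareTissues` uses a two-sided
Wilcoxon signed-rank test (Mann–Whitney for unpaired summaries) and
`adjustComparisons` applies Benjamini–Hochberg across a family of
measure/axis comparisons. The source analyses never name their tests; the
rank-based choice is ours — it respects the bounded, non-normal prevalence
scale — and is therefore configurable and reported alongside the median
difference and its direction.

## Concordance without a gold standard

No biochemical criterion defines "hydroxymethylated" in terms of
intensities, so measures are compared against *each other*:

* simple matching coefficient $S$ — fraction of concordant calls per unit;
* Hamann coefficient $SH = 2S - 1$ — mismatch-corrected, preferred when the
  agreement consists only of concordant negatives. Units with no
  jointly-positive call but $S > 0$ are flagged (`degenerateUnits`) because
  $S$ is driven there entirely by joint absence;
* relative sensitivity/specificity (co-positivity/co-negativity) and the
  relative false discovery rate, with the exact identity
  $FDR_r(x_1|x_2) = 1 - SE_r(x_2|x_1)$.

Expectations of $S$/$SH$ are provided under two constructions
(`expectedSimilarity`): the default `empirical_mean` over units, and an
`independence_null` that randomises the observed marginal positive counts
within each unit, $E[S] = (ab + (n-a)(n-b))/n^2$. The published expectation
construction for the 38-pair colorectal cohort is not printed in detail, so
we report both side by side; under either, $E[SH] = 2E[S]-1$ holds exactly.
The published expectation tables for that cohort ship as plain-text
reference inputs (`referenceExpectations`) and the package's identity
functions (`hamannFromMatching`, `fdrFromSensitivity`) reproduce each
derived table from its primary counterpart exactly at the printed four
decimals; the cohort's raw data are an external deposit and are not
re-analysed here.

The canonical unit for $S$ is the CpG (across samples); sample-wise values
are also used in practice, so both axes are supported and recorded in the
output metadata.

## The synthetic generator

`simulatePanels` draws, per probe, proportions $p_{5mC} \sim$
Beta(0.4, 0.4) (roughly bimodal, as methylomes are) and $p_{5hmC} \sim$
Beta(1, 40) (low, right-skewed; mean 2.4%, appropriate for colorectal
tissue where 5hmC is scarce), truncated to the simplex by joint resampling
so the marginals stay interpretable. Per probe and sample a depth scale $D$
is drawn log-normal (median 3000, sdlog 0.4 — raw 450k totals in the low
thousands), and

$$M_{BS} = D\,(p_{5mC}+p_{5hmC})\,\varepsilon + bg,\qquad
  U_{BS} = D\,(1-p_{5mC}-p_{5hmC})\,\varepsilon' + bg,$$
$$M_{oxBS} = D\,(1-\gamma p_{5hmC})\,p_{5mC}\,\varepsilon'' + bg,\qquad
  U_{oxBS} = D\,(1-\gamma p_{5hmC})\,(1-p_{5mC})\,\varepsilon''' + bg,$$

with independent multiplicative log-normal noise of CV 0.1 (mean 1) and
background $bg = 50$. The attenuation $\gamma = 0.5$ operationalises the
assumption behind $\Delta h$ — that substantial 5hmC depresses the overall
oxBS intensity; $\gamma = 0$ generates a world in which $\Delta h$ carries
no signal, itself a documented test case. The cancer arm shares each
probe's $p_{5mC}$ and multiplies $p_{5hmC}$ by 0.5 (two-fold depletion),
giving a matched-pair structure of 38 samples at study scale. With
$bg = 0$ and no noise, $\Delta h = \gamma\, p_{5hmC}$ entrywise in closed
form; with 5% noise the per-probe mean over 50 samples recovers
$\gamma p_{5hmC}$ with absolute bias well below 0.02 (the Jensen bias of
the intensity ratio is of order $CV^2$).

What the generator does *not* emulate: Infinium I/II probe-type chemistry,
dye bias, batch effects, spatial artefacts, or between-probe dependence.
Passing tests on synthetic panels therefore validate the algebra and the
statistical machinery, not robustness to array-specific artefacts — on real
data those belong to the (out-of-scope) normalisation layer upstream.

## Numerical choices and problem sizes

* Masked-on-read policy: negative or non-numeric input cells are masked and
  counted, not fatal; only structural misalignment of the four tables
  aborts.
* Output tables serialise numbers at 15 significant digits and round-trip
  through their readers to better than 1e-12; `NA` is the sole missing
  token.
* Strict `>` defines a positive call; ties at the threshold are negative.
* The closed-form $\alpha^*$ is preferred over iterative root finding; the
  bisection route exists only as an independent oracle in the tests.
* Property suites run on panels of 400–10,000 probes and the validation
  checks use 1,000–10,000 random probes, 500 probes × 50 samples for noise
  recovery, and 5,000 probes × 38 matched pairs for the tissue effect —
  sizes at which every suite completes in seconds while keeping Monte-Carlo
  error far from the asserted bounds.
* The large-offset limit checks evaluate at $\alpha = 10^6$ on probes with
  a clear methylated-intensity contrast ($|M_{BS}-M_{oxBS}| \ge 100$ at
  totals of a few hundred): the first-order law
  $\alpha\,\Delta\beta(\alpha) \approx M_{BS}-M_{oxBS}$ is ill-conditioned
  as a *relative* statement when the contrast is near zero, so the
  validation ensemble is chosen where the statement is sharp rather than
  the tolerance widened.

## A worked example

```{r example}
sim <- simulatePanels(SimulationConfig(nProbes = 2000, nSamples = 12,
                                       seed = 7))
db <- deltaBeta(sim$healthy, 100)
dm <- deltaMInf(sim$healthy)
dh <- deltaH(sim$healthy)

cb <- callPositive(db); cmi <- callPositive(dm); ch <- callPositive(dh)
median(proportions(prevalence(cb, "per_sample")))
length(substantialCpGs(cb))

s <- simpleMatching(cb, cmi, "per_probe_across_samples")
expectation(s)
expectation(hamann(cb, cmi, "per_probe_across_samples"))

ra <- relativeAccuracy(cb, cmi, "per_probe_across_samples")
expectation(ra[["FDR_r(x1|x2)"]])
1 - expectation(ra[["SE_r(x2|x1)"]])  # identical by the FDR identity

ph <- prevalence(callPositive(deltaBeta(sim$healthy, 100)), "per_sample")
pc <- prevalence(callPositive(deltaBeta(sim$cancer, 100)), "per_sample")
compareTissues(ph, pc, paired = TRUE)
```

## Known limitations

* Raw intensities only: IDAT parsing, channel conversion and normalisation
  happen upstream; probe ids are opaque strings and no genomic annotation
  is joined.
* The full beta-distribution maximum-likelihood 5hmC estimators are out of
  scope; only their screening-equivalent sign surrogate (`naive5hmC`) is
  provided.
* Reference expectation values for the colorectal cohort are consumed as
  published numbers; reproducing them from raw data requires the external
  deposit.
* Density estimation of measure distributions is not implemented; the alpha
  scan reports summary suprema and discordance counts instead.
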