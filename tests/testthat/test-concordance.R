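test_that("simple matching and Hamann match enumeration on small vectors", {
  x1 <- callsFromLogical(matrix(c(TRUE, TRUE, FALSE, FALSE), 1, 4))
  x2 <- callsFromLogical(matrix(c(TRUE, FALSE, FALSE, FALSE), 1, 4))
  s <- simpleMatching(x1, x2, "per_probe_across_samples")
  expect_equal(unname(concordanceValues(s)), 0.75)   # 3 matches of 4
  sh <- hamann(x1, x2, "per_probe_across_samples")
  expect_equal(unname(concordanceValues(sh)), 0.5)   # (3 - 1) / 4
  # identical and opposite vectors hit the extremes
  sI <- simpleMatching(x1, x1, "per_probe_across_samples")
  expect_equal(unname(concordanceValues(sI)), 1)
  x3 <- callsFromLogical(matrix(c(FALSE, FALSE, TRUE, TRUE), 1, 4))
  expect_equal(unname(concordanceValues(
    simpleMatching(x1, x3, "per_probe_across_samples"))), 0)
  expect_equal(unname(concordanceValues(
    hamann(x1, x3, "per_probe_across_samples"))), -1)
})

test_that("SH = 2S - 1 unit-wise and at expectation level", {
  set.seed(23)
  a <- callsFromLogical(matrix(runif(300) > 0.5, 30, 10))
  b <- callsFromLogical(matrix(runif(300) > 0.4, 30, 10))
  for (ax in c("per_probe_across_samples", "per_sample_across_probes")) {
    s <- simpleMatching(a, b, ax)
    sh <- hamann(a, b, ax)
    expect_equal(concordanceValues(sh), 2 * concordanceValues(s) - 1)
    expect_equal(expectation(sh), 2 * expectation(s) - 1)
    expect_true(all(concordanceValues(sh) <= concordanceValues(s) + 1e-15))
  }
  expect_equal(hamannFromMatching(c(0.7946, 0.8052)), c(0.5892, 0.6104))
})

test_that("degenerate-matching units are flagged for Hamann consultation", {
  # no jointly-positive entries yet S > 0 from concordant negatives
  x1 <- callsFromLogical(matrix(c(TRUE, FALSE, FALSE, FALSE), 1, 4))
  x2 <- callsFromLogical(matrix(c(FALSE, TRUE, FALSE, FALSE), 1, 4))
  s <- simpleMatching(x1, x2, "per_probe_across_samples")
  expect_equal(unname(concordanceValues(s)), 0.5)
  expect_true(degenerateUnits(s)[1])
  # a unit with joint positives is not flagged
  x3 <- callsFromLogical(matrix(c(TRUE, TRUE, FALSE, FALSE), 1, 4))
  expect_false(degenerateUnits(
    simpleMatching(x1, x3, "per_probe_across_samples"))[1])
})

test_that("independence-null expectation matches exhaustive enumeration", {
  # one unit, n = 4, a = 2, b = 1 marginal positives
  x1 <- callsFromLogical(matrix(c(TRUE, TRUE, FALSE, FALSE), 1, 4))
  x2 <- callsFromLogical(matrix(c(TRUE, FALSE, FALSE, FALSE), 1, 4))
  en <- expectedSimilarity(x1, x2, "per_probe_across_samples",
                           method = "independence_null")
  expect_equal(en, (2 * 1 + 2 * 3) / 16)  # 0.5
  # brute-force enumeration over all C(4,2) x C(4,1) placements
  smatch <- function(u, v) mean((u & v) | (!u & !v))
  vals <- c()
  for (i in seq_len(ncol(combn(4, 2)))) for (j in 1:4) {
    u <- v <- rep(FALSE, 4)
    u[combn(4, 2)[, i]] <- TRUE; v[j] <- TRUE
    vals <- c(vals, smatch(u, v))
  }
  expect_equal(en, mean(vals))
  # E[SH] = 2 E[S] - 1 under either method
  expect_equal(expectedSimilarity(x1, x2, "per_probe_across_samples", "SH",
                                  "independence_null"), 2 * en - 1)
  expect_equal(expectedSimilarity(x1, x1, "per_probe_across_samples"), 1)
  expect_error(expectedSimilarity(x1, x2, method = "bogus"))
})

test_that("relative accuracy matches enumeration and the FDR identity", {
  x1 <- callsFromLogical(matrix(c(TRUE, TRUE, FALSE, FALSE), 1, 4), "m1")
  x2 <- callsFromLogical(matrix(c(TRUE, FALSE, FALSE, FALSE), 1, 4), "m2")
  ra <- relativeAccuracy(x1, x2, "per_probe_across_samples")
  expect_equal(unname(concordanceValues(ra[["SE_r(x1|x2)"]])), 1.0)
  expect_equal(unname(concordanceValues(ra[["SE_r(x2|x1)"]])), 0.5)
  expect_equal(unname(concordanceValues(ra[["FDR_r(x1|x2)"]])), 0.5)
  expect_equal(unname(concordanceValues(ra[["SP_r(x1|x2)"]])), 2 / 3)
  # direct ratio route: 1 - P(x1>0, x2>0) / P(x1>0)
  expect_equal(unname(concordanceValues(ra[["FDR_r(x1|x2)"]])),
               1 - (1 / 4) / (2 / 4))
  # diagonal: SE_r(x|x) = 1, FDR_r(x|x) = 0, SP_r(x|x) = 1
  raxx <- relativeAccuracy(x1, x1, "per_probe_across_samples")
  expect_equal(unname(concordanceValues(raxx[["SE_r(x1|x2)"]])), 1)
  expect_equal(unname(concordanceValues(raxx[["FDR_r(x1|x2)"]])), 0)
  expect_equal(unname(concordanceValues(raxx[["SP_r(x1|x2)"]])), 1)
  # identity FDR_r(x1|x2) + SE_r(x2|x1) = 1 on random calls, both axes
  set.seed(29)
  a <- callsFromLogical(matrix(runif(300) > 0.5, 30, 10))
  b <- callsFromLogical(matrix(runif(300) > 0.3, 30, 10))
  for (ax in c("per_probe_across_samples", "per_sample_across_probes")) {
    r <- relativeAccuracy(a, b, ax)
    keep <- !is.na(concordanceValues(r[["FDR_r(x1|x2)"]]))
    expect_equal(concordanceValues(r[["FDR_r(x1|x2)"]])[keep] +
                   concordanceValues(r[["SE_r(x2|x1)"]])[keep],
                 rep(1, sum(keep)), ignore_attr = TRUE)
  }
})

test_that("fdrFromSensitivity transposes the conditional identity", {
  se <- matrix(c(1, 0.7456, 0.794,
                 0.7739, 1, 0.5613,
                 0.8624, 0.5938, 1),
               3, 3, byrow = TRUE,
               dimnames = list(c("m_inf", "dbeta", "dh"),
                               c("m_inf", "dbeta", "dh")))
  fdr <- fdrFromSensitivity(se)
  expect_equal(fdr["dbeta", "m_inf"], 1 - se["m_inf", "dbeta"],
               ignore_attr = TRUE)
  expect_equal(diag(fdr), rep(0, 3), ignore_attr = TRUE)
})

test_that("measures sharing a latent signal beat the independence null", {
  sim <- simulatePanels(SimulationConfig(400, 12, seed = 101))
  c1 <- callPositive(deltaBeta(sim$healthy, 100))
  c2 <- callPositive(deltaMInf(sim$healthy))
  emp <- expectedSimilarity(c1, c2, "per_sample_across_probes",
                            method = "empirical_mean")
  nul <- expectedSimilarity(c1, c2, "per_sample_across_probes",
                            method = "independence_null")
  expect_gt(emp, nul)
})
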