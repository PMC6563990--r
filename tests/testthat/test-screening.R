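test_that("positive calls use a strict threshold and respect masks", {
  vals <- matrix(c(-0.1, 0, 0.2, 0.25, 0.35, NA), 6, 1,
                 dimnames = list(sprintf("p%02d", 1:6), "s1"))
  mask <- is.na(vals)
  mm <- new("MeasureMatrix", measure = "delta_m_inf", alpha = numeric(0),
            values = vals, mask = mask,
            noise = matrix(FALSE, 6, 1, dimnames = dimnames(vals)))
  cc <- callPositive(mm)
  expect_equal(unname(calls(cc)[1:3, 1]), c(FALSE, FALSE, TRUE))
  expect_true(is.na(calls(cc)[6, 1]))
  # published stricter cut on the beta-difference scale
  cc3 <- callPositive(mm, threshold = 0.3)
  expect_equal(unname(calls(cc3)[4:5, 1]), c(FALSE, TRUE))
})

test_that("prevalence divides positives by unmasked denominators", {
  cc <- callsFromLogical(matrix(c(TRUE, TRUE, FALSE, FALSE), 4, 1))
  expect_equal(unname(proportions(prevalence(cc, "per_sample"))), 0.5)
  # per-probe axis: one probe across many samples
  cc2 <- callsFromLogical(matrix(rep(c(TRUE, FALSE), 19), 1, 38))
  pp <- prevalence(cc2, "per_probe")
  expect_equal(unname(proportions(pp)), 0.5)
  expect_equal(unname(denominators(pp)), 38L)
  # all-positive matrix
  cc3 <- callsFromLogical(matrix(TRUE, 3, 2))
  expect_true(all(proportions(prevalence(cc3, "per_sample")) == 1))
  # masked entries leave the denominator
  m <- matrix(c(TRUE, TRUE, FALSE, FALSE), 4, 1)
  msk <- matrix(c(FALSE, FALSE, FALSE, TRUE), 4, 1)
  cc4 <- callsFromLogical(m, mask = msk)
  expect_equal(unname(proportions(prevalence(cc4, "per_sample"))), 2 / 3)
  expect_equal(unname(denominators(prevalence(cc4, "per_sample"))), 3L)
})

test_that("joint prevalence obeys its identities", {
  c1 <- callsFromLogical(matrix(c(TRUE, TRUE, FALSE, FALSE), 4, 1))
  c2 <- callsFromLogical(matrix(c(TRUE, FALSE, FALSE, FALSE), 4, 1))
  expect_equal(unname(proportions(jointPrevalence(c1, c2, "per_sample"))), 0.25)
  # joint with itself equals the marginal
  expect_equal(proportions(jointPrevalence(c1, c1, "per_sample")),
               proportions(prevalence(c1, "per_sample")))
  # all-true second factor recovers the first marginal
  ct <- callsFromLogical(matrix(TRUE, 4, 1))
  expect_equal(proportions(jointPrevalence(c1, ct, "per_sample")),
               proportions(prevalence(c1, "per_sample")))
  # disjoint positives give zero
  c3 <- callsFromLogical(matrix(c(FALSE, FALSE, TRUE, FALSE), 4, 1))
  expect_equal(unname(proportions(jointPrevalence(c1, c3, "per_sample"))), 0)
  # joint never exceeds either marginal (random property)
  set.seed(5)
  a <- callsFromLogical(matrix(runif(200) > 0.5, 20, 10))
  b <- callsFromLogical(matrix(runif(200) > 0.3, 20, 10))
  for (ax in c("per_sample", "per_probe")) {
    jp <- proportions(jointPrevalence(a, b, ax))
    expect_true(all(jp <= pmin(proportions(prevalence(a, ax)),
                               proportions(prevalence(b, ax))) + 1e-12))
  }
  expect_error(jointPrevalence(c1, callsFromLogical(matrix(TRUE, 2, 1)),
                               "per_sample"))
})

test_that("substantially hydroxymethylated CpGs use an inclusive boundary", {
  m <- rbind(p1 = c(TRUE, TRUE, TRUE, FALSE),   # 3/4: included at 0.75
             p2 = c(TRUE, TRUE, FALSE, FALSE),  # 2/4: excluded
             p3 = c(TRUE, TRUE, TRUE, TRUE))
  colnames(m) <- sprintf("s%d", 1:4)
  cc <- callsFromLogical(m)
  expect_identical(substantialCpGs(cc, 0.75), c("p1", "p3"))
  # intersection across measures equals brute-force set intersection
  set.seed(9)
  mk <- function() callsFromLogical(matrix(runif(120) > 0.4, 30, 4))
  cs <- list(mk(), mk(), mk())
  sets <- lapply(cs, substantialCpGs, minFraction = 0.5)
  brute <- rownames(calls(cs[[1]]))[
    rowMeans(calls(cs[[1]])) >= 0.5 & rowMeans(calls(cs[[2]])) >= 0.5 &
    rowMeans(calls(cs[[3]])) >= 0.5]
  expect_identical(Reduce(intersect, sets), brute)
})

test_that("tissue comparison reports direction and a permutation-consistent p", {
  ps <- function(v) new("PrevalenceSummary", axis = "per_sample",
                        measure = "delta_beta",
                        proportions = v,
                        denominators = rep(100L, length(v)))
  set.seed(17)
  b <- runif(38, 0.3, 0.6)
  a <- b + 0.1
  rep_ab <- compareTissues(ps(a), ps(b), paired = TRUE)
  expect_equal(rep_ab$direction, "a>b")
  expect_lt(rep_ab$p_value, 0.001)
  expect_equal(rep_ab$median_diff, 0.1)
  # permutation oracle on the same vectors: sign-flip null
  d <- a - b
  obs <- sum(d)
  set.seed(18)
  perm <- replicate(2000, sum(d * sample(c(-1, 1), length(d), TRUE)))
  p_perm <- mean(abs(perm) >= abs(obs))
  expect_lt(p_perm, 0.01)  # both routes call the same strong signal
  # identical vectors: no direction
  expect_warning(r0 <- compareTissues(ps(b), ps(b)), "informative")
  expect_equal(r0$direction, "none")
  expect_true(is.na(r0$p_value))
  # single pair: degenerate
  expect_warning(r1 <- compareTissues(ps(c(x = 0.5)), ps(c(x = 0.4))),
                 "informative")
  expect_true(is.na(r1$p_value))
  # BH adjustment across a family
  fam <- adjustComparisons(list(m1 = rep_ab, m2 = rep_ab))
  expect_true(all(fam$p_adjusted >= fam$p_value))
})
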