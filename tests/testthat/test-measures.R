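test_that("beta value matches direct evaluation and handles edge cases", {
  expect_equal(betaValue(100, 100, 100), 100 / 300)
  expect_equal(betaValue(0, 37, 100), 0)
  expect_equal(betaValue(50, 0, alpha = 0), 1)
  expect_true(is.na(betaValue(0, 0, alpha = 0)))
  expect_error(betaValue(1, 1, alpha = -1))
})

test_that("delta-beta matches direct arithmetic and respects bounds", {
  p <- panelFromRows(110, 1000, 100, 100)
  expect_equal(measureValues(deltaBeta(p, 0))[1, 1], 110 / 1110 - 100 / 200)
  expect_equal(measureValues(deltaBeta(p, 10000))[1, 1],
               110 / 11110 - 100 / 10200)
  # sign change across alpha for the same probe
  expect_lt(measureValues(deltaBeta(p, 0))[1, 1], 0)
  expect_gt(measureValues(deltaBeta(p, 10000))[1, 1], 0)
  # identical treatments give exact zero
  m <- matrix(runif(20, 10, 100), 10, 2,
              dimnames = list(sprintf("p%d", 1:10), c("a", "b")))
  q <- HmcPanel(m, m, m, m)
  expect_true(all(measureValues(deltaBeta(q)) == 0))
  # bounds on a large random panel
  rp <- randomPanel(200, 4, seed = 5)
  v <- measureValues(deltaBeta(rp, 100))
  expect_true(all(v >= -1 & v <= 1))
})

test_that("delta-m has the stated form, masking, and log2 limit target", {
  p <- panelFromRows(200, 100, 100, 100)
  expect_equal(measureValues(deltaM(p, 0))[1, 1], 1.0)
  expect_equal(measureValues(deltaMInf(p))[1, 1], 1.0)
  # identical treatments: zero
  p0 <- panelFromRows(500, 250, 500, 250)
  expect_equal(measureValues(deltaM(p0, 100))[1, 1], 0)
  expect_equal(measureValues(deltaMInf(p0))[1, 1], 0)
  # non-positive methylated intensity is masked
  pz <- panelFromRows(c(100, 0), c(50, 50), c(0, 100), c(50, 50))
  expect_message(dmi <- deltaMInf(pz), "masked")
  expect_true(all(measureMask(dmi)[, 1]))
  # alpha = 0 with U = 0 stays defined only through M (m-value = log2(M/U))
  pu <- panelFromRows(100, 0, 100, 10)
  expect_true(measureMask(deltaM(pu, 0))[1, 1])
})

test_that("zero set of delta-beta is the intensity proportionality condition", {
  # M_bs / M_ox = (U_bs + 100) / (U_ox + 100) forces delta-beta(100) = 0
  set.seed(11)
  M_bs <- sample(50:500, 25, replace = TRUE)
  U_bs <- sample(50:800, 25, replace = TRUE)
  k <- sample(2:5, 25, replace = TRUE)
  p <- panelFromRows(M_bs, U_bs, k * M_bs, k * (U_bs + 100) - 100)
  expect_true(all(measureValues(deltaBeta(p, 100)) == 0))
  # and conversely a perturbation off the proportionality line breaks it
  p2 <- panelFromRows(M_bs, U_bs, k * M_bs, k * (U_bs + 100) - 100 + 7)
  expect_true(all(measureValues(deltaBeta(p2, 100)) != 0))
})

test_that("delta-h matches closed forms, masks zero BS totals, flags noise", {
  p <- panelFromRows(c(300, 50, 100), c(100, 50, 300),
                     c(80, 100, 250), c(20, 0, 250))
  dh <- deltaH(p)
  v <- measureValues(dh)
  expect_equal(v[1, 1], 0.75)        # totals 400 vs 100
  expect_equal(v[2, 1], 0)           # equal totals
  expect_equal(v[3, 1], -0.25)       # totals 400 vs 500: retained, flagged
  expect_equal(noiseFlag(dh)[, 1], c(p01 = FALSE, p02 = FALSE, p03 = TRUE))
  pz <- panelFromRows(0, 0, 10, 10)
  expect_message(dz <- deltaH(pz), "masked")
  expect_true(measureMask(dz)[1, 1])
})

test_that("naive estimate clamps at zero and shares its positives with delta-beta(0)", {
  p <- panelFromRows(c(110, 200), c(1000, 100), c(100, 100), c(100, 100))
  nv <- measureValues(naive5hmC(p))
  expect_equal(nv[1, 1], 0)                       # delta-beta(0) < 0 clamped
  expect_equal(nv[2, 1], 200 / 300 - 100 / 200)   # = 1/6
  rp <- randomPanel(300, 3, seed = 7)
  db0 <- measureValues(deltaBeta(rp, 0))
  expect_identical(measureValues(naive5hmC(rp)) > 0, db0 > 0)
})

test_that("sign equivalence of delta-beta and delta-m holds against the algebraic oracle", {
  rp <- randomPanel(500, 2, seed = 13)
  M_bs <- methylBS(rp); U_bs <- unmethBS(rp)
  M_ox <- methOxBS(rp); U_ox <- unmethOxBS(rp)
  for (a in c(0, 1, 100, 2000)) {
    oracle <- sign(M_bs * (U_ox + a) - M_ox * (U_bs + a))
    expect_identical(sign(measureValues(deltaBeta(rp, a))), oracle)
    expect_identical(sign(measureValues(deltaM(rp, a))), oracle)
  }
})

test_that("computeMeasure dispatches to the named measure", {
  rp <- randomPanel(50, 2, seed = 3)
  expect_equal(measureValues(computeMeasure(rp, "delta_h")),
               measureValues(deltaH(rp)))
  expect_equal(measureValues(computeMeasure(rp, "delta_beta", alpha = 7)),
               measureValues(deltaBeta(rp, 7)))
  expect_equal(alphaOffset(computeMeasure(rp, "delta_beta", alpha = 7)), 7)
  expect_length(alphaOffset(computeMeasure(rp, "delta_h")), 0)
})

test_that("masks propagate by union from panel to measures", {
  m <- matrix(10, 3, 2, dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  mask <- matrix(FALSE, 3, 2, dimnames = dimnames(m)); mask[2, 1] <- TRUE
  p <- HmcPanel(m, m, m, m, mask = mask)
  for (f in list(deltaBeta, deltaMInf, deltaH, naive5hmC)) {
    mm <- f(p)
    expect_true(measureMask(mm)[2, 1])
    expect_true(is.na(measureValues(mm)[2, 1]))
  }
})
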