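# Shared fixtures and independent oracles.

# panel from explicit per-probe intensity rows (one sample per column set)
panelFromRows <- function(M_bs, U_bs, M_oxbs, U_oxbs,
                          tissue = "unspecified") {
  n <- length(M_bs)
  ids <- sprintf("p%02d", seq_len(n))
  one <- function(v) matrix(as.numeric(v), ncol = 1,
                            dimnames = list(ids, "s1"))
  HmcPanel(one(M_bs), one(U_bs), one(M_oxbs), one(U_oxbs), tissue = tissue)
}

# random positive-intensity panel
randomPanel <- function(n_probes, n_samples, seed, lo = 1, hi = 2000) {
  set.seed(seed)
  r <- function() matrix(runif(n_probes * n_samples, lo, hi), n_probes,
                         n_samples,
                         dimnames = list(sprintf("cg%05d", seq_len(n_probes)),
                                         sprintf("s%02d", seq_len(n_samples))))
  HmcPanel(r(), r(), r(), r())
}

# CallMatrix from a plain logical matrix (for concordance unit tests)
callsFromLogical <- function(m, measure = "x", mask = NULL) {
  m <- as.matrix(m)
  if (is.null(mask)) mask <- matrix(FALSE, nrow(m), ncol(m))
  if (is.null(rownames(m)))
    dimnames(m) <- list(sprintf("p%02d", seq_len(nrow(m))),
                        sprintf("s%02d", seq_len(ncol(m))))
  dimnames(mask) <- dimnames(m)
  new("CallMatrix", measure = measure, threshold = 0, calls = m, mask = mask)
}

# independent difference-of-proportions evaluation (scalar, no package code)
dbeta_ref <- function(M_bs, U_bs, M_oxbs, U_oxbs, alpha) {
  M_bs / (M_bs + U_bs + alpha) - M_oxbs / (M_oxbs + U_oxbs + alpha)
}

# vectorised bisection root-finder for delta-beta(alpha) = 0, independent of
# the closed form; assumes a crossing exists in (0, Inf)
bisectCriticalAlpha <- function(M_bs, U_bs, M_oxbs, U_oxbs, iters = 100) {
  f <- function(a) dbeta_ref(M_bs, U_bs, M_oxbs, U_oxbs, a)
  lo <- rep(1e-9, length(M_bs))
  hi <- rep(1, length(M_bs))
  s0 <- sign(f(lo))
  for (i in 1:80) {
    need <- sign(f(hi)) == s0
    if (!any(need)) break
    hi[need] <- hi[need] * 2
  }
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    smid <- sign(f(mid))
    up <- smid == s0 | smid == 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  (lo + hi) / 2
}
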