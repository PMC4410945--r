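# shared fixtures and independent oracles used across the suite

# small phantom for fast unit tests (full geometry, quarter-size slab)
smallSpec <- function(field = "3T", snr = NULL, seed = 1L,
                      params = phantomParams()) {
  phantomSpec(field, snr = snr, seed = seed, grid = c(12L, 12L, 2L),
              params = params)
}

# brute-force CMRO2 inversion: bisection on the Davis forward model
bisectCMRO2 <- function(dBOLDtask, ftask, M, params, tol = 1e-12) {
  g <- function(r) davisForward(M, ftask, r, params) - dBOLDtask
  lo <- 1e-3; hi <- 10
  stopifnot(g(lo) > 0, g(hi) < 0)  # forward is decreasing in r
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# exhaustive sort-based oracle for top-fraction selection
topFractionOracle <- function(stat, mask, fraction) {
  idx <- which(mask & is.finite(stat))
  k <- ceiling(fraction * length(idx))
  ord <- idx[order(stat[idx], -idx, decreasing = TRUE)]
  sort(ord[seq_len(k)])
}

# independent DCT-projection oracle built on base lm residuals
dctHighpassOracle <- function(x, cutoffS, TR) {
  n <- length(x)
  K <- ceiling(2 * n * TR / cutoffS) - 1
  if (K < 1) return(x)
  t <- 0:(n - 1)
  B <- sapply(seq_len(K), function(k) cos(pi * k * (t + 0.5) / n))
  unname(stats::lm.fit(cbind(1, B), x)$residuals + mean(x))
}
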