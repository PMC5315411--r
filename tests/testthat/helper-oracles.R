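# Shared fixtures and independent oracles used across test files.

# Reduced but adequate MCMC schedule for the small conditional models
# exercised in tests (split R-hat is checked wherever it matters).
test_schedule <- function() mcmc_schedule(chains = 4, iter = 6000,
                                          warmup = 2000, thin = 4)

# Brute-force two-tailed Fisher p: enumerate every table with the observed
# margins, compute its probability from factorials, and sum probabilities
# not exceeding that of the observed table. Independent of the dhyper-based
# kernel under test.
fisher_oracle <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  if (m == 0 || n == 0 || k == 0 || c + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  log_prob <- function(x) {
    lfactorial(m) + lfactorial(n) + lfactorial(k) + lfactorial(m + n - k) -
      lfactorial(m + n) - lfactorial(x) - lfactorial(m - x) -
      lfactorial(k - x) - lfactorial(n - k + x)
  }
  lp <- vapply(support, log_prob, numeric(1))
  p <- exp(lp)
  sum(p[p <= exp(log_prob(a)) * (1 + 1e-7)])
}

# Brute-force HWE exact p: enumerate every genotype configuration with the
# same sample size and allele count, with probabilities from first
# principles (permanents of allele pairings).
hwe_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  if (n == 0) return(1)
  na <- 2 * naa + nAa
  if (na > n) na <- 2 * n - na
  if (na == 0) return(1)
  hets <- seq(na %% 2, na, by = 2)
  prob <- vapply(hets, function(h) {
    raa <- (na - h) / 2
    rAA <- n - raa - h
    exp(lfactorial(n) - lfactorial(rAA) - lfactorial(h) - lfactorial(raa) +
          h * log(2) + lfactorial(na) + lfactorial(2 * n - na) -
          lfactorial(2 * n))
  }, numeric(1))
  obs <- prob[hets == nAa]
  sum(prob[prob <= obs * (1 + 1e-7)])
}

# Haplotype-frequency r2 oracle from phased truth haplotypes.
hap_r2_oracle <- function(haps, i, j) {
  pA <- mean(haps[, i]); pB <- mean(haps[, j])
  pAB <- mean(haps[, i] == 1 & haps[, j] == 1)
  d <- pAB - pA * pB
  d^2 / (pA * (1 - pA) * pB * (1 - pB))
}
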