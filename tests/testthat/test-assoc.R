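test_that("point-probability Fisher p equals brute-force enumeration on all small tables", {
  # exact equality on every 2x2 table with total n <= 25
  for (n in c(1, 5, 12, 25)) {
    for (a in 0:n) for (b in 0:(n - a)) for (c_ in 0:(n - a - b)) {
      d <- n - a - b - c_
      expect_equal(fisher2x2_p(a, b, c_, d), fisher_oracle(a, b, c_, d),
                   tolerance = 1e-12)
    }
  }
  # and against stats::fisher.test on random larger tables
  set.seed(7)
  for (i in 1:100) {
    t <- sample(0:40, 4, replace = TRUE)
    if (sum(t[1:2]) == 0 || sum(t[3:4]) == 0) next
    expect_equal(fisher2x2_p(t[1], t[2], t[3], t[4]),
                 stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("Fisher p is invariant under row and column swaps; degenerate tables warn", {
  set.seed(1)
  for (i in 1:50) {
    t <- sample(0:15, 4, replace = TRUE) + c(1, 0, 0, 1)
    p <- fisher_exact_two_tailed(t[1], t[2], t[3], t[4])
    expect_equal(fisher_exact_two_tailed(t[3], t[4], t[1], t[2]), p)
    expect_equal(fisher_exact_two_tailed(t[2], t[1], t[4], t[3]), p)
  }
  expect_equal(fisher_exact_two_tailed(10, 10, 10, 10), 1)
  # a zero row together with a zero column leaves nothing to compare
  expect_warning(p <- fisher_exact_two_tailed(0, 0, 0, 7), "degenerate")
  expect_equal(p, 1)
  # a zero margin alone is not degenerate but carries no information
  expect_equal(fisher_exact_two_tailed(0, 5, 0, 7), 1)
})

test_that("Woolf odds ratios and CIs reproduce the reference DLA statistics", {
  # 2n haplotype-level table for the risk haplotype in Shetland sheepdogs
  r <- odds_ratio_woolf(158, 26, 301, 109)
  expect_equal(round(r$odds_ratio, 2), 2.20)
  expect_equal(round(r$ci_low, 2), 1.38)
  expect_equal(round(r$ci_high, 2), 3.52)
  expect_equal(r$p_two_tailed, 0.0006848263, tolerance = 1e-6)
  # dog-level homozygosity table
  r2 <- odds_ratio_woolf(71, 21, 109, 96)
  expect_equal(round(r2$odds_ratio, 2), 2.98)
  expect_equal(round(r2$ci_low, 2), 1.70)
  expect_equal(round(r2$ci_high, 2), 5.21)
  expect_equal(round(r2$p_two_tailed, 4), 0.0001)
  # protective haplotype
  r3 <- odds_ratio_woolf(24, 160, 102, 308)
  expect_equal(round(r3$odds_ratio, 2), 0.45)
  expect_equal(round(r3$ci_low, 2), 0.28)
  expect_equal(round(r3$ci_high, 2), 0.73)
  expect_equal(round(r3$p_two_tailed, 4), 0.0011)
})

test_that("odds ratio obeys symmetry and reciprocity; zero cells are flagged", {
  for (k in c(1, 4, 9)) {
    r <- odds_ratio_woolf(k, k, k, k)
    expect_equal(r$odds_ratio, 1)
    expect_equal(log(r$ci_low), -log(r$ci_high))   # symmetric on log scale
  }
  r <- odds_ratio_woolf(12, 3, 7, 9)
  rt <- odds_ratio_woolf(3, 12, 9, 7)             # transposed exposure
  expect_equal(rt$odds_ratio, 1 / r$odds_ratio)
  expect_equal(rt$ci_low, 1 / r$ci_high)
  z <- odds_ratio_woolf(5, 0, 3, 8)
  expect_true(is.na(z$odds_ratio))
  zc <- odds_ratio_woolf(5, 0, 3, 8, correct = TRUE)
  expect_true(zc$corrected && is.finite(zc$odds_ratio))
})

test_that("haplotype counting uses 2n alleles and matches the reference fixture", {
  coh <- simulate_table3_cohort(seed = 11)
  ha <- haplotype_association(coh, breed = "sheltie")
  # case alleles match the reference table exactly; the control count is
  # implied by the genotype distribution (302; the published haplotype
  # table prints 301, a one-allele internal discrepancy of the source)
  expect_equal(unname(ha$counts["hap_cases"]), 158)
  expect_equal(unname(ha$counts["other_cases"]), 26)
  expect_equal(unname(ha$counts["hap_controls"]) +
                 unname(ha$counts["other_controls"]), 410)
  hom <- homozygosity_association(coh, breed = "sheltie")
  expect_equal(unname(hom$counts), c(71, 21, 109, 96))
  # internal consistency with the Fisher kernel
  expect_equal(hom$p_two_tailed,
               fisher_exact_two_tailed(71, 21, 109, 96))
  # a cohort of one heterozygous dog contributes 1 of 2 alleles
  one <- as_cohort(data.frame(dog_id = "d1", breed = "sheltie",
                              status = "case", pan2 = "aa",
                              map3k7cl = "bb", drb1_1 = "002:01",
                              drb1_2 = "023:01", stringsAsFactors = FALSE))
  ha1 <- haplotype_association(one)
  expect_equal(unname(ha1$counts[c("hap_cases", "other_cases")]), c(1, 1))
})

test_that("near-fixed haplotypes trigger the low-power flag", {
  coh <- simulate_table3_cohort(seed = 11)
  expect_warning(ha <- haplotype_association(coh, breed = "collie"),
                 "low-power")
  expect_true(ha$low_power)
})

test_that("permuted case labels give odds ratios centred on 1", {
  coh <- simulate_table3_cohort(seed = 2)
  sh <- coh[coh$breed == "sheltie", ]
  is_case <- sh$status == "case"
  hap2 <- (sh$drb1_1 == DLA_RISK_DRB1) + (sh$drb1_2 == DLA_RISK_DRB1)
  set.seed(99)
  log_or <- replicate(1000, {
    perm <- sample(is_case)
    a <- sum(hap2[perm]); b <- 2 * sum(perm) - a
    c_ <- sum(hap2[!perm]); d <- 2 * sum(!perm) - c_
    log((a * d) / (b * c_))
  })
  expect_lt(abs(median(log_or)), 0.1)
})

test_that("genotype-vs-population test reproduces the published per-genotype p-values", {
  # exact binomial against p0 = 132/522, the published convention
  expect_equal(genotype_vs_population_test(7, 0, 132, 522),
               6.611865e-05, tolerance = 1e-5)
  expect_equal(round(genotype_vs_population_test(1, 0, 132, 522), 3), 0.253)
  expect_equal(round(genotype_vs_population_test(0, 6, 132, 522), 3), 0.348)
  expect_equal(genotype_vs_population_test(0, 23, 132, 522),
               0.002618708, tolerance = 1e-6)
  # unobserved genotype and proportional genotype
  expect_equal(genotype_vs_population_test(0, 0, 132, 522), 1)
  expect_gt(genotype_vs_population_test(25, 74, 132, 522), 0.5)
  # the Fisher genotype-vs-rest alternative agrees in order of magnitude
  expect_lt(genotype_vs_population_test(7, 0, 132, 522,
                                        method = "fisher_rest"), 1e-4)
})
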