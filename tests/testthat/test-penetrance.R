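test_that("three-locus tabulation reproduces the reference distribution", {
  coh <- simulate_table3_cohort(seed = 4)
  tab <- tabulate_three_locus(coh)
  ref <- dms_reference_counts()
  expect_equal(nrow(tab), 27)
  expect_equal(tab$cases_collie, ref$collie_cases)
  expect_equal(tab$controls_collie, ref$collie_controls)
  expect_equal(tab$cases_sheltie, ref$sheltie_cases)
  expect_equal(tab$controls_sheltie, ref$sheltie_controls)
  expect_equal(sum(tab$cases), 132)
  expect_equal(sum(tab$controls), 390)
  # combined counts for the flagship genotype
  i <- tab$genotype == "AaBBCC"
  expect_equal(tab$cases[i], 26L)
  expect_equal(tab$controls[i], 3L)
  # empty cohort gives 27 all-zero entries
  tab0 <- tabulate_three_locus(coh[0, ])
  expect_equal(sum(tab0$cases) + sum(tab0$controls), 0)
  expect_equal(nrow(tab0), 27)
})

test_that("rounded penetrance percents match the published values", {
  tab <- tabulate_three_locus(simulate_table3_cohort(seed = 4))
  pct <- setNames(tab$percent, tab$genotype)
  expect_equal(unname(pct[c("AAbbCC", "aaBBCC", "AaBBCC", "AABbCC",
                            "AABBCC", "AABBCc")]),
               c(39L, 46L, 90L, 92L, 100L, 100L))
})

test_that("Clopper-Pearson intervals match closed forms and binom.test", {
  expect_equal(round(clopper_pearson_ci(22, 22)$low, 3), 0.846)
  expect_equal(round(clopper_pearson_ci(7, 7)$low, 3), 0.590)
  expect_equal(round(clopper_pearson_ci(0, 2)$high, 3), 0.842)
  expect_equal(clopper_pearson_ci(0, 2)$low, 0)
  expect_equal(clopper_pearson_ci(22, 22)$high, 1)
  # closed forms at the edges
  for (n in c(2, 7, 22)) {
    expect_equal(clopper_pearson_ci(0, n)$high, 1 - 0.025^(1 / n))
    expect_equal(clopper_pearson_ci(n, n)$low, 0.025^(1 / n))
  }
  # cross-check against the independent stats::binom.test implementation
  set.seed(3)
  for (i in 1:25) {
    n <- sample(1:40, 1)
    x <- sample(0:n, 1)
    ci <- clopper_pearson_ci(x, n)
    bt <- stats::binom.test(x, n)$conf.int
    expect_equal(c(ci$low, ci$high), as.numeric(bt), tolerance = 1e-10)
  }
  expect_true(is.na(clopper_pearson_ci(0, 0)$low))
})

test_that("Clopper-Pearson coverage is at least nominal", {
  set.seed(42)
  n_sim <- 10000
  n <- sample(5:30, n_sim, replace = TRUE)
  p <- sample(seq(0.1, 0.9, 0.1), n_sim, replace = TRUE)
  x <- rbinom(n_sim, n, p)
  ci <- clopper_pearson_ci(x, n)
  coverage <- mean(ci$low <= p & p <= ci$high)
  expect_gte(coverage, 0.95 - 0.01)
})

test_that("risk classification reproduces every published label", {
  tab <- tabulate_three_locus(simulate_table3_cohort(seed = 4))
  expected <- c(
    aabbcc = "unclassified", aabbCc = "low", aabbCC = "low",
    Aabbcc = "unclassified", AabbCc = "low", AabbCC = "low",
    aaBbcc = "low", aaBbCc = "low", aaBbCC = "low",
    AaBbcc = "unclassified", AaBbCc = "low", AaBbCC = "low",
    AAbbcc = "unclassified", AAbbCc = "moderate", AAbbCC = "moderate",
    aaBBcc = "unclassified", aaBBCc = "low", aaBBCC = "moderate",
    AaBBcc = "unclassified", AaBBCc = "moderate", AaBBCC = "high",
    AABbcc = "unclassified", AABbCc = "moderate", AABbCC = "high",
    AABBcc = "unclassified", AABBCc = "high", AABBCC = "high")
  got <- setNames(as.character(tab$risk), tab$genotype)
  expect_equal(got[names(expected)], expected)
  # classification is a pure function of combined counts
  expect_equal(as.character(classify_risk(26, 3)), "high")
  expect_equal(as.character(classify_risk(22, 34)), "moderate")
  expect_equal(as.character(classify_risk(2, 1)), "unclassified")
  expect_equal(as.character(classify_risk(0, 5)), "low")
})

test_that("penetrance is invariant to dog order", {
  coh <- simulate_table3_cohort(seed = 8)
  tab1 <- tabulate_three_locus(coh)
  tab2 <- tabulate_three_locus(coh[rev(seq_len(nrow(coh))), ])
  expect_equal(tab1$penetrance, tab2$penetrance)
})

test_that("cases explained sums case fractions over risk classes", {
  tab <- tabulate_three_locus(simulate_table3_cohort(seed = 4))
  expect_equal(cases_explained(tab, c("moderate", "high")), 117 / 132)
  expect_equal(cases_explained(tab, levels(tab$risk)), 1)
  expect_equal(cases_explained(tab, character(0)), 0)
})
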