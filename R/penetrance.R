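# Penetrance estimation and risk classification over the 27 three-locus
# genotypes, with exact binomial confidence intervals.

#' Reference three-locus genotype distribution (132 cases, 390 controls)
#'
#' Per-breed case/control counts of all 27 PAN2 x MAP3K7CL x DLA genotype
#' combinations in the reference case-control cohort of 522 collies and
#' Shetland sheepdogs (40 + 92 cases, 185 + 205 controls) on which the
#' penetrance architecture of canine dermatomyositis was established. These
#' counts drive the exact fixture generator [simulate_table3_cohort()] and
#' the default penetrance specification of the synthetic generator.
#'
#' @return Data frame with columns `genotype`, `collie_cases`,
#'   `collie_controls`, `sheltie_cases`, `sheltie_controls`.
#' @export
dms_reference_counts <- function() {
  counts <- read.table(text = "
genotype collie_cases collie_controls sheltie_cases sheltie_controls
aabbcc 0 1 0 1
aabbCc 0 5 0 18
aabbCC 1 43 1 17
Aabbcc 0 0 0 3
AabbCc 0 3 1 15
AabbCC 2 71 2 23
aaBbcc 0 0 0 5
aaBbCc 0 1 0 21
aaBbCC 0 10 0 32
AaBbcc 0 0 0 1
AaBbCc 0 0 0 14
AaBbCC 0 13 2 23
AAbbcc 1 0 0 0
AAbbCc 4 6 1 1
AAbbCC 15 31 7 3
aaBBcc 0 0 0 1
aaBBCc 0 0 0 6
aaBBCC 0 0 6 7
AaBBcc 0 0 2 1
AaBBCc 0 0 5 5
AaBBCC 3 0 23 3
AABbcc 0 0 3 0
AABbCc 0 0 2 4
AABbCC 11 1 11 1
AABBcc 0 0 0 0
AABBCc 0 0 7 0
AABBCC 3 0 19 0
", header = TRUE, stringsAsFactors = FALSE)
  counts[match(all_three_locus_labels(), counts$genotype), , drop = FALSE] |>
    (\(x) { rownames(x) <- NULL; x })()
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact two-sided interval from beta tail inversion: the same interval
#' reported by `stats::binom.test`. Degenerate edges follow the closed
#' forms `x = 0 -> (0, 1 - (alpha/2)^(1/n))` and
#' `x = n -> ((alpha/2)^(1/n), 1)`.
#'
#' @param x Successes (vectorized). @param n Trials. @param alpha Two-sided
#'   error rate (default 0.05 for a 95% interval).
#' @return Data frame with columns `low`, `high`; `NA` rows where `n = 0`.
#' @export
clopper_pearson_ci <- function(x, n, alpha = 0.05) {
  stopifnot(all(x >= 0 & x <= n | n == 0))
  low <- ifelse(n == 0, NA_real_,
                ifelse(x == 0, 0, stats::qbeta(alpha / 2, x, n - x + 1)))
  high <- ifelse(n == 0, NA_real_,
                 ifelse(x == n & n > 0, 1,
                        stats::qbeta(1 - alpha / 2, x + 1, n - x)))
  data.frame(low = low, high = high)
}

#' Risk classification from case/control counts
#'
#' A genotype observed fewer than `min_obs` times (default 5) is
#' `unclassified`. Otherwise penetrance bands assign `low` below the first
#' cut, `moderate` between the cuts and `high` at or above the second. The
#' default cuts 0.25 and 0.75 cover the observed ranges in the reference
#' cohort (low-risk genotypes under 6% penetrance, moderate 33-50%, high
#' 90-100%) and reproduce every published label without ambiguity.
#'
#' @param cases,controls Combined counts per genotype (vectorized).
#' @param min_obs Minimum observations for classification.
#' @param cuts Length-2 numeric: low/moderate and moderate/high cut points.
#' @return Factor with levels `low`, `moderate`, `high`, `unclassified`.
#' @export
classify_risk <- function(cases, controls, min_obs = 5,
                          cuts = c(0.25, 0.75)) {
  n <- cases + controls
  pen <- ifelse(n > 0, cases / n, NA_real_)
  cls <- rep("unclassified", length(n))
  ok <- n >= min_obs
  cls[ok & pen < cuts[1]] <- "low"
  cls[ok & pen >= cuts[1] & pen < cuts[2]] <- "moderate"
  cls[ok & pen >= cuts[2]] <- "high"
  factor(cls, levels = c("low", "moderate", "high", "unclassified"))
}

#' Tabulate the 27 three-locus genotypes of a cohort
#'
#' Counts cases and controls per genotype and breed, estimates penetrance
#' (combined cases / combined observations) with its Clopper-Pearson
#' interval, classifies risk, and tests each genotype against the
#' population-wide disease rate.
#'
#' @param cohort A fully genotyped `dms_cohort`.
#' @param statuses Statuses counted as unaffected, in addition to `"case"`.
#' @param min_obs,cuts Passed to [classify_risk()].
#' @param p_method Passed to [genotype_vs_population_test()].
#' @return Data frame of 27 rows (class `penetrance_table`) with columns
#'   `genotype`, per-breed counts (`cases_<breed>`, `controls_<breed>` for
#'   collie and sheltie; other breeds pooled as `other`), `cases`,
#'   `controls`, `penetrance`, `percent` (rounded integer percent),
#'   `ci_low`, `ci_high`, `risk`, `p_vs_population`.
#' @export
tabulate_three_locus <- function(cohort,
                                 statuses = c("control",
                                              "unaffected_unscreened"),
                                 min_obs = 5, cuts = c(0.25, 0.75),
                                 p_method = c("binomial", "fisher_rest")) {
  p_method <- match.arg(p_method)
  keep <- cohort$status %in% c("case", statuses)
  sub <- cohort[keep, , drop = FALSE]
  labels <- all_three_locus_labels()
  lab <- three_locus_label(sub)$label
  is_case <- sub$status == "case"
  breed <- ifelse(sub$breed %in% c("collie", "sheltie"), sub$breed, "other")
  out <- data.frame(genotype = labels, stringsAsFactors = FALSE)
  for (b in intersect(c("collie", "sheltie", "other"), unique(breed))) {
    out[[paste0("cases_", b)]] <-
      as.integer(table(factor(lab[is_case & breed == b], levels = labels)))
    out[[paste0("controls_", b)]] <-
      as.integer(table(factor(lab[!is_case & breed == b], levels = labels)))
  }
  out$cases <- as.integer(table(factor(lab[is_case], levels = labels)))
  out$controls <- as.integer(table(factor(lab[!is_case], levels = labels)))
  n <- out$cases + out$controls
  out$penetrance <- ifelse(n > 0, out$cases / n, NA_real_)
  out$percent <- ifelse(n > 0, as.integer(round(100 * out$penetrance)), NA)
  ci <- clopper_pearson_ci(out$cases, n)
  out$ci_low <- ci$low
  out$ci_high <- ci$high
  out$risk <- classify_risk(out$cases, out$controls, min_obs, cuts)
  total_cases <- sum(out$cases)
  total_n <- sum(n)
  out$p_vs_population <- vapply(seq_len(nrow(out)), function(i) {
    genotype_vs_population_test(out$cases[i], out$controls[i],
                                total_cases, total_n, method = p_method)
  }, numeric(1))
  class(out) <- c("penetrance_table", "data.frame")
  out
}

#' Fraction of cases explained by a set of risk classes
#'
#' Sum of case counts over genotypes in the given classes, divided by all
#' cases. With the reference counts, the moderate and high classes together
#' cover 117 of 132 cases (88.6%).
#'
#' @param entries A `penetrance_table` from [tabulate_three_locus()].
#' @param classes Character vector of risk classes to include.
#' @return Fraction in \[0, 1\] (0 when the class set is empty or no cases).
#' @export
cases_explained <- function(entries, classes = c("moderate", "high")) {
  total <- sum(entries$cases)
  if (total == 0) return(0)
  sum(entries$cases[entries$risk %in% classes]) / total
}
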