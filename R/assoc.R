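# Exact 2x2 association machinery: Fisher's exact test (point-probability
# two-tailed rule), odds ratios with Woolf confidence intervals, and the
# haplotype- and dog-level DLA association layouts.

#' Fisher's exact two-tailed p-value for a 2x2 table
#'
#' Two-tailing follows the point-probability rule: the p-value is the sum of
#' hypergeometric probabilities, over all tables with the observed margins,
#' that do not exceed the probability of the observed table. This is the rule
#' used by `stats::fisher.test` and by classical exact-test calculators.
#'
#' @param a,b,c,d Cell counts: `a` exposed cases, `b` unexposed cases,
#'   `c` exposed controls, `d` unexposed controls.
#' @return p-value in (0, 1]. A degenerate table (a zero row together with a
#'   zero column, leaving nothing to compare) returns 1 with a warning.
#' @export
fisher_exact_two_tailed <- function(a, b, c, d) {
  stopifnot(length(a) == 1, a >= 0, b >= 0, c >= 0, d >= 0)
  if ((a + b == 0 || c + d == 0) && (a + c == 0 || b + d == 0)) {
    warning("degenerate 2x2 table (zero row and zero column); p = 1")
    return(1)
  }
  fisher2x2_p(a, b, c, d)
}

# Vectorized point-probability two-tailed Fisher kernel. For each table the
# support of the hypergeometric count in cell `a` given fixed margins is
# enumerated directly; probabilities <= that of the observed table (within a
# relative tolerance guarding against floating-point ties) are summed.
fisher2x2_p <- function(a, b, c, d) {
  mapply(function(a, b, c, d) {
    m <- a + c            # exposed margin
    n <- b + d            # unexposed margin
    k <- a + b            # case margin
    if (m == 0 || n == 0 || k == 0 || c + d == 0) return(1)
    support <- max(0, k - n):min(k, m)
    probs <- stats::dhyper(support, m, n, k)
    p_obs <- stats::dhyper(a, m, n, k)
    min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }, a, b, c, d)
}

#' Odds ratio with Woolf (log-normal) confidence interval
#'
#' OR = (a d)/(b c); the CI is `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c +
#' 1/d))`. With any zero cell the OR and CI are undefined unless
#' `correct = TRUE`, in which case 0.5 is added to every cell (Haldane
#' correction) and the result is flagged `corrected`.
#'
#' @param a,b,c,d Cell counts as in [fisher_exact_two_tailed()].
#' @param alpha Two-sided confidence level is `1 - alpha` (default 0.05).
#' @param correct Apply the 0.5 continuity correction when a cell is zero.
#' @return An object of class `assoc_result`: list with `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_two_tailed`, `method`, `corrected`, `table`.
#' @export
odds_ratio_woolf <- function(a, b, c, d, alpha = 0.05, correct = FALSE) {
  p <- fisher_exact_two_tailed(a, b, c, d)
  cells <- c(a, b, c, d)
  corrected <- FALSE
  if (any(cells == 0)) {
    if (correct) {
      cells <- cells + 0.5
      corrected <- TRUE
    } else {
      return(structure(list(odds_ratio = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, p_two_tailed = p,
                            method = "fisher_exact", corrected = FALSE,
                            table = c(a = a, b = b, c = c, d = d)),
                       class = "assoc_result"))
    }
  }
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - alpha / 2)
  structure(list(
    odds_ratio = or,
    ci_low = exp(log(or) - z * se),
    ci_high = exp(log(or) + z * se),
    p_two_tailed = p,
    method = "fisher_exact",
    corrected = corrected,
    table = c(a = a, b = b, c = c, d = d)
  ), class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("2x2 association (a=%g b=%g c=%g d=%g)\n",
              x$table["a"], x$table["b"], x$table["c"], x$table["d"]))
  if (is.na(x$odds_ratio)) {
    cat("  OR undefined (zero cell, no continuity correction)\n")
  } else {
    cat(sprintf("  OR = %.2f  95%% CI %.2f-%.2f%s\n", x$odds_ratio,
                x$ci_low, x$ci_high,
                if (x$corrected) "  (0.5 correction)" else ""))
  }
  cat(sprintf("  Fisher exact two-tailed p = %.4g\n", x$p_two_tailed))
  invisible(x)
}

# Dogs eligible for DLA case-control comparisons, with haplotypes typed.
dla_complete <- function(cohort, breed = NULL,
                         statuses = c("case", "control",
                                      "unaffected_unscreened")) {
  keep <- cohort$status %in% statuses
  if (!is.null(breed)) keep <- keep & cohort$breed %in% breed
  sub <- cohort[keep, , drop = FALSE]
  typed <- !is.na(sub$drb1_1) & !is.na(sub$drb1_2)
  list(dogs = sub[typed, , drop = FALSE], n_excluded = sum(!typed))
}

#' Haplotype-level (2n) DLA case-control association
#'
#' Each diploid dog contributes two haplotype observations, so a cohort of
#' `n` dogs yields `2n` alleles per disease group. The 2x2 table compares the
#' target haplotype against all other haplotypes in cases versus controls.
#' Haplotypes are identified by their DRB1 allele (each observed haplotype
#' has a unique DRB1 allele). When a single haplotype exceeds 90% frequency
#' in the stratum the result is flagged low-power: such near-fixation
#' precludes detection of association, as in the collie population.
#'
#' @param cohort A `dms_cohort`.
#' @param haplotype DRB1 allele string naming the haplotype (default the
#'   risk haplotype).
#' @param breed Optional breed filter (e.g. `"sheltie"`).
#' @param statuses Statuses counted as unaffected comparison dogs, in
#'   addition to `"case"`; defaults to both control sets.
#' @return An `assoc_result` with extra fields `counts`
#'   (named vector: haplotype/other alleles by group), `n_excluded`
#'   (dogs dropped for missing haplotypes) and `low_power`.
#' @export
haplotype_association <- function(cohort, haplotype = DLA_RISK_DRB1,
                                  breed = NULL,
                                  statuses = c("control",
                                               "unaffected_unscreened")) {
  sub <- dla_complete(cohort, breed, c("case", statuses))
  dogs <- sub$dogs
  is_case <- dogs$status == "case"
  alleles <- c(dogs$drb1_1, dogs$drb1_2)
  case_allele <- rep(is_case, 2)
  a <- sum(alleles == haplotype & case_allele)
  b <- sum(alleles != haplotype & case_allele)
  c_ <- sum(alleles == haplotype & !case_allele)
  d <- sum(alleles != haplotype & !case_allele)
  res <- odds_ratio_woolf(a, b, c_, d)
  res$counts <- c(hap_cases = a, other_cases = b,
                  hap_controls = c_, other_controls = d)
  res$n_excluded <- sub$n_excluded
  tab <- table(alleles)
  res$low_power <- length(tab) > 0 && max(tab) / sum(tab) > 0.9
  if (res$low_power) {
    warning("one haplotype exceeds 90% frequency; association is low-power",
            call. = FALSE)
  }
  res
}

#' Dog-level homozygosity association for a DLA haplotype
#'
#' Exposure is homozygosity for the target haplotype; the 2x2 table counts
#' homozygous versus non-homozygous dogs in cases and controls.
#'
#' @inheritParams haplotype_association
#' @return An `assoc_result` with `counts`
#'   (hom/non-hom dogs by group) and `n_excluded`.
#' @export
homozygosity_association <- function(cohort, haplotype = DLA_RISK_DRB1,
                                     breed = NULL,
                                     statuses = c("control",
                                                  "unaffected_unscreened")) {
  sub <- dla_complete(cohort, breed, c("case", statuses))
  dogs <- sub$dogs
  hom <- dogs$drb1_1 == haplotype & dogs$drb1_2 == haplotype
  is_case <- dogs$status == "case"
  a <- sum(hom & is_case)
  b <- sum(!hom & is_case)
  c_ <- sum(hom & !is_case)
  d <- sum(!hom & !is_case)
  res <- odds_ratio_woolf(a, b, c_, d)
  res$counts <- c(hom_cases = a, nonhom_cases = b,
                  hom_controls = c_, nonhom_controls = d)
  res$n_excluded <- sub$n_excluded
  res
}

#' Genotype-versus-population test for a three-locus genotype
#'
#' Tests whether the case fraction within one three-locus genotype departs
#' from the cohort-wide disease rate. The default is the exact binomial test
#' of the genotype's case count against the population rate
#' `p0 = total_cases / total_n` (the convention that reproduces the
#' published per-genotype p-values, e.g. 0.253 for a single AAbbcc case
#' observed once). `method = "fisher_rest"` instead runs Fisher's exact test
#' of the genotype's dogs against all remaining dogs.
#'
#' @param genotype_cases,genotype_controls Case/control counts in the
#'   genotype class.
#' @param total_cases Total cases in the cohort.
#' @param total_n Total dogs in the cohort.
#' @param method `"binomial"` (default) or `"fisher_rest"`.
#' @param p0 Population disease rate for the binomial test; defaults to
#'   `total_cases / total_n`.
#' @return Two-tailed p-value; a genotype observed zero times returns 1.
#' @export
genotype_vs_population_test <- function(genotype_cases, genotype_controls,
                                        total_cases, total_n,
                                        method = c("binomial", "fisher_rest"),
                                        p0 = NULL) {
  method <- match.arg(method)
  n_geno <- genotype_cases + genotype_controls
  stopifnot(genotype_cases <= total_cases, n_geno <= total_n)
  if (n_geno == 0) return(1)
  if (method == "binomial") {
    if (is.null(p0)) p0 <- total_cases / total_n
    stats::binom.test(genotype_cases, n_geno, p = p0)$p.value
  } else {
    fisher_exact_two_tailed(genotype_cases, genotype_controls,
                            total_cases - genotype_cases,
                            (total_n - total_cases) - genotype_controls)
  }
}
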