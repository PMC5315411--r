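# SNP panel container, quality control, dominant-model Fisher GWAS,
# Bonferroni threshold and genomic-control inflation factor.

#' Construct a SNP panel
#'
#' Container for an array-style genotype matrix: a map of SNPs (positions
#' strictly increasing within chromosome), a dogs x SNPs matrix of minor
#' allele counts (0/1/2/NA), and per-dog metadata.
#'
#' @param map Data frame with columns `chrom`, `pos` (1-based), `id`.
#' @param geno Integer matrix, dogs in rows, SNPs in columns (0, 1, 2, NA).
#' @param samples Data frame with at least `dog_id` and `status`
#'   (`case`/`control`); optionally `breed`.
#' @return Object of class `snp_panel`.
#' @export
snp_panel <- function(map, geno, samples) {
  stopifnot(nrow(map) == ncol(geno), nrow(samples) == nrow(geno),
            all(c("chrom", "pos", "id") %in% names(map)),
            all(c("dog_id", "status") %in% names(samples)))
  for (chr in unique(map$chrom)) {
    p <- map$pos[map$chrom == chr]
    if (any(diff(p) <= 0)) {
      stop("positions must be strictly increasing within chromosome ", chr)
    }
  }
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) stop("genotype values must be 0, 1, 2 or NA")
  colnames(geno) <- map$id
  structure(list(map = map, geno = geno, samples = samples),
            class = "snp_panel")
}

#' Read a PLINK-style .ped/.map text pair into a SNP panel
#'
#' Minimal reader for uncompressed PLINK text files: the .map gives
#' chromosome, id, (ignored genetic distance) and position; the .ped gives
#' family/individual ids, parents, sex, phenotype (1 = control, 2 = case)
#' and two allele columns per SNP (`0` = missing). Genotypes are recoded as
#' counts of the panel-wide minor allele.
#'
#' @param ped,map Paths to the .ped and .map files.
#' @return An `snp_panel`.
#' @export
read_ped_map <- function(ped, map) {
  mp <- utils::read.table(map, header = FALSE, stringsAsFactors = FALSE)
  names(mp)[c(1, 2, 4)] <- c("chrom", "id", "pos")
  pd <- utils::read.table(ped, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  meta <- pd[, 1:6]
  allele <- as.matrix(pd[, -(1:6), drop = FALSE])
  n_snp <- ncol(allele) / 2
  stopifnot(n_snp == nrow(mp))
  geno <- matrix(NA_integer_, nrow(pd), n_snp)
  for (j in seq_len(n_snp)) {
    a1 <- allele[, 2 * j - 1]
    a2 <- allele[, 2 * j]
    obs <- c(a1[a1 != "0"], a2[a2 != "0"])
    alleles <- names(sort(table(obs)))          # minor allele first
    if (length(alleles) == 0) next
    minor <- alleles[1]
    g <- (a1 == minor) + (a2 == minor)
    g[a1 == "0" | a2 == "0"] <- NA
    geno[, j] <- as.integer(g)
  }
  samples <- data.frame(
    dog_id = meta[, 2],
    status = ifelse(meta[, 6] == "2", "case", "control"),
    stringsAsFactors = FALSE
  )
  snp_panel(mp[, c("chrom", "pos", "id")], geno, samples)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the observed allele counts, the p-value is
#' the sum of probabilities of heterozygote counts whose conditional
#' probability does not exceed that of the observed count. Vectorized over
#' SNPs. Robust near the 5% minor-allele-frequency filter boundary, where
#' chi-square approximations misbehave.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (vectorized).
#' @return p-values in (0, 1]; monomorphic or empty samples give 1.
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  mapply(function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    if (n == 0) return(1)
    n_a <- 2 * naa + nAa            # rare-allele count (by convention below)
    if (n_a > n) n_a <- 2 * n - n_a # fold so n_a is the rarer allele count
    if (n_a == 0) return(1)
    hets <- seq(n_a %% 2, n_a, by = 2)
    # conditional probability of each heterozygote count given allele counts:
    # multinomial over (rare hom, het, common hom) / binomial over alleles
    rare_hom <- (n_a - hets) / 2
    common_hom <- n - rare_hom - hets
    logp <- lgamma(n + 1) - lgamma(rare_hom + 1) - lgamma(hets + 1) -
      lgamma(common_hom + 1) + hets * log(2) -
      (lgamma(2 * n + 1) - lgamma(n_a + 1) - lgamma(2 * n - n_a + 1))
    p <- exp(logp - max(logp))
    p <- p / sum(p)
    obs <- which(hets == nAa)
    if (length(obs) == 0) return(1)
    min(1, sum(p[p <= p[obs] * (1 + 1e-7)]))
  }, n_AA, n_Aa, n_aa)
}

#' SNP and sample quality control
#'
#' Applies the array QC used before association testing: samples with call
#' rates below `sample_call_rate` are removed first; then SNPs are excluded
#' for call rate below `call_rate`, minor allele frequency below `maf`, or
#' deviation from Hardy-Weinberg equilibrium in the control dogs at
#' `hwe_p` (exact test). Every exclusion is logged with its reason.
#'
#' @param panel An `snp_panel`.
#' @param call_rate,maf,hwe_p,sample_call_rate QC thresholds
#'   (defaults 0.95, 0.05, 1e-4, 0.95).
#' @return List: `panel` (filtered), `snp_exclusions` (data frame id,
#'   reason), `sample_exclusions` (dog ids).
#' @export
qc_filter_snps <- function(panel, call_rate = 0.95, maf = 0.05,
                           hwe_p = 1e-4, sample_call_rate = 0.95) {
  geno <- panel$geno
  sample_cr <- rowMeans(!is.na(geno))
  drop_samples <- sample_cr < sample_call_rate
  geno <- geno[!drop_samples, , drop = FALSE]
  samples <- panel$samples[!drop_samples, , drop = FALSE]

  cr <- colMeans(!is.na(geno))
  freq <- colMeans(geno, na.rm = TRUE) / 2
  maf_obs <- pmin(freq, 1 - freq)
  maf_obs[is.nan(maf_obs)] <- 0

  is_control <- samples$status == "control"
  if (!any(is_control)) {
    warning("no control dogs; HWE filter skipped", call. = FALSE)
    hwe <- rep(1, ncol(geno))
  } else {
    gc <- geno[is_control, , drop = FALSE]
    n2 <- colSums(gc == 2, na.rm = TRUE)
    n1 <- colSums(gc == 1, na.rm = TRUE)
    n0 <- colSums(gc == 0, na.rm = TRUE)
    hwe <- hwe_exact_p(n0, n1, n2)
  }

  reason <- rep(NA_character_, ncol(geno))
  reason[hwe < hwe_p] <- "hwe"
  reason[maf_obs < maf] <- "maf"
  reason[cr < call_rate] <- "call_rate"   # highest precedence in the log
  keep <- is.na(reason)
  filtered <- snp_panel(panel$map[keep, , drop = FALSE],
                        geno[, keep, drop = FALSE], samples)
  list(panel = filtered,
       snp_exclusions = data.frame(id = panel$map$id[!keep],
                                   reason = reason[!keep],
                                   stringsAsFactors = FALSE),
       sample_exclusions = panel$samples$dog_id[drop_samples])
}

#' Dominant-model Fisher exact GWAS
#'
#' Per SNP, dogs are collapsed to carriers (one or two copies of the minor
#' allele) versus non-carriers, and a two-tailed Fisher exact test compares
#' carrier status between cases and controls. Monomorphic SNPs give p = 1.
#'
#' @param panel A QC'd `snp_panel`.
#' @return Data frame with columns `chrom`, `pos`, `id`, `carrier_cases`,
#'   `noncarrier_cases`, `carrier_controls`, `noncarrier_controls`, `p`.
#' @export
dominant_fisher_gwas <- function(panel) {
  is_case <- panel$samples$status == "case"
  carrier <- panel$geno >= 1
  a <- colSums(carrier & is_case, na.rm = TRUE)
  b <- colSums(!carrier & is_case, na.rm = TRUE)
  c_ <- colSums(carrier & !is_case, na.rm = TRUE)
  d <- colSums(!carrier & !is_case, na.rm = TRUE)
  out <- panel$map[, c("chrom", "pos", "id")]
  out$carrier_cases <- a
  out$noncarrier_cases <- b
  out$carrier_controls <- c_
  out$noncarrier_controls <- d
  out$p <- fisher2x2_p(a, b, c_, d)
  rownames(out) <- NULL
  out
}

#' Bonferroni significance threshold
#'
#' `alpha / n_tests`; with the 98,520 SNPs that survive QC this is
#' 5.08e-7.
#'
#' @param n_tests Number of tests (>= 1). @param alpha Family-wise error
#'   rate (default 0.05).
#' @return The per-test threshold.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  stopifnot(n_tests >= 1)
  alpha / n_tests
}

#' Genomic-control inflation factor
#'
#' Median-based lambda: observed p-values are converted to 1-df chi-square
#' quantiles and the median is divided by the null median
#' `qchisq(0.5, 1) = 0.4549`.
#'
#' @param p Vector of p-values (at least 100 for a stable median).
#' @return lambda (1 under a well-calibrated null).
#' @export
genomic_inflation <- function(p) {
  p <- p[is.finite(p)]
  if (length(p) < 100) stop("need at least 100 p-values")
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}
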