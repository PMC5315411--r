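# Synthetic-cohort and synthetic-input generators. These produce every
# input the analyses consume -- cohort tables, SNP panels, pooled allele
# counts and VCFs -- with the statistical structure the analyses assume:
# breed-specific risk-allele and DLA haplotype frequencies, the reference
# penetrance architecture, Weibull onset ages decreasing with risk-allele
# count, first-order LD with a lead SNP, a low-heterozygosity sweep region
# and Merle/PAN2 repulsion. Every generator is a pure function of its
# arguments and seed: identical inputs give identical outputs.

#' Breed genetics specification
#'
#' Allele and haplotype frequencies for one simulated breed. Defaults (via
#' [default_breed_specs()]) are implied by the reference genotype counts,
#' which keeps the generator internally consistent with the penetrance
#' architecture; the published per-breed allele-frequency summaries
#' (collie A 42%, B 5%; Shetland sheepdog A 25%, B 38%) are available as an
#' alternative parameterization through `freq_A`/`freq_B`.
#'
#' @param breed Breed name.
#' @param freq_A,freq_B Risk-allele frequencies of PAN2 A and MAP3K7CL B.
#' @param dla_freqs Named numeric vector of DLA haplotype frequencies
#'   (names are DRB1 alleles; must sum to 1).
#' @param merle_freq Frequency of the PMEL Merle allele M.
#' @param merle_dprime Target repulsion D' between M and A (M occurs on
#'   a-haplotypes).
#' @return List of class `breed_genetics_spec`.
#' @export
breed_genetics_spec <- function(breed, freq_A, freq_B, dla_freqs,
                                merle_freq = 0.1, merle_dprime = 0.998) {
  stopifnot(freq_A >= 0, freq_A <= 1, freq_B >= 0, freq_B <= 1,
            abs(sum(dla_freqs) - 1) < 1e-8, merle_freq >= 0,
            merle_dprime >= 0, merle_dprime <= 1)
  structure(list(breed = breed, freq_A = freq_A, freq_B = freq_B,
                 dla_freqs = dla_freqs, merle_freq = merle_freq,
                 merle_dprime = merle_dprime),
            class = "breed_genetics_spec")
}

# Allele frequency of the upper-case risk allele implied by genotype counts
# over the 27 reference labels.
implied_freq <- function(counts, letter_pos) {
  labels <- counts$genotype
  n <- rowSums(counts[, -1])
  geno <- substr(labels, letter_pos, letter_pos + 1)
  dose <- (substr(geno, 1, 1) %in% LETTERS) + (substr(geno, 2, 2) %in% LETTERS)
  sum(dose * n) / (2 * sum(n))
}

#' Default per-breed genetics specifications
#'
#' Collie and Shetland sheepdog specs with A/B allele frequencies implied
#' by the reference genotype counts and DLA haplotype frequencies matching
#' the observed control haplotype distributions (collies nearly fixed for
#' the 002:01 risk haplotype; Shetland sheepdogs segregating 002:01 and the
#' protective 023:01).
#'
#' @return Named list of two `breed_genetics_spec` objects.
#' @export
default_breed_specs <- function() {
  counts <- dms_reference_counts()
  col <- counts[, c("genotype", "collie_cases", "collie_controls")]
  sh <- counts[, c("genotype", "sheltie_cases", "sheltie_controls")]
  list(
    collie = breed_genetics_spec(
      "collie",
      freq_A = implied_freq(col, 1),
      freq_B = implied_freq(col, 3),
      dla_freqs = c("002:01" = 353 / 370, "006:01" = 3 / 370,
                    "015:01" = 14 / 370)),
    sheltie = breed_genetics_spec(
      "sheltie",
      freq_A = implied_freq(sh, 1),
      freq_B = implied_freq(sh, 3),
      dla_freqs = c("002:01" = 301 / 410, "015:01" = 6 / 410,
                    "023:01" = 102 / 410, "other" = 1 / 410))
  )
}

#' Penetrance specification
#'
#' Maps each of the 27 three-locus genotypes to a disease probability and
#' sets the Weibull onset distribution per risk-allele-count class. The
#' default assigns every moderate- and high-risk genotype its observed
#' combined penetrance from the reference counts and 0.02 to low-risk and
#' unclassified genotypes; onset uses shape 1.6 with class medians of 18.5,
#' 9 and 5 months for two, three and four risk alleles (the intermediate
#' class is interpolated; dogs with fewer than two risk alleles, rare among
#' cases, reuse the two-allele scale).
#'
#' @param pen Named numeric vector over the 27 labels (probabilities).
#' @param onset_shape Weibull shape r.
#' @param onset_medians Named vector of class median onset ages (months)
#'   for AB risk-allele counts `"0"`..`"4"`.
#' @return List of class `penetrance_spec` (includes derived `onset_scales`).
#' @export
penetrance_spec <- function(pen = NULL, onset_shape = 1.6,
                            onset_medians = c("0" = 18.5, "1" = 18.5,
                                              "2" = 18.5, "3" = 9,
                                              "4" = 5)) {
  if (is.null(pen)) {
    counts <- dms_reference_counts()
    cases <- counts$collie_cases + counts$sheltie_cases
    controls <- counts$collie_controls + counts$sheltie_controls
    risk <- classify_risk(cases, controls)
    pen <- ifelse(risk %in% c("moderate", "high"),
                  cases / (cases + controls), 0.02)
    names(pen) <- counts$genotype
  }
  stopifnot(all(pen >= 0 & pen <= 1),
            setequal(names(pen), all_three_locus_labels()))
  scales <- onset_medians / log(2)^(1 / onset_shape)
  structure(list(pen = pen, onset_shape = onset_shape,
                 onset_medians = onset_medians, onset_scales = scales),
            class = "penetrance_spec")
}

# Draw onset ages (months) for cases given AB risk-allele counts.
draw_onset <- function(ab_count, pen_spec) {
  scales <- pen_spec$onset_scales[as.character(ab_count)]
  stats::rweibull(length(ab_count), shape = pen_spec$onset_shape,
                  scale = scales)
}

#' Simulate a cohort under breed genetics and penetrance specifications
#'
#' Loci are drawn independently per breed under Hardy-Weinberg equilibrium
#' (the three risk loci lie on different chromosomes); the one deliberate
#' LD exception is PMEL Merle, generated jointly with PAN2 at the haplotype
#' level to hit the target repulsion D'. DLA haplotypes are drawn as pairs
#' from the breed haplotype frequency vector. Disease status is
#' Bernoulli(penetrance of the three-locus genotype); cases receive Weibull
#' onset ages by risk-allele-count class.
#'
#' @param n_per_breed Named integer vector of cohort sizes (names must
#'   match `specs`).
#' @param specs Per-breed specs (default [default_breed_specs()]).
#' @param pen_spec A [penetrance_spec()].
#' @param seed Integer seed.
#' @return A `dms_cohort`.
#' @export
simulate_cohort <- function(n_per_breed = c(collie = 225, sheltie = 297),
                            specs = default_breed_specs(),
                            pen_spec = penetrance_spec(), seed = 1) {
  set.seed(seed)
  rows <- list()
  for (b in names(n_per_breed)) {
    spec <- specs[[b]]
    n <- n_per_breed[[b]]
    if (n == 0) next
    # PAN2 and PMEL haplotypes drawn jointly to realize Merle repulsion:
    # hap classes (A,M), (A,m), (a,M), (a,m) with D' pulling A away from M
    fa <- spec$freq_A
    fm <- spec$merle_freq
    d <- -spec$merle_dprime * min(fa * fm, (1 - fa) * (1 - fm))
    hfreq <- c(AM = fa * fm + d, Am = fa * (1 - fm) - d,
               aM = (1 - fa) * fm - d, am = (1 - fa) * (1 - fm) + d)
    hfreq <- pmax(hfreq, 0)
    hap1 <- sample(names(hfreq), n, replace = TRUE, prob = hfreq)
    hap2 <- sample(names(hfreq), n, replace = TRUE, prob = hfreq)
    a_dose <- (substr(hap1, 1, 1) == "A") + (substr(hap2, 1, 1) == "A")
    m_dose <- (substr(hap1, 2, 2) == "M") + (substr(hap2, 2, 2) == "M")
    b_dose <- stats::rbinom(n, 2, spec$freq_B)
    dla1 <- sample(names(spec$dla_freqs), n, replace = TRUE,
                   prob = spec$dla_freqs)
    dla2 <- sample(names(spec$dla_freqs), n, replace = TRUE,
                   prob = spec$dla_freqs)
    pan2 <- c("aa", "Aa", "AA")[a_dose + 1L]
    map3 <- c("bb", "Bb", "BB")[b_dose + 1L]
    c_dose <- (dla1 == DLA_RISK_DRB1) + (dla2 == DLA_RISK_DRB1)
    label <- paste0(pan2, map3, c("cc", "Cc", "CC")[c_dose + 1L])
    p_disease <- pen_spec$pen[label]
    is_case <- stats::runif(n) < p_disease
    onset <- rep(NA_real_, n)
    if (any(is_case)) {
      ab <- (a_dose + b_dose)[is_case]
      onset[is_case] <- draw_onset(ab, pen_spec)
    }
    rows[[b]] <- data.frame(
      dog_id = sprintf("%s_%04d", b, seq_len(n)),
      breed = b,
      status = ifelse(is_case, "case", "control"),
      pan2 = pan2, map3k7cl = map3,
      drb1_1 = dla1, drb1_2 = dla2,
      onset_age_months = onset,
      merle = m_dose > 0,
      stringsAsFactors = FALSE
    )
  }
  as_cohort(do.call(rbind, rows))
}

#' Simulate a cohort reproducing the reference genotype counts exactly
#'
#' Emits one record per dog of the reference distribution: per breed and
#' three-locus genotype, exactly the case/control counts of
#' [dms_reference_counts()] (522 dogs; 132 cases). Dog ids are synthetic
#' and row order is shuffled by the seed. Onset ages are drawn from the
#' onset model of `pen_spec`; merle flags are drawn only for dogs carrying
#' at least one wild-type a allele, respecting the Merle/PAN2 repulsion.
#' This fixture drives the exact reproduction tests of the association and
#' penetrance statistics.
#'
#' @param seed Integer seed (affects order, onset ages and merle flags
#'   only, never the genotype counts).
#' @param pen_spec A [penetrance_spec()] for onset ages.
#' @return A `dms_cohort` of 522 dogs.
#' @export
simulate_table3_cohort <- function(seed = 1, pen_spec = penetrance_spec()) {
  set.seed(seed)
  counts <- dms_reference_counts()
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    label <- counts$genotype[i]
    pan2 <- substr(label, 1, 2)
    map3 <- substr(label, 3, 4)
    cg <- substr(label, 5, 6)
    c_dose <- (substr(cg, 1, 1) == "C") + (substr(cg, 2, 2) == "C")
    for (b in c("collie", "sheltie")) {
      alt_hap <- if (b == "collie") "015:01" else "023:01"
      drb1_1 <- if (c_dose >= 1) DLA_RISK_DRB1 else alt_hap
      drb1_2 <- if (c_dose == 2) DLA_RISK_DRB1 else alt_hap
      for (st in c("case", "control")) {
        n <- counts[i, paste0(b, if (st == "case") "_cases" else
                                "_controls")]
        if (n == 0) next
        rows[[length(rows) + 1L]] <- data.frame(
          breed = b, status = st, pan2 = pan2, map3k7cl = map3,
          drb1_1 = drb1_1, drb1_2 = drb1_2, stringsAsFactors = FALSE
        )[rep(1, n), , drop = FALSE]
      }
    }
  }
  df <- do.call(rbind, rows)
  df <- df[sample.int(nrow(df)), , drop = FALSE]
  rownames(df) <- NULL
  df$dog_id <- sprintf("dog_%04d", seq_len(nrow(df)))
  a_dose <- genotype_dose(df$pan2, "A")
  b_dose <- genotype_dose(df$map3k7cl, "B")
  df$onset_age_months <- NA_real_
  is_case <- df$status == "case"
  df$onset_age_months[is_case] <- draw_onset((a_dose + b_dose)[is_case],
                                             pen_spec)
  has_a <- a_dose < 2
  df$merle <- has_a & stats::runif(nrow(df)) < 0.25
  as_cohort(df)
}

#' Simulate an unphased SNP panel with first-order LD
#'
#' Haplotypes are generated with first-order LD decay (each allele copies
#' its left neighbour with probability `ld_rho`, otherwise draws fresh at
#' the SNP's frequency) and paired at random into unphased genotypes. An
#' optional causal SNP raises the disease probability of carriers by the
#' given relative risk. The phased haplotypes are retained as an attribute
#' so haplotype-frequency LD oracles can be checked against the phase-free
#' estimators.
#'
#' @param n_dogs Number of diploid samples.
#' @param n_snps Number of SNPs (>= 100).
#' @param causal_index SNP index of the causal variant, or NULL for a null
#'   panel.
#' @param carrier_rr Relative risk of carriers of the causal allele.
#' @param ld_rho Neighbour-copy probability in \[0, 1\] (0 = linkage
#'   equilibrium).
#' @param maf_range Range of simulated allele frequencies.
#' @param base_risk Baseline disease probability.
#' @param spacing_bp Mean inter-SNP spacing in bp.
#' @param seed Integer seed.
#' @return An `snp_panel` with attributes `haplotypes` (2n x m 0/1 matrix)
#'   and `causal_index`.
#' @export
simulate_snp_panel <- function(n_dogs = 160, n_snps = 1000,
                               causal_index = NULL, carrier_rr = 1,
                               ld_rho = 0.8, maf_range = c(0.1, 0.5),
                               base_risk = 0.3, spacing_bp = 1000,
                               seed = 1) {
  stopifnot(n_snps >= 100)
  set.seed(seed)
  freqs <- stats::runif(n_snps, maf_range[1], maf_range[2])
  n_hap <- 2 * n_dogs
  haps <- matrix(0L, n_hap, n_snps)
  haps[, 1] <- stats::rbinom(n_hap, 1, freqs[1])
  if (n_snps > 1) {
    for (j in 2:n_snps) {
      copy <- stats::runif(n_hap) < ld_rho
      fresh <- stats::rbinom(n_hap, 1, freqs[j])
      haps[, j] <- ifelse(copy, haps[, j - 1], fresh)
    }
  }
  geno <- haps[seq(1, n_hap, 2), ] + haps[seq(2, n_hap, 2), ]
  pos <- cumsum(pmax(1, stats::rpois(n_snps, spacing_bp)))
  map <- data.frame(chrom = "1", pos = pos,
                    id = sprintf("snp%05d", seq_len(n_snps)),
                    stringsAsFactors = FALSE)
  p_case <- rep(base_risk, n_dogs)
  if (!is.null(causal_index)) {
    carrier <- geno[, causal_index] >= 1
    p_case[carrier] <- pmin(0.95, base_risk * carrier_rr)
  }
  status <- ifelse(stats::runif(n_dogs) < p_case, "case", "control")
  samples <- data.frame(dog_id = sprintf("dog%04d", seq_len(n_dogs)),
                        status = status, stringsAsFactors = FALSE)
  panel <- snp_panel(map, geno, samples)
  attr(panel, "haplotypes") <- haps
  attr(panel, "causal_index") <- causal_index
  panel
}

#' Simulate pooled allele counts with an optional selective sweep
#'
#' Background SNPs draw their pooled minor-allele count from a neutral-like
#' spectrum (probability proportional to 1/k for k minor alleles among the
#' pooled genomes); inside the sweep region minor counts are thinned
#' binomially toward zero according to the fixation level (1 = complete
#' fixation, Hp 0 in fully contained windows).
#'
#' @param chrom_length Chromosome length in bp.
#' @param n_snps Number of SNPs.
#' @param sweep List `(start, end, fixation)` or NULL for a neutral
#'   chromosome.
#' @param n_genomes Number of pooled diploid genomes (default 5).
#' @param chrom Chromosome name (default `"12"`).
#' @param seed Integer seed.
#' @return Data frame `chrom`, `pos`, `n_major`, `n_minor` sorted by
#'   position.
#' @export
simulate_pooled_counts <- function(chrom_length = 60e6, n_snps = 10000,
                                   sweep = list(start = 20e6, end = 21.2e6,
                                                fixation = 1),
                                   n_genomes = 5, chrom = "12", seed = 1) {
  set.seed(seed)
  pos <- sort(sample.int(chrom_length, n_snps))
  n_alleles <- 2 * n_genomes
  kmax <- floor(n_alleles / 2)
  k <- sample.int(kmax, n_snps, replace = TRUE, prob = 1 / seq_len(kmax))
  if (!is.null(sweep)) {
    stopifnot(sweep$start >= 1, sweep$end <= chrom_length)
    inside <- pos >= sweep$start & pos <= sweep$end
    k[inside] <- stats::rbinom(sum(inside), k[inside], 1 - sweep$fixation)
  }
  data.frame(chrom = chrom, pos = pos, n_major = n_alleles - k, n_minor = k,
             stringsAsFactors = FALSE)
}

#' Simulate a VCF with a planted segregation pattern
#'
#' Writes `n_total` biallelic variants inside the interval, of which
#' exactly `n_matching` satisfy the given segregation pattern; every
#' non-matching variant violates the pattern in at least one sample. A
#' truth table records which variants were planted as matching.
#'
#' @param interval Region string or list (`chrom`, `start`, `end`).
#' @param pattern Named character vector as for [segregation_filter()].
#' @param n_total,n_matching Variant counts (`n_matching <= n_total`).
#' @param extra_samples Number of additional unconstrained samples.
#' @param path Optional output path; when given the VCF is written there.
#' @param seed Integer seed.
#' @return List: `variants` (a `variant_set`), `truth` (data frame `id`,
#'   `matches`), `path` (NULL unless written).
#' @export
simulate_variant_vcf <- function(interval, pattern, n_total, n_matching,
                                 extra_samples = 2, path = NULL, seed = 1) {
  stopifnot(n_matching <= n_total)
  set.seed(seed)
  r <- parse_region(interval)
  samples <- c(names(pattern),
               if (extra_samples > 0) sprintf("other%02d",
                                              seq_len(extra_samples)))
  pos <- sort(sample(seq(r$start, r$end), n_total))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_total, replace = TRUE)
  alt <- vapply(ref, function(x) sample(setdiff(bases, x), 1), character(1))
  matches <- rep(FALSE, n_total)
  matches[sample.int(n_total, n_matching)] <- TRUE
  state_for <- function(req, match) {
    satisfy <- switch(req,
                      hom = sample(c("hom_ref", "hom_alt"), 1),
                      req)
    violate_pool <- switch(req,
                           hom = "het",
                           het = c("hom_ref", "hom_alt"),
                           hom_alt = c("hom_ref", "het"),
                           hom_ref = c("hom_alt", "het"))
    if (match) satisfy else sample(violate_pool, 1)
  }
  df <- data.frame(chrom = r$chrom, pos = pos,
                   id = sprintf("var%04d", seq_len(n_total)),
                   ref = ref, alt = alt, stringsAsFactors = FALSE)
  for (s in samples) df[[paste0("gt_", s)]] <- NA_character_
  for (i in seq_len(n_total)) {
    if (length(pattern) > 0) {
      if (matches[i]) {
        states <- vapply(pattern, state_for, character(1), match = TRUE)
      } else {
        # violate in at least one randomly chosen constrained sample
        states <- vapply(pattern, state_for, character(1), match = TRUE)
        viol <- sample(seq_along(pattern), 1)
        states[viol] <- state_for(pattern[[viol]], match = FALSE)
      }
      for (s in names(pattern)) df[[paste0("gt_", s)]][i] <- states[[s]]
    }
    for (s in setdiff(samples, names(pattern))) {
      df[[paste0("gt_", s)]][i] <- sample(c("hom_ref", "het", "hom_alt"), 1)
    }
  }
  vs <- variant_set(df, samples)
  if (!is.null(path)) write_variants_vcf(vs, path)
  list(variants = vs, truth = data.frame(id = df$id, matches = matches,
                                         stringsAsFactors = FALSE),
       path = path)
}
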