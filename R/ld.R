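# Linkage disequilibrium: phase-free genotype-correlation r-squared, the
# candidate-interval demarcation rule, and EM-based D' between unphased
# biallelic loci (used for the PMEL Merle / PAN2 repulsion analysis).

#' Pairwise r-squared of every SNP with a lead SNP
#'
#' Composite (phase-free) LD estimate: the squared Pearson correlation of
#' minor-allele counts across dogs, computed per SNP against the lead. No
#' phasing or EM is required, matching the unphased array data. By default
#' only control dogs enter the calculation.
#'
#' @param panel An `snp_panel`.
#' @param lead SNP id of the lead SNP.
#' @param statuses Samples to use (default `"control"`; use
#'   `c("case", "control")` for all dogs).
#' @return Object of class `ld_profile`: the panel map restricted to the
#'   lead's chromosome with columns `r2` and `monomorphic` (such SNPs get
#'   r2 = 0 and are flagged); attributes `lead`, `lead_pos`.
#' @export
pairwise_r2 <- function(panel, lead, statuses = "control") {
  stopifnot(lead %in% panel$map$id)
  keep <- panel$samples$status %in% statuses
  geno <- panel$geno[keep, , drop = FALSE]
  chrom <- panel$map$chrom[panel$map$id == lead]
  on_chrom <- panel$map$chrom == chrom
  map <- panel$map[on_chrom, c("chrom", "pos", "id")]
  g <- geno[, on_chrom, drop = FALSE]
  g_lead <- geno[, lead]
  sds <- apply(g, 2, stats::sd, na.rm = TRUE)
  mono <- is.na(sds) | sds == 0
  r2 <- rep(0, ncol(g))
  if (stats::sd(g_lead, na.rm = TRUE) > 0) {
    r2[!mono] <- suppressWarnings(
      as.vector(stats::cor(g_lead, g[, !mono, drop = FALSE],
                           use = "pairwise.complete.obs"))^2)
  }
  r2[is.na(r2)] <- 0
  map$r2 <- r2
  map$monomorphic <- mono
  rownames(map) <- NULL
  structure(map, lead = lead, lead_pos = map$pos[map$id == lead],
            class = c("ld_profile", "data.frame"))
}

#' Demarcate a candidate interval around a lead SNP
#'
#' The candidate region is characterized by the SNPs in high LD with the
#' lead (pairwise r2 >= `r2_min`, default 0.6) and defined by the first
#' flanking *associated* SNPs in lower LD: on each side the interval
#' endpoint is the position of the nearest SNP with `p <= p_threshold` and
#' r2 below the cut. Where no such flanking SNP exists the interval
#' truncates at the chromosome end (start clamps to 1; the end clamps to
#' the last mapped position) and is flagged `truncated`. If no SNP besides
#' the lead reaches `r2_min`, the interval degenerates to the nearest
#' flanking associated SNPs and is flagged `degenerate`.
#'
#' @param profile An `ld_profile` from [pairwise_r2()].
#' @param assoc GWAS results containing `id` and `p`
#'   (from [dominant_fisher_gwas()]).
#' @param p_threshold Association threshold defining "associated" flanking
#'   SNPs; defaults to the Bonferroni threshold for the number of tests in
#'   `assoc`.
#' @param r2_min LD cut (default 0.6).
#' @return List of class `candidate_interval`: `chrom`, `start`, `end`
#'   (1-based inclusive), `core_start`/`core_end` (span of the high-LD
#'   block), `flags`.
#' @export
demarcate_candidate_interval <- function(profile, assoc,
                                         p_threshold = NULL, r2_min = 0.6) {
  if (is.null(p_threshold)) p_threshold <- bonferroni_threshold(nrow(assoc))
  p <- assoc$p[match(profile$id, assoc$id)]
  lead_pos <- attr(profile, "lead_pos")
  chrom <- profile$chrom[1]
  flags <- character(0)
  block <- profile$pos[profile$r2 >= r2_min]
  if (length(block) <= 1) {
    flags <- c(flags, "degenerate")
    core <- c(lead_pos, lead_pos)
  } else {
    core <- range(block)
  }
  flank_ok <- !is.na(p) & p <= p_threshold & profile$r2 < r2_min
  left <- profile$pos[flank_ok & profile$pos < core[1]]
  right <- profile$pos[flank_ok & profile$pos > core[2]]
  if (length(left) > 0) {
    start <- max(left)
  } else {
    start <- 1
    flags <- c(flags, "truncated_left")
  }
  if (length(right) > 0) {
    end <- min(right)
  } else {
    end <- max(profile$pos)
    flags <- c(flags, "truncated_right")
  }
  structure(list(chrom = chrom, start = start, end = end,
                 core_start = core[1], core_end = core[2], flags = flags),
            class = "candidate_interval")
}

#' Convert a 1-based inclusive interval to a 0-based half-open BED row
#'
#' @param interval A `candidate_interval` or list with `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @return Data frame with columns `chrom`, `start` (0-based), `end`.
#' @export
as_bed <- function(interval) {
  data.frame(chrom = interval$chrom, start = interval$start - 1L,
             end = interval$end, stringsAsFactors = FALSE)
}

# EM estimation of two-locus haplotype frequencies from unphased biallelic
# genotypes (dose coding 0/1/2 at each locus). Returns the 2x2 haplotype
# frequency table for alleles (A1, a1) x (A2, a2).
em_haplotype_freqs <- function(g1, g2, max_iter = 1000, tol = 1e-12) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  if (n == 0) stop("no complete genotype pairs")
  pA <- mean(g1) / 2
  pB <- mean(g2) / 2
  # haplotype frequencies: h[1]=AB, h[2]=Ab, h[3]=aB, h[4]=ab
  h <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  h <- pmax(h, 1e-10); h <- h / sum(h)
  dh <- g1 == 1 & g2 == 1                 # double heterozygotes
  # haplotype contributions from unambiguous genotypes: every dog except a
  # double heterozygote has a unique phase resolution
  counts_fixed <- c(AB = 0, Ab = 0, aB = 0, ab = 0)
  for (i in which(!dh)) {
    a_copies <- g1[i]; b_copies <- g2[i]
    hapAB <- min(a_copies, b_copies)
    hapAb <- a_copies - hapAB
    hapaB <- b_copies - hapAB
    hapab <- 2 - hapAB - hapAb - hapaB
    counts_fixed <- counts_fixed + c(hapAB, hapAb, hapaB, hapab)
  }
  n_dh <- sum(dh)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # E-step: double-hets are AB/ab with probability prop. to h1*h4
    denom <- h[1] * h[4] + h[2] * h[3]
    w <- if (denom > 0) h[1] * h[4] / denom else 0.5
    counts <- counts_fixed +
      n_dh * c(w, 1 - w, 1 - w, w)
    h_new <- counts / (2 * n)
    if (max(abs(h_new - h)) < tol) {
      h <- h_new
      converged <- TRUE
      break
    }
    h <- h_new
  }
  list(h = h, n = n, converged = converged)
}

# Log-likelihood of unphased genotype pairs under haplotype frequencies h.
ll_genotypes <- function(g1, g2, h) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  hap_dose <- rbind(AB = c(1, 1), Ab = c(1, 0), aB = c(0, 1), ab = c(0, 0))
  ll <- 0
  for (i in seq_along(g1)) {
    prob <- 0
    for (j in 1:4) for (k in j:4) {
      if (hap_dose[j, 1] + hap_dose[k, 1] == g1[i] &&
          hap_dose[j, 2] + hap_dose[k, 2] == g2[i]) {
        prob <- prob + (if (j == k) h[j]^2 else 2 * h[j] * h[k])
      }
    }
    ll <- ll + log(max(prob, 1e-300))
  }
  ll
}

#' D-prime between two unphased biallelic loci
#'
#' Haplotype frequencies are estimated by EM over the unphased genotype
#' pairs (the only ambiguity, double heterozygotes, is resolved
#' probabilistically each iteration); D' is the disequilibrium coefficient
#' normalized by its maximum given the allele frequencies, reported as an
#' absolute value. Significance of D != 0 is assessed with a likelihood
#' ratio test (1 df) against the independence model.
#'
#' @param g1,g2 Integer vectors of allele-dose genotypes (0/1/2) at the two
#'   loci; `NA` pairs are dropped.
#' @return List of class `dprime_result`: `d_prime`, `d`, `p_value`,
#'   `hap_freqs` (AB, Ab, aB, ab), `n`, `converged`.
#' @export
d_prime <- function(g1, g2) {
  em <- em_haplotype_freqs(g1, g2)
  if (!em$converged) {
    warning("EM did not converge; returning best estimate", call. = FALSE)
  }
  h <- unname(em$h)
  pA <- h[1] + h[2]
  pB <- h[1] + h[3]
  d <- h[1] - pA * pB
  d_max <- if (d >= 0) {
    min(pA * (1 - pB), (1 - pA) * pB)
  } else {
    min(pA * pB, (1 - pA) * (1 - pB))
  }
  dp <- if (d_max > 0) abs(d) / d_max else 0
  h0 <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  lrt <- 2 * (ll_genotypes(g1, g2, h) - ll_genotypes(g1, g2, h0))
  p <- stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
  structure(list(d_prime = dp, d = d, p_value = p,
                 hap_freqs = c(AB = h[1], Ab = h[2], aB = h[3], ab = h[4]),
                 n = em$n, converged = em$converged),
            class = "dprime_result")
}

#' Merle/PAN2 linkage disequilibrium from a cohort
#'
#' Encodes the PMEL Merle locus from the merle phenotype flag (merle dogs
#' are assumed heterozygous Mm, non-merle mm) and computes D' against the
#' PAN2 genotype. In the affected breeds Merle occurs in repulsion with the
#' PAN2 risk allele A: the M-A haplotype is essentially absent.
#'
#' @param cohort A `dms_cohort` with merle flags; dogs with missing flags
#'   are dropped.
#' @return A `dprime_result` (D' between M and A).
#' @export
pmel_pan2_dprime <- function(cohort) {
  ok <- !is.na(cohort$merle) & !is.na(cohort$pan2)
  sub <- cohort[ok, , drop = FALSE]
  g_m <- as.integer(sub$merle)            # Mm = 1 copy of M, mm = 0
  g_a <- genotype_dose(sub$pan2, "A")
  d_prime(g_m, g_a)
}
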