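# Pooled-heterozygosity selective-sweep scan: creeping windows over pooled
# per-SNP allele counts, the Hp statistic, Z-transformation and calling of
# regions more than `z` standard deviations below the mean.

#' Build creeping windows over ordered pooled SNP counts
#'
#' Greedy variable-size non-overlapping windows: a window accrues
#' consecutive SNPs while its accumulated span stays within `max_span`
#' (default 1 Mb), where inter-SNP gaps larger than `gap` (default 10 kb)
#' contribute nothing to the accumulated span; when the span would overflow,
#' the window closes and the next begins at the following SNP. Windows with
#' fewer than `min_snps` SNPs (default 50) are kept in the output but
#' flagged `retained = FALSE` and excluded from the Z-distribution. With
#' `gap_mode = "break"` a gap larger than `gap` instead closes the current
#' window.
#'
#' @param counts Data frame with columns `chrom`, `pos`, `n_major`,
#'   `n_minor`, sorted by position within chromosome.
#' @param max_span Maximum accumulated window span in bp (default 1e6).
#' @param min_snps Minimum SNPs for a window to enter statistics.
#' @param gap Gap size in bp beyond which inter-SNP distance is ignored
#'   (or breaks the window, per `gap_mode`).
#' @param gap_mode `"ignore"` (default: large gaps add nothing to the span)
#'   or `"break"` (large gaps terminate the window).
#' @param mode `"creeping"` (default) or `"sliding"`: overlapping
#'   fixed-span windows advanced by `step` bp, for sensitivity analysis.
#' @param step Step size in bp for `mode = "sliding"` (default half the
#'   span).
#' @return Data frame of windows: `chrom`, `start`, `end`, `n_snps`,
#'   `first_snp`, `last_snp` (row indices into `counts`), `retained`.
#' @export
build_creeping_windows <- function(counts, max_span = 1e6, min_snps = 50,
                                   gap = 1e4, gap_mode = c("ignore",
                                                           "break"),
                                   mode = c("creeping", "sliding"),
                                   step = max_span / 2) {
  gap_mode <- match.arg(gap_mode)
  mode <- match.arg(mode)
  if (mode == "sliding") {
    out <- list()
    for (chr in unique(counts$chrom)) {
      idx <- which(counts$chrom == chr)
      pos <- counts$pos[idx]
      starts <- seq(min(pos), max(pos), by = step)
      for (s in starts) {
        inside <- which(pos >= s & pos < s + max_span)
        if (length(inside) == 0) next
        out[[length(out) + 1L]] <- data.frame(
          chrom = chr, start = s, end = min(s + max_span - 1, max(pos)),
          n_snps = length(inside), first_snp = idx[inside[1]],
          last_snp = idx[inside[length(inside)]])
      }
    }
    windows <- do.call(rbind, out)
    windows$retained <- windows$n_snps >= min_snps
    rownames(windows) <- NULL
    return(windows)
  }
  out <- list()
  for (chr in unique(counts$chrom)) {
    idx <- which(counts$chrom == chr)
    pos <- counts$pos[idx]
    stopifnot(!is.unsorted(pos, strictly = FALSE))
    w_start <- 1L
    span <- 0
    i <- 1L
    while (i < length(idx) + 1L) {
      if (i > w_start) {
        d <- pos[i] - pos[i - 1L]
        big_gap <- d > gap
        add <- if (big_gap) 0 else d
        if ((gap_mode == "break" && big_gap) || span + add > max_span) {
          out[[length(out) + 1L]] <- data.frame(
            chrom = chr, start = pos[w_start], end = pos[i - 1L],
            n_snps = i - w_start, first_snp = idx[w_start],
            last_snp = idx[i - 1L])
          w_start <- i
          span <- 0
        } else {
          span <- span + add
        }
      }
      i <- i + 1L
    }
    if (w_start <= length(idx)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = pos[w_start], end = pos[length(idx)],
        n_snps = length(idx) - w_start + 1L, first_snp = idx[w_start],
        last_snp = idx[length(idx)])
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_snps = integer(0),
                      first_snp = integer(0), last_snp = integer(0),
                      retained = logical(0)))
  }
  windows <- do.call(rbind, out)
  windows$retained <- windows$n_snps >= min_snps
  rownames(windows) <- NULL
  windows
}

#' Pooled heterozygosity of a window
#'
#' `Hp = 2 * sum(n_major) * sum(n_minor) / (sum(n_major) + sum(n_minor))^2`
#' where the sums run over the SNPs of the window and the counts are pooled
#' major/minor allele counts across sequenced genomes. Hp lies in
#' \[0, 0.5\]: 0 when every SNP is fixed for the major allele, 0.5 when the
#' pooled counts balance.
#'
#' @param n_major,n_minor Pooled allele counts of the window's SNPs.
#' @return Hp.
#' @export
pooled_heterozygosity <- function(n_major, n_minor) {
  stopifnot(length(n_major) == length(n_minor), all(n_major >= n_minor),
            all(n_minor >= 0))
  maj <- sum(n_major)
  mnr <- sum(n_minor)
  if (maj + mnr == 0) stop("empty window: no alleles")
  2 * maj * mnr / (maj + mnr)^2
}

#' Z-transformed pooled-heterozygosity scan
#'
#' Computes Hp per window, Z-transforms over the retained windows (mean 0,
#' standard deviation 1) and flags windows with `-ZHp > z` (default 3.4
#' standard deviations below the mean heterozygosity) as putatively swept.
#' Adjacent flagged windows are merged into regions.
#'
#' @param counts Pooled allele counts (`chrom`, `pos`, `n_major`,
#'   `n_minor`).
#' @param windows Windows from [build_creeping_windows()]; built with
#'   defaults when omitted.
#' @param z Flagging threshold in standard deviations (default 3.4).
#' @param ... Passed to [build_creeping_windows()] when `windows` is NULL.
#' @return The window data frame with columns `hp`, `zhp`, `flagged`
#'   (NA zhp for non-retained windows) and an attribute `regions`: a data
#'   frame of merged flagged regions (`chrom`, `start`, `end`, `n_windows`,
#'   `span`).
#' @export
zhp_scan <- function(counts, windows = NULL, z = 3.4, ...) {
  if (is.null(windows)) windows <- build_creeping_windows(counts, ...)
  if (sum(windows$retained) < 2) {
    stop("need at least two retained windows for the Z-transform")
  }
  windows$hp <- vapply(seq_len(nrow(windows)), function(i) {
    rows <- windows$first_snp[i]:windows$last_snp[i]
    pooled_heterozygosity(counts$n_major[rows], counts$n_minor[rows])
  }, numeric(1))
  hp_ret <- windows$hp[windows$retained]
  s <- stats::sd(hp_ret)
  if (s == 0) stop("zero variance in Hp across retained windows")
  windows$zhp <- ifelse(windows$retained,
                        (windows$hp - mean(hp_ret)) / s, NA_real_)
  windows$flagged <- !is.na(windows$zhp) & (-windows$zhp > z)
  # merge adjacent flagged retained windows into regions
  regions <- list()
  flagged_idx <- which(windows$flagged)
  if (length(flagged_idx) > 0) {
    grp <- cumsum(c(1, diff(flagged_idx) != 1 |
                      windows$chrom[flagged_idx[-1]] !=
                      windows$chrom[flagged_idx[-length(flagged_idx)]]))
    for (gi in unique(grp)) {
      rows <- flagged_idx[grp == gi]
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = windows$chrom[rows[1]],
        start = min(windows$start[rows]),
        end = max(windows$end[rows]),
        n_windows = length(rows))
    }
  }
  regions <- if (length(regions) > 0) {
    r <- do.call(rbind, regions)
    r$span <- r$end - r$start + 1
    r
  } else {
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               n_windows = integer(0), span = numeric(0))
  }
  attr(windows, "regions") <- regions
  windows
}

#' Flagged sweep regions of a scan
#'
#' @param scan Result of [zhp_scan()].
#' @return The merged flagged-region data frame.
#' @export
sweep_regions <- function(scan) {
  attr(scan, "regions")
}

#' Derive pooled allele counts from a multi-sample VCF
#'
#' Pools GT fields across all samples of a VCF into per-SNP major/minor
#' allele counts suitable for [zhp_scan()].
#'
#' @param path Path to an uncompressed or bgzipped VCF.
#' @return Data frame `chrom`, `pos`, `n_major`, `n_minor`.
#' @export
pooled_counts_from_vcf <- function(path) {
  v <- read_variants_vcf(path)
  gt_cols <- attr(v, "gt_cols")
  gt <- as.matrix(v[, gt_cols, drop = FALSE])
  n_alt <- rowSums(matrix(c(hom_ref = 0, het = 1, hom_alt = 2,
                            missing = NA)[gt], nrow = nrow(gt)),
                   na.rm = TRUE)
  n_called <- rowSums(matrix(gt != "missing", nrow = nrow(gt)))
  n_total <- 2 * n_called
  n_ref <- n_total - n_alt
  data.frame(chrom = v$chrom, pos = v$pos,
             n_major = pmax(n_ref, n_alt), n_minor = pmin(n_ref, n_alt))
}
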