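# Sequence-variant filtering: candidate-interval restriction, segregation
# patterns across sequenced samples, exon +/- 10 bp annotation, and
# cross-breed uniqueness screening.

gt_states <- c("hom_ref", "het", "hom_alt", "missing")

#' Construct a variant set
#'
#' A variant set is a data frame of biallelic records (`chrom`, `pos`,
#' `id`, `ref`, `alt`) with one genotype column per sequenced sample
#' (`gt_<sample>`) holding one of `hom_ref`, `het`, `hom_alt`, `missing`.
#'
#' @param df Data frame with the columns above.
#' @param samples Character vector of sample names (the `gt_` columns must
#'   exist for each).
#' @return Object of class `variant_set`.
#' @export
variant_set <- function(df, samples) {
  gt_cols <- paste0("gt_", samples)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(df)),
            all(gt_cols %in% names(df)))
  for (col in gt_cols) {
    bad <- !df[[col]] %in% gt_states
    if (any(bad)) stop("invalid genotype state(s) in ", col, ": ",
                       paste(unique(df[[col]][bad]), collapse = ", "))
  }
  if (any(!nzchar(df$ref)) || any(!nzchar(df$alt))) {
    stop("ref and alt alleles must be non-empty")
  }
  structure(df, samples = samples, gt_cols = gt_cols,
            class = c("variant_set", "data.frame"))
}

# Re-attach variant_set attributes after subsetting rows.
reset_vs <- function(df, template, excluded = NULL) {
  structure(df, samples = attr(template, "samples"),
            gt_cols = attr(template, "gt_cols"), excluded = excluded,
            class = c("variant_set", "data.frame"))
}

#' Read a VCF into a variant set
#'
#' Parses a plain or bgzipped VCFv4.x with `vcfR`. Multi-allelic records
#' are split into one biallelic record per alternate allele; a sample's
#' state for a given alternate allele is the number of copies of that
#' allele it carries (so a 1/2 call is `het` for both split records).
#'
#' @param path VCF path.
#' @return A `variant_set`.
#' @export
read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- t(fx)    # single-record VCF drops to vector
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- t(gt)
  samples <- colnames(gt)
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      alleles <- lapply(strsplit(gt[i, ], "[/|]"), as.integer)
      state <- vapply(alleles, function(al) {
        if (length(al) == 0 || anyNA(al)) return("missing")
        copies <- sum(al == k)
        c("hom_ref", "het", "hom_alt")[copies + 1L]
      }, character(1))
      row <- data.frame(chrom = fix$CHROM[i], pos = as.numeric(fix$POS[i]),
                        id = if (is.na(fix$ID[i])) "." else fix$ID[i],
                        ref = fix$REF[i], alt = alts[k],
                        stringsAsFactors = FALSE)
      for (s in seq_along(samples)) row[[paste0("gt_", samples[s])]] <- state[s]
      rows[[length(rows) + 1L]] <- row
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  variant_set(df, samples)
}

#' Write a variant set as VCFv4.2 text
#'
#' @param variants A `variant_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  samples <- attr(variants, "samples")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t")), con)
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
               missing = "./.")
  for (i in seq_len(nrow(variants))) {
    gts <- vapply(attr(variants, "gt_cols"),
                  function(cl) gt_code[[variants[[cl]][i]]], character(1))
    writeLines(paste(c(variants$chrom[i], format(variants$pos[i],
                                                 scientific = FALSE),
                       variants$id[i], variants$ref[i], variants$alt[i],
                       ".", "PASS", ".", "GT", gts), collapse = "\t"), con)
  }
  invisible(path)
}

#' Parse a region string
#'
#' @param x Region like `"chr10:1-1333693"` (1-based inclusive), or a list
#'   with `chrom`, `start`, `end` (returned unchanged).
#' @return List with `chrom`, `start`, `end`.
#' @export
parse_region <- function(x) {
  if (is.list(x)) return(x[c("chrom", "start", "end")])
  m <- regmatches(x, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", x))[[1]]
  if (length(m) != 4) stop("cannot parse region: ", x)
  list(chrom = m[2], start = as.numeric(gsub(",", "", m[3])),
       end = as.numeric(gsub(",", "", m[4])))
}

#' Restrict variants to a candidate interval
#'
#' Keeps variants whose position lies inside the 1-based inclusive
#' interval; both boundary positions are retained.
#'
#' @param variants A `variant_set`.
#' @param interval Region string, list, or `candidate_interval`.
#' @return Filtered `variant_set` with an `excluded` attribute (count).
#' @export
restrict_to_interval <- function(variants, interval) {
  r <- parse_region(interval)
  keep <- variants$chrom == r$chrom & variants$pos >= r$start &
    variants$pos <= r$end
  reset_vs(variants[keep, , drop = FALSE], variants,
           excluded = c(out_of_interval = sum(!keep)))
}

#' Filter variants by a segregation pattern
#'
#' A pattern names, per sequenced sample, the genotype state a variant must
#' show to be consistent with the allele states at the associated lead
#' SNPs: `het`, `hom_alt`, `hom_ref`, or `hom` (either homozygote,
#' reference/reference or alternate/alternate). A variant with a missing
#' call in any required sample is dropped and counted separately.
#'
#' @param variants A `variant_set`.
#' @param pattern Named character vector, names = sample names,
#'   values = required states. An empty pattern is the identity filter.
#' @return Filtered `variant_set`; attribute `excluded` holds counts
#'   `mismatch` and `missing`.
#' @export
segregation_filter <- function(variants, pattern) {
  if (length(pattern) == 0) {
    return(reset_vs(variants, variants,
                    excluded = c(mismatch = 0L, missing = 0L)))
  }
  samples <- attr(variants, "samples")
  unknown <- setdiff(names(pattern), samples)
  if (length(unknown) > 0) {
    stop("pattern names sample(s) absent from the call set: ",
         paste(unknown, collapse = ", "))
  }
  ok <- rep(TRUE, nrow(variants))
  has_missing <- rep(FALSE, nrow(variants))
  for (s in names(pattern)) {
    gt <- variants[[paste0("gt_", s)]]
    has_missing <- has_missing | gt == "missing"
    matches <- if (pattern[[s]] == "hom") {
      gt %in% c("hom_ref", "hom_alt")
    } else {
      gt == pattern[[s]]
    }
    ok <- ok & matches
  }
  keep <- ok & !has_missing
  reset_vs(variants[keep, , drop = FALSE], variants,
           excluded = c(mismatch = sum(!ok & !has_missing),
                        missing = sum(has_missing)))
}

#' Read exon intervals from BED or GFF3
#'
#' BED input (0-based half-open) is converted to 1-based inclusive; GFF3
#' input keeps rows whose feature type is `exon`.
#'
#' @param path Path to a `.bed`, `.gff`/`.gff3` file.
#' @return Data frame `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_exons <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    g <- utils::read.table(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
    g <- g[g[[3]] == "exon", , drop = FALSE]
    data.frame(chrom = g[[1]], start = g[[4]], end = g[[5]],
               stringsAsFactors = FALSE)
  } else {
    b <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    data.frame(chrom = b[[1]], start = b[[2]] + 1L, end = b[[3]],
               stringsAsFactors = FALSE)
  }
}

#' Keep variants in exons or splice-site flanks
#'
#' Retains variants lying within any exon extended by `flank` bp (default
#' 10) on each side, capturing canonical splice sites.
#'
#' @param variants A `variant_set`.
#' @param exons Data frame `chrom`, `start`, `end` (1-based inclusive) or a
#'   path readable by [read_exons()].
#' @param flank Flank size in bp.
#' @return Filtered `variant_set` with `excluded` count attribute.
#' @export
exonic_splice_filter <- function(variants, exons, flank = 10) {
  if (is.character(exons)) exons <- read_exons(exons)
  ex <- GenomicRanges::GRanges(
    exons$chrom,
    IRanges::IRanges(pmax(1L, exons$start - flank), exons$end + flank))
  vr <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, variants$pos))
  keep <- IRanges::overlapsAny(vr, ex)
  reset_vs(variants[keep, , drop = FALSE], variants,
           excluded = c(not_exonic = sum(!keep)))
}

#' Keep variants unique to the study breeds
#'
#' Retains a variant only if its alternate allele is absent from every
#' sample of the comparison panel (other-breed genomes) and absent from the
#' known-variant catalog (dbSNP-style), matching on chromosome, position
#' and alternate allele.
#'
#' @param variants A `variant_set`.
#' @param panel_variants Data frame `chrom`, `pos`, `alt` of variants
#'   observed in other-breed genomes (NULL = no panel).
#' @param catalog Data frame `chrom`, `pos`, `alt` of known variants
#'   (NULL = no catalog).
#' @return Filtered `variant_set`; `excluded` counts `in_panel` and
#'   `in_catalog`.
#' @export
uniqueness_filter <- function(variants, panel_variants = NULL,
                              catalog = NULL) {
  key <- paste(variants$chrom, variants$pos, variants$alt)
  in_panel <- if (is.null(panel_variants)) rep(FALSE, nrow(variants)) else {
    key %in% paste(panel_variants$chrom, panel_variants$pos,
                   panel_variants$alt)
  }
  in_catalog <- if (is.null(catalog)) rep(FALSE, nrow(variants)) else {
    key %in% paste(catalog$chrom, catalog$pos, catalog$alt)
  }
  keep <- !in_panel & !in_catalog
  reset_vs(variants[keep, , drop = FALSE], variants,
           excluded = c(in_panel = sum(in_panel),
                        in_catalog = sum(in_catalog & !in_panel)))
}

#' Run the full variant-filter cascade
#'
#' Applies interval restriction, segregation filtering, exon/splice
#' annotation and uniqueness screening in sequence (the filters commute as
#' set operations; the order only affects which filter an excluded variant
#' is attributed to) and reports per-filter exclusion counts.
#'
#' @param variants A `variant_set`.
#' @param interval,pattern,exons,panel_variants,catalog Passed to the
#'   respective filters; NULL skips a step.
#' @param flank Exon flank (default 10).
#' @return List: `retained` (a `variant_set`) and `report` (data frame
#'   `filter`, `excluded`, `remaining`).
#' @export
filter_variants <- function(variants, interval = NULL, pattern = NULL,
                            exons = NULL, panel_variants = NULL,
                            catalog = NULL, flank = 10) {
  report <- list()
  log_step <- function(name, before, after) {
    data.frame(filter = name, excluded = before - nrow(after),
               remaining = nrow(after), stringsAsFactors = FALSE)
  }
  cur <- variants
  if (!is.null(interval)) {
    nxt <- restrict_to_interval(cur, interval)
    report[[length(report) + 1L]] <- log_step("interval", nrow(cur), nxt)
    cur <- nxt
  }
  if (!is.null(pattern)) {
    nxt <- segregation_filter(cur, pattern)
    report[[length(report) + 1L]] <- log_step("segregation", nrow(cur), nxt)
    cur <- nxt
  }
  if (!is.null(exons)) {
    nxt <- exonic_splice_filter(cur, exons, flank)
    report[[length(report) + 1L]] <- log_step("exonic_splice", nrow(cur), nxt)
    cur <- nxt
  }
  if (!is.null(panel_variants) || !is.null(catalog)) {
    nxt <- uniqueness_filter(cur, panel_variants, catalog)
    report[[length(report) + 1L]] <- log_step("uniqueness", nrow(cur), nxt)
    cur <- nxt
  }
  list(retained = cur, report = do.call(rbind, report))
}
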