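# Cohort data model: one row per dog with breed, disease status, PAN2 and
# MAP3K7CL genotypes, DLA class II haplotypes, age at onset and merle flag.

#' DLA-DRB1 allele marking the risk haplotype
#'
#' The class II risk haplotype *DLA-DRB1\*002:01/-DQA1\*009:01/-DQB1\*001:01*
#' is identified by its DRB1 allele alone, because every observed haplotype
#' carries a unique DRB1 allele. A dog's C dose is the number of its
#' haplotypes whose DRB1 allele equals this constant.
#' @export
DLA_RISK_DRB1 <- "002:01"

#' Known DLA class II haplotypes, keyed by DRB1 allele
#'
#' Lookup used to infer full three-locus DLA haplotypes from a DRB1 genotype.
#' Each row is one haplotype observed in collies or Shetland sheepdogs; the
#' DRB1 allele is unique per haplotype, so DQA1/DQB1 can be filled in from
#' DRB1 alone. The table is editable: pass your own data frame with the same
#' columns to [infer_haplotype_from_drb1()].
#'
#' @param path Optional path to a tab-separated lookup with columns
#'   `drb1`, `dqa1`, `dqb1`; defaults to the copy shipped in
#'   `inst/extdata/dla_haplotypes.tsv`.
#' @return A data frame with columns `drb1`, `dqa1`, `dqb1`.
#' @export
dla_haplotype_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dla_haplotypes.tsv",
                        package = "trilocus")
  }
  if (nzchar(path) && file.exists(path)) {
    return(utils::read.table(path, header = TRUE, sep = "\t",
                             colClasses = "character"))
  }
  data.frame(
    drb1 = c("002:01", "006:01", "015:01", "023:01"),
    dqa1 = c("009:01", "050:11", "009:01", "003:01"),
    dqb1 = c("001:01", "007:01", "001:01", "005:01"),
    stringsAsFactors = FALSE
  )
}

#' Infer a full DLA haplotype from a DRB1 allele
#'
#' Unknown DRB1 alleles are flagged rather than fatal: the risk status is
#' still computed (it depends on DRB1 only) but the DQA1/DQB1 partners are
#' returned as `NA`.
#'
#' @param drb1 Character vector of DRB1 allele strings (e.g. `"002:01"`).
#' @param lookup Data frame mapping `drb1` to `dqa1`/`dqb1`;
#'   defaults to [dla_haplotype_table()].
#' @return Data frame with one row per input allele: `drb1`, `dqa1`, `dqb1`,
#'   `is_risk_C` (TRUE iff DRB1 equals [DLA_RISK_DRB1]) and `known`
#'   (FALSE when the allele was absent from the lookup).
#' @export
infer_haplotype_from_drb1 <- function(drb1, lookup = dla_haplotype_table()) {
  stopifnot(is.character(drb1), all(c("drb1", "dqa1", "dqb1") %in% names(lookup)))
  idx <- match(drb1, lookup$drb1)
  data.frame(
    drb1 = drb1,
    dqa1 = lookup$dqa1[idx],
    dqb1 = lookup$dqb1[idx],
    is_risk_C = !is.na(drb1) & drb1 == DLA_RISK_DRB1,
    known = !is.na(idx),
    stringsAsFactors = FALSE
  )
}

cohort_statuses <- c("case", "control", "unaffected_unscreened")

# Normalize an unphased biallelic genotype string to one of exactly three
# states (e.g. "aA" -> "Aa"). `risk` is the upper-case risk allele letter.
normalize_genotype <- function(x, risk) {
  wild <- tolower(risk)
  valid <- c(paste0(risk, risk), paste0(risk, wild), paste0(wild, wild))
  x <- as.character(x)
  # order-normalize heterozygotes
  x[x == paste0(wild, risk)] <- paste0(risk, wild)
  bad <- !is.na(x) & !(x %in% valid)
  if (any(bad)) {
    stop(sprintf("malformed %s/%s genotype at row(s) %s: %s",
                 risk, wild, paste(which(bad), collapse = ", "),
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  x
}

# Allele dose of the risk allele implied by a normalized genotype string.
genotype_dose <- function(x, risk) {
  wild <- tolower(risk)
  unname(c(2L, 1L, 0L)[match(x, c(paste0(risk, risk), paste0(risk, wild),
                                  paste0(wild, wild)))])
}

#' Construct and validate a cohort
#'
#' Validates the invariants of the cohort data model: unique dog ids, exactly
#' three genotype states per locus (order-normalized at entry, `Aa == aA`),
#' both DLA haplotypes typed or both missing (half-typed records are
#' rejected rather than guessed), onset age positive and present only for
#' cases, and statuses drawn from `case`, `control`,
#' `unaffected_unscreened`. `control` denotes screened GWAS-grade controls;
#' `unaffected_unscreened` denotes the relaxed unaffected set (8 years or
#' older, no clinical signs, family history not screened). Analyses declare
#' which statuses they accept.
#'
#' @param df Data frame with columns `dog_id`, `breed`, `status`, `pan2`,
#'   `map3k7cl`, `drb1_1`, `drb1_2`; optionally `onset_age_months`, `merle`.
#' @return The validated data frame with class `dms_cohort`, heterozygote
#'   order normalized and missing optional columns filled with `NA`.
#' @export
as_cohort <- function(df) {
  required <- c("dog_id", "breed", "status", "pan2", "map3k7cl",
                "drb1_1", "drb1_2")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$dog_id)) {
    stop("duplicated dog_id: ",
         paste(unique(df$dog_id[duplicated(df$dog_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_status <- !df$status %in% cohort_statuses
  if (any(bad_status)) {
    stop("invalid status at row(s) ",
         paste(which(bad_status), collapse = ", "), ": ",
         paste(unique(df$status[bad_status]), collapse = ", "), call. = FALSE)
  }
  known_breeds <- c("collie", "sheltie")
  if (any(!df$breed %in% known_breeds)) {
    warning("cohort contains breed(s) other than collie/sheltie: ",
            paste(setdiff(unique(df$breed), known_breeds), collapse = ", "),
            call. = FALSE)
  }
  df$pan2 <- normalize_genotype(df$pan2, "A")
  df$map3k7cl <- normalize_genotype(df$map3k7cl, "B")
  half <- xor(is.na(df$drb1_1), is.na(df$drb1_2))
  if (any(half)) {
    stop("half-typed DLA haplotypes (exactly one of drb1_1/drb1_2 present) ",
         "at row(s) ", paste(which(half), collapse = ", "), call. = FALSE)
  }
  if (is.null(df$onset_age_months)) {
    df$onset_age_months <- rep(NA_real_, nrow(df))
  }
  df$onset_age_months <- as.numeric(df$onset_age_months)
  if (any(!is.na(df$onset_age_months) & df$onset_age_months <= 0)) {
    stop("onset_age_months must be positive", call. = FALSE)
  }
  orphan_onset <- !is.na(df$onset_age_months) & df$status != "case"
  if (any(orphan_onset)) {
    stop("onset_age_months present for non-case row(s) ",
         paste(which(orphan_onset), collapse = ", "), call. = FALSE)
  }
  if (is.null(df$merle)) df$merle <- rep(NA, nrow(df))
  df$merle <- as.logical(df$merle)
  class(df) <- c("dms_cohort", "data.frame")
  df
}

#' Read a cohort from a delimited text file
#'
#' Expects a UTF-8 TSV or CSV (chosen by file extension, `.csv` means comma)
#' with a header naming at least the required columns of [as_cohort()].
#'
#' @param path Path to the file.
#' @return A validated `dms_cohort` data frame.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          colClasses = "character")
  if ("onset_age_months" %in% names(df)) {
    df$onset_age_months <- as.numeric(df$onset_age_months)
  }
  if ("merle" %in% names(df)) df$merle <- as.logical(df$merle)
  as_cohort(df)
}

#' Write a cohort to a delimited text file
#'
#' Inverse of [load_cohort()]: `load_cohort(write_cohort(x, f))` restores all
#' fields.
#'
#' @param cohort A `dms_cohort`.
#' @param path Output path (`.csv` writes comma-separated, else tabs).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(cohort, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' All 27 three-locus genotype labels
#'
#' Labels over \{AA,Aa,aa\} x \{BB,Bb,bb\} x \{CC,Cc,cc\} in a fixed canonical
#' order (A slowest, then B, then C), where A is the PAN2 p.Arg492Cys risk
#' allele, B the MAP3K7CL indel risk allele, C the DLA-DRB1*002:01 risk
#' haplotype, and lower case the corresponding wild-type allele (c is any
#' alternate DRB1 allele).
#' @return Character vector of length 27.
#' @export
all_three_locus_labels <- function() {
  g <- expand.grid(C = c("cc", "Cc", "CC"), B = c("bb", "Bb", "BB"),
                   A = c("aa", "Aa", "AA"), stringsAsFactors = FALSE)
  paste0(g$A, g$B, g$C)
}

#' Three-locus genotype labels for a cohort
#'
#' Collapses each dog's PAN2 genotype, MAP3K7CL genotype and DLA haplotype
#' pair into one of the 27 labels (e.g. `"AaBBCC"`). The C dose is the number
#' of haplotypes whose DRB1 allele equals [DLA_RISK_DRB1]. The AB risk-allele
#' count is the total dose of A plus B alleles (0-4), the grouping used by
#' the age-of-onset analysis.
#'
#' @param cohort A `dms_cohort`; all three genotypes must be non-missing.
#' @return Data frame with columns `dog_id`, `label`,
#'   `risk_allele_count_AB`.
#' @export
three_locus_label <- function(cohort) {
  miss <- is.na(cohort$pan2) | is.na(cohort$map3k7cl) |
    is.na(cohort$drb1_1) | is.na(cohort$drb1_2)
  if (any(miss)) {
    stop("missing genotype data for dog(s): ",
         paste(cohort$dog_id[miss], collapse = ", "), call. = FALSE)
  }
  c_dose <- (cohort$drb1_1 == DLA_RISK_DRB1) + (cohort$drb1_2 == DLA_RISK_DRB1)
  c_geno <- c("cc", "Cc", "CC")[c_dose + 1L]
  a_dose <- genotype_dose(cohort$pan2, "A")
  b_dose <- genotype_dose(cohort$map3k7cl, "B")
  data.frame(
    dog_id = cohort$dog_id,
    label = paste0(cohort$pan2, cohort$map3k7cl, c_geno),
    risk_allele_count_AB = a_dose + b_dose,
    stringsAsFactors = FALSE
  )
}
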