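# Run configuration, pipeline orchestration and report assembly. All
# stage outputs are plain TSV; a JSON manifest records inputs, seed and
# thresholds so a run can be reproduced exactly.

#' Run configuration
#'
#' Bundles a command, its inputs, seed, MCMC schedule and thresholds.
#' Threshold defaults are the analysis defaults used throughout the
#' package: alpha 0.05, LD cut r2 >= 0.6, sweep cut 3.4 SD, QC cuts
#' 95% call rate / 5% MAF / HWE p 1e-4.
#'
#' @param command One of `assoc`, `penetrance`, `epistasis`, `onset`,
#'   `sweep`, `variants`, `simulate`.
#' @param inputs Named list of input paths or objects.
#' @param out_dir Output directory (created if absent).
#' @param seed Integer master seed; every stochastic stage derives its
#'   randomness from it.
#' @param schedule [mcmc_schedule()] for Bayesian stages.
#' @param thresholds Named list overriding any of `alpha`, `r2_min`,
#'   `z_cut`, `call_rate`, `maf`, `hwe_p`.
#' @param options Named list of stage-specific options (e.g. `stratum`,
#'   `breed`, `haplotype`, `pattern`).
#' @return List of class `run_config`.
#' @export
run_config <- function(command, inputs = list(), out_dir = tempfile("run"),
                       seed = 1, schedule = mcmc_schedule(),
                       thresholds = list(), options = list()) {
  defaults <- list(alpha = 0.05, r2_min = 0.6, z_cut = 3.4,
                   call_rate = 0.95, maf = 0.05, hwe_p = 1e-4)
  defaults[names(thresholds)] <- thresholds
  structure(list(command = command, inputs = inputs, out_dir = out_dir,
                 seed = seed, schedule = schedule, thresholds = defaults,
                 options = options),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  path
}

#' Execute a configured pipeline stage
#'
#' Loads the inputs, runs the corresponding analysis and writes the stage
#' report(s) plus a `manifest.json` (command, inputs, seed, thresholds,
#' package version, outputs) to the output directory. Deterministic stages
#' rerun from the same manifest byte-identically; stochastic stages are
#' identical given the same seed and sampler backend.
#'
#' @param config A [run_config()].
#' @return Named list of result objects (also written as TSV), invisibly
#'   annotated with the manifest path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(config$inputs)) {
    inp <- config$inputs[[nm]]
    if (is.character(inp) && length(inp) == 1 && !file.exists(inp)) {
      stop("input file not found: ", inp, call. = FALSE)
    }
  }
  opt <- config$options
  results <- switch(
    config$command,
    penetrance = {
      cohort <- load_cohort(config$inputs$cohort)
      tab <- tabulate_three_locus(cohort)
      list(penetrance = tab)
    },
    assoc = {
      cohort <- load_cohort(config$inputs$cohort)
      hap <- if (is.null(opt$haplotype)) DLA_RISK_DRB1 else opt$haplotype
      ha <- haplotype_association(cohort, hap, breed = opt$breed)
      hom <- homozygosity_association(cohort, hap, breed = opt$breed)
      list(assoc = data.frame(
        level = c("haplotype_2n", "homozygosity"),
        exposed_cases = c(ha$counts[1], hom$counts[1]),
        other_cases = c(ha$counts[2], hom$counts[2]),
        exposed_controls = c(ha$counts[3], hom$counts[3]),
        other_controls = c(ha$counts[4], hom$counts[4]),
        odds_ratio = c(ha$odds_ratio, hom$odds_ratio),
        ci_low = c(ha$ci_low, hom$ci_low),
        ci_high = c(ha$ci_high, hom$ci_high),
        p = c(ha$p_two_tailed, hom$p_two_tailed)))
    },
    epistasis = {
      cohort <- load_cohort(config$inputs$cohort)
      stratum <- if (is.null(opt$stratum)) "CC" else opt$stratum
      counts <- epistasis_counts(cohort, stratum)
      fit <- fit_epistasis(counts, config$schedule, seed = config$seed)
      surface <- disease_probability_surface(fit)
      list(epistasis_surface = surface,
           epistasis_rhat = data.frame(
             parameter = names(fit$convergence$rhat),
             rhat = fit$convergence$rhat))
    },
    onset = {
      cohort <- load_cohort(config$inputs$cohort)
      fit <- fit_weibull_onset(onset_groups(cohort), config$schedule,
                               seed = config$seed)
      list(onset = onset_summaries(fit))
    },
    sweep = {
      counts <- utils::read.table(config$inputs$counts, header = TRUE,
                                  stringsAsFactors = FALSE)
      scan <- zhp_scan(counts, z = config$thresholds$z_cut)
      list(sweep_windows = as.data.frame(scan),
           sweep_regions = sweep_regions(scan))
    },
    variants = {
      variants <- read_variants_vcf(config$inputs$vcf)
      res <- filter_variants(variants, interval = opt$interval,
                             pattern = opt$pattern, exons = opt$exons,
                             panel_variants = opt$panel_variants,
                             catalog = opt$catalog)
      list(variants_retained = as.data.frame(res$retained),
           variants_report = res$report)
    },
    simulate = {
      cohort <- simulate_table3_cohort(seed = config$seed)
      path <- file.path(config$out_dir, "cohort.tsv")
      write_cohort(cohort, path)
      list(cohort = as.data.frame(cohort))
    },
    stop("unknown command: ", config$command)
  )
  outputs <- character(0)
  for (nm in names(results)) {
    out <- file.path(config$out_dir, paste0(nm, ".tsv"))
    write_tsv(as.data.frame(results[[nm]]), out)
    outputs <- c(outputs, out)
  }
  manifest <- list(
    command = config$command,
    inputs = lapply(config$inputs, function(x) {
      if (is.character(x) && length(x) == 1) x else "<in-memory>"
    }),
    seed = config$seed,
    schedule = unclass(config$schedule),
    thresholds = config$thresholds,
    package_version = as.character(utils::packageVersion("trilocus")),
    outputs = basename(outputs)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(structure(results,
                      manifest = file.path(config$out_dir, "manifest.json")))
}
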