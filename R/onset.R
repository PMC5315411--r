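# Bayesian Weibull model of age at onset across risk-allele-count classes.
# y_ij ~ Weibull(r, exp(-b_i)) where r is the shape and exp(-b_i) the scale
# of the i-th class (the median/mean formulas exp(-b_i) log(2)^(1/r) and
# exp(-b_i) Gamma(1 + 1/r) fix this reading: r enters as the shape).

#' Group onset ages by PAN2+MAP3K7CL risk-allele count
#'
#' Collects the observed onset ages (months) of cases into genotypic
#' classes defined by the number of A plus B risk alleles, ignoring the DLA
#' genotype (CC and Cc dogs are pooled; this is the grouping used for the
#' onset comparison, where class medians fell from 18.5 months with two risk
#' alleles to 5 months with four).
#'
#' @param cohort A `dms_cohort`.
#' @param classes Risk-allele counts to keep (default 2:4).
#' @return Named list of positive numeric vectors, one per class present.
#' @export
onset_groups <- function(cohort, classes = 2:4) {
  cases <- cohort[cohort$status == "case" & !is.na(cohort$onset_age_months), ,
                  drop = FALSE]
  lab <- three_locus_label(cases)
  keep <- lab$risk_allele_count_AB %in% classes
  split(cases$onset_age_months[keep],
        factor(lab$risk_allele_count_AB[keep], levels = classes))
}

weibull_model_string <- "
model {
  for (k in 1:N) {
    y[k] ~ dweib(r, lam[g[k]])
  }
  for (i in 1:G) {
    b[i] ~ dnorm(0, tau)
    lam[i] <- exp(r * b[i])
  }
  sigma ~ dt(0, prec_scale, 1) T(0,)
  tau <- pow(sigma, -2)
  r ~ dexp(rate_r)
}
"

# Internal constructor; also used to build degenerate posteriors in tests.
new_weibull_fit <- function(draws, chain, classes, schedule = NULL,
                            convergence = NULL) {
  structure(list(draws = draws, chain = chain, classes = classes,
                 schedule = schedule, convergence = convergence),
            class = "weibull_fit")
}

#' Fit the Bayesian Weibull age-of-onset model
#'
#' Likelihood `y_ij ~ Weibull(shape r, scale exp(-b_i))` for the j-th dog in
#' the i-th genotypic class. Priors: `b_i ~ N(0, sigma)` with
#' `sigma ~ half-Cauchy(0, 25)`, and `r ~ Exponential(0.001)`. Sampling and
#' the split R-hat convergence contract (adequate below 1.05) are shared
#' with [fit_epistasis()]. Ages are treated as fully observed (no
#' censoring): age at diagnosis is taken as the event time.
#'
#' @param groups Named list of positive onset-age vectors, as produced by
#'   [onset_groups()]; at least one group with two or more observations.
#' @param schedule An [mcmc_schedule()].
#' @param seed Integer seed.
#' @param prior_scale Cauchy scale for sigma (default 25).
#' @param rate_r Exponential prior rate for the shape (default 0.001).
#' @return Object of class `weibull_fit` with retained draws of `r`, the
#'   class effects `b_i` and `sigma`, chain labels and convergence report.
#' @export
fit_weibull_onset <- function(groups, schedule = mcmc_schedule(), seed = 1,
                              prior_scale = 25, rate_r = 0.001) {
  groups <- groups[lengths(groups) > 0]
  if (length(groups) == 0 || max(lengths(groups)) < 2) {
    stop("need at least one group with two or more onset ages")
  }
  y <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(y) | y <= 0)) stop("onset ages must be positive")
  g <- rep(seq_along(groups), lengths(groups))
  data <- list(N = length(y), G = length(groups), y = y, g = g,
               prec_scale = prior_scale^-2, rate_r = rate_r)
  run <- run_jags(weibull_model_string, data,
                  monitor = c("r", "b", "sigma"), schedule, seed,
                  inits_extra = list(r = 1))
  b_cols <- grep("^b($|\\[)", colnames(run$draws))
  colnames(run$draws)[b_cols] <- paste0("b_", names(groups))
  rhat <- rhat_by_parameter(run$draws, run$chain)
  new_weibull_fit(run$draws, run$chain, names(groups), schedule,
                  convergence_report(rhat))
}

#' Per-class posterior summaries of onset median and mean
#'
#' For every retained draw the class median `exp(-b_i) log(2)^(1/r)` and
#' mean `exp(-b_i) Gamma(1 + 1/r)` are computed, then summarized across
#' draws (posterior mean and central credible interval) -- not plugged in at
#' the posterior means of the parameters.
#'
#' @param fit A `weibull_fit`.
#' @param prob Credible-interval mass (default 0.95).
#' @return Data frame with one row per class: `class`, `n` (`NA` when the
#'   fit was constructed without data), `median`, `median_lo`, `median_hi`,
#'   `mean`, `mean_lo`, `mean_hi`.
#' @export
onset_summaries <- function(fit, prob = 0.95) {
  r <- fit$draws[, "r"]
  qs <- c((1 - prob) / 2, 1 - (1 - prob) / 2)
  rows <- lapply(seq_along(fit$classes), function(i) {
    b <- fit$draws[, paste0("b_", fit$classes[i])]
    med <- exp(-b) * log(2)^(1 / r)
    mn <- exp(-b) * gamma(1 + 1 / r)
    med_q <- stats::quantile(med, qs, names = FALSE)
    mn_q <- stats::quantile(mn, qs, names = FALSE)
    data.frame(class = fit$classes[i],
               median = mean(med), median_lo = med_q[1], median_hi = med_q[2],
               mean = mean(mn), mean_lo = mn_q[1], mean_hi = mn_q[2])
  })
  do.call(rbind, rows)
}

#' Posterior draws of per-class onset medians
#'
#' Draw-level medians `exp(-b_i) log(2)^(1/r)`, useful for posterior
#' probability statements such as the ordering of classes.
#'
#' @param fit A `weibull_fit`.
#' @return Matrix draws x classes.
#' @export
onset_median_draws <- function(fit) {
  r <- fit$draws[, "r"]
  out <- sapply(fit$classes, function(cl) {
    exp(-fit$draws[, paste0("b_", cl)]) * log(2)^(1 / r)
  })
  colnames(out) <- fit$classes
  out
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat("Bayesian Weibull onset fit:", length(x$classes), "classes,",
      nrow(x$draws), "retained draws\n")
  if (!is.null(x$convergence)) {
    cat("  max split R-hat:",
        format(max(x$convergence$rhat, na.rm = TRUE), digits = 4), "\n")
  }
  print(onset_summaries(x), digits = 3)
  invisible(x)
}
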