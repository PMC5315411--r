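# Shared MCMC plumbing: sampling schedule, JAGS runner, and the
# Gelman-Rubin (split R-hat) convergence diagnostic.

#' MCMC sampling schedule
#'
#' Default schedule: 4 chains of 50,000 iterations each, the first 20,000
#' discarded as warm-up, the remainder thinned to every 20th draw, retaining
#' 4 x 30,000 / 20 = 6,000 posterior samples. All components are
#' configurable; reduced schedules are appropriate for the small conditional
#' models fitted here once R-hat is below the 1.05 adequacy bound.
#'
#' @param chains Number of chains (>= 2 for convergence diagnostics).
#' @param iter Total iterations per chain, including warm-up.
#' @param warmup Warm-up (burn-in) iterations discarded per chain.
#' @param thin Keep every `thin`-th post-warm-up draw.
#' @return List of class `mcmc_schedule` with an added `retained` count.
#' @export
mcmc_schedule <- function(chains = 4, iter = 50000, warmup = 20000,
                          thin = 20) {
  stopifnot(chains >= 1, iter > warmup, warmup >= 0, thin >= 1)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), thin = as.integer(thin),
                 retained = as.integer(chains * floor((iter - warmup) / thin))),
            class = "mcmc_schedule")
}

# Run a JAGS model and return a draws matrix plus chain labels.
# Chain RNGs are seeded deterministically from `seed` so runs are
# reproducible bit-for-bit given (seed, schedule, JAGS version).
run_jags <- function(model_string, data, monitor, schedule, seed,
                     inits_extra = NULL) {
  inits <- lapply(seq_len(schedule$chains), function(k) {
    c(list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = (seed * 101 + k) %% 2147483647L), inits_extra)
  })
  model <- rjags::jags.model(textConnection(model_string), data = data,
                             inits = inits, n.chains = schedule$chains,
                             n.adapt = max(100, min(1000, schedule$warmup)),
                             quiet = TRUE)
  if (schedule$warmup > 0) update(model, schedule$warmup, progress.bar = "none")
  samples <- rjags::coda.samples(model, variable.names = monitor,
                                 n.iter = schedule$iter - schedule$warmup,
                                 thin = schedule$thin,
                                 progress.bar = "none")
  draws <- do.call(rbind, lapply(samples, as.matrix))
  chain <- rep(seq_len(schedule$chains), each = nrow(samples[[1]]))
  list(draws = draws, chain = chain)
}

#' Gelman-Rubin split R-hat convergence diagnostic
#'
#' Compares within- and between-chain variance after splitting each chain in
#' half (so non-stationarity within a chain is also detected). Values below
#' 1.05 are taken as adequate mixing. R-hat is >= 1 up to numerical
#' tolerance.
#'
#' @param chains A list of equal-length numeric vectors (one per chain) or a
#'   matrix with one column per chain.
#' @return R-hat, or `NA` with a warning for degenerate (constant) chains.
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- asplit(chains, 2)
  if (length(chains) < 2) stop("at least two chains are required")
  if (length(unique(lengths(chains))) != 1) {
    stop("all chains must have equal length")
  }
  n <- lengths(chains)[1]
  if (n < 4) stop("chains too short to split")
  half <- floor(n / 2)
  split_chains <- unlist(lapply(chains, function(x) {
    list(x[seq_len(half)], x[(n - half + 1):n])
  }), recursive = FALSE)
  m <- length(split_chains)
  means <- vapply(split_chains, mean, numeric(1))
  vars <- vapply(split_chains, stats::var, numeric(1))
  w <- mean(vars)
  b <- half * stats::var(means)
  if (!is.finite(w) || w <= .Machine$double.eps * max(abs(means), 1)) {
    warning("constant or degenerate chains; R-hat undefined", call. = FALSE)
    return(NA_real_)
  }
  sqrt(((half - 1) / half * w + b / half) / w)
}

# Split R-hat per column of a retained-draws matrix given chain labels.
rhat_by_parameter <- function(draws, chain) {
  apply(draws, 2, function(x) {
    suppressWarnings(gelman_rubin(split(x, chain)))
  })
}

# Attach a convergence report; flags (but still returns) failed runs.
convergence_report <- function(rhat, bound = 1.05) {
  ok <- !is.na(rhat) & rhat < bound
  if (!all(ok)) {
    warning("Gelman-Rubin statistic >= ", bound, " (or undefined) for: ",
            paste(names(rhat)[!ok], collapse = ", "),
            "; MCMC run may be inadequate", call. = FALSE)
  }
  list(rhat = rhat, bound = bound, converged = all(ok))
}
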