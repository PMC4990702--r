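#' Prior configuration for the occupancy model
#'
#' The model uses deliberately weak priors: Normal(0, `hyperMeanSd`)
#' on all hyper-means (and implicitly on logit-scale coefficients
#' through their hierarchical priors), a half-Cauchy (default) or
#' half-normal prior of scale `sdPriorScale` on every hyper standard
#' deviation, and Uniform(0, 1) on each species' first-year occupancy
#' probability.
#'
#' @param hyperMeanSd standard deviation of the Normal prior on
#'   hyper-means (default 10).
#' @param sdPrior `"halfcauchy"` (default) or `"halfnormal"` prior for
#'   hyper-sds.
#' @param sdPriorScale scale of the hyper-sd prior (default 2.5).
#' @return a list of class `"occPriors"`.
#' @export
occupancyPriors <- function(hyperMeanSd = 10,
                            sdPrior = c("halfcauchy", "halfnormal"),
                            sdPriorScale = 2.5) {
  sdPrior <- match.arg(sdPrior)
  structure(list(hyperMeanSd = hyperMeanSd, sdPrior = sdPrior,
                 sdPriorScale = sdPriorScale), class = "occPriors")
}

# flatten a BeeOccData into the arrays the C++ core consumes
occDataArrays <- function(data) {
  v <- visitInfo(data)
  sites <- siteNames(data)
  years <- modelYears(data)
  T <- length(years)
  panel <- covariatePanel(data)
  if (nrow(panel) == 0)
    stop("no covariate panel attached; use covariatePanel(data) <- panel")
  lagYears <- years[-T]
  key <- paste(panel$cell5km_id, panel$year)
  mkX <- function(col) {
    m <- matrix(panel[[col]][match(as.vector(outer(sites, lagYears, paste)),
                                   key)],
                nrow = length(sites), ncol = T - 1)
    if (anyNA(m)) stop("covariate panel has gaps for column ", col)
    m
  }
  list(y = detections(data),
       vSite = match(v$cell5km_id, sites) - 1L,
       vYear = match(v$year, years) - 1L,
       vShort = as.integer(v$is_short),
       vLong = as.integer(v$is_long),
       Xosr = mkX("osr_c"), Xneo = mkX("neonic_c"), Xfii = mkX("fii_c"),
       nSites = length(sites), nYears = T,
       forager = as.integer(speciesInfo(data)$osr_forager))
}

paramNames <- function(data) {
  sp <- speciesInfo(data)$species
  years <- modelYears(data)
  spPar <- c("psi0", "gamma", "beta0", "beta1", "beta2", "beta3",
             "beta4", "beta5", "beta6")
  nm <- as.vector(t(outer(sp, spPar,
                          function(s, p) paste0(p, "[", s, "]"))))
  nm <- c(nm, paste0("alpha[", years, "]"))
  nm <- c(nm, c("mu_gamma", "sd_gamma", "mu_beta0", "sd_beta0",
                "mu_beta4", "sd_beta4", "mu_beta5", "sd_beta5",
                "mu_beta6", "sd_beta6"))
  for (cv in c("beta1", "beta2", "beta3"))
    for (g in c("forager", "nonforager"))
      nm <- c(nm, paste0("mu_", cv, "_", g), paste0("sd_", cv, "_", g))
  c(nm, "sd_alpha")
}

hyperNames <- function() {
  c("mu_gamma", "sd_gamma", "mu_beta0", "sd_beta0", "mu_beta4",
    "sd_beta4", "mu_beta5", "sd_beta5", "mu_beta6", "sd_beta6",
    as.vector(sapply(c("beta1", "beta2", "beta3"), function(cv)
      sapply(c("forager", "nonforager"), function(g)
        c(paste0("mu_", cv, "_", g), paste0("sd_", cv, "_", g))))),
    "sd_alpha")
}

initialValues <- function(arrays, jitterSd = 0.3) {
  y <- arrays$y
  n <- nrow(y)
  T <- arrays$nYears
  J <- arrays$nSites
  # crude naive starting points from the observed detection frequencies
  siteDet <- vapply(seq_len(n), function(i) {
    hit <- unique(arrays$vSite[y[i, ] == 1L])
    length(hit) / arrays$nSites
  }, numeric(1))
  naive <- pmin(pmax(siteDet, 0.05), 0.9)
  # detection-naive persistence regression per species: treat
  # "detected at site in year" as occupancy and regress year-to-year
  # re-detection on the lagged covariates. Biased toward zero (absence
  # of detection is not absence), but a far better starting point than
  # the origin, shortening burn-in of the covariate effects.
  crude <- t(vapply(seq_len(n), function(i) {
    D <- matrix(0L, J, T)
    hit <- y[i, ] == 1L
    D[cbind(arrays$vSite[hit] + 1L, arrays$vYear[hit] + 1L)] <- 1L
    prev <- D[, -T, drop = FALSE] == 1L
    if (sum(prev) < 20) return(c(1, 0, 0, 0))
    df <- data.frame(y = D[, -1, drop = FALSE][prev],
                     x1 = arrays$Xosr[prev], x2 = arrays$Xneo[prev],
                     x3 = arrays$Xfii[prev])
    co <- tryCatch(coef(glm(y ~ x1 + x2 + x3, df, family = binomial)),
                   error = function(e) c(0, 0, 0, 0))
    co[!is.finite(co)] <- 0
    pmin(pmax(co, -8), 8)
  }, numeric(4)))
  jit <- function(x) x + rnorm(length(x), 0, jitterSd)
  init <- list(
    psi0l = jit(qlogis(naive)),
    lgam = jit(rep(qlogis(0.1), n)),
    b0 = jit(pmax(crude[, 1], 0)),
    b1 = jit(crude[, 2]), b2 = jit(crude[, 3]), b3 = jit(crude[, 4]),
    b4 = jit(rep(-2, n)), b5 = jit(rep(0.5, n)), b6 = jit(rep(1, n)),
    alpha = rnorm(T, 0, 0.1),
    mu_gam = qlogis(0.1), sd_gam = 0.5,
    mu_b0 = 1, sd_b0 = 0.5,
    mu_b4 = -2, sd_b4 = 0.5,
    mu_b5 = 0.5, sd_b5 = 0.5,
    mu_b6 = 1, sd_b6 = 0.5,
    sd_alpha = 0.3,
    mu_cov = matrix(0, 3, 2),
    sd_cov = matrix(0.5, 3, 2))
  init
}

#' Fit the multi-species dynamic occupancy-detection model by MCMC
#'
#' Samples the joint posterior of all species-level parameters
#' (first-year occupancy, colonisation, persistence intercept and
#' covariate effects, detection intercept and list-category effects),
#' the shared year effects, and the group-level hyper-parameters. The
#' persistence covariate effects (oilseed-rape cover, neonicotinoid
#' exposure, FII) have separate hyper-distributions for oilseed-rape
#' foragers and non-foragers; all other species-level parameters share
#' a single hyper-distribution.
#'
#' The default (`"marginal"`) sampler is a Metropolis-within-Gibbs
#' scheme on the marginal likelihood: the latent occupancy states are
#' integrated out exactly by a forward recursion, species-level
#' parameters and year effects are updated by adaptive random-walk
#' Metropolis (adaptation stops at the end of burn-in), hyper-means by
#' conjugate Gibbs draws and hyper-sds by random-walk moves on the log
#' scale. The `"augmented"` sampler is the explicit-latent-state
#' formulation (forward-filter backward-sample of z, then conditional
#' updates); it is much slower and intended for small cross-validation
#' instances.
#'
#' Chains run sequentially with deterministic per-chain seeds derived
#' from `seed`, so results are exactly reproducible.
#'
#' @param data a [BeeOccData-class] with a covariate panel attached.
#' @param chains number of chains (default 3).
#' @param iterations iterations per chain (default 10000).
#' @param burnin burn-in iterations discarded (default 5000).
#' @param thin thinning interval (default 3).
#' @param seed master seed; per-chain seeds fan out from it.
#' @param priors an [occupancyPriors()] list.
#' @param sampler `"marginal"` (default) or `"augmented"`.
#' @param rhatThreshold convergence flag threshold on monitored
#'   parameters (default 1.1).
#' @param nMonitorSpecies how many species-level parameters to add to
#'   the monitored set alongside all hyper-parameters (default 5,
#'   chosen reproducibly from `seed`).
#' @return a [BeeOccFit-class] object. Non-convergence is flagged in
#'   the fit (see [rhatTable()]), not an error.
#' @export
fitOccupancyModel <- function(data, chains = 3, iterations = 10000,
                              burnin = 5000, thin = 3, seed = 1,
                              priors = occupancyPriors(),
                              sampler = c("marginal", "augmented"),
                              rhatThreshold = 1.1,
                              nMonitorSpecies = 5) {
  sampler <- match.arg(sampler)
  stopifnot(chains >= 1, iterations > burnin, thin >= 1)
  arrays <- occDataArrays(data)
  nm <- paramNames(data)
  nKeep <- (iterations - burnin) %/% thin
  draws <- array(NA_real_, dim = c(nKeep, length(nm), chains),
                 dimnames = list(NULL, nm, NULL))
  priorCfg <- list(hyperMeanSd = priors$hyperMeanSd,
                   sdPriorType = if (priors$sdPrior == "halfcauchy") 0L
                                 else 1L,
                   sdPriorScale = priors$sdPriorScale)
  accept <- numeric(0)
  for (ch in seq_len(chains)) {
    set.seed(seed + 7919L * ch)
    init <- initialValues(arrays)
    if (sampler == "marginal") {
      res <- cpp_occ_mcmc_chain(arrays$y, arrays$vSite, arrays$vYear,
                                arrays$vShort, arrays$vLong,
                                arrays$Xosr, arrays$Xneo, arrays$Xfii,
                                arrays$nSites, arrays$nYears,
                                arrays$forager,
                                iterations, burnin, thin, init, priorCfg)
    } else {
      res <- augmentedChain(arrays, iterations, burnin, thin, init,
                            priorCfg)
    }
    stopifnot(nrow(res$draws) == nKeep, ncol(res$draws) == length(nm))
    draws[, , ch] <- res$draws
    accept[paste0("species_ch", ch)] <- res$acceptSpecies
    accept[paste0("alpha_ch", ch)] <- res$acceptAlpha
  }

  monitored <- hyperNames()
  spPars <- setdiff(nm, c(monitored, paste0("alpha[", modelYears(data), "]")))
  if (nMonitorSpecies > 0 && chains >= 2) {
    set.seed(seed)
    monitored <- c(monitored,
                   sample(spPars, min(nMonitorSpecies, length(spPars))))
  }
  rh <- if (chains >= 2) {
    data.frame(parameter = monitored,
               rhat = vapply(monitored, function(p)
                 rhat(draws[, p, ]), numeric(1)),
               row.names = NULL)
  } else data.frame(parameter = character(), rhat = numeric())
  converged <- !nrow(rh) || all(rh$rhat <= rhatThreshold)
  if (!converged)
    warning("MCMC not converged: max monitored Rhat = ",
            round(max(rh$rhat), 3))
  new("BeeOccFit", draws = draws, data = data,
      config = list(chains = chains, iterations = iterations,
                    burnin = burnin, thin = thin, seed = seed,
                    sampler = sampler, priors = priors,
                    rhatThreshold = rhatThreshold),
      accept = accept, rhat = rh, converged = converged)
}

#' Gelman--Rubin potential scale reduction factor
#'
#' Classic multi-chain PSRF: the ratio of the pooled posterior
#' variance estimate to the mean within-chain variance. With `split =
#' TRUE` each chain is first split in half (the split-chain variant,
#' which also detects within-chain non-stationarity). Exactly
#' identical chains have zero between-chain variance and return 1; the
#' estimator is floored at 1, since values below 1 are finite-sample
#' noise.
#'
#' @param x matrix of posterior draws, iterations x chains (at least 2
#'   chains, 2 draws each).
#' @param split split each chain in half first (default FALSE).
#' @return the PSRF, a scalar >= 1.
#' @export
rhat <- function(x, split = FALSE) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("rhat needs at least 2 chains")
  if (nrow(x) < 2) stop("rhat needs at least 2 draws per chain")
  if (split) {
    half <- nrow(x) %/% 2
    x <- cbind(x[seq_len(half), , drop = FALSE],
               x[(nrow(x) - half + 1):nrow(x), , drop = FALSE])
  }
  n <- nrow(x); m <- ncol(x)
  chainMeans <- colMeans(x)
  W <- mean(apply(x, 2, var))
  B <- n * var(chainMeans)
  if (W == 0) return(1)
  varPlus <- (n - 1) / n * W + B / n
  max(1, sqrt(varPlus / W))
}
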