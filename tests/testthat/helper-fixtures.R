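# Small study configurations and hand-built objects shared by tests.

tinyConfig <- function(...) {
  args <- list(nForager = 4, nNonforager = 3, nSites = 12,
               cellsPerSite = 4, nRegions = 2, meanVisits = 6)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulationDefaults, args)
}

tinyStudy <- function(seed = 42, config = tinyConfig(), minSurveys = 20) {
  sim <- simulateBeeStudy(seed = seed, config = config)
  dat <- assembleFromTables(sim$tables, panel = sim$panel,
                            years = config$years, minSurveys = minSurveys)
  list(sim = sim, dat = dat)
}

# a random detection history for the likelihood oracle comparisons
randomHistory <- function(T, maxVisitsPerYear = 2) {
  nv <- sample(0:maxVisitsPerYear, T, replace = TRUE)
  vy <- rep(seq_len(T), nv)
  isShort <- rbinom(length(vy), 1, 0.3)
  list(nYears = T,
       y = rbinom(length(vy), 1, 0.5),
       visitYear = vy,
       isShort = isShort,
       isLong = ifelse(isShort == 1, 0L, rbinom(length(vy), 1, 0.3)),
       X = matrix(rnorm(3 * max(T - 1, 1)), ncol = 3))
}

randomParams <- function(T) {
  list(psi0 = runif(1, 0.05, 0.95), gamma = runif(1, 0.05, 0.95),
       beta0 = rnorm(1), beta1 = rnorm(1), beta2 = rnorm(1),
       beta3 = rnorm(1), beta4 = rnorm(1), beta5 = rnorm(1),
       beta6 = rnorm(1), alpha = rnorm(T, 0, 0.5))
}

paramDrawsVec <- function(fit, p) {
  as.vector(beepersist:::paramDraws(fit, p))
}

# build a BeeOccFit with draws fabricated from a named list:
# values[[param]] is a vector (recycled) of draws for that parameter;
# everything not named defaults to zero.
manualFit <- function(dat, values, nDraws = 50, nChains = 2) {
  nm <- beepersist:::paramNames(dat)
  draws <- array(0, dim = c(nDraws, length(nm), nChains),
                 dimnames = list(NULL, nm, NULL))
  for (p in names(values))
    draws[, p, ] <- rep_len(values[[p]], nDraws * nChains)
  new("BeeOccFit", draws = draws, data = dat,
      config = list(chains = nChains, iterations = nDraws, burnin = 0,
                    thin = 1, seed = 0, sampler = "manual",
                    priors = occupancyPriors(), rhatThreshold = 1.1),
      accept = numeric(0),
      rhat = data.frame(parameter = character(), rhat = numeric()),
      converged = TRUE)
}
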