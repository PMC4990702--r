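covariateHyper <- function(covariate = c("osr", "neonic", "fii"),
                           group = c("forager", "nonforager")) {
  covariate <- match.arg(covariate)
  group <- match.arg(group)
  beta <- c(osr = "beta1", neonic = "beta2", fii = "beta3")[covariate]
  paste0("mu_", beta, "_", group)
}

# draws of one parameter as an iterations x chains matrix
paramDraws <- function(fit, parameter) {
  d <- fit@draws
  if (!parameter %in% dimnames(d)[[2]])
    stop("no such parameter in the posterior: ", parameter)
  d[, parameter, , drop = TRUE]
}

# all draws of a species-level parameter family: (iters*chains) x species
speciesParamDraws <- function(fit, par) {
  sp <- speciesInfo(fit@data)$species
  out <- sapply(sp, function(s) as.vector(paramDraws(
    fit, paste0(par, "[", s, "]"))))
  colnames(out) <- sp
  out
}

#' Posterior summary of a group-level covariate effect
#'
#' Summarises the hyper-mean of a persistence covariate effect
#' (oilseed-rape cover, neonicotinoid exposure or FII) for one species
#' group: posterior mean, equal-tailed 95% credible interval, and the
#' fraction of posterior draws below zero.
#'
#' @param fit a [BeeOccFit-class].
#' @param group `"forager"` or `"nonforager"`.
#' @param covariate `"osr"`, `"neonic"` or `"fii"`.
#' @return one-row data.frame: `group`, `covariate`, `posterior_mean`,
#'   `ci95_low`, `ci95_high`, `fraction_below_zero`.
#' @export
summarizeGroupEffect <- function(fit, group = c("forager", "nonforager"),
                                 covariate = c("osr", "neonic", "fii")) {
  group <- match.arg(group)
  covariate <- match.arg(covariate)
  x <- as.vector(paramDraws(fit, covariateHyper(covariate, group)))
  q <- unname(quantile(x, c(0.025, 0.975)))
  data.frame(group = group, covariate = covariate,
             posterior_mean = mean(x), ci95_low = q[1], ci95_high = q[2],
             fraction_below_zero = mean(x < 0))
}

#' All six group x covariate effect summaries
#'
#' @param fit a [BeeOccFit-class].
#' @return data.frame with one row per group x covariate.
#' @export
effectTable <- function(fit) {
  do.call(rbind, lapply(c("osr", "neonic", "fii"), function(cv)
    do.call(rbind, lapply(c("forager", "nonforager"), function(g)
      summarizeGroupEffect(fit, g, cv)))))
}

#' Posterior difference between forager and non-forager effects
#'
#' Computes, pairwise within draws (same chain and iteration), the
#' difference of the group hyper-means for one covariate. The sign
#' convention follows the convention of subtracting the forager
#' posterior from the non-forager posterior, so that a *positive*
#' difference means foragers are more negatively affected (for the
#' neonicotinoid effect this is the direction of the headline
#' difference).
#'
#' @param fit a [BeeOccFit-class].
#' @param covariate `"osr"`, `"neonic"` or `"fii"`.
#' @return list with `draws` (the per-draw differences) and `summary`
#'   (mean, 95% CI, fraction of draws above zero).
#' @export
groupDifference <- function(fit, covariate = c("neonic", "osr", "fii")) {
  covariate <- match.arg(covariate)
  f <- paramDraws(fit, covariateHyper(covariate, "forager"))
  nf <- paramDraws(fit, covariateHyper(covariate, "nonforager"))
  if (!identical(dim(f), dim(nf)))
    stop("cannot pair draws of unequal dimensions")
  d <- as.vector(nf - f)
  q <- unname(quantile(d, c(0.025, 0.975)))
  list(draws = d,
       summary = data.frame(covariate = covariate, mean = mean(d),
                            ci95_low = q[1], ci95_high = q[2],
                            fraction_above_zero = mean(d > 0)))
}

scenarioCovariates <- function(data, scenario, firstTreatmentYear) {
  panel <- covariatePanel(data)
  means <- attr(panel, "covariate_means")
  if (is.null(means)) stop("covariate panel lacks stored means")
  sites <- siteNames(data)
  years <- modelYears(data)
  lagYears <- years[-length(years)]
  key <- paste(panel$cell5km_id, panel$year)
  grab <- function(col) {
    matrix(panel[[col]][match(as.vector(outer(sites, lagYears, paste)),
                              key)],
           nrow = length(sites))
  }
  neonRaw <- grab("neonic")
  if (scenario == "no_neonic") {
    if (firstTreatmentYear > max(lagYears))
      stop("firstTreatmentYear lies outside the modelled years")
    # zero the raw exposure from the first treatment year on, then
    # re-centre with the ORIGINAL mean: the fitted coefficients are
    # defined against the original centring
    neonRaw[, lagYears >= firstTreatmentYear] <- 0
  }
  list(Xosr = grab("osr_c"),
       Xneo = neonRaw - means["neonic"],
       Xfii = grab("fii_c"))
}

#' Project expected occupancy trajectories under a scenario
#'
#' For every posterior draw and species, propagates the expected
#' occupancy probability of each site through the colonisation/
#' persistence dynamics from the first modelled year (starting at the
#' draw's first-year occupancy, i.e. fitted values rather than
#' conditioning on the observed detections), and averages over sites.
#' Under the `"no_neonic"` scenario the raw neonicotinoid exposure is
#' set to zero from `firstTreatmentYear` onward before re-centring
#' with the original covariate mean, emulating a world where seed
#' treatments were never adopted.
#'
#' @param fit a [BeeOccFit-class].
#' @param scenario `"factual"` or `"no_neonic"`.
#' @param firstTreatmentYear first year of widespread seed-treatment
#'   use (default 2002).
#' @param keepDraws store the full species x year x draw trajectory
#'   array in the `"trajDraws"` attribute (default FALSE).
#' @return data.frame `species`, `scenario`, `year`, `mean`, `ci95_low`,
#'   `ci95_high` of the occupied-site proportion, with attribute
#'   `"finals"`: a species x draw matrix of final-year occupancy used
#'   by [occupancyLoss()].
#' @export
projectOccupancy <- function(fit, scenario = c("factual", "no_neonic"),
                             firstTreatmentYear = 2002,
                             keepDraws = FALSE) {
  scenario <- match.arg(scenario)
  data <- fit@data
  years <- modelYears(data)
  T <- length(years)
  X <- scenarioCovariates(data, scenario, firstTreatmentYear)
  sp <- speciesInfo(data)$species
  psi0 <- speciesParamDraws(fit, "psi0")
  gam <- speciesParamDraws(fit, "gamma")
  b0 <- speciesParamDraws(fit, "beta0")
  b1 <- speciesParamDraws(fit, "beta1")
  b2 <- speciesParamDraws(fit, "beta2")
  b3 <- speciesParamDraws(fit, "beta3")
  D <- nrow(psi0)
  J <- nSites(data)
  traj <- array(NA_real_, dim = c(length(sp), T, D))
  for (i in seq_along(sp)) {
    occ <- matrix(psi0[, i], D, J)   # draws x sites
    traj[i, 1, ] <- rowMeans(occ)
    for (t in 2:T) {
      phi <- plogis(b0[, i] + outer(b1[, i], X$Xosr[, t - 1]) +
                    outer(b2[, i], X$Xneo[, t - 1]) +
                    outer(b3[, i], X$Xfii[, t - 1]))
      occ <- occ * phi + (1 - occ) * gam[, i]
      traj[i, t, ] <- rowMeans(occ)
    }
  }
  out <- data.frame(
    species = rep(sp, each = T),
    scenario = scenario,
    year = rep(years, times = length(sp)),
    mean = as.vector(t(apply(traj, 1, rowMeans))),
    ci95_low = as.vector(t(apply(traj, 1, function(m)
      apply(m, 1, quantile, 0.025)))),
    ci95_high = as.vector(t(apply(traj, 1, function(m)
      apply(m, 1, quantile, 0.975)))))
  finals <- traj[, T, , drop = TRUE]
  if (is.null(dim(finals))) finals <- matrix(finals, nrow = length(sp))
  rownames(finals) <- sp
  attr(out, "finals") <- finals
  if (keepDraws) attr(out, "trajDraws") <- traj
  out
}

#' Percent loss of occupied cells attributable to neonicotinoid exposure
#'
#' Compares the factual projection with the no-neonicotinoid
#' counterfactual in the final modelled year:
#' `100 * (counterfactual - factual) / counterfactual`. The default
#' evaluates the ratio within each posterior draw and averages;
#' `method = "mean"` uses the ratio of posterior-mean occupancies
#' instead. Species whose counterfactual occupancy is (numerically)
#' zero are reported as `NA`.
#'
#' @param factual,counterfactual trajectory data.frames from
#'   [projectOccupancy()] (same fit, same species).
#' @param thresholds loss percentages at which to list species
#'   (default 10/15/20).
#' @param method `"per_draw"` (default) or `"mean"`.
#' @return data.frame `species`, `pct_loss`, sorted by decreasing
#'   loss, with attribute `"exceeds"`: named list of species above
#'   each threshold.
#' @export
occupancyLoss <- function(factual, counterfactual,
                          thresholds = c(10, 15, 20),
                          method = c("per_draw", "mean")) {
  method <- match.arg(method)
  fF <- attr(factual, "finals")
  fC <- attr(counterfactual, "finals")
  if (is.null(fF) || is.null(fC) || !identical(rownames(fF), rownames(fC)))
    stop("trajectories must come from projectOccupancy on the same fit")
  if (method == "per_draw") {
    ratio <- 100 * (fC - fF) / fC
    ratio[fC == 0] <- NA
    loss <- rowMeans(ratio, na.rm = FALSE)
  } else {
    mC <- rowMeans(fC); mF <- rowMeans(fF)
    loss <- ifelse(mC == 0, NA, 100 * (mC - mF) / mC)
  }
  out <- data.frame(species = rownames(fF), pct_loss = unname(loss))
  out <- out[order(-out$pct_loss), ]
  rownames(out) <- NULL
  attr(out, "exceeds") <- setNames(
    lapply(thresholds, function(th)
      out$species[!is.na(out$pct_loss) & out$pct_loss > th]),
    paste0(">", thresholds, "%"))
  out
}
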