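#' Model components of the dynamic occupancy-detection model
#'
#' The latent occupancy state z of a species in a 5 km cell follows a
#' two-state Markov chain: an occupied cell persists with probability
#' phi (a logit-linear function of the previous year's centred
#' oilseed-rape cover, neonicotinoid exposure and FII index), an
#' unoccupied cell is colonised with species-specific probability
#' gamma. Detection on a visit, conditional on presence, is
#' logit-linear in the visit's list-length categories plus a year
#' random effect.
#'
#' @name occupancy-model
NULL

#' Annual persistence probability
#'
#' `plogis(beta0 + beta1*osr + beta2*neonic + beta3*fii)` where the
#' covariates are centred values from the *previous* year. With all
#' centred covariates at 0 this is the persistence in the average
#' occupied grid square.
#'
#' @param beta0,beta1,beta2,beta3 species-level coefficients
#'   (intercept, oilseed-rape cover, neonicotinoid exposure, FII), on
#'   the log-odds scale.
#' @param osr,neonic,fii centred lagged covariate values.
#' @return persistence probability in (0, 1); vectorised.
#' @export
persistenceProb <- function(beta0, beta1, beta2, beta3, osr, neonic, fii) {
  if (any(is.na(osr) | is.na(neonic) | is.na(fii)))
    stop("missing lagged covariate value")
  plogis(beta0 + beta1 * osr + beta2 * neonic + beta3 * fii)
}

#' Occupancy transition probability
#'
#' Probability the cell is occupied in year t given its state in year
#' t-1: occupied cells persist with probability `phi`, unoccupied
#' cells are colonised with probability `gamma`.
#'
#' @param z_prev previous occupancy state, 0/1.
#' @param phi persistence probability.
#' @param gamma colonisation probability.
#' @return P(z_t = 1); vectorised.
#' @export
transitionProb <- function(z_prev, phi, gamma) {
  z_prev * phi + (1 - z_prev) * gamma
}

#' Per-visit detection probability
#'
#' `plogis(beta4 + beta5*is_short + beta6*is_long + alpha_t)`. At
#' `alpha_t = 0` (the average year) and on a single-species list,
#' detection is `plogis(beta4)`.
#'
#' @param beta4,beta5,beta6 detection intercept and the short/long
#'   list-category effects, log-odds scale.
#' @param alpha year random effect for the visit's year.
#' @param is_short,is_long binary list-category covariates.
#' @return detection probability; vectorised.
#' @export
detectionProb <- function(beta4, beta5, beta6, alpha, is_short, is_long) {
  plogis(beta4 + beta5 * is_short + beta6 * is_long + alpha)
}

checkHistory <- function(params, history) {
  T <- history$nYears
  stopifnot(T >= 1, length(params$alpha) >= T)
  if (T > 1) {
    if (is.null(history$X) || nrow(history$X) < T - 1 ||
        anyNA(history$X[seq_len(T - 1), ]))
      stop("missing lagged covariates for transitions into years 2..", T)
  }
  if (length(history$y)) {
    stopifnot(length(history$visitYear) == length(history$y),
              all(history$visitYear >= 1), all(history$visitYear <= T))
  }
  invisible(TRUE)
}

visitDetProbs <- function(params, history) {
  detectionProb(params$beta4, params$beta5, params$beta6,
                params$alpha[history$visitYear],
                history$isShort, history$isLong)
}

# P(observed detections in year t | z_t), for both states.
# Without false positives the unoccupied state has likelihood 1 if no
# detection that year and 0 otherwise.
yearEmissions <- function(history, p) {
  T <- history$nYears
  e1 <- rep(1, T)
  e0 <- rep(1, T)
  if (length(history$y)) {
    lik <- ifelse(history$y == 1, p, 1 - p)
    for (k in seq_along(history$y)) {
      t <- history$visitYear[k]
      e1[t] <- e1[t] * lik[k]
      if (history$y[k] == 1) e0[t] <- 0
    }
  }
  list(e1 = e1, e0 = e0)
}

#' Marginal log-likelihood of one species' detection history at a site
#'
#' Computes the exact probability of the observed detection/
#' non-detection sequence with the latent occupancy chain summed out
#' by a scaled forward recursion over the two occupancy states. Years
#' with no visits contribute only transition factors (their emission
#' likelihood is 1 for both states), which is how unsurveyed years are
#' imputed implicitly.
#'
#' @param params list with scalars `psi0` (first-year occupancy
#'   probability), `gamma` (colonisation), `beta0`...`beta6`, and
#'   vector `alpha` of year effects (length >= `nYears`).
#' @param history list describing one species x site: `nYears`;
#'   per-visit vectors `y` (0/1 detection of the focal species),
#'   `visitYear` (1-based year index), `isShort`, `isLong`; and `X`, a
#'   `(nYears-1) x 3` matrix of centred lagged covariates
#'   (osr, neonic, fii), row `t-1` feeding the transition into year
#'   `t`.
#' @return the log marginal likelihood (may be `-Inf`).
#' @seealso [bruteForceLogLikelihood()] for the enumeration oracle.
#' @export
siteLogLikelihood <- function(params, history) {
  checkHistory(params, history)
  T <- history$nYears
  p <- visitDetProbs(params, history)
  em <- yearEmissions(history, p)
  pr1 <- params$psi0 * em$e1[1]
  pr0 <- (1 - params$psi0) * em$e0[1]
  ll <- 0
  s <- pr1 + pr0
  if (s <= 0) return(-Inf)
  ll <- ll + log(s); pr1 <- pr1 / s; pr0 <- pr0 / s
  if (T > 1) {
    for (t in 2:T) {
      phi <- persistenceProb(params$beta0, params$beta1, params$beta2,
                             params$beta3, history$X[t - 1, 1],
                             history$X[t - 1, 2], history$X[t - 1, 3])
      n1 <- (pr1 * phi + pr0 * params$gamma) * em$e1[t]
      n0 <- (pr1 * (1 - phi) + pr0 * (1 - params$gamma)) * em$e0[t]
      s <- n1 + n0
      if (s <= 0) return(-Inf)
      ll <- ll + log(s)
      pr1 <- n1 / s; pr0 <- n0 / s
    }
  }
  ll
}

#' Brute-force marginal log-likelihood by path enumeration
#'
#' Test oracle: sums P(path) * P(y | path) over all `2^nYears`
#' occupancy paths. Refuses histories longer than 12 years.
#'
#' @inheritParams siteLogLikelihood
#' @return the log marginal likelihood.
#' @export
bruteForceLogLikelihood <- function(params, history) {
  checkHistory(params, history)
  T <- history$nYears
  if (T > 12) stop("refusing to enumerate 2^", T, " occupancy paths")
  p <- visitDetProbs(params, history)
  em <- yearEmissions(history, p)
  total <- 0
  for (code in 0:(2^T - 1)) {
    z <- as.integer(intToBits(code)[seq_len(T)])
    pr <- if (z[1] == 1) params$psi0 else 1 - params$psi0
    if (T > 1) {
      for (t in 2:T) {
        phi <- persistenceProb(params$beta0, params$beta1, params$beta2,
                               params$beta3, history$X[t - 1, 1],
                               history$X[t - 1, 2], history$X[t - 1, 3])
        pz1 <- transitionProb(z[t - 1], phi, params$gamma)
        pr <- pr * (if (z[t] == 1) pz1 else 1 - pz1)
      }
    }
    for (t in seq_len(T))
      pr <- pr * (if (z[t] == 1) em$e1[t] else em$e0[t])
    total <- total + pr
  }
  log(total)
}
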