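# Data-augmented formulation of the occupancy sampler: the latent
# occupancy states z[i,j,t] are sampled explicitly by forward-filter
# backward-sampling, and all parameters are then updated conditional
# on z. Statistically equivalent to the marginalised sampler (the same
# joint posterior), but much slower; intended for small
# cross-validation instances and as a check of the marginal
# implementation.

lpUnifLogit <- function(l) -l - 2 * log1p(exp(-l))

lpSd <- function(sd, type, scale) {
  if (type == 0L) -log1p((sd / scale)^2) else -0.5 * (sd / scale)^2
}

gibbsMu <- function(x, sd, priorSd) {
  prec <- length(x) / sd^2 + 1 / priorSd^2
  rnorm(1, (sum(x) / sd^2) / prec, sqrt(1 / prec))
}

mhLogSd <- function(x, mu, sd, type, scale, step = 0.25) {
  lsNew <- log(sd) + rnorm(1, 0, step)
  sdNew <- exp(lsNew)
  cur <- lpSd(sd, type, scale) + log(sd) + sum(dnorm(x, mu, sd, log = TRUE))
  prop <- lpSd(sdNew, type, scale) + lsNew +
    sum(dnorm(x, mu, sdNew, log = TRUE))
  if (log(runif(1)) < prop - cur) sdNew else sd
}

augmentedChain <- function(arrays, nIter, nBurn, nThin, init, priorCfg) {
  y <- arrays$y
  n <- nrow(y); T <- arrays$nYears; J <- arrays$nSites
  if (T < 2) stop("the augmented sampler needs at least 2 years")
  nV <- ncol(y)
  vSite <- arrays$vSite + 1L; vYear <- arrays$vYear + 1L
  vShort <- arrays$vShort; vLong <- arrays$vLong
  forager <- arrays$forager
  Xosr <- arrays$Xosr; Xneo <- arrays$Xneo; Xfii <- arrays$Xfii
  hmSd <- priorCfg$hyperMeanSd
  sdType <- priorCfg$sdPriorType; sdScale <- priorCfg$sdPriorScale

  p <- init
  grpF <- which(forager == 1); grpN <- which(forager == 0)
  z <- array(0L, dim = c(n, J, T))

  # per (site, year): visit indices
  visAt <- vector("list", J * T)
  for (k in seq_len(nV)) {
    slot <- (vSite[k] - 1L) * T + vYear[k]
    visAt[[slot]] <- c(visAt[[slot]], k)
  }

  detP <- function(i) plogis(p$b4[i] + p$b5[i] * vShort +
                             p$b6[i] * vLong + p$alpha[vYear])

  ffbs <- function(i, pd) {
    psi0 <- plogis(p$psi0l[i]); gam <- plogis(p$lgam[i])
    for (j in seq_len(J)) {
      e1 <- rep(1, T); e0 <- rep(1, T)
      for (t in seq_len(T)) {
        ks <- visAt[[(j - 1L) * T + t]]
        for (k in ks) {
          if (y[i, k] == 1L) { e1[t] <- e1[t] * pd[k]; e0[t] <- 0 }
          else e1[t] <- e1[t] * (1 - pd[k])
        }
      }
      phi <- plogis(p$b0[i] + p$b1[i] * Xosr[j, ] + p$b2[i] * Xneo[j, ] +
                    p$b3[i] * Xfii[j, ])
      f1 <- numeric(T); f0 <- numeric(T)
      a1 <- psi0 * e1[1]; a0 <- (1 - psi0) * e0[1]
      s <- a1 + a0; f1[1] <- a1 / s; f0[1] <- a0 / s
      for (t in 2:T) {
        a1 <- (f1[t - 1] * phi[t - 1] + f0[t - 1] * gam) * e1[t]
        a0 <- (f1[t - 1] * (1 - phi[t - 1]) +
               f0[t - 1] * (1 - gam)) * e0[t]
        s <- a1 + a0; f1[t] <- a1 / s; f0[t] <- a0 / s
      }
      z[i, j, T] <<- rbinom(1, 1, f1[T])
      for (t in (T - 1):1) {
        tr1 <- if (z[i, j, t + 1] == 1L) phi[t] else 1 - phi[t]
        tr0 <- if (z[i, j, t + 1] == 1L) gam else 1 - gam
        w1 <- f1[t] * tr1; w0 <- f0[t] * tr0
        z[i, j, t] <<- rbinom(1, 1, w1 / (w1 + w0))
      }
    }
  }

  transLL <- function(i, lgam, b0, b1, b2, b3) {
    gam <- plogis(lgam)
    ll <- 0
    zi <- matrix(z[i, , ], nrow = J, ncol = T)
    prev <- zi[, seq_len(T - 1), drop = FALSE]
    cur <- zi[, 2:T, drop = FALSE]
    phi <- plogis(b0 + b1 * Xosr + b2 * Xneo + b3 * Xfii)
    occ <- prev == 1L
    ll <- ll + sum(log(ifelse(cur[occ] == 1L, phi[occ], 1 - phi[occ])))
    emp <- !occ
    n01 <- sum(cur[emp] == 1L); n00 <- sum(cur[emp] == 0L)
    ll + n01 * log(gam) + n00 * log(1 - gam)
  }

  detLL <- function(i, b4, b5, b6, alpha) {
    zv <- z[cbind(i, vSite, vYear)]
    occ <- zv == 1L
    pd <- plogis(b4 + b5 * vShort[occ] + b6 * vLong[occ] +
                 alpha[vYear[occ]])
    sum(log(ifelse(y[i, occ] == 1L, pd, 1 - pd)))
  }

  nKeep <- (nIter - nBurn) %/% nThin
  out <- matrix(NA_real_, nKeep, 9 * n + T + 23)
  row <- 0; accS <- 0; totS <- 0; accA <- 0; totA <- 0
  step <- 0.3

  for (it in seq_len(nIter)) {
    for (i in seq_len(n)) ffbs(i, detP(i))

    for (i in seq_len(n)) {
      grp <- if (forager[i] == 1) 1 else 2
      # first-year occupancy: conjugate beta draw from z[,,1]
      k1 <- sum(z[i, , 1])
      p$psi0l[i] <- qlogis(rbeta(1, 1 + k1, 1 + J - k1))
      # transition block
      cur <- c(p$lgam[i], p$b0[i], p$b1[i], p$b2[i], p$b3[i])
      priors <- function(v) {
        dnorm(v[1], p$mu_gam, p$sd_gam, log = TRUE) +
          dnorm(v[2], p$mu_b0, p$sd_b0, log = TRUE) +
          dnorm(v[3], p$mu_cov[1, grp], p$sd_cov[1, grp], log = TRUE) +
          dnorm(v[4], p$mu_cov[2, grp], p$sd_cov[2, grp], log = TRUE) +
          dnorm(v[5], p$mu_cov[3, grp], p$sd_cov[3, grp], log = TRUE)
      }
      for (q in seq_along(cur)) {
        prop <- cur; prop[q] <- cur[q] + rnorm(1, 0, step)
        lpC <- transLL(i, cur[1], cur[2], cur[3], cur[4], cur[5]) +
          priors(cur)
        lpP <- transLL(i, prop[1], prop[2], prop[3], prop[4], prop[5]) +
          priors(prop)
        totS <- totS + 1
        if (log(runif(1)) < lpP - lpC) { cur <- prop; accS <- accS + 1 }
      }
      p$lgam[i] <- cur[1]; p$b0[i] <- cur[2]; p$b1[i] <- cur[3]
      p$b2[i] <- cur[4]; p$b3[i] <- cur[5]
      # detection block
      cur <- c(p$b4[i], p$b5[i], p$b6[i])
      dpriors <- function(v)
        dnorm(v[1], p$mu_b4, p$sd_b4, log = TRUE) +
        dnorm(v[2], p$mu_b5, p$sd_b5, log = TRUE) +
        dnorm(v[3], p$mu_b6, p$sd_b6, log = TRUE)
      for (q in seq_along(cur)) {
        prop <- cur; prop[q] <- cur[q] + rnorm(1, 0, step)
        lpC <- detLL(i, cur[1], cur[2], cur[3], p$alpha) + dpriors(cur)
        lpP <- detLL(i, prop[1], prop[2], prop[3], p$alpha) + dpriors(prop)
        totS <- totS + 1
        if (log(runif(1)) < lpP - lpC) { cur <- prop; accS <- accS + 1 }
      }
      p$b4[i] <- cur[1]; p$b5[i] <- cur[2]; p$b6[i] <- cur[3]
    }

    # year effects: joint over species, conditional on z
    for (t in seq_len(T)) {
      prop <- p$alpha; prop[t] <- p$alpha[t] + rnorm(1, 0, step)
      lpC <- dnorm(p$alpha[t], 0, p$sd_alpha, log = TRUE)
      lpP <- dnorm(prop[t], 0, p$sd_alpha, log = TRUE)
      for (i in seq_len(n)) {
        lpC <- lpC + detLL(i, p$b4[i], p$b5[i], p$b6[i], p$alpha)
        lpP <- lpP + detLL(i, p$b4[i], p$b5[i], p$b6[i], prop)
      }
      totA <- totA + 1
      if (log(runif(1)) < lpP - lpC) { p$alpha <- prop; accA <- accA + 1 }
    }

    # hyper-parameters
    p$mu_gam <- gibbsMu(p$lgam, p$sd_gam, hmSd)
    p$sd_gam <- mhLogSd(p$lgam, p$mu_gam, p$sd_gam, sdType, sdScale)
    p$mu_b0 <- gibbsMu(p$b0, p$sd_b0, hmSd)
    p$sd_b0 <- mhLogSd(p$b0, p$mu_b0, p$sd_b0, sdType, sdScale)
    p$mu_b4 <- gibbsMu(p$b4, p$sd_b4, hmSd)
    p$sd_b4 <- mhLogSd(p$b4, p$mu_b4, p$sd_b4, sdType, sdScale)
    p$mu_b5 <- gibbsMu(p$b5, p$sd_b5, hmSd)
    p$sd_b5 <- mhLogSd(p$b5, p$mu_b5, p$sd_b5, sdType, sdScale)
    p$mu_b6 <- gibbsMu(p$b6, p$sd_b6, hmSd)
    p$sd_b6 <- mhLogSd(p$b6, p$mu_b6, p$sd_b6, sdType, sdScale)
    covVals <- list(p$b1, p$b2, p$b3)
    for (cv in 1:3) for (g in 1:2) {
      idx <- if (g == 1) grpF else grpN
      x <- covVals[[cv]][idx]
      p$mu_cov[cv, g] <- gibbsMu(x, p$sd_cov[cv, g], hmSd)
      p$sd_cov[cv, g] <- mhLogSd(x, p$mu_cov[cv, g], p$sd_cov[cv, g],
                                 sdType, sdScale)
    }
    p$sd_alpha <- mhLogSd(p$alpha, 0, p$sd_alpha, sdType, sdScale)

    if (it > nBurn && (it - nBurn) %% nThin == 0) {
      row <- row + 1
      sp <- as.vector(rbind(plogis(p$psi0l), plogis(p$lgam), p$b0, p$b1,
                            p$b2, p$b3, p$b4, p$b5, p$b6))
      hy <- c(p$mu_gam, p$sd_gam, p$mu_b0, p$sd_b0, p$mu_b4, p$sd_b4,
              p$mu_b5, p$sd_b5, p$mu_b6, p$sd_b6)
      for (cv in 1:3) for (g in 1:2)
        hy <- c(hy, p$mu_cov[cv, g], p$sd_cov[cv, g])
      out[row, ] <- c(sp, p$alpha, hy, p$sd_alpha)
    }
  }
  list(draws = out, acceptSpecies = accS / totS, acceptAlpha = accA / totA)
}
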