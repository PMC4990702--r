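test_that("model components match their closed forms", {
  expect_equal(persistenceProb(0, 1, 1, 1, 0, 0, 0), 0.5)
  expect_equal(persistenceProb(1.2, 0.5, -2, 0.1, 0.3, 0.2, 1),
               plogis(1.2 + 0.5 * 0.3 - 2 * 0.2 + 0.1))
  # a negative exposure effect makes persistence strictly decreasing
  expos <- seq(0, 2, 0.25)
  expect_true(all(diff(persistenceProb(1, 0, -1.37, 0, 0, expos, 0)) < 0))
  expect_error(persistenceProb(0, 0, 0, 0, NA, 0, 0), "covariate")

  expect_equal(transitionProb(1, 0.8, 0.1), 0.8)
  expect_equal(transitionProb(0, 0.8, 0.1), 0.1)
  # occupied branch ignores colonisation; probabilities conserve
  expect_equal(transitionProb(1, 0.8, 0.99), transitionProb(1, 0.8, 0.01))
  p1 <- transitionProb(c(0, 1), 0.7, 0.2)
  expect_equal(p1 + (1 - p1), c(1, 1))

  expect_equal(detectionProb(-1, 2, 3, 0, 0, 0), plogis(-1))
  expect_equal(detectionProb(-1, 2, 3, 0.5, 1, 0), plogis(1.5))
  expect_equal(detectionProb(-1, 0, 0, 0, 1, 0),
               detectionProb(-1, 0, 0, 0, 0, 1))
  expect_equal(detectionProb(-1, 2, 3, -1e6, 0, 1), 0)
})

test_that("single-year likelihoods match hand-derived forms", {
  par <- randomParams(1)
  h <- list(nYears = 1, y = 1L, visitYear = 1L, isShort = 0L,
            isLong = 0L, X = matrix(numeric(0), ncol = 3))
  p <- plogis(par$beta4 + par$alpha[1])
  expect_equal(siteLogLikelihood(par, h), log(par$psi0 * p))
  h$y <- 0L
  expect_equal(siteLogLikelihood(par, h),
               log(par$psi0 * (1 - p) + (1 - par$psi0)))
})

test_that("forward recursion equals brute-force path enumeration", {
  set.seed(101)
  worst <- 0
  for (r in 1:1000) {
    T <- sample(1:3, 1)
    h <- randomHistory(T)
    par <- randomParams(T)
    a <- siteLogLikelihood(par, h)
    b <- bruteForceLogLikelihood(par, h)
    if (is.infinite(a) || is.infinite(b)) {
      expect_identical(a, b)
    } else {
      worst <- max(worst, abs(a - b))
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("oracle handles degenerate certainty and impossibility", {
  par <- randomParams(2)
  par$psi0 <- 1; par$gamma <- 0
  par$beta0 <- 1e3          # phi ~ 1
  par$beta1 <- par$beta2 <- par$beta3 <- 0
  par$beta4 <- 1e3          # p ~ 1
  par$beta5 <- par$beta6 <- 0; par$alpha <- c(0, 0)
  h <- list(nYears = 2, y = c(1L, 1L), visitYear = c(1L, 2L),
            isShort = c(0L, 0L), isLong = c(0L, 0L),
            X = matrix(0, 1, 3))
  expect_equal(bruteForceLogLikelihood(par, h), 0)
  expect_equal(siteLogLikelihood(par, h), 0)
  par$beta4 <- -1e3         # p ~ 0 but a detection happened
  expect_identical(siteLogLikelihood(par, h), -Inf)
  expect_identical(bruteForceLogLikelihood(par, h), -Inf)
  expect_error(bruteForceLogLikelihood(randomParams(13),
                                       randomHistory(13)), "2\\^13")
})

test_that("the compiled likelihood agrees with the R recursion", {
  st <- tinyStudy(seed = 3)
  arr <- beepersist:::occDataArrays(st$dat)
  n <- nrow(arr$y); T <- arr$nYears
  set.seed(8)
  par <- list(psi0l = rnorm(n), lgam = rnorm(n), b0 = rnorm(n),
              b1 = rnorm(n), b2 = rnorm(n), b3 = rnorm(n),
              b4 = rnorm(n), b5 = rnorm(n), b6 = rnorm(n),
              alpha = rnorm(T))
  cppll <- beepersist:::cpp_species_logliks(
    arr$y, arr$vSite, arr$vYear, arr$vShort, arr$vLong,
    arr$Xosr, arr$Xneo, arr$Xfii, arr$nSites, arr$nYears, par)
  rll <- vapply(seq_len(n), function(i) {
    tot <- 0
    for (j in seq_len(arr$nSites)) {
      sel <- arr$vSite == j - 1
      h <- list(nYears = T, y = arr$y[i, sel],
                visitYear = arr$vYear[sel] + 1L,
                isShort = arr$vShort[sel], isLong = arr$vLong[sel],
                X = cbind(arr$Xosr[j, ], arr$Xneo[j, ], arr$Xfii[j, ]))
      p <- list(psi0 = plogis(par$psi0l[i]), gamma = plogis(par$lgam[i]),
                beta0 = par$b0[i], beta1 = par$b1[i], beta2 = par$b2[i],
                beta3 = par$b3[i], beta4 = par$b4[i], beta5 = par$b5[i],
                beta6 = par$b6[i], alpha = par$alpha)
      tot <- tot + siteLogLikelihood(p, h)
    }
    tot
  }, numeric(1))
  expect_equal(as.numeric(cppll), rll, tolerance = 1e-12)
})
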