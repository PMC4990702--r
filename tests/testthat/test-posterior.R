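# most tests here fabricate posterior draws with known values so the
# results-stage arithmetic can be checked exactly

test_that("group-effect summaries are hand-checkable", {
  st <- tinyStudy(seed = 13)
  fit <- manualFit(st$dat, list(mu_beta2_forager = c(-2, -1, 0, 1)),
                   nDraws = 2, nChains = 2)
  s <- summarizeGroupEffect(fit, "forager", "neonic")
  expect_equal(s$posterior_mean, -0.5)
  expect_equal(s$fraction_below_zero, 0.5)
  expect_true(s$ci95_low <= s$posterior_mean &&
              s$posterior_mean <= s$ci95_high)
  fit2 <- manualFit(st$dat, list(mu_beta1_nonforager = c(-3, -2, -1, -4)),
                    nDraws = 2, nChains = 2)
  expect_equal(summarizeGroupEffect(fit2, "nonforager",
                                    "osr")$fraction_below_zero, 1)
  expect_equal(nrow(effectTable(fit2)), 6)
  expect_error(summarizeGroupEffect(fit, "forager", "rainfall"))
})

test_that("group differences pair draws and follow the sign convention", {
  st <- tinyStudy(seed = 13)
  fit <- manualFit(st$dat, list(mu_beta2_forager = -1,
                                mu_beta2_nonforager = -0.5))
  gd <- groupDifference(fit, "neonic")
  # non-forager minus forager: foragers more negative => positive
  expect_equal(unique(gd$draws), 0.5)
  expect_equal(gd$summary$mean, 0.5)
  expect_equal(gd$summary$fraction_above_zero, 1)
  # with the reported group means the difference is +0.91 and the
  # group means have ratio ~ 3
  fit2 <- manualFit(st$dat, list(mu_beta2_forager = -1.37,
                                 mu_beta2_nonforager = -0.46))
  expect_equal(groupDifference(fit2, "neonic")$summary$mean, 0.91)
  expect_equal(-1.37 / -0.46, 2.98, tolerance = 0.01)
  # pairwise consistency: mean of differences = difference of means
  set.seed(2)
  fit3 <- manualFit(st$dat, list(mu_beta2_forager = rnorm(100),
                                 mu_beta2_nonforager = rnorm(100)))
  gd3 <- groupDifference(fit3, "neonic")
  expect_equal(gd3$summary$mean,
               mean(paramDrawsVec(fit3, "mu_beta2_nonforager")) -
                 mean(paramDrawsVec(fit3, "mu_beta2_forager")))
})

test_that("zero exposure effect makes scenarios coincide exactly", {
  st <- tinyStudy(seed = 13)
  sp <- speciesInfo(st$dat)$species
  vals <- list()
  for (s in sp) {
    vals[[paste0("psi0[", s, "]")]] <- 0.6
    vals[[paste0("gamma[", s, "]")]] <- 0.2
    vals[[paste0("beta0[", s, "]")]] <- 1
    vals[[paste0("beta1[", s, "]")]] <- 0.4
    vals[[paste0("beta2[", s, "]")]] <- 0
    vals[[paste0("beta3[", s, "]")]] <- -0.02
  }
  fit <- manualFit(st$dat, vals, nDraws = 10)
  f <- projectOccupancy(fit, "factual")
  cf <- projectOccupancy(fit, "no_neonic")
  expect_equal(f$mean, cf$mean)
  expect_equal(attr(f, "finals"), attr(cf, "finals"))
})

test_that("negative exposure effects make the counterfactual dominate", {
  st <- tinyStudy(seed = 13)
  sp <- speciesInfo(st$dat)$species
  vals <- list()
  set.seed(31)
  for (s in sp) {
    vals[[paste0("psi0[", s, "]")]] <- runif(20, 0.4, 0.7)
    vals[[paste0("gamma[", s, "]")]] <- runif(20, 0.1, 0.3)
    vals[[paste0("beta0[", s, "]")]] <- rnorm(20, 1.2, 0.2)
    vals[[paste0("beta1[", s, "]")]] <- rnorm(20, 0.5, 0.2)
    vals[[paste0("beta2[", s, "]")]] <- -runif(20, 0.5, 2)
    vals[[paste0("beta3[", s, "]")]] <- rnorm(20, -0.02, 0.01)
  }
  fit <- manualFit(st$dat, vals, nDraws = 20)
  f <- projectOccupancy(fit, "factual", keepDraws = TRUE)
  cf <- projectOccupancy(fit, "no_neonic", keepDraws = TRUE)
  tf <- attr(f, "trajDraws"); tc <- attr(cf, "trajDraws")
  # dominance holds year-by-year within every draw
  expect_true(all(tc - tf >= -1e-12))
  # pre-treatment years are identical across scenarios
  years <- modelYears(st$dat)
  pre <- which(years <= 2002)  # transitions into 2002 use 2001 covariates
  expect_equal(tc[, pre, ], tf[, pre, ])
  # and someone actually loses occupancy after adoption
  expect_gt(max(tc - tf), 0.01)
})

test_that("percent loss of extant cells follows its definition", {
  mkTraj <- function(finals) {
    out <- data.frame(species = rownames(finals))
    attr(out, "finals") <- finals
    out
  }
  f <- mkTraj(matrix(c(0.4, 0.3), 2, 5,
                     dimnames = list(c("a", "b"), NULL)))
  cf <- mkTraj(matrix(c(0.5, 0.3), 2, 5,
                      dimnames = list(c("a", "b"), NULL)))
  loss <- occupancyLoss(f, cf)
  expect_equal(loss$pct_loss[loss$species == "a"], 20)
  expect_equal(loss$pct_loss[loss$species == "b"], 0)
  expect_setequal(attr(loss, "exceeds")[[">15%"]], "a")
  expect_setequal(attr(loss, "exceeds")[[">20%"]], character(0))
  # both methods agree on constant draws
  loss2 <- occupancyLoss(f, cf, method = "mean")
  expect_equal(loss$pct_loss, loss2$pct_loss)
  # zero counterfactual occupancy is undefined
  cf0 <- mkTraj(matrix(c(0, 0.3), 2, 5,
                       dimnames = list(c("a", "b"), NULL)))
  expect_true(is.na(occupancyLoss(f, cf0)$pct_loss[2]))
})

test_that("species with strongly negative exposure effects dominate the\n          high-loss list", {
  st <- tinyStudy(seed = 13)
  sp <- speciesInfo(st$dat)$species
  fg <- speciesInfo(st$dat)$osr_forager == 1
  vals <- list()
  for (k in seq_along(sp)) {
    s <- sp[k]
    vals[[paste0("psi0[", s, "]")]] <- 0.6
    vals[[paste0("gamma[", s, "]")]] <- 0.15
    vals[[paste0("beta0[", s, "]")]] <- 1.2
    vals[[paste0("beta1[", s, "]")]] <- 0
    vals[[paste0("beta2[", s, "]")]] <- if (fg[k]) -2.5 else -0.1
    vals[[paste0("beta3[", s, "]")]] <- 0
  }
  fit <- manualFit(st$dat, vals, nDraws = 10)
  loss <- occupancyLoss(projectOccupancy(fit, "factual"),
                        projectOccupancy(fit, "no_neonic"))
  topHalf <- loss$species[seq_len(sum(fg))]
  expect_true(all(fg[match(topHalf, sp)]))
})
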