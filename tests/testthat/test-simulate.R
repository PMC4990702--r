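test_that("landscape nesting and region partition are deterministic", {
  ls4 <- simulateLandscape(nSites = 4, cellsPerSite = 25, nRegions = 2)
  expect_length(unique(ls4$cell_lookup$cell1km_id), 100)
  # every 1 km cell maps to exactly one 5 km cell
  expect_equal(nrow(ls4$cell_lookup),
               length(unique(ls4$cell_lookup$cell1km_id)))
  expect_setequal(unique(ls4$cell_lookup$cell5km_id), ls4$sites)
  # the region partition covers all sites
  expect_setequal(ls4$cell_regions$cell5km_id, ls4$sites)
  expect_length(unique(ls4$cell_regions$region), 2)
  expect_error(simulateLandscape(nSites = 0), "at least one")
})

test_that("the adoption curve matches the reported endpoints", {
  set.seed(1)
  ls <- simulateLandscape(10, 4, 2)
  cov <- simulateCovariates(ls, years = 1994:2011)
  tr <- cov$treated_table
  expect_true(all(tr$proportion_treated[tr$year < 2002] == 0))
  # biennial emission: odd years absent
  expect_true(all(tr$year %% 2 == 0))
  p2002 <- tr$proportion_treated[tr$year == 2002]
  expect_equal(mean(p2002), 0.374, tolerance = 0.12)
  p2010 <- tr$proportion_treated[tr$year == 2010]
  expect_gt(mean(p2010), 0.7)
  expect_true(all(tr$proportion_treated >= 0 &
                    tr$proportion_treated <= 1))
})

test_that("identical seeds reproduce the study bit-for-bit", {
  cfg <- tinyConfig()
  a <- simulateBeeStudy(seed = 77, config = cfg)
  b <- simulateBeeStudy(seed = 77, config = cfg)
  expect_identical(a$tables, b$tables)
  expect_identical(a$truth$states, b$truth$states)
  c <- simulateBeeStudy(seed = 78, config = cfg)
  expect_false(identical(a$tables$records, c$tables$records))
})

test_that("dynamics honour absorbing corner cases and transition rates", {
  set.seed(3)
  panel <- data.frame(cell5km_id = rep(sprintf("S%02d", 1:30), each = 4),
                      year = rep(2000:2003, 30))
  panel$osr_c <- 0; panel$neonic_c <- 0; panel$fii_c <- 0
  sites <- sprintf("S%02d", 1:30)
  base <- list(species = data.frame(species = "x", osr_forager = 1L),
               psi0 = 0, gamma = 0, beta0 = 1.2, beta1 = 0, beta2 = 0,
               beta3 = 0, beta4 = 0, beta5 = 0, beta6 = 0,
               alpha = rep(0, 5))
  z <- simulateDynamics(base, panel, sites, 2000:2004)
  expect_true(all(z == 0L))          # absorbing absence
  full <- base; full$psi0 <- 1; full$beta0 <- 1e6
  z <- simulateDynamics(full, panel, sites, 2000:2004)
  expect_true(all(z == 1L))          # absorbing presence
  # empirical persistence frequency approaches phi
  many <- base; many$psi0 <- 1; many$gamma <- 0; many$beta0 <- 1
  zz <- replicate(60, {
    z <- simulateDynamics(many, panel, sites, 2000:2004)
    occ <- z[1, , 1:4] == 1L
    sum(z[1, , 2:5][occ]) / sum(occ)
  })
  expect_equal(mean(zz), plogis(1), tolerance = 0.02)
})

test_that("visits never detect species that are absent", {
  cfg <- tinyConfig()
  sim <- simulateBeeStudy(seed = 99, config = cfg)
  recs <- sim$tables$records
  mod <- sim$truth$params$species$species
  recs <- recs[recs$species %in% mod, ]
  z <- sim$truth$states
  sites <- match(substr(recs$cell1km_id, 1, 4), sprintf("S%03d",
    seq_len(cfg$nSites)))
  yrs <- as.integer(substr(recs$date, 1, 4)) - min(cfg$years) + 1L
  isp <- match(recs$species, mod)
  expect_true(all(z[cbind(isp, sites, yrs)] == 1L))
})

test_that("the survey pipeline reconstructs simulated detections exactly", {
  cfg <- tinyConfig()
  sim <- simulateBeeStudy(seed = 55, config = cfg)
  dat <- assembleFromTables(sim$tables, panel = sim$panel,
                            years = cfg$years, minSurveys = 1)
  recs <- sim$tables$records
  v <- visitInfo(dat)
  # records from 1 km cells failing the >=2-year filter are not part of
  # the assembled dataset
  keep <- recs$species %in% speciesInfo(dat)$species &
    paste(recs$cell1km_id, recs$date, sep = "|") %in% v$visit_id
  # conservation: one matrix cell per unique (species, visit) record
  expect_equal(sum(detections(dat)), sum(keep))
  # and each individual record is present in y
  vid <- paste(recs$cell1km_id[keep], recs$date[keep], sep = "|")
  expect_true(all(detections(dat)[cbind(
    match(recs$species[keep], speciesInfo(dat)$species),
    match(vid, v$visit_id))] == 1L))
})
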