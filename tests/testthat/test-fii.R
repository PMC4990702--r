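test_that("toxicity classification follows the 5/3/1 EIQ brackets", {
  expect_identical(classifyToxicity(c(0.5, 50, 500)), c(5L, 3L, 1L))
  # boundaries are open in the published brackets; both go to the
  # middle class by default
  expect_identical(classifyToxicity(c(1, 100)), c(3L, 3L))
  expect_identical(classifyToxicity(c(1, 100), boundaries = "outer"),
                   c(5L, 1L))
  # partition: every positive value maps to exactly one class, and the
  # map is non-increasing in LD50
  ld <- sort(exp(runif(200, log(1e-3), log(1e4))))
  z <- classifyToxicity(ld)
  expect_true(all(z %in% c(5L, 3L, 1L)))
  expect_true(all(diff(z) <= 0))
  expect_error(classifyToxicity(0), "positive")
  expect_error(classifyToxicity(c(2, NA), ingredient = c("a", "bad_ai")),
               "bad_ai")
})

test_that("plant-surface half-life is DT50 / 4", {
  expect_equal(plantSurfaceHalfLife(40), 10)
  expect_equal(plantSurfaceHalfLife(4), 1)
  expect_error(plantSurfaceHalfLife(0), "positive")
  expect_error(plantSurfaceHalfLife(-3, ingredient = "x"), "x")
})

test_that("a single application contributes 3 * Z * P * (M/A)", {
  expect_equal(fiiContribution(100, 1000, ld50 = 0.5, dt50 = 40), 15)
  expect_equal(fiiContribution(100, 1000, ld50 = 500, dt50 = 4), 0.3)
  expect_equal(fiiContribution(0, 1000, ld50 = 0.5, dt50 = 40), 0)
  expect_error(fiiContribution(10, 0, 1, 1), "positive")
  expect_error(fiiContribution(-1, 10, 1, 1), "non-negative")
})

test_that("regional FII sums contributions and checks the join", {
  props <- data.frame(active_ingredient = c("a", "b"),
                      ld50_ug_per_bee = c(0.5, 500),
                      dt50_days = c(40, 4))
  usage <- data.frame(region = "R1", year = 2003,
                      active_ingredient = c("a", "b"),
                      mass_applied_kg = c(100, 100),
                      area_sprayed_ha = c(1000, 1000))
  expect_equal(regionalFii(usage, props)$fii, 15.3)
  # empty usage scores nothing
  expect_equal(nrow(regionalFii(usage[0, ], props)), 0)
  # duplicate rows are separate applications and add up
  expect_equal(regionalFii(rbind(usage, usage), props)$fii, 30.6)
  expect_error(regionalFii(transform(usage, active_ingredient = "zz"),
                           props), "zz")
})

test_that("FII is additive and scales linearly in mass", {
  set.seed(4)
  props <- data.frame(active_ingredient = letters[1:4],
                      ld50_ug_per_bee = c(0.2, 5, 120, 0.9),
                      dt50_days = c(25, 12, 6, 33))
  usage <- data.frame(region = "R1", year = 2004,
                      active_ingredient = letters[1:4],
                      mass_applied_kg = runif(4, 10, 500),
                      area_sprayed_ha = runif(4, 1e3, 1e4))
  whole <- regionalFii(usage, props)$fii
  partA <- regionalFii(usage[1:2, ], props)$fii
  partB <- regionalFii(usage[3:4, ], props)$fii
  expect_equal(whole, partA + partB)
  doubled <- transform(usage, mass_applied_kg = 2 * mass_applied_kg)
  expect_equal(regionalFii(doubled, props)$fii, 2 * whole)
})

test_that("regional scores map to cells through the majority region", {
  scores <- data.frame(region = c("R1", "R2"), year = 2003,
                       fii = c(15.3, 2))
  cr <- data.frame(cell5km_id = c("c1", "c2", "c2"),
                   region = c("R1", "R1", "R2"),
                   area_fraction = c(1, 0.6, 0.4))
  out <- assignRegionScoreToCells(scores, cr)
  expect_equal(out$fii[out$cell5km_id == "c1"], 15.3)
  # the 0.6 fraction wins for the straddling cell
  expect_equal(out$fii[out$cell5km_id == "c2"], 15.3)
  expect_error(assignRegionScoreToCells(scores, cr, cells = c("c1", "c9")),
               "c9")
  # a region-year with no recorded applications scores zero
  out2 <- assignRegionScoreToCells(scores[1, ],
    data.frame(cell5km_id = "c3", region = "R9"))
  expect_equal(out2$fii, 0)
})
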