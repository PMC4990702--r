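test_that("biennial interpolation uses the midpoint rule", {
  out <- interpolateBiennial(data.frame(year = c(2004, 2006),
                                        v = c(10, 20)))
  expect_equal(out$v, c(10, 15, 20))
  out <- interpolateBiennial(data.frame(year = c(2004, 2006),
                                        v = c(10, 10)))
  expect_equal(out$v[out$year == 2005], 10)
  expect_error(interpolateBiennial(data.frame(year = c(2004, 2008),
                                              v = c(10, 20))), "gap")
})

test_that("interpolation is idempotent on annual series", {
  s <- data.frame(year = 2000:2006, v = rnorm(7))
  expect_equal(interpolateBiennial(s), s)
  once <- interpolateBiennial(data.frame(year = seq(2000, 2008, 2),
                                         v = rnorm(5)))
  expect_equal(interpolateBiennial(once), once)
})

test_that("neonicotinoid exposure is cover times proportion treated", {
  expect_equal(neonicExposure(100, 0.374), 37.4)
  expect_equal(neonicExposure(250, 0), 0)
  expect_equal(neonicExposure(0, 0.8), 0)
  expect_error(neonicExposure(10, 1.2), "\\[0, 1\\]")
  expect_error(neonicExposure(10, -0.1), "\\[0, 1\\]")
})

test_that("centring subtracts grand means and is invertible", {
  panel <- data.frame(osr = c(1, 2, 3), neonic = c(0, 0, 3),
                      fii = c(5, 5, 5))
  out <- centerCovariates(panel)
  expect_equal(out$osr_c, c(-1, 0, 1))
  expect_equal(out$fii_c, c(0, 0, 0))
  m <- attr(out, "covariate_means")
  expect_equal(m[["osr"]], 2)
  expect_equal(out$neonic_c + m[["neonic"]], panel$neonic)
  # centring preserves differences
  expect_equal(diff(out$osr_c), diff(panel$osr))
  expect_error(centerCovariates(data.frame(osr = c(1, NA), neonic = 1,
                                           fii = 1)), "missing")
})

test_that("the covariate panel assembles from raw biennial tables", {
  osr <- expand.grid(cell5km_id = c("c1", "c2"),
                     year = c(2000, 2002, 2004),
                     stringsAsFactors = FALSE)
  osr$osr <- c(10, 20, 12, 22, 14, 24)
  treated <- data.frame(region = "R1", year = c(2000, 2002, 2004),
                        proportion_treated = c(0, 0.4, 0.6))
  cr <- data.frame(cell5km_id = c("c1", "c2"), region = "R1")
  panel <- buildCovariatePanel(osr, treated, fii_panel = NULL,
                               cell_regions = cr, years = 2000:2004)
  expect_equal(nrow(panel), 10)
  # interpolated OSR for c1 in 2001 is the 2000/2002 midpoint
  expect_equal(panel$osr[panel$cell5km_id == "c1" & panel$year == 2001],
               11)
  # exposure is the product of the interpolated inputs
  expect_equal(panel$neonic[panel$cell5km_id == "c2" &
                              panel$year == 2003],
               23 * 0.5)
  expect_true(all(panel$neonic <= panel$osr))
  expect_equal(mean(panel$osr_c), 0)
  expect_equal(mean(panel$neonic_c), 0)
  # a cell present in surveys but absent from the crop table errors
  expect_error(buildCovariatePanel(osr, treated, NULL, cr,
                                   cells = c("c1", "c2", "c3")), "c3")
})

test_that("all-zero proportions give an all-zero exposure column", {
  osr <- data.frame(cell5km_id = "c1", year = c(2000, 2002),
                    osr = c(5, 7))
  treated <- data.frame(region = "R1", year = c(2000, 2002),
                        proportion_treated = 0)
  cr <- data.frame(cell5km_id = "c1", region = "R1")
  panel <- buildCovariatePanel(osr, treated, NULL, cr)
  expect_true(all(panel$neonic == 0))
})
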