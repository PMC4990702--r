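#' Default configuration of the synthetic study generator
#'
#' The generator emulates the structure of the national study at desk
#' scale: 20 oilseed-rape-forager and 15 non-forager modelled species
#' on 150 5 km grid cells (each nesting 25 1 km cells) in 5 regions
#' over 1994--2011, with biennially-surveyed covariate panels, a
#' neonicotinoid adoption curve rising from ~37.4% of the crop treated
#' in 2002 to ~83% by 2011, and volunteer-style visit effort in which
#' roughly half of the realised surveys are single-species lists.
#'
#' Group-level truth for the persistence covariate effects defaults to
#' the headline posterior means of the national analysis (neonicotinoid
#' exposure: forager -1.37, non-forager -0.46; oilseed-rape cover:
#' 1.06, -0.09; FII: -0.017, -0.013), so parameter-recovery
#' experiments target those values. Oilseed-rape cover is expressed as
#' the fraction of the 25 km^2 cell under the crop (exposure inherits
#' that unit); the FII index is on its natural scale (tens). Units
#' only scale coefficients since covariates are centred before
#' fitting.
#'
#' @param nForager,nNonforager modelled species per group.
#' @param nSites number of 5 km cells.
#' @param cellsPerSite 1 km cells nested per 5 km cell.
#' @param nRegions number of regions.
#' @param years modelled calendar years.
#' @param meanVisits mean visits per 5 km cell-year (Poisson).
#' @param classProbs latent effort-class probabilities
#'   (single/short/long propensity of a visit).
#' @param longListExtra mean Poisson excess of a long list's target
#'   length above 4 species.
#' @param nBackground size of the background species pool
#'   (non-modelled community standing in for the rest of the bee
#'   fauna). Background species fill each visit's list up to its
#'   effort class's target length, so every visit yields records and
#'   the realised list category tracks the latent effort class rather
#'   than the modelled species' occupancy (the exogenous-effort
#'   assumption of the detection sub-model).
#' @param truth list of generating hyper-parameters (see source).
#' @return a config list for [simulateBeeStudy()].
#' @export
simulationDefaults <- function(nForager = 20, nNonforager = 15,
                               nSites = 150, cellsPerSite = 25,
                               nRegions = 5, years = 1994:2011,
                               meanVisits = 12,
                               classProbs = c(single = 0.51, short = 0.24,
                                              long = 0.25),
                               longListExtra = 2.5,
                               nBackground = 150,
                               truth = list()) {
  tr <- list(
    mu_beta1 = c(forager = 1.06, nonforager = -0.09),
    mu_beta2 = c(forager = -1.37, nonforager = -0.46),
    mu_beta3 = c(forager = -0.017, nonforager = -0.013),
    sd_beta1 = 0.25, sd_beta2 = 0.25, sd_beta3 = 0.02,
    mu_beta0 = 1.4, sd_beta0 = 0.4,
    mu_lgamma = qlogis(0.18), sd_lgamma = 0.4,
    mu_beta4 = -4.3, sd_beta4 = 0.35,
    mu_beta5 = 1.2, sd_beta5 = 0.3,
    mu_beta6 = 3.3, sd_beta6 = 0.3,
    sd_alpha = 0.3,
    psi0_range = c(0.35, 0.8),
    adoption = c(p2002 = 0.374, p2011 = 0.83),
    adoptionNoiseSd = c(y2002 = 0.08, y2011 = 0.052),
    firstTreatmentYear = 2002)
  tr[names(truth)] <- truth
  list(nForager = nForager, nNonforager = nNonforager, nSites = nSites,
       cellsPerSite = cellsPerSite, nRegions = nRegions, years = years,
       meanVisits = meanVisits, classProbs = classProbs,
       longListExtra = longListExtra, nBackground = nBackground,
       truth = tr)
}

#' Simulate the grid landscape
#'
#' Deterministic nesting of 1 km cells in 5 km cells and a contiguous
#' partition of the 5 km cells into regions.
#'
#' @param nSites,cellsPerSite,nRegions see [simulationDefaults()].
#' @return list with `sites`, `cell_lookup` (cell1km_id, cell5km_id)
#'   and `cell_regions` (cell5km_id, region, area_fraction).
#' @export
simulateLandscape <- function(nSites = 150, cellsPerSite = 25,
                              nRegions = 5) {
  if (nSites < 1) stop("need at least one site")
  sites <- sprintf("S%03d", seq_len(nSites))
  lookup <- data.frame(
    cell1km_id = paste0(rep(sites, each = cellsPerSite), "_",
                        sprintf("%02d", seq_len(cellsPerSite))),
    cell5km_id = rep(sites, each = cellsPerSite))
  region <- paste0("R", ((seq_len(nSites) - 1) %/%
                           ceiling(nSites / nRegions)) + 1)
  cellRegions <- data.frame(cell5km_id = sites, region = region,
                            area_fraction = 1)
  list(sites = sites, cell_lookup = lookup, cell_regions = cellRegions)
}

#' Simulate covariate input tables
#'
#' Produces the biennial raw panels the covariate module expects:
#' per-cell oilseed-rape cover (spatially heterogeneous with a gentle
#' upward national drift), the regional proportion of the crop
#' seed-treated (zero until 2002, then a logistic ramp between the
#' reported 2002 and 2011 adoption levels with regional spread shrinking
#' from the reported early to late standard errors), and regional
#' foliar-insecticide usage plus an ingredient-properties table
#' spanning all three toxicity classes. Tables are emitted only for
#' even years to exercise midpoint interpolation.
#'
#' @param landscape from [simulateLandscape()].
#' @param years modelled calendar years.
#' @param truth generator truth list (see [simulationDefaults()]).
#' @return list `osr_table`, `treated_table`, `usage`, `properties`.
#' @export
simulateCovariates <- function(landscape, years = 1994:2011,
                               truth = simulationDefaults()$truth) {
  sites <- landscape$sites
  regions <- unique(landscape$cell_regions$region)
  covYears <- seq(min(years), max(years) - 1)        # lag years
  obsYears <- covYears[covYears %% 2 == 0]           # biennial panel

  base <- runif(length(sites), 0.03, 0.8)
  osr <- expand.grid(cell5km_id = sites, year = obsYears,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  drift <- 1 + 0.012 * (osr$year - min(years))
  osr$osr <- pmin(0.95, pmax(0.01,
    base[match(osr$cell5km_id, sites)] * drift *
      exp(rnorm(nrow(osr), 0, 0.08))))

  first <- truth$firstTreatmentYear
  ramp <- function(y) {
    l0 <- qlogis(truth$adoption["p2002"])
    l1 <- qlogis(truth$adoption["p2011"])
    plogis(l0 + (y - 2002) / 9 * (l1 - l0))
  }
  noiseSd <- function(y) {
    w <- pmin(1, pmax(0, (y - 2002) / 9))
    (1 - w) * truth$adoptionNoiseSd[1] + w * truth$adoptionNoiseSd[2]
  }
  treated <- expand.grid(region = regions, year = obsYears,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  prop <- ifelse(treated$year < first, 0,
                 ramp(treated$year) + rnorm(nrow(treated),
                                            0, noiseSd(treated$year)))
  treated$proportion_treated <- pmin(1, pmax(0, prop))

  properties <- data.frame(
    active_ingredient = c("pyrethroid_a", "pyrethroid_b", "carbamate_a",
                          "organophosphate_a", "neonic_foliar",
                          "low_tox_a"),
    ld50_ug_per_bee = c(0.05, 0.2, 5, 50, 0.02, 500),
    dt50_days = c(30, 20, 16, 8, 40, 4))
  usage <- expand.grid(region = regions, year = obsYears,
                       active_ingredient = properties$active_ingredient,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  usage$area_sprayed_ha <- runif(nrow(usage), 2e4, 8e4)
  rate <- runif(nrow(usage), 0.02, 0.18) *
    (1 + 0.3 * sin((usage$year - min(years)) / 4))
  usage$mass_applied_kg <- rate * usage$area_sprayed_ha

  list(osr_table = osr, treated_table = treated, usage = usage,
       properties = properties)
}

#' Draw species-level generating parameters from the group-level truth
#'
#' @param config a [simulationDefaults()] list.
#' @return list with the species table (`species`, `osr_forager`) and
#'   all species-level parameter vectors plus the year effects.
#' @export
simulateParams <- function(config = simulationDefaults()) {
  tr <- config$truth
  nF <- config$nForager; nN <- config$nNonforager
  species <- c(sprintf("for%02d", seq_len(nF)),
               sprintf("non%02d", seq_len(nN)))
  forager <- c(rep(1L, nF), rep(0L, nN))
  n <- nF + nN
  g <- ifelse(forager == 1, "forager", "nonforager")
  T <- length(config$years)
  list(
    species = data.frame(species = species, osr_forager = forager),
    psi0 = runif(n, tr$psi0_range[1], tr$psi0_range[2]),
    gamma = plogis(rnorm(n, tr$mu_lgamma, tr$sd_lgamma)),
    beta0 = rnorm(n, tr$mu_beta0, tr$sd_beta0),
    beta1 = rnorm(n, tr$mu_beta1[g], tr$sd_beta1),
    beta2 = rnorm(n, tr$mu_beta2[g], tr$sd_beta2),
    beta3 = rnorm(n, tr$mu_beta3[g], tr$sd_beta3),
    beta4 = rnorm(n, tr$mu_beta4, tr$sd_beta4),
    beta5 = rnorm(n, tr$mu_beta5, tr$sd_beta5),
    beta6 = rnorm(n, tr$mu_beta6, tr$sd_beta6),
    alpha = rnorm(T, 0, tr$sd_alpha))
}

#' Simulate true occupancy dynamics
#'
#' Generative mirror of the fitted model: first-year occupancy is
#' Bernoulli(psi0), subsequent years follow the colonisation/
#' persistence transition with persistence driven by the centred
#' lagged covariates.
#'
#' @param params from [simulateParams()].
#' @param panel centred covariate panel from [buildCovariatePanel()].
#' @param sites character vector of 5 km cells.
#' @param years modelled years.
#' @return integer array species x sites x years of true occupancy.
#' @export
simulateDynamics <- function(params, panel, sites, years) {
  n <- length(params$psi0)
  J <- length(sites)
  T <- length(years)
  key <- paste(panel$cell5km_id, panel$year)
  lagYears <- years[-T]
  grab <- function(col) matrix(
    panel[[col]][match(as.vector(outer(sites, lagYears, paste)), key)],
    nrow = J)
  Xosr <- grab("osr_c"); Xneo <- grab("neonic_c"); Xfii <- grab("fii_c")
  if (anyNA(Xosr) || anyNA(Xneo) || anyNA(Xfii))
    stop("covariate panel does not cover all site lag-years")
  z <- array(0L, dim = c(n, J, T))
  for (i in seq_len(n)) {
    z[i, , 1] <- rbinom(J, 1, params$psi0[i])
    for (t in 2:T) {
      phi <- plogis(params$beta0[i] + params$beta1[i] * Xosr[, t - 1] +
                    params$beta2[i] * Xneo[, t - 1] +
                    params$beta3[i] * Xfii[, t - 1])
      pr <- transitionProb(z[i, , t - 1], phi, params$gamma[i])
      z[i, , t] <- rbinom(J, 1, pr)
    }
  }
  z
}

#' Simulate volunteer survey visits and occurrence records
#'
#' Visit effort: per 5 km cell-year a Poisson number of visits lands
#' on random (1 km cell, date) combinations. Each visit first draws a
#' latent effort class (single/short/long propensity) that sets the
#' detection covariates; modelled species present in the cell are then
#' detected with their class-dependent detection probability, and
#' background (non-modelled community) species fill the list up to the
#' class's target length — a recorder's effort determines roughly how
#' many species get written down, and the modelled species are a
#' minority of the fauna. Every visit therefore records something, and
#' the realised list category (recomputed by the analysis pipeline
#' from the realised lists) almost always equals the latent class.
#'
#' @param states true occupancy from [simulateDynamics()].
#' @param params from [simulateParams()].
#' @param landscape from [simulateLandscape()].
#' @param years modelled years.
#' @param config a [simulationDefaults()] list.
#' @return list `records` (species, date, cell1km_id) and
#'   `visit_truth` (per realised visit: cell, year, latent class).
#' @export
simulateVisits <- function(states, params, landscape, years,
                           config = simulationDefaults()) {
  sites <- landscape$sites
  lookup <- landscape$cell_lookup
  T <- length(years)
  n <- dim(states)[1]
  classes <- c("single", "short", "long")
  cp <- config$classProbs / sum(config$classProbs)

  visits <- vector("list", length(sites) * T)
  for (j in seq_along(sites)) {
    cells <- lookup$cell1km_id[lookup$cell5km_id == sites[j]]
    for (t in seq_len(T)) {
      nv <- rpois(1, config$meanVisits)
      if (nv == 0) next
      # distinct (1 km cell, day) slots: one visit per cell-date
      slots <- sample(length(cells) * 365, min(nv, length(cells) * 365))
      visits[[(j - 1) * T + t]] <- data.frame(
        site = j, year_idx = t,
        cell1km_id = cells[(slots - 1) %/% 365 + 1],
        date = as.Date(sprintf("%d-01-01", years[t])) + (slots - 1) %% 365,
        class = sample(classes, length(slots), replace = TRUE, prob = cp))
    }
  }
  visits <- do.call(rbind, visits)
  isShort <- as.integer(visits$class == "short")
  isLong <- as.integer(visits$class == "long")

  spNames <- params$species$species
  recs <- list(); rn <- 0
  nDetected <- integer(nrow(visits))
  for (i in seq_len(n)) {
    zv <- states[cbind(i, visits$site, visits$year_idx)]
    occ <- which(zv == 1L)
    if (!length(occ)) next
    p <- plogis(params$beta4[i] + params$beta5[i] * isShort[occ] +
                params$beta6[i] * isLong[occ] +
                params$alpha[visits$year_idx[occ]])
    hit <- occ[rbinom(length(occ), 1, p) == 1L]
    if (length(hit)) {
      nDetected[hit] <- nDetected[hit] + 1L
      rn <- rn + 1
      recs[[rn]] <- data.frame(species = spNames[i],
                               date = visits$date[hit],
                               cell1km_id = visits$cell1km_id[hit])
    }
  }
  # Background community: the rest of the bee fauna. Each effort class
  # targets a list length (single: 1, short: 2-3, long: >3) and
  # background species fill whatever the modelled detections leave
  # open. Two consequences the detection sub-model relies on: every
  # visit yields a record (visit existence is exogenous), and the
  # realised list category almost always equals the latent effort
  # class, so the effort covariates are not driven by the modelled
  # species' occupancy.
  target <- integer(nrow(visits))
  cls <- visits$class
  target[cls == "single"] <- 1L
  nShort <- sum(cls == "short")
  target[cls == "short"] <- sample(2:3, nShort, replace = TRUE)
  nLong <- sum(cls == "long")
  target[cls == "long"] <- 4L + rpois(nLong, config$longListExtra)
  bgPool <- sprintf("bg%03d", seq_len(config$nBackground))
  nbg <- pmax(0L, target - nDetected)
  withBg <- which(nbg > 0)
  if (length(withBg)) {
    bgSpecies <- lapply(withBg, function(v)
      sample(bgPool, min(nbg[v], length(bgPool))))
    rn <- rn + 1
    recs[[rn]] <- data.frame(
      species = unlist(bgSpecies),
      date = rep(visits$date[withBg], lengths(bgSpecies)),
      cell1km_id = rep(visits$cell1km_id[withBg], lengths(bgSpecies)))
  }
  records <- do.call(rbind, recs)
  records <- records[order(records$date, records$cell1km_id,
                           records$species), ]
  records$date <- as.character(records$date)
  rownames(records) <- NULL
  list(records = records,
       visit_truth = data.frame(cell1km_id = visits$cell1km_id,
                                date = as.character(visits$date),
                                year = years[visits$year_idx],
                                class = visits$class))
}

#' Generate a complete synthetic study with known truth
#'
#' Runs the whole generative pipeline under one seed: landscape,
#' biennial covariate tables, the FII usage tables, centred covariate
#' panel (via the same covariate-assembly code the analysis uses),
#' species-level parameters drawn from the group-level truth, true
#' occupancy dynamics, and volunteer visit records. Regenerating with
#' the same seed reproduces every table exactly.
#'
#' @param seed integer master seed.
#' @param config a [simulationDefaults()] list.
#' @param outDir optional directory; when given, the five input CSVs
#'   (records, species_traits, osr_cover, neonic_treated,
#'   pesticide_usage + pesticide_properties + cell files) are written
#'   there along with `truth.json`.
#' @return list with `tables` (all input data.frames), `panel` (the
#'   centred covariate panel), `truth` (generating parameters, true
#'   states, seed, config).
#' @export
simulateBeeStudy <- function(seed = 1, config = simulationDefaults(),
                             outDir = NULL) {
  set.seed(seed)
  years <- config$years
  landscape <- simulateLandscape(config$nSites, config$cellsPerSite,
                                 config$nRegions)
  cov <- simulateCovariates(landscape, years, config$truth)
  fiiPanel <- buildFiiPanel(cov$usage, cov$properties,
                            landscape$cell_regions)
  panel <- buildCovariatePanel(cov$osr_table, cov$treated_table, fiiPanel,
                               landscape$cell_regions,
                               years = seq(min(years), max(years) - 1))
  params <- simulateParams(config)
  z <- simulateDynamics(params, panel, landscape$sites, years)
  vis <- simulateVisits(z, params, landscape, years, config)
  bgTraits <- data.frame(species = sprintf("bg%03d",
                                           seq_len(config$nBackground)),
                         osr_forager = 0L)
  traits <- rbind(params$species, bgTraits)

  tables <- list(records = vis$records,
                 species_traits = traits,
                 osr_cover = cov$osr_table,
                 neonic_treated = cov$treated_table,
                 pesticide_usage = cov$usage,
                 pesticide_properties = cov$properties,
                 cell_lookup = landscape$cell_lookup,
                 cell_regions = landscape$cell_regions)
  truth <- list(seed = seed, config = config, params = params,
                states = z, visit_truth = vis$visit_truth)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (nmTab in names(tables))
      write.csv(tables[[nmTab]], file.path(outDir, paste0(nmTab, ".csv")),
                row.names = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      tj <- truth; tj$states <- NULL; tj$visit_truth <- NULL
      jsonlite::write_json(tj, file.path(outDir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  list(tables = tables, panel = panel, truth = truth)
}

#' Run the analysis pipeline on raw tables
#'
#' Convenience wrapper applying the survey-assembly rules (visit
#' construction, >=2-year cell filter, optional aggregation, minimum
#' survey count per species) and attaching the covariate panel.
#'
#' @param tables list of input tables as produced by
#'   [simulateBeeStudy()] (or read from CSVs with the same columns).
#' @param panel centred covariate panel; when NULL it is rebuilt from
#'   the tables.
#' @param years modelled years.
#' @param minYears,minSurveys inclusion filters.
#' @param aggregates optional aggregation map.
#' @return a [BeeOccData-class].
#' @export
assembleFromTables <- function(tables, panel = NULL, years = NULL,
                               minYears = 2, minSurveys = 500,
                               aggregates = NULL) {
  if (is.null(panel)) {
    fiiPanel <- buildFiiPanel(tables$pesticide_usage,
                              tables$pesticide_properties,
                              tables$cell_regions)
    panelYears <- if (is.null(years)) NULL
                  else seq(min(years), max(years) - 1)
    panel <- buildCovariatePanel(tables$osr_cover, tables$neonic_treated,
                                 fiiPanel, tables$cell_regions,
                                 years = panelYears)
  }
  ss <- buildSurveys(tables$records, studyYears = years)
  ss <- filterCells(ss, minYears = minYears)
  ss <- aggregateSpecies(ss, aggregates)
  retained <- filterSpecies(ss, minSurveys = minSurveys)
  assembleDetectionDataset(ss, tables$species_traits,
                           retained = retained,
                           cell_lookup = tables$cell_lookup,
                           years = years, covariates = panel)
}
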