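#' Annualise a biennial series by midpoint interpolation
#'
#' The national crop-cover and pesticide-usage panels are surveyed
#' every second year; missing interior years are filled with the mean
#' of the two adjacent observed years (e.g. 2005 = mean of 2004 and
#' 2006). Already-annual stretches pass through unchanged, so the
#' operation is idempotent. Leading/trailing years outside the observed
#' range are not extrapolated.
#'
#' @param series data.frame with a `year` column and one value column,
#'   or a numeric vector named by year.
#' @param value name of the value column when `series` is a
#'   data.frame; defaults to the first non-`year` column.
#' @return data.frame `year`, `<value>` covering every year from the
#'   first to the last observed year.
#' @examples
#' interpolateBiennial(data.frame(year = c(2004, 2006), osr = c(10, 20)))
#' @export
interpolateBiennial <- function(series, value = NULL) {
  if (is.numeric(series) && !is.null(names(series)))
    series <- data.frame(year = as.integer(names(series)), value = series)
  if (is.null(value))
    value <- setdiff(names(series), "year")[1]
  s <- series[order(series$year), ]
  yrs <- as.integer(s$year)
  if (anyDuplicated(yrs)) stop("duplicate years in series")
  gaps <- diff(yrs)
  if (any(gaps > 2))
    stop("cannot interpolate a gap of ", max(gaps),
         " years (only gaps of exactly 2 are filled): after year ",
         yrs[which.max(gaps)])
  allYears <- seq(min(yrs), max(yrs))
  v <- s[[value]][match(allYears, yrs)]
  miss <- which(is.na(v))
  if (length(miss))
    v[miss] <- (v[miss - 1] + v[miss + 1]) / 2
  out <- data.frame(year = allYears, v)
  names(out)[2] <- value
  out
}

#' Neonicotinoid exposure of a grid cell
#'
#' Hectares of oilseed rape in the cell times the regional proportion
#' of the crop receiving a neonicotinoid seed treatment.
#'
#' @param osr_area oilseed-rape area (same unit as the covariate
#'   panel's `osr` column).
#' @param proportion_treated fraction of the crop treated, in `[0, 1]`.
#' @return exposure, in the `osr_area` unit.
#' @examples
#' neonicExposure(100, 0.374)  # 37.4
#' @export
neonicExposure <- function(osr_area, proportion_treated) {
  if (any(is.na(proportion_treated) | proportion_treated < 0 |
          proportion_treated > 1))
    stop("proportion_treated must lie in [0, 1]")
  if (any(is.na(osr_area) | osr_area < 0))
    stop("osr_area must be non-negative")
  osr_area * proportion_treated
}

#' Centre covariate columns on their grand means
#'
#' Each covariate is centred on its mean over all cell-years in the
#' panel (the cell-years entering the model); the means are stored in
#' the `"covariate_means"` attribute so the original scale can be
#' recovered and so counterfactual scenarios can be re-centred
#' consistently.
#'
#' @param panel data.frame covariate panel.
#' @param cols columns to centre; `<col>_c` companions are appended.
#' @return the panel with centred columns and the means attribute.
#' @export
centerCovariates <- function(panel, cols = c("osr", "neonic", "fii")) {
  missing <- setdiff(cols, names(panel))
  if (length(missing))
    stop("panel is missing covariate columns: ",
         paste(missing, collapse = ", "))
  means <- numeric(0)
  for (cl in cols) {
    if (anyNA(panel[[cl]]))
      stop("covariate ", cl, " has missing values in modelled cell-years")
    m <- mean(panel[[cl]])
    panel[[paste0(cl, "_c")]] <- panel[[cl]] - m
    means[cl] <- m
  }
  attr(panel, "covariate_means") <- means
  panel
}

#' Build the per-cell annual covariate panel
#'
#' Assembles, for every modelled 5 km cell and year: oilseed-rape
#' cover (annualised from the biennial crop survey), neonicotinoid
#' exposure (cover times the annualised regional proportion of crop
#' treated), and the FII index, then centres all three covariates on
#' their grand means.
#'
#' @param osr_table data.frame `cell5km_id`, `year`, `osr` (biennial or
#'   annual crop cover per cell).
#' @param treated_table data.frame `region`, `year`,
#'   `proportion_treated` (biennial or annual). Years missing entirely
#'   from a region's interpolated range default to proportion 0 only if
#'   `fillProportion` is TRUE (they error otherwise).
#' @param fii_panel data.frame `cell5km_id`, `year`, `fii` from
#'   [buildFiiPanel()]; optional, defaults to 0 everywhere (no foliar
#'   applications recorded).
#' @param cell_regions cell-to-region map (see [majorityRegion()]).
#' @param years integer vector of years the panel must cover (the
#'   modelled covariate years, i.e. the lag years of the occupancy
#'   model). Defaults to the union of years in `osr_table` after
#'   interpolation.
#' @param cells cells the panel must cover; defaults to all cells in
#'   `osr_table`.
#' @param fillProportion logical; treat years before a region's first
#'   recorded proportion as untreated (proportion 0). Defaults TRUE,
#'   matching seed treatments that did not exist before first
#'   licensing.
#' @return data.frame `cell5km_id`, `year`, `osr`, `neonic`, `fii`,
#'   `osr_c`, `neonic_c`, `fii_c` with a `"covariate_means"` attribute.
#' @export
buildCovariatePanel <- function(osr_table, treated_table, fii_panel = NULL,
                                cell_regions, years = NULL, cells = NULL,
                                fillProportion = TRUE) {
  if (!all(c("cell5km_id", "year", "osr") %in% names(osr_table)))
    stop("osr_table needs columns cell5km_id, year, osr")
  if (!all(c("region", "year", "proportion_treated") %in%
           names(treated_table)))
    stop("treated_table needs columns region, year, proportion_treated")
  if (is.null(cells)) cells <- sort(unique(osr_table$cell5km_id))
  missingCells <- setdiff(cells, osr_table$cell5km_id)
  if (length(missingCells))
    stop("cell(s) absent from osr_table: ",
         paste(missingCells, collapse = ", "))
  reg <- majorityRegion(cell_regions)
  unmapped <- setdiff(cells, names(reg))
  if (length(unmapped))
    stop("no region mapping for cell(s): ", paste(unmapped, collapse = ", "))

  osrAnnual <- do.call(rbind, lapply(split(osr_table, osr_table$cell5km_id),
    function(s) {
      a <- interpolateBiennial(s[, c("year", "osr")], value = "osr")
      data.frame(cell5km_id = s$cell5km_id[1], a)
    }))
  propAnnual <- do.call(rbind, lapply(split(treated_table,
                                            treated_table$region),
    function(s) {
      a <- interpolateBiennial(s[, c("year", "proportion_treated")],
                               value = "proportion_treated")
      data.frame(region = s$region[1], a)
    }))

  if (is.null(years)) years <- sort(unique(osrAnnual$year))
  panel <- expand.grid(cell5km_id = cells, year = years,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  panel$osr <- osrAnnual$osr[match(paste(panel$cell5km_id, panel$year),
                                   paste(osrAnnual$cell5km_id,
                                         osrAnnual$year))]
  if (anyNA(panel$osr))
    stop("oilseed-rape cover does not span the modelled years for ",
         "cell(s): ",
         paste(unique(panel$cell5km_id[is.na(panel$osr)]), collapse = ", "))
  prop <- propAnnual$proportion_treated[
    match(paste(reg[panel$cell5km_id], panel$year),
          paste(propAnnual$region, propAnnual$year))]
  if (fillProportion) {
    firstYear <- tapply(propAnnual$year, propAnnual$region, min)
    before <- panel$year < firstYear[reg[panel$cell5km_id]]
    prop[is.na(prop) & before] <- 0
  }
  if (anyNA(prop))
    stop("proportion treated does not cover all modelled region-years")
  panel$neonic <- neonicExposure(panel$osr, prop)

  if (is.null(fii_panel)) {
    panel$fii <- 0
  } else {
    panel$fii <- fii_panel$fii[match(paste(panel$cell5km_id, panel$year),
                                     paste(fii_panel$cell5km_id,
                                           fii_panel$year))]
    if (anyNA(panel$fii))
      stop("FII panel does not cover all modelled cell-years")
  }
  panel <- panel[order(panel$cell5km_id, panel$year), , drop = FALSE]
  rownames(panel) <- NULL
  centerCovariates(panel)
}
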