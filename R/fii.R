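#' Foliar Insecticide Impact (FII) index
#'
#' The FII index scores the pressure that foliar-sprayed (non-systemic)
#' insecticides put on bees in a region and year. It is the bee
#' component of the Environmental Impact Quotient (EIQ): each active
#' ingredient contributes
#'
#' \deqn{3 \, Z_{ai} \, P_{ai} \, (M_{ai,R} / A_R)}
#'
#' where \eqn{Z_{ai}} is a 5/3/1 toxicity class from the contact
#' LD50, \eqn{P_{ai}} is the plant-surface half-life (soil DT50 / 4,
#' days), \eqn{M_{ai,R}} the mass of active ingredient applied in
#' region R (kg) and \eqn{A_R} the area of crop sprayed (ha). The
#' factor 3 is the EIQ bee-exposure weighting, retained for
#' consistency with the published EIQ even though it is a constant
#' here. Regional scores are the sum over active ingredients, and are
#' assigned to each 5 km grid cell through the region holding the
#' majority of the cell's area.
#'
#' Only the bee component is computed; the consumer, farm-worker and
#' other ecological EIQ components are out of scope.
#'
#' @name fii
NULL

#' Classify contact toxicity to bees into the EIQ 5/3/1 coefficient
#'
#' High-toxicity compounds (LD50 < 1 ug/bee) score 5, medium
#' (1--100 ug/bee) score 3, low (LD50 > 100 ug/bee) score 1. The
#' published brackets are open at both ends; boundary values (exactly
#' 1 or 100) are assigned to the middle class, controllable via
#' `boundaries`.
#'
#' @param ld50 numeric vector of contact LD50 values, ug per bee.
#' @param ingredient optional character vector of active-ingredient
#'   names used in error messages.
#' @param boundaries class assigned to LD50 values falling exactly on
#'   1 or 100; `"middle"` (default) gives both the coefficient 3.
#' @return integer vector of toxicity coefficients in \{5, 3, 1\}.
#' @examples
#' classifyToxicity(c(0.5, 50, 500))  # 5 3 1
#' @export
classifyToxicity <- function(ld50, ingredient = NULL,
                             boundaries = c("middle", "outer")) {
  boundaries <- match.arg(boundaries)
  bad <- is.na(ld50) | ld50 <= 0
  if (any(bad)) {
    who <- if (!is.null(ingredient)) paste(ingredient[bad], collapse = ", ")
           else paste(which(bad), collapse = ", ")
    stop("LD50 must be positive and non-missing for: ", who)
  }
  z <- ifelse(ld50 < 1, 5L, ifelse(ld50 > 100, 1L, 3L))
  if (boundaries == "outer")
    z <- ifelse(ld50 <= 1, 5L, ifelse(ld50 >= 100, 1L, 3L))
  as.integer(z)
}

#' Plant-surface half-life of an active ingredient
#'
#' Estimated as the soil degradation half-life (DT50) divided by four.
#'
#' @param dt50 numeric vector of soil DT50 values, days.
#' @param ingredient optional names for error messages.
#' @return numeric vector, plant-surface half-life in days.
#' @export
plantSurfaceHalfLife <- function(dt50, ingredient = NULL) {
  bad <- is.na(dt50) | dt50 <= 0
  if (any(bad)) {
    who <- if (!is.null(ingredient)) paste(ingredient[bad], collapse = ", ")
           else paste(which(bad), collapse = ", ")
    stop("DT50 must be positive and non-missing for: ", who)
  }
  dt50 / 4
}

#' FII contribution of one pesticide application
#'
#' @param mass_applied mass of active ingredient applied in the region
#'   (kg).
#' @param area_sprayed area of crop sprayed in the region (ha); must be
#'   positive.
#' @param ld50 contact LD50 (ug/bee) of the ingredient.
#' @param dt50 soil half-life (days) of the ingredient.
#' @return numeric: 3 * Z * P * (M / A), dimensionless (given the
#'   declared kg/ha input units; covariates are centred before model
#'   fitting so the absolute unit convention only scales coefficients).
#' @examples
#' fiiContribution(100, 1000, ld50 = 0.5, dt50 = 40)  # 3*5*10*0.1 = 15
#' @export
fiiContribution <- function(mass_applied, area_sprayed, ld50, dt50) {
  if (any(is.na(mass_applied) | mass_applied < 0))
    stop("mass_applied must be non-negative")
  if (any(is.na(area_sprayed) | area_sprayed <= 0))
    stop("area_sprayed must be positive")
  3 * classifyToxicity(ld50) * plantSurfaceHalfLife(dt50) *
    (mass_applied / area_sprayed)
}

#' Regional FII scores per year
#'
#' Sums [fiiContribution()] over all foliar applications recorded in
#' each region-year. Duplicate rows for one ingredient are treated as
#' separate applications and their contributions add.
#'
#' @param usage data.frame with columns `region`, `year`,
#'   `active_ingredient`, `mass_applied_kg`, `area_sprayed_ha`.
#' @param properties data.frame with columns `active_ingredient`,
#'   `ld50_ug_per_bee`, `dt50_days`.
#' @return data.frame `region`, `year`, `fii` (one row per region-year
#'   present in `usage`; region-years with no applications simply do
#'   not appear and score 0).
#' @export
regionalFii <- function(usage, properties) {
  need <- c("region", "year", "active_ingredient",
            "mass_applied_kg", "area_sprayed_ha")
  if (!all(need %in% names(usage)))
    stop("usage is missing columns: ",
         paste(setdiff(need, names(usage)), collapse = ", "))
  if (nrow(usage) == 0)
    return(data.frame(region = character(), year = integer(),
                      fii = numeric()))
  unknown <- setdiff(usage$active_ingredient, properties$active_ingredient)
  if (length(unknown))
    stop("no pesticide properties for active ingredient(s): ",
         paste(unknown, collapse = ", "))
  idx <- match(usage$active_ingredient, properties$active_ingredient)
  contrib <- fiiContribution(usage$mass_applied_kg, usage$area_sprayed_ha,
                             properties$ld50_ug_per_bee[idx],
                             properties$dt50_days[idx])
  out <- aggregate(contrib,
                   by = list(region = usage$region, year = usage$year),
                   FUN = sum)
  names(out)[3] <- "fii"
  out[order(out$region, out$year), , drop = FALSE]
}

#' Majority region of each 5 km grid cell
#'
#' @param cell_regions data.frame `cell5km_id`, `region`, optional
#'   `area_fraction` (defaults to 1; the region with the largest
#'   fraction wins, ties broken by first occurrence).
#' @return named character vector: cell id -> region.
#' @export
majorityRegion <- function(cell_regions) {
  if (!all(c("cell5km_id", "region") %in% names(cell_regions)))
    stop("cell_regions needs columns cell5km_id and region")
  af <- if ("area_fraction" %in% names(cell_regions))
    cell_regions$area_fraction else rep(1, nrow(cell_regions))
  ord <- order(cell_regions$cell5km_id, -af)
  cr <- cell_regions[ord, ]
  keep <- !duplicated(cr$cell5km_id)
  setNames(as.character(cr$region[keep]), cr$cell5km_id[keep])
}

#' Assign regional FII scores to 5 km grid cells
#'
#' Each cell-year receives the FII score of the region holding the
#' majority of the cell's area. Cells with no region mapping raise an
#' error naming the offending ids.
#'
#' @param scores data.frame `region`, `year`, `fii` (see
#'   [regionalFii()]; typically annualised first with
#'   [interpolateBiennial()]).
#' @param cell_regions cell-to-region map, see [majorityRegion()].
#' @param cells optional character vector of cells that must be
#'   covered; defaults to every cell in `cell_regions`.
#' @return data.frame `cell5km_id`, `year`, `fii`. Region-years absent
#'   from `scores` score 0 (no recorded foliar applications).
#' @export
assignRegionScoreToCells <- function(scores, cell_regions, cells = NULL) {
  reg <- majorityRegion(cell_regions)
  if (is.null(cells)) cells <- names(reg)
  unmapped <- setdiff(cells, names(reg))
  if (length(unmapped))
    stop("no region mapping for cell(s): ", paste(unmapped, collapse = ", "))
  years <- sort(unique(scores$year))
  out <- expand.grid(cell5km_id = cells, year = years,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(scores$region, scores$year)
  fii <- scores$fii[match(paste(reg[out$cell5km_id], out$year), key)]
  out$fii <- ifelse(is.na(fii), 0, fii)
  out[order(out$cell5km_id, out$year), , drop = FALSE]
}

#' Build the per-cell annual FII panel from raw usage tables
#'
#' Convenience pipeline: [regionalFii()], then annualisation of each
#' region's biennial series with [interpolateBiennial()], then
#' [assignRegionScoreToCells()].
#'
#' @inheritParams regionalFii
#' @inheritParams assignRegionScoreToCells
#' @return data.frame `cell5km_id`, `year`, `fii`.
#' @export
buildFiiPanel <- function(usage, properties, cell_regions, cells = NULL) {
  scores <- regionalFii(usage, properties)
  annual <- do.call(rbind, lapply(split(scores, scores$region), function(s) {
    a <- interpolateBiennial(s[, c("year", "fii")], value = "fii")
    data.frame(region = s$region[1], year = a$year, fii = a$fii)
  }))
  rownames(annual) <- NULL
  assignRegionScoreToCells(annual, cell_regions, cells = cells)
}
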