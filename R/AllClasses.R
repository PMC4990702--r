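#' @import methods
#' @importFrom stats plogis qlogis rbinom rnorm runif rpois quantile sd var
#'   setNames aggregate na.omit dnorm rbeta glm binomial coef
#' @importFrom utils read.csv write.csv head
#' @useDynLib beepersist, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Detection dataset for the multi-species dynamic occupancy model
#'
#' `BeeOccData` holds everything the occupancy-detection model consumes:
#' the binary detection matrix (species x visit), per-visit metadata
#' (5 km site, year, list-length effort categories), species traits
#' (the oilseed-rape forager flag that selects the group-level prior),
#' and the annual per-site covariate panel (oilseed-rape cover,
#' neonicotinoid exposure, foliar insecticide impact index; raw and
#' centred).
#'
#' Visits are unique date x 1 km grid-cell survey events pooled under
#' their parent 5 km cell. Site-years without any visit are legitimate:
#' the model marginalises (or imputes) the latent occupancy state for
#' those years.
#'
#' @slot y integer matrix, species x visits, 0/1 detections.
#' @slot visits data.frame with one row per visit: `visit_id`,
#'   `cell5km_id`, `year`, `is_short`, `is_long` (and optionally
#'   `cell1km_id`, `date`, `list_length`).
#' @slot species data.frame with `species` and `osr_forager` (0/1).
#' @slot sites character vector of modelled 5 km cell identifiers.
#' @slot years integer vector of consecutive modelled calendar years.
#' @slot covariates data.frame covariate panel (`cell5km_id`, `year`,
#'   `osr`, `neonic`, `fii`, `osr_c`, `neonic_c`, `fii_c`) carrying a
#'   `"covariate_means"` attribute; may have zero rows before
#'   [covariatePanel<-] is called.
#' @seealso [assembleDetectionDataset()], [fitOccupancyModel()]
#' @export
setClass("BeeOccData",
  representation(
    y = "matrix",
    visits = "data.frame",
    species = "data.frame",
    sites = "character",
    years = "integer",
    covariates = "data.frame"
  )
)

setValidity("BeeOccData", function(object) {
  msg <- character()
  if (!all(object@y %in% c(0L, 1L)))
    msg <- c(msg, "detections y must be binary 0/1")
  if (nrow(object@y) != nrow(object@species))
    msg <- c(msg, "nrow(y) must equal number of species")
  if (ncol(object@y) != nrow(object@visits))
    msg <- c(msg, "ncol(y) must equal number of visits")
  need <- c("visit_id", "cell5km_id", "year", "is_short", "is_long")
  if (!all(need %in% names(object@visits)))
    msg <- c(msg, paste("visits needs columns:", paste(need, collapse = ", ")))
  else {
    if (!all(object@visits$cell5km_id %in% object@sites))
      msg <- c(msg, "every visit must belong to a modelled site")
    if (!all(object@visits$year %in% object@years))
      msg <- c(msg, "every visit year must be a modelled year")
    if (any(object@visits$is_short == 1 & object@visits$is_long == 1))
      msg <- c(msg, "a visit cannot be both a short and a long list")
  }
  if (!all(c("species", "osr_forager") %in% names(object@species)))
    msg <- c(msg, "species needs columns species, osr_forager")
  else if (!all(object@species$osr_forager %in% c(0L, 1L)))
    msg <- c(msg, "osr_forager must be 0/1")
  if (length(object@years) > 1 && !all(diff(object@years) == 1L))
    msg <- c(msg, "modelled years must be consecutive")
  if (length(msg)) msg else TRUE
})

#' Fitted multi-species dynamic occupancy model
#'
#' Posterior draws and sampler metadata returned by
#' [fitOccupancyModel()]. Draws are stored as an iterations x
#' parameters x chains array (coda-style layout); [posteriorDraws()]
#' returns them as a long table and [rhatTable()] reports split-chain
#' Gelman--Rubin diagnostics for the monitored parameters.
#'
#' @slot draws numeric array, kept iterations x parameters x chains,
#'   with parameter dimnames such as `"beta2[sp07]"`,
#'   `"mu_beta2_forager"`, `"alpha[2003]"`.
#' @slot data the [BeeOccData-class] object the model was fitted to.
#' @slot config list of sampler settings (chains, iterations, burnin,
#'   thin, seed, sampler variant, priors).
#' @slot accept named numeric vector of acceptance rates.
#' @slot rhat data.frame of convergence diagnostics for the monitored
#'   parameter set.
#' @slot converged logical; TRUE when all monitored Rhat values fall at
#'   or below the configured threshold.
#' @export
setClass("BeeOccFit",
  representation(
    draws = "array",
    data = "BeeOccData",
    config = "list",
    accept = "numeric",
    rhat = "data.frame",
    converged = "logical"
  )
)

setValidity("BeeOccFit", function(object) {
  msg <- character()
  if (length(dim(object@draws)) != 3)
    msg <- c(msg, "draws must be an iterations x parameters x chains array")
  if (any(!is.finite(object@draws)))
    msg <- c(msg, "draws must be finite")
  if (length(msg)) msg else TRUE
})

#' Survey set: visits and detections built from raw occurrence records
#'
#' Intermediate container produced by [buildSurveys()] and consumed by
#' the filtering/aggregation steps. A *visit* (synonym: survey) is a
#' unique combination of calendar date and 1 km grid cell; its species
#' list defines the list-length effort categories used by the detection
#' sub-model.
#'
#' @slot visits data.frame: `visit_id`, `cell1km_id`, `date`, `year`,
#'   `list_length`, `is_short`, `is_long`.
#' @slot detections data.frame: `visit_id`, `species` (one row per
#'   species recorded on the visit).
#' @export
setClass("SurveySet",
  representation(visits = "data.frame", detections = "data.frame")
)

setValidity("SurveySet", function(object) {
  msg <- character()
  if (!all(c("visit_id", "cell1km_id", "year", "list_length",
             "is_short", "is_long") %in% names(object@visits)))
    msg <- c(msg, "visits is missing required columns")
  if (!all(c("visit_id", "species") %in% names(object@detections)))
    msg <- c(msg, "detections needs visit_id and species")
  else if (!all(object@detections$visit_id %in% object@visits$visit_id))
    msg <- c(msg, "detections reference unknown visits")
  if (length(msg)) msg else TRUE
})
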