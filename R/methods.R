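#' @rdname beepersist-accessors
#' @aliases nSpecies,BeeOccData-method
setMethod("nSpecies", "BeeOccData", function(object) nrow(object@species))

#' @rdname beepersist-accessors
setMethod("nSites", "BeeOccData", function(object) length(object@sites))

#' @rdname beepersist-accessors
setMethod("nYears", "BeeOccData", function(object) length(object@years))

#' @rdname beepersist-accessors
setMethod("nVisits", "BeeOccData", function(object) nrow(object@visits))

#' @rdname beepersist-accessors
setMethod("detections", "BeeOccData", function(object) object@y)

#' @rdname beepersist-accessors
setMethod("visitInfo", "BeeOccData", function(object) object@visits)

#' @rdname beepersist-accessors
setMethod("speciesInfo", "BeeOccData", function(object) object@species)

#' @rdname beepersist-accessors
setMethod("siteNames", "BeeOccData", function(object) object@sites)

#' @rdname beepersist-accessors
setMethod("modelYears", "BeeOccData", function(object) object@years)

#' @rdname beepersist-accessors
setMethod("covariatePanel", "BeeOccData", function(object) object@covariates)

#' @rdname beepersist-accessors
setReplaceMethod("covariatePanel", "BeeOccData", function(object, value) {
  need <- c("cell5km_id", "year", "osr", "neonic", "fii",
            "osr_c", "neonic_c", "fii_c")
  if (!all(need %in% names(value)))
    stop("covariate panel is missing columns: ",
         paste(setdiff(need, names(value)), collapse = ", "))
  # transitions into year t use covariates at t-1, so the panel must
  # cover all modelled years except the last
  lagYears <- object@years[-length(object@years)]
  have <- paste(value$cell5km_id, value$year)
  want <- as.vector(outer(object@sites, lagYears, paste))
  missing <- setdiff(want, have)
  if (length(missing))
    stop("covariate panel does not cover ", length(missing),
         " modelled site-years, e.g. ", missing[1])
  object@covariates <- value
  validObject(object)
  object
})

setMethod("show", "BeeOccData", function(object) {
  cat("BeeOccData:", nSpecies(object), "species,",
      nSites(object), "sites (5 km),",
      nYears(object), "years (", min(object@years), "-",
      max(object@years), "),", nVisits(object), "visits\n")
  cat("  detections:", sum(object@y), "   forager species:",
      sum(object@species$osr_forager), "\n")
  ll <- object@visits$is_short + 2L * object@visits$is_long
  cat("  visit lists: ", sum(ll == 0), " single, ",
      sum(object@visits$is_short == 1), " short, ",
      sum(object@visits$is_long == 1), " long\n", sep = "")
  cat("  covariate panel rows:", nrow(object@covariates), "\n")
})

#' @rdname beepersist-accessors
setMethod("nSpecies", "BeeOccFit", function(object) nSpecies(object@data))

#' @rdname beepersist-accessors
setMethod("posteriorDraws", "BeeOccFit", function(object) {
  d <- object@draws
  out <- data.frame(
    chain = rep(seq_len(dim(d)[3]), each = dim(d)[1] * dim(d)[2]),
    draw = rep(rep(seq_len(dim(d)[1]), times = dim(d)[2]), times = dim(d)[3]),
    parameter = rep(rep(dimnames(d)[[2]], each = dim(d)[1]), times = dim(d)[3]),
    value = as.vector(d)
  )
  out
})

#' @rdname beepersist-accessors
setMethod("rhatTable", "BeeOccFit", function(object) object@rhat)

setMethod("show", "BeeOccFit", function(object) {
  d <- object@draws
  cfg <- object@config
  cat("BeeOccFit (", cfg$sampler, " sampler): ",
      dim(d)[3], " chains x ", dim(d)[1], " kept draws x ",
      dim(d)[2], " parameters\n", sep = "")
  cat("  protocol: ", cfg$iterations, " iterations, burn-in ",
      cfg$burnin, ", thinning ", cfg$thin, ", seed ", cfg$seed, "\n", sep = "")
  if (nrow(object@rhat)) {
    cat("  max monitored Rhat: ",
        round(max(object@rhat$rhat), 4),
        if (object@converged) "  (converged)" else "  (NOT converged)",
        "\n", sep = "")
  }
})

setMethod("nVisits", "SurveySet", function(object) nrow(object@visits))

#' @rdname beepersist-accessors
setMethod("visitInfo", "SurveySet", function(object) object@visits)

#' @rdname beepersist-accessors
setMethod("detections", "SurveySet", function(object) object@detections)

setMethod("show", "SurveySet", function(object) {
  v <- object@visits
  cat("SurveySet:", nrow(v), "visits,",
    length(unique(v$cell1km_id)), "1 km cells,",
    length(unique(object@detections$species)), "species,",
    nrow(object@detections), "detections\n")
  cat("  lists: ", sum(v$list_length == 1), " single / ",
      sum(v$is_short), " short / ", sum(v$is_long), " long\n", sep = "")
})
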