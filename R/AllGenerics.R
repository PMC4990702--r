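#' @name beepersist-accessors
#' @title Accessors for BeeOccData and BeeOccFit
#' @description Small accessor generics so downstream code never touches
#'   slots directly.
#' @param object a [BeeOccData-class], [BeeOccFit-class] or
#'   [SurveySet-class] object.
#' @param value replacement value.
#' @return The requested component (see the individual methods).
NULL

#' @rdname beepersist-accessors
#' @export
setGeneric("nSpecies", function(object) standardGeneric("nSpecies"))

#' @rdname beepersist-accessors
#' @export
setGeneric("nSites", function(object) standardGeneric("nSites"))

#' @rdname beepersist-accessors
#' @export
setGeneric("nYears", function(object) standardGeneric("nYears"))

#' @rdname beepersist-accessors
#' @export
setGeneric("nVisits", function(object) standardGeneric("nVisits"))

#' @rdname beepersist-accessors
#' @export
setGeneric("detections", function(object) standardGeneric("detections"))

#' @rdname beepersist-accessors
#' @export
setGeneric("visitInfo", function(object) standardGeneric("visitInfo"))

#' @rdname beepersist-accessors
#' @export
setGeneric("speciesInfo", function(object) standardGeneric("speciesInfo"))

#' @rdname beepersist-accessors
#' @export
setGeneric("siteNames", function(object) standardGeneric("siteNames"))

#' @rdname beepersist-accessors
#' @export
setGeneric("modelYears", function(object) standardGeneric("modelYears"))

#' @rdname beepersist-accessors
#' @export
setGeneric("covariatePanel", function(object) standardGeneric("covariatePanel"))

#' @rdname beepersist-accessors
#' @export
setGeneric("covariatePanel<-",
           function(object, value) standardGeneric("covariatePanel<-"))

#' @rdname beepersist-accessors
#' @export
setGeneric("posteriorDraws", function(object) standardGeneric("posteriorDraws"))

#' @rdname beepersist-accessors
#' @export
setGeneric("rhatTable", function(object) standardGeneric("rhatTable"))
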