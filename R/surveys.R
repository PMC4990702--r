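listCategories <- function(list_length) {
  data.frame(is_short = as.integer(list_length %in% c(2L, 3L)),
             is_long = as.integer(list_length > 3L))
}

#' Build survey visits from raw occurrence records
#'
#' A survey (visit) is a unique combination of calendar date and 1 km
#' grid cell; the species recorded on a visit form its list, whose
#' length drives the effort categories of the detection sub-model:
#' single (1 species), short (2--3) or long (>3). Records with missing
#' dates or missing 1 km cell ids are at coarser spatio-temporal
#' resolution than a survey and are excluded with a message.
#'
#' @param records data.frame with columns `species`, `date` (ISO-8601
#'   string or Date) and `cell1km_id`.
#' @param studyYears optional integer range; records outside it are
#'   excluded (counted as out-of-window, not as coarse-resolution).
#' @return a [SurveySet-class] object.
#' @export
buildSurveys <- function(records, studyYears = NULL) {
  need <- c("species", "date", "cell1km_id")
  if (!all(need %in% names(records)))
    stop("records needs columns: ", paste(need, collapse = ", "))
  dates <- as.Date(records$date)
  coarse <- is.na(dates) | is.na(records$cell1km_id) |
    records$cell1km_id == ""
  if (any(coarse)) {
    message("excluded ", sum(coarse),
            " record(s) at coarser spatio-temporal resolution")
    records <- records[!coarse, , drop = FALSE]
    dates <- dates[!coarse]
  }
  year <- as.integer(format(dates, "%Y"))
  if (!is.null(studyYears)) {
    out <- year < min(studyYears) | year > max(studyYears)
    if (any(out)) {
      message("excluded ", sum(out), " record(s) outside the study window")
      records <- records[!out, , drop = FALSE]
      dates <- dates[!out]
      year <- year[!out]
    }
  }
  key <- paste(records$cell1km_id, as.character(dates), sep = "|")
  det <- unique(data.frame(visit_id = key,
                           species = as.character(records$species),
                           stringsAsFactors = FALSE))
  ll <- table(det$visit_id)
  first <- !duplicated(key)
  visits <- data.frame(visit_id = key[first],
                       cell1km_id = as.character(records$cell1km_id[first]),
                       date = dates[first],
                       year = year[first],
                       stringsAsFactors = FALSE)
  visits$list_length <- as.integer(ll[visits$visit_id])
  visits <- cbind(visits, listCategories(visits$list_length))
  visits <- visits[order(visits$visit_id), , drop = FALSE]
  rownames(visits) <- NULL
  det <- det[order(det$visit_id, det$species), , drop = FALSE]
  rownames(det) <- NULL
  new("SurveySet", visits = visits, detections = det)
}

#' Keep only 1 km cells surveyed in at least `minYears` distinct years
#'
#' @param surveys a [SurveySet-class].
#' @param minYears minimum number of distinct calendar years with at
#'   least one visit (default 2).
#' @return the filtered [SurveySet-class] (possibly empty).
#' @export
filterCells <- function(surveys, minYears = 2) {
  v <- surveys@visits
  nyr <- tapply(v$year, v$cell1km_id, function(y) length(unique(y)))
  keep <- names(nyr)[nyr >= minYears]
  v2 <- v[v$cell1km_id %in% keep, , drop = FALSE]
  d2 <- surveys@detections[surveys@detections$visit_id %in% v2$visit_id, ,
                           drop = FALSE]
  if (nrow(v2) == 0)
    message("no 1 km cells surveyed in >= ", minYears, " years")
  rownames(v2) <- rownames(d2) <- NULL
  new("SurveySet", visits = v2, detections = d2)
}

#' Merge hard-to-separate species into aggregates
#'
#' Member species are renamed to their aggregate id (e.g. the
#' Bombus terrestris/lucorum worker aggregate); duplicate detections of
#' two members on one visit collapse to a single detection and list
#' lengths (and the derived short/long categories) are recomputed.
#'
#' @param surveys a [SurveySet-class].
#' @param aggregates data.frame `species`, `aggregate` mapping member
#'   species to aggregate ids; NULL is the identity.
#' @return the aggregated [SurveySet-class].
#' @export
aggregateSpecies <- function(surveys, aggregates = NULL) {
  if (is.null(aggregates) || nrow(aggregates) == 0) return(surveys)
  if (!all(c("species", "aggregate") %in% names(aggregates)))
    stop("aggregates needs columns species and aggregate")
  if (anyDuplicated(aggregates$species))
    stop("species mapped to more than one aggregate: ",
         paste(unique(aggregates$species[duplicated(aggregates$species)]),
               collapse = ", "))
  det <- surveys@detections
  idx <- match(det$species, aggregates$species)
  det$species <- ifelse(is.na(idx), det$species,
                        as.character(aggregates$aggregate[idx]))
  det <- unique(det)
  v <- surveys@visits
  ll <- table(det$visit_id)
  v$list_length <- as.integer(ll[v$visit_id])
  v[c("is_short", "is_long")] <- listCategories(v$list_length)
  det <- det[order(det$visit_id, det$species), , drop = FALSE]
  rownames(det) <- rownames(v) <- NULL
  new("SurveySet", visits = v, detections = det)
}

#' Species recorded on at least `minSurveys` visits
#'
#' Returns the modelled species set. Species below the threshold stay
#' out of the detection matrix but their records still count toward
#' each visit's list length: list length measures recording effort,
#' not the modelled community, so dropping a species never changes a
#' visit's short/long category.
#'
#' @param surveys a [SurveySet-class] (after aggregation).
#' @param minSurveys minimum number of visits a species must appear on
#'   (default 500).
#' @return character vector of retained species, sorted.
#' @export
filterSpecies <- function(surveys, minSurveys = 500) {
  counts <- table(surveys@detections$species)
  sort(names(counts)[counts >= minSurveys])
}

#' Assemble the detection dataset for the occupancy model
#'
#' Pools visits under their parent 5 km grid cell (the modelling
#' resolution), builds the binary species x visit detection matrix for
#' the retained species, and records the modelled year range. Site
#' years without visits remain in the model; their occupancy states
#' are marginalised/imputed during fitting.
#'
#' @param surveys a [SurveySet-class] after filtering/aggregation.
#' @param species_traits data.frame `species`, `osr_forager` (0/1
#'   oilseed-rape forager flag selecting the group-level prior).
#' @param retained character vector of modelled species, from
#'   [filterSpecies()]; defaults to every species with a trait row
#'   present in the data.
#' @param cell_lookup data.frame `cell1km_id`, `cell5km_id` nesting
#'   each surveyed 1 km cell in its 5 km cell.
#' @param years integer vector of modelled years; defaults to
#'   `min(visit years):max(visit years)`.
#' @param covariates optional covariate panel to attach (see
#'   [buildCovariatePanel()]).
#' @return a [BeeOccData-class] object.
#' @export
assembleDetectionDataset <- function(surveys, species_traits,
                                     retained = NULL, cell_lookup,
                                     years = NULL, covariates = NULL) {
  v <- surveys@visits
  det <- surveys@detections
  if (nrow(v) == 0) stop("no visits to assemble")
  if (!all(c("cell1km_id", "cell5km_id") %in% names(cell_lookup)))
    stop("cell_lookup needs columns cell1km_id and cell5km_id")
  if (is.null(retained))
    retained <- sort(intersect(unique(det$species), species_traits$species))
  noTrait <- setdiff(retained, species_traits$species)
  if (length(noTrait))
    stop("no forager flag for species: ", paste(noTrait, collapse = ", "))
  m5 <- match(v$cell1km_id, cell_lookup$cell1km_id)
  if (anyNA(m5))
    stop("1 km cell(s) missing from cell_lookup: ",
         paste(unique(v$cell1km_id[is.na(m5)]), collapse = ", "))
  v$cell5km_id <- as.character(cell_lookup$cell5km_id[m5])
  if (is.null(years)) years <- seq(min(v$year), max(v$year))
  years <- as.integer(years)
  if (any(v$year < min(years) | v$year > max(years)))
    stop("visits fall outside the modelled years")
  sites <- sort(unique(v$cell5km_id))

  y <- matrix(0L, nrow = length(retained), ncol = nrow(v),
              dimnames = list(retained, v$visit_id))
  keep <- det$species %in% retained
  y[cbind(match(det$species[keep], retained),
          match(det$visit_id[keep], v$visit_id))] <- 1L

  sp <- data.frame(
    species = retained,
    osr_forager = as.integer(
      species_traits$osr_forager[match(retained, species_traits$species)]))
  obj <- new("BeeOccData", y = y, visits = v, species = sp,
             sites = sites, years = years,
             covariates = data.frame())
  if (!is.null(covariates)) covariatePanel(obj) <- covariates
  obj
}

#' One-paragraph summary of a detection dataset assembly
#'
#' @param data a [BeeOccData-class].
#' @return invisibly, a list of the reported counts.
#' @export
surveySummary <- function(data) {
  v <- visitInfo(data)
  res <- list(surveys = nrow(v),
              cells1km = length(unique(v$cell1km_id)),
              sites5km = nSites(data),
              species = nSpecies(data),
              detections = sum(detections(data)),
              singleLists = sum(v$is_short == 0 & v$is_long == 0),
              shortLists = sum(v$is_short),
              longLists = sum(v$is_long))
  message(sprintf(
    "%d surveys in %d 1 km cells (%d 5 km sites); %d species, %d detections; %d/%d/%d single/short/long lists",
    res$surveys, res$cells1km, res$sites5km, res$species, res$detections,
    res$singleLists, res$shortLists, res$longLists))
  invisible(res)
}
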