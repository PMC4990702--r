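mkRecords <- function(...) {
  rows <- list(...)
  data.frame(species = sapply(rows, `[[`, 1),
             date = sapply(rows, `[[`, 2),
             cell1km_id = sapply(rows, `[[`, 3))
}

test_that("a survey is a unique date x 1 km cell with list categories", {
  rec <- mkRecords(list("a", "2001-05-01", "k1"),
                   list("b", "2001-05-01", "k1"),
                   list("c", "2001-05-01", "k1"),
                   list("a", "2001-05-02", "k1"),
                   list("a", "2001-05-03", "k2"),
                   list("b", "2001-05-03", "k2"),
                   list("c", "2001-05-03", "k2"),
                   list("d", "2001-05-03", "k2"),
                   list("e", "2001-05-03", "k2"))
  ss <- buildSurveys(rec)
  v <- visitInfo(ss)
  expect_equal(nrow(v), 3)
  three <- v[v$cell1km_id == "k1" & v$list_length == 3, ]
  expect_equal(c(three$is_short, three$is_long), c(1L, 0L))
  single <- v[v$list_length == 1, ]
  expect_equal(c(single$is_short, single$is_long), c(0L, 0L))
  five <- v[v$list_length == 5, ]
  expect_equal(c(five$is_short, five$is_long), c(0L, 1L))
  # every visit is exactly one of single/short/long
  expect_true(all(v$is_short + v$is_long <= 1))
})

test_that("coarse-resolution records are excluded with a message", {
  rec <- mkRecords(list("a", "2001-05-01", "k1"),
                   list("b", NA, "k1"),
                   list("c", "2001-05-01", ""))
  expect_message(ss <- buildSurveys(rec), "2 record")
  expect_equal(nrow(visitInfo(ss)), 1)
  expect_equal(visitInfo(ss)$list_length, 1L)
})

test_that("duplicate records of one species on one visit collapse", {
  rec <- mkRecords(list("a", "2001-05-01", "k1"),
                   list("a", "2001-05-01", "k1"))
  ss <- buildSurveys(rec)
  expect_equal(visitInfo(ss)$list_length, 1L)
  expect_equal(nrow(detections(ss)), 1)
})

test_that("cells need surveys in >= 2 distinct years", {
  rec <- mkRecords(list("a", "1997-05-01", "k1"),
                   list("a", "2003-06-01", "k1"),
                   list("a", "1997-05-01", "k2"),
                   list("b", "1997-08-01", "k2"))
  ss <- filterCells(buildSurveys(rec))
  expect_setequal(unique(visitInfo(ss)$cell1km_id), "k1")
  # two visits in one year are not enough
  expect_equal(nrow(visitInfo(filterCells(buildSurveys(
    mkRecords(list("a", "1997-05-01", "k2"),
              list("b", "1997-08-01", "k2")))))), 0)
  # raising minYears never enlarges the retained set
  ss1 <- filterCells(buildSurveys(rec), minYears = 1)
  expect_true(all(visitInfo(ss)$visit_id %in% visitInfo(ss1)$visit_id))
})

test_that("species aggregation collapses members and recomputes lists", {
  rec <- mkRecords(list("terrestris", "2001-05-01", "k1"),
                   list("lucorum", "2001-05-01", "k1"),
                   list("other", "2001-05-01", "k1"),
                   list("lucorum", "2001-05-02", "k1"))
  agg <- data.frame(species = c("terrestris", "lucorum"),
                    aggregate = "terrestris_agg")
  ss <- aggregateSpecies(buildSurveys(rec), agg)
  v <- visitInfo(ss)
  # both members on one visit collapse: length 3 -> 2
  expect_equal(sort(v$list_length), c(1L, 2L))
  expect_true("terrestris_agg" %in% detections(ss)$species)
  expect_false("lucorum" %in% detections(ss)$species)
  # a member alone is renamed, length unchanged
  expect_equal(v$list_length[v$date == as.Date("2001-05-02")], 1L)
  # no aggregates configured is the identity
  ss0 <- buildSurveys(rec)
  expect_equal(visitInfo(aggregateSpecies(ss0, NULL)), visitInfo(ss0))
  expect_error(aggregateSpecies(ss0, data.frame(
    species = c("lucorum", "lucorum"), aggregate = c("x", "y"))),
    "more than one")
})

test_that("the survey-count filter keeps species at the threshold", {
  recs <- do.call(mkRecords, c(
    lapply(1:5, function(i) list("common", sprintf("2001-05-%02d", i),
                                 "k1")),
    lapply(1:4, function(i) list("rare", sprintf("2001-06-%02d", i),
                                 "k1"))))
  ss <- buildSurveys(recs)
  expect_setequal(filterSpecies(ss, minSurveys = 5), "common")
  expect_setequal(filterSpecies(ss, minSurveys = 4), c("common", "rare"))
  # monotone: raising the threshold never adds species
  expect_true(all(filterSpecies(ss, 5) %in% filterSpecies(ss, 4)))
})

test_that("dropping a species does not change any list category", {
  st <- tinyStudy(seed = 9)
  ss <- buildSurveys(st$sim$tables$records)
  before <- visitInfo(ss)[, c("visit_id", "is_short", "is_long")]
  # assemble with a harsh threshold: many species drop out of y, but
  # the visits' effort categories are untouched
  dat <- assembleDetectionDataset(ss, st$sim$tables$species_traits,
    retained = filterSpecies(ss, minSurveys = 60),
    cell_lookup = st$sim$tables$cell_lookup,
    years = 1994:2011)
  after <- visitInfo(dat)[, c("visit_id", "is_short", "is_long")]
  expect_equal(before[order(before$visit_id), ],
               after[order(after$visit_id), ])
})

test_that("assembly pools 1 km cells under 5 km sites and keeps counts", {
  rec <- mkRecords(list("a", "2001-05-01", "S001_01"),
                   list("a", "2002-05-01", "S001_02"),
                   list("b", "2001-05-01", "S001_01"),
                   list("b", "2002-07-01", "S001_02"))
  lookup <- data.frame(cell1km_id = c("S001_01", "S001_02"),
                       cell5km_id = "S001")
  traits <- data.frame(species = c("a", "b"), osr_forager = c(1L, 0L))
  dat <- assembleDetectionDataset(buildSurveys(rec), traits,
                                  cell_lookup = lookup,
                                  years = 2000:2003)
  expect_equal(nSites(dat), 1)
  expect_equal(nVisits(dat), 3)
  # conservation: y row sums equal per-species detection counts
  expect_equal(unname(rowSums(detections(dat))), c(2, 2))
  expect_error(assembleDetectionDataset(buildSurveys(rec),
    data.frame(species = "a", osr_forager = 1L),
    retained = c("a", "b"), cell_lookup = lookup), "forager flag")
  expect_error(assembleDetectionDataset(buildSurveys(rec), traits,
    cell_lookup = lookup[1, , drop = FALSE]), "S001_02")
})
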