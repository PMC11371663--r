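# Occurrence ingest, quality filters, and downscaling to grid cells.

make_csv <- function(df) {
  p <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(df, p, row.names = FALSE)
  p
}

test_that("GBIF-dialect files parse and unparseable coordinates are counted", {
  df <- data.frame(genus = c("A", "A", "B"),
                   decimalLongitude = c("100.1", "100.2", "abc"),
                   decimalLatitude = c("-0.1", "-0.2", "-0.3"),
                   coordinateUncertaintyInMeters = c(100, NA, 50),
                   basisOfRecord = "PRESERVED_SPECIMEN")
  p <- make_csv(df)
  rec <- read_occurrences(p)
  expect_equal(nrow(rec), 2)
  expect_equal(unname(attr(rec, "drop_counts")["bad_coordinates"]), 1)
  expect_equal(names(rec), c("taxon", "lon", "lat", "uncertainty", "basis"))

  expect_error(read_occurrences(p, column_map = c(gbif_column_map(),
                                                  taxon = "nope")[-1]),
               "mandatory")
})

test_that("coordinates outside valid ranges are treated as unparseable", {
  df <- data.frame(genus = "A", decimalLongitude = c(100, 190),
                   decimalLatitude = c(-95, -10),
                   coordinateUncertaintyInMeters = 1,
                   basisOfRecord = "LIVING_SPECIMEN")
  rec <- as_occurrence_records(df)
  expect_equal(nrow(rec), 0)
  expect_equal(unname(attr(rec, "drop_counts")["bad_coordinates"]), 2)
})

test_that("the uncertainty threshold is strict and fossils are excluded", {
  rec <- data.frame(taxon = "A",
                    lon = 100.1, lat = -0.1,
                    uncertainty = c(2250, 2249.99, 0, NA, 100),
                    basis = c(rep("PRESERVED_SPECIMEN", 4),
                              "FOSSIL_SPECIMEN"),
                    stringsAsFactors = FALSE)
  out <- filter_records(rec, max_uncertainty_m = 2250)
  # 2250 m at a 2250 m threshold is excluded (strict "<"); 0 m retained
  expect_equal(out$uncertainty, c(2249.99, 0))
  dc <- attr(out, "drop_counts")
  expect_equal(unname(dc["basis"]), 1)
  expect_equal(unname(dc["missing_uncertainty"]), 1)
  expect_equal(unname(dc["uncertainty"]), 1)
  expect_equal(nrow(out) + sum(dc), nrow(rec))

  kept <- filter_records(rec, 2250, missing_uncertainty = "keep")
  expect_true(any(is.na(kept$uncertainty)))
  expect_equal(nrow(kept), 3)

  expect_error(filter_records(rec, -5), "positive")
})

test_that("cell assignment follows the half-open edge rule", {
  grid <- toy_grid()  # west 100, north 0, cell 0.25
  bg <- apply_background_mask(grid, rep(TRUE, 16))
  base <- data.frame(taxon = "A", uncertainty = 1, basis = "x",
                     stringsAsFactors = FALSE)
  # western edge of cell (1,2) at lon 100.25 -> that cell;
  # eastern edge of cell (1,1) is the same lon -> also cell (1,2)
  r <- cbind(base, lon = 100.25, lat = -0.1)
  expect_equal(assign_to_cells(r, grid, bg)$cells, 2L)
  # interior of cell (1,1)
  r2 <- cbind(base, lon = 100.2, lat = -0.1)
  expect_equal(assign_to_cells(r2, grid, bg)$cells, 1L)
  # latitude on the boundary between rows 1 and 2 belongs to row 2
  r3 <- cbind(base, lon = 100.1, lat = -0.25)
  expect_equal(assign_to_cells(r3, grid, bg)$cells, 5L)
  # the grid's northern edge belongs to row 1
  r4 <- cbind(base, lon = 100.1, lat = 0)
  expect_equal(assign_to_cells(r4, grid, bg)$cells, 1L)
})

test_that("downscaling collapses duplicates and drops off-grid records", {
  grid <- toy_grid(nodata_cells = 6)
  bg <- apply_background_mask(grid, rep(TRUE, 16))
  rec <- data.frame(
    taxon = "A",
    lon = c(100.1, 100.12, 100.18,  # three records in cell 1
            100.3,                  # nodata cell 6? (row1 col2 = cell 2)
            100.26, 99.0),          # cell 2; off grid
    lat = c(-0.1, -0.1, -0.1, -0.3, -0.1, -0.1),
    uncertainty = 1, basis = "x", stringsAsFactors = FALSE)
  co <- assign_to_cells(rec, grid, bg)
  # cell 6 (row 2, col 2) is nodata: the record at (100.3, -0.3) drops
  expect_equal(co$cells, c(1L, 2L))
  expect_equal(unname(co$drop_counts["outside_grid"]), 1)
  expect_equal(unname(co$drop_counts["invalid_cell"]), 1)
  expect_equal(co$n_retained + sum(co$drop_counts), nrow(rec))

  # row order does not matter
  co2 <- assign_to_cells(rec[sample(nrow(rec)), ], grid, bg)
  expect_identical(co2$cells, co$cells)

  expect_error(assign_to_cells(transform(rec, taxon = c("A", "B")[c(1, 1, 1, 1, 1, 2)]),
                               grid, bg),
               "single taxon")
})

test_that("records on non-background cells are dropped and counted", {
  grid <- toy_grid()
  mask <- rep(TRUE, 16)
  mask[1] <- FALSE
  bg <- apply_background_mask(grid, mask)
  rec <- data.frame(taxon = "A", lon = c(100.1, 100.3),
                    lat = -0.1, uncertainty = 1, basis = "x",
                    stringsAsFactors = FALSE)
  co <- assign_to_cells(rec, grid, bg)
  expect_equal(co$cells, 2L)
  expect_equal(unname(co$drop_counts["not_background"]), 1)
})
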