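# Synthetic landscape and occurrence generators: determinism, known
# structure, and the Gaussian niche sampling contract.

test_that("landscape generation is deterministic and spec-validated", {
  spec <- landscape_spec(n_rows = 12, n_cols = 12, n_vars = 5, seed = 3)
  l1 <- generate_climate_landscape(spec)
  l2 <- generate_climate_landscape(spec)
  expect_identical(l1$grid$values, l2$grid$values)
  expect_identical(l1$mask, l2$mask)

  expect_error(landscape_spec(n_rows = 2), "n_rows")
  expect_error(landscape_spec(latent_dim = 5, n_vars = 3), "latent_dim")
  expect_error(landscape_spec(noise_sd = -1))
  expect_error(landscape_spec(n_vars = 3, latent_dim = 1,
                              mixing = matrix(0, 3, 1)),
               "degenerate mixing")
})

test_that("rank-1 noiseless landscape yields identical variables", {
  l <- generate_climate_landscape(
    landscape_spec(n_rows = 10, n_cols = 10, n_vars = 4, latent_dim = 1,
                   mixing = matrix(1, 4, 1), noise_sd = 0, seed = 1))
  cors <- stats::cor(l$grid$values)
  expect_true(all(abs(cors - 1) < 1e-12))
})

test_that("two latent factors dominate the variable correlation structure", {
  l <- generate_climate_landscape(
    landscape_spec(latent_dim = 2, n_vars = 19, noise_sd = 0.1, seed = 1))
  ev <- eigen(stats::cor(l$grid$values), symmetric = TRUE,
              only.values = TRUE)$values
  expect_gte(sum(ev[1:2]) / sum(ev), 0.95)
})

test_that("background mask matches the configured quantile band", {
  l <- generate_climate_landscape(
    landscape_spec(n_rows = 20, n_cols = 40, mask_band = 0.7, seed = 2))
  frac <- mean(l$mask)
  # band on a discrete column gradient: allow one column row of slack
  expect_lt(abs(frac - 0.7), 1 / 40 + 0.03)
})

test_that("occurrence sampling is deterministic and niche-shaped", {
  land <- fixture_landscape()
  sp <- niche_spec("T", c(0, 0), 0.5, 200, seed = 11)
  o1 <- sample_occurrences(land, sp)
  o2 <- sample_occurrences(land, sp)
  expect_identical(o1, o2)
  expect_equal(nrow(o1), 200)
  expect_true(all(c("genus", "decimalLongitude", "decimalLatitude",
                    "coordinateUncertaintyInMeters", "basisOfRecord")
                  %in% names(o1)))
})

test_that("very broad niches sample the background uniformly", {
  land <- generate_climate_landscape(
    landscape_spec(n_rows = 20, n_cols = 20, seed = 7))
  bg <- which(land$mask & land$grid$valid)
  sp <- niche_spec("T", c(0, 0), 1e6, 10000, seed = 21)
  occ <- sample_occurrences(land, sp)
  cells <- nichelegacy:::locate_cells(land$grid, occ$decimalLongitude, occ$decimalLatitude)
  counts <- table(factor(cells, levels = bg))
  expect_gt(stats::chisq.test(as.numeric(counts))$p.value, 0.01)
})

test_that("a point-mass niche concentrates all records in one cell", {
  land <- fixture_landscape()
  bg <- which(land$mask & land$grid$valid)
  target <- bg[17]
  sp <- niche_spec("T", land$latent[target, ], 1e-4, 50, seed = 5)
  occ <- sample_occurrences(land, sp)
  cells <- nichelegacy:::locate_cells(land$grid, occ$decimalLongitude, occ$decimalLatitude)
  expect_true(all(cells == target))
})

test_that("a centroid far outside the landscape is an explicit error", {
  land <- fixture_landscape()
  sp <- niche_spec("T", c(1e4, 1e4), 0.5, 10, seed = 1)
  expect_error(sample_occurrences(land, sp),
               "selection probabilities are zero")
})

test_that("pair scenario presets build the stated niche geometry", {
  expect_error(make_pair_scenario("bogus"), "arg")
  sc_id <- make_pair_scenario("identical", n_per_species = 20, seed = 9)
  expect_identical(sc_id$niche_a$centroid, sc_id$niche_b$centroid)
  expect_identical(sc_id$niche_a$breadth, sc_id$niche_b$breadth)

  sc_sh <- make_pair_scenario("shifted", separation = 2, n_per_species = 20,
                              seed = 9, landscape = sc_id$landscape)
  sep <- sqrt(sum((sc_sh$niche_a$centroid - sc_sh$niche_b$centroid)^2))
  expect_equal(sep, 2)

  sc_ne <- make_pair_scenario("nested", n_per_species = 20, seed = 9,
                              landscape = sc_id$landscape, breadth = 0.4,
                              nested_ratio = 2)
  expect_identical(sc_ne$niche_a$centroid, sc_ne$niche_b$centroid)
  expect_equal(sc_ne$niche_b$breadth / sc_ne$niche_a$breadth, 2)
})

test_that("landscapes round-trip through the raster ingest path", {
  land <- generate_climate_landscape(
    landscape_spec(n_rows = 8, n_cols = 10, n_vars = 3, seed = 13))
  dir <- withr::local_tempdir()
  paths <- write_landscape(land, dir)
  grid2 <- read_climate_grid(paths$variables)
  expect_equal(colnames(grid2$values), colnames(land$grid$values))
  expect_equal(grid2$values, land$grid$values, tolerance = 1e-8)
  bg2 <- apply_background_mask(grid2, paths$mask)
  expect_identical(bg2$cells, which(land$mask & land$grid$valid))
})
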