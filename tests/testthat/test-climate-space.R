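# Raster ingest, background masking, and the environmental PCA.

write_toy_raster <- function(m, path, west = 100, south = -1,
                             cell_size = 0.25) {
  write_ascii_grid(m, path, west = west, south = south,
                   cell_size = cell_size)
}

test_that("ESRI ASCII grids round-trip including nodata", {
  m <- matrix(c(1.5, NA, 3, 4, 5, 6), 2, 3)
  p <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(m, p, west = 10, south = 20, cell_size = 0.5)
  g <- read_ascii_grid(p)
  expect_equal(g$values, m)
  expect_equal(g$west, 10)
  expect_equal(g$south, 20)
  expect_equal(g$cell_size, 0.5)
})

test_that("aligned rasters assemble; mismatched geometry is an error", {
  dir <- withr::local_tempdir()
  m <- matrix(1:12, 3, 4)
  paths <- file.path(dir, paste0("bio", 1:3, ".asc"))
  for (p in paths) write_toy_raster(m, p)
  grid <- read_climate_grid(paths)
  expect_equal(ncol(grid$values), 3)
  expect_equal(colnames(grid$values), paste0("bio", 1:3))
  expect_equal(grid$n_rows, 3)
  expect_equal(grid$n_cols, 4)

  shifted <- file.path(dir, "bio_shift.asc")
  write_toy_raster(m, shifted, west = 100.125)  # half a cell off
  expect_error(read_climate_grid(c(paths[1], shifted)),
               "geometry mismatch")
  expect_error(read_climate_grid(paths, var_names = c("a", "a", "b")),
               "duplicate")
})

test_that("nodata cells invalidate all variables at that cell", {
  dir <- withr::local_tempdir()
  m1 <- matrix(as.numeric(1:16), 4, 4)
  m2 <- m1 + 100
  m2[c(1, 6, 16)] <- NA  # three nodata cells in one layer
  p1 <- file.path(dir, "a.asc")
  p2 <- file.path(dir, "b.asc")
  write_toy_raster(m1, p1)
  write_toy_raster(m2, p2)
  grid <- read_climate_grid(c(p1, p2))
  expect_equal(sum(!grid$valid), 3)
})

test_that("background masking counts cells and rejects empty backgrounds", {
  grid <- toy_grid()
  all_bg <- apply_background_mask(grid, rep(TRUE, 16))
  expect_equal(length(all_bg$cells), 16)

  checker <- matrix(rep(c(TRUE, FALSE), 8), 4, 4)
  bg <- apply_background_mask(grid, checker)
  expect_equal(length(bg$cells), 8)

  expect_error(apply_background_mask(grid, rep(FALSE, 16)), "empty")
  expect_error(apply_background_mask(grid, matrix(TRUE, 3, 3)),
               "geometry")
})

test_that("PCA handles rank-1 tables and the hand-worked 4-cell table", {
  x <- withr::with_seed(1, {
    a <- rnorm(100)
    cbind(v1 = a, v2 = 2 * a + 3)  # perfectly correlated
  })
  sp <- fit_environmental_pca(x)
  expect_equal(sp$var_fraction[[1]], 1.0)

  hand <- cbind(v1 = c(1, 1, -1, -1), v2 = c(1, -1, 1, -1))
  sp2 <- fit_environmental_pca(hand)
  expect_equal(unname(sp2$var_fraction), c(0.5, 0.5))
})

test_that("zero-variance variables are dropped with a warning", {
  x <- withr::with_seed(2, cbind(v1 = rnorm(50), v2 = rnorm(50),
                                 flat = rep(3, 50)))
  expect_warning(sp <- fit_environmental_pca(x), "zero-variance")
  expect_equal(length(sp$center), 2)
  expect_error(suppressWarnings(
    fit_environmental_pca(cbind(v1 = rnorm(50), flat = rep(1, 50)))),
    "informative")
})

test_that("projection is centred, variance-preserving, and affine", {
  fx <- fixture_space()
  sp <- fx$space
  bg_vals <- fx$background$values

  centre_score <- predict(sp, t(as.matrix(colMeans(bg_vals))))
  expect_equal(unname(centre_score[1, 1:2]), c(0, 0), tolerance = 1e-10)

  sc <- predict(sp, bg_vals)
  expect_equal(unname(apply(sc, 2, stats::var)), unname(sp$sdev^2),
               tolerance = 1e-10)
  expect_equal(unname(sc), unname(sp$scores), tolerance = 1e-10)

  x <- bg_vals[1, , drop = FALSE]
  y <- bg_vals[2, , drop = FALSE]
  a <- 0.3
  mix <- predict(sp, a * x + (1 - a) * y)
  expect_equal(mix, a * predict(sp, x) + (1 - a) * predict(sp, y),
               tolerance = 1e-10)
})

test_that("scores and loadings reconstruct the climate table", {
  fx <- fixture_space()
  sp <- fx$space
  bg_vals <- fx$background$values
  rec <- sp$scores %*% t(sp$loadings)
  rec <- sweep(rec, 2, sp$scale, "*")
  rec <- sweep(rec, 2, sp$center, "+")
  expect_equal(unname(rec), unname(bg_vals[, names(sp$center)]),
               tolerance = 1e-8)
})

test_that("variance fractions are sorted and sum to one; signs deterministic", {
  fx <- fixture_space()
  sp <- fx$space
  expect_equal(sum(sp$var_fraction), 1)
  expect_true(all(diff(sp$var_fraction) <= 1e-12))
  expect_true(all(crossprod(sp$loadings) - diag(ncol(sp$loadings)) < 1e-8))
  # refit on row-permuted cells: same axes, same signs
  perm <- withr::with_seed(4, sample(nrow(fx$background$values)))
  sp2 <- fit_environmental_pca(fx$background$values[perm, ])
  expect_equal(sp2$loadings, sp$loadings, tolerance = 1e-8)

  expect_error(predict(sp, fx$background$values[, -1]), "lacks retained")
})
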