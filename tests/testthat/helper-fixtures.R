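# Shared fixtures, built in code once per test run.

# Small synthetic landscape reused by most downstream tests.
fixture_landscape <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_climate_landscape(
        landscape_spec(n_rows = 30, n_cols = 30, seed = 101))
    }
    cache
  }
})

# Background + fitted PCA for the fixture landscape.
fixture_space <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      land <- fixture_landscape()
      bg <- apply_background_mask(land$grid, land$mask)
      cache <<- list(landscape = land, background = bg,
                     space = fit_environmental_pca(bg))
    }
    cache
  }
})

# A toy 4x4 climate grid with two variables and explicit geometry, handy
# for edge-rule and masking tests. cell_size chosen binary-exact.
toy_grid <- function(n_rows = 4, n_cols = 4, nodata_cells = integer(0)) {
  n <- n_rows * n_cols
  vals <- cbind(bio1 = as.numeric(seq_len(n)),
                bio12 = rev(as.numeric(seq_len(n))))
  vals[nodata_cells, ] <- NA_real_
  climate_grid(vals, west = 100, north = 0, cell_size = 0.25,
               n_rows = n_rows, n_cols = n_cols)
}

# Random normalized occupancy matrix.
random_mass <- function(R, seed = NULL) {
  m <- matrix(stats::runif(R * R), R, R)
  m / sum(m)
}

# Unit mass placed in one cell of an R x R grid.
point_mass <- function(R, row, col) {
  m <- matrix(0, R, R)
  m[row, col] <- 1
  m
}

# Availability density over a roughly uniform square score cloud.
uniform_availability <- function(n = 800, R = 60, seed = 5) {
  withr::with_seed(seed, {
    sc <- cbind(runif(n), runif(n))
    build_availability_density(sc, R = R)
  })
}
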