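# Synthetic climate landscapes and occurrence sets with known niche
# structure, so every downstream stage is testable without external
# downloads.
#
# Each climate variable is a linear mix of smooth latent spatial factors
# (an east-west gradient, a north-south gradient, and optionally smoothed
# noise fields) plus independent per-variable noise. This reproduces the
# two-axis "temperature versus seasonality/precipitation" structure that an
# environmental PCA recovers from real bioclim grids. The background mask is
# a central quantile band on the first latent factor, mimicking the
# exclusion of an arid interior without implementing a climate
# classification.

#' Specify a synthetic climate landscape
#'
#' @param n_rows,n_cols Lattice dimensions (>= 4).
#' @param cell_size Cell width in degrees; the default 1/24 deg emulates a
#'   2.5 arc-min climate grid.
#' @param n_vars Number of climate variables (default 19, bio1..bio19
#'   naming).
#' @param latent_dim Number of latent spatial factors (>= 1, <= n_vars).
#' @param mixing Optional latent-to-variable loading matrix
#'   (n_vars x latent_dim); by default drawn once from the spec seed with
#'   magnitudes in [0.3, 1].
#' @param noise_sd Per-variable independent noise standard deviation.
#' @param mask_band Central quantile width of the factor-1 band flagged as
#'   background (default 0.70).
#' @param west,north Geographic origin of the lattice, degrees.
#' @param seed RNG seed.
#' @return An object of class `landscape_spec`.
#' @export
landscape_spec <- function(n_rows = 40, n_cols = 40, cell_size = 1 / 24,
                           n_vars = 19, latent_dim = 2, mixing = NULL,
                           noise_sd = 0.1, mask_band = 0.70,
                           west = 140, north = -20, seed = 1) {
  stopifnot(is_count(n_rows, 4), is_count(n_cols, 4),
            is_count(n_vars, 1), is_count(latent_dim, 1),
            latent_dim <= n_vars, is_number(noise_sd), noise_sd >= 0,
            is_number(mask_band), mask_band > 0, mask_band <= 1)
  if (!is.null(mixing)) {
    mixing <- as.matrix(mixing)
    if (nrow(mixing) != n_vars || ncol(mixing) != latent_dim) {
      stop("mixing must be an n_vars x latent_dim matrix")
    }
    if (all(mixing == 0)) stop("degenerate mixing: all-zero matrix")
  }
  structure(list(n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
                 n_vars = n_vars, latent_dim = latent_dim, mixing = mixing,
                 noise_sd = noise_sd, mask_band = mask_band,
                 west = west, north = north, seed = as.integer(seed)),
            class = "landscape_spec")
}

# 3x3 moving-average smoothing with edge replication; used for the optional
# low-frequency latent noise fields.
smooth_field <- function(m, passes = 4) {
  for (p in seq_len(passes)) {
    pad <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
    pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, ncol(pad), drop = FALSE])
    i <- 2:(nrow(pad) - 1)
    j <- 2:(ncol(pad) - 1)
    m <- (pad[i - 1, j - 1] + pad[i - 1, j] + pad[i - 1, j + 1] +
          pad[i, j - 1] + pad[i, j] + pad[i, j + 1] +
          pad[i + 1, j - 1] + pad[i + 1, j] + pad[i + 1, j + 1]) / 9
  }
  m
}

#' Generate a synthetic climate landscape
#'
#' Deterministic given the spec seed. Factor 1 is a standardized east-west
#' gradient, factor 2 a north-south gradient; any further factors are
#' smoothed Gaussian noise fields. The background mask flags cells whose
#' factor-1 value lies inside the central `mask_band` quantile band.
#'
#' @param spec A `landscape_spec`.
#' @return An object of class `synthetic_landscape`: a list with `grid`
#'   (a [climate_grid()]), `mask` (logical per cell), `latent` (cell x
#'   factor matrix) and `spec`.
#' @export
generate_climate_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  n <- spec$n_rows * spec$n_cols
  with_seed(spec$seed, {
    rc <- cbind(row = rep(seq_len(spec$n_rows), each = spec$n_cols),
                col = rep(seq_len(spec$n_cols), times = spec$n_rows))
    latent <- matrix(0, n, spec$latent_dim)
    latent[, 1] <- as.vector(scale(rc[, "col"]))
    if (spec$latent_dim >= 2) latent[, 2] <- as.vector(scale(rc[, "row"]))
    if (spec$latent_dim >= 3) {
      for (k in 3:spec$latent_dim) {
        f <- smooth_field(matrix(stats::rnorm(n), spec$n_rows, spec$n_cols))
        latent[, k] <- as.vector(scale(as.vector(t(f))))
      }
    }
    mixing <- spec$mixing
    if (is.null(mixing)) {
      mixing <- matrix(stats::runif(spec$n_vars * spec$latent_dim, 0.3, 1) *
                         sample(c(-1, 1), spec$n_vars * spec$latent_dim,
                                replace = TRUE),
                       spec$n_vars, spec$latent_dim)
    }
    if (all(mixing == 0)) stop("degenerate mixing: all-zero matrix")
    vals <- latent %*% t(mixing)
    if (spec$noise_sd > 0) {
      vals <- vals + matrix(stats::rnorm(n * spec$n_vars, sd = spec$noise_sd),
                            n, spec$n_vars)
    }
    colnames(vals) <- paste0("bio", seq_len(spec$n_vars))
    grid <- climate_grid(vals, west = spec$west, north = spec$north,
                         cell_size = spec$cell_size,
                         n_rows = spec$n_rows, n_cols = spec$n_cols)
    lo <- (1 - spec$mask_band) / 2
    qs <- stats::quantile(latent[, 1], c(lo, 1 - lo), names = FALSE)
    mask <- latent[, 1] >= qs[1] & latent[, 1] <= qs[2]
    structure(list(grid = grid, mask = mask, latent = latent, spec = spec),
              class = "synthetic_landscape")
  })
}

#' Specify a synthetic taxon niche
#'
#' The niche is a Gaussian preference surface in latent climate-factor
#' space: a cell is selected with probability proportional to
#' `exp(-0.5 * (x - centroid)' Sigma^-1 (x - centroid))` where `x` is the
#' cell's latent-factor value.
#'
#' @param taxon Taxon label written into the occurrence records.
#' @param centroid Niche centre in latent-factor space.
#' @param breadth Per-factor standard deviations (recycled), or a full
#'   covariance matrix.
#' @param n_records Number of occurrence records to draw (>= 1).
#' @param p_missing_uncertainty Fraction of records whose coordinate
#'   uncertainty is missing (exercises the filter's missing-value policy).
#' @param uncertainty_meanlog,uncertainty_sdlog Log-normal parameters of
#'   the coordinate-uncertainty draw, metres (default median 500 m).
#' @param basis Record basis string stamped on the records.
#' @param seed RNG seed.
#' @return An object of class `niche_spec`.
#' @export
niche_spec <- function(taxon, centroid, breadth, n_records,
                       p_missing_uncertainty = 0.1,
                       uncertainty_meanlog = log(500),
                       uncertainty_sdlog = 0.75,
                       basis = "PRESERVED_SPECIMEN", seed = 1) {
  centroid <- as.numeric(centroid)
  if (is.matrix(breadth)) {
    if (any(diag(breadth) <= 0)) stop("breadth covariance must be positive")
  } else {
    breadth <- as.numeric(breadth)
    if (any(breadth <= 0)) stop("breadth entries must be positive")
  }
  stopifnot(is_count(n_records, 1),
            p_missing_uncertainty >= 0, p_missing_uncertainty <= 1)
  structure(list(taxon = taxon, centroid = centroid, breadth = breadth,
                 n_records = as.integer(n_records),
                 p_missing_uncertainty = p_missing_uncertainty,
                 uncertainty_meanlog = uncertainty_meanlog,
                 uncertainty_sdlog = uncertainty_sdlog,
                 basis = basis, seed = as.integer(seed)),
            class = "niche_spec")
}

#' Sample occurrence records from a known niche
#'
#' Background cells are drawn with Gaussian niche weights evaluated at the
#' cells' latent-factor values; record coordinates are jittered uniformly
#' within the selected cell. Deterministic given the niche seed.
#'
#' @param landscape A `synthetic_landscape`.
#' @param niche A `niche_spec`.
#' @return Data frame in GBIF-style columns (`genus`, `species`,
#'   `decimalLongitude`, `decimalLatitude`,
#'   `coordinateUncertaintyInMeters`, `basisOfRecord`).
#' @export
sample_occurrences <- function(landscape, niche) {
  stopifnot(inherits(landscape, "synthetic_landscape"),
            inherits(niche, "niche_spec"))
  bg_cells <- which(landscape$mask & landscape$grid$valid)
  if (length(bg_cells) < 1) stop("landscape has no background cells")
  x <- landscape$latent[bg_cells, , drop = FALSE]
  d <- length(niche$centroid)
  if (d != ncol(x)) stop("niche centroid dimension must match latent_dim")
  sigma <- if (is.matrix(niche$breadth)) niche$breadth
           else diag(rep(niche$breadth, length.out = d)^2, d)
  md <- stats::mahalanobis(x, niche$centroid, sigma)
  w <- exp(-0.5 * md)
  if (all(w == 0)) {
    stop("all selection probabilities are zero: niche centroid lies far ",
         "outside the landscape's climate space")
  }
  with_seed(niche$seed, {
    cells <- sample(bg_cells, niche$n_records, replace = TRUE, prob = w)
    ctr <- cell_centers(landscape$grid, cells)
    half <- landscape$grid$cell_size / 2
    n <- niche$n_records
    lon <- ctr[, "lon"] + stats::runif(n, -half, half)
    lat <- ctr[, "lat"] + stats::runif(n, -half, half)
    unc <- stats::rlnorm(n, niche$uncertainty_meanlog, niche$uncertainty_sdlog)
    unc[stats::runif(n) < niche$p_missing_uncertainty] <- NA_real_
    data.frame(genus = niche$taxon,
               species = paste0(niche$taxon, " sp."),
               decimalLongitude = lon, decimalLatitude = lat,
               coordinateUncertaintyInMeters = unc,
               basisOfRecord = niche$basis,
               stringsAsFactors = FALSE)
  })
}

#' Build a paired-taxon test scenario
#'
#' Presets: `"identical"` gives both taxa the same niche; `"shifted"`
#' separates the centroids by `separation` along the last latent factor
#' (the factor not truncated by the background band); `"nested"` keeps a
#' common centroid but scales one taxon's breadth by `nested_ratio`.
#'
#' @param preset One of `"identical"`, `"shifted"`, `"nested"`.
#' @param separation Centroid separation in latent-factor units (shifted
#'   preset).
#' @param n_per_species Records drawn per taxon.
#' @param seed Master seed for the scenario.
#' @param landscape Optional pre-built `synthetic_landscape` to reuse.
#' @param breadth Baseline niche breadth (latent-factor standard
#'   deviations).
#' @param nested_ratio Breadth ratio of the wider taxon (nested preset).
#' @return List with `landscape`, `occurrences_a`, `occurrences_b`, and the
#'   two `niche_spec`s.
#' @export
make_pair_scenario <- function(preset = c("identical", "shifted", "nested"),
                               separation = 1, n_per_species = 500, seed = 1,
                               landscape = NULL, breadth = 0.5,
                               nested_ratio = 2) {
  preset <- match.arg(preset)
  if (is.null(landscape)) {
    landscape <- generate_climate_landscape(
      landscape_spec(seed = derive_seed(seed, "landscape")))
  }
  bg <- which(landscape$mask & landscape$grid$valid)
  base <- colMeans(landscape$latent[bg, , drop = FALSE])
  d <- length(base)
  ax <- d  # separation axis: last latent factor
  c_a <- c_b <- base
  b_a <- b_b <- breadth
  if (preset == "shifted") {
    c_a[ax] <- base[ax] - separation / 2
    c_b[ax] <- base[ax] + separation / 2
  } else if (preset == "nested") {
    b_b <- breadth * nested_ratio
  }
  sp_a <- niche_spec("TaxonA", c_a, b_a, n_per_species,
                     seed = derive_seed(seed, "taxon_a"))
  sp_b <- niche_spec("TaxonB", c_b, b_b, n_per_species,
                     seed = derive_seed(seed, "taxon_b"))
  list(landscape = landscape,
       occurrences_a = sample_occurrences(landscape, sp_a),
       occurrences_b = sample_occurrences(landscape, sp_b),
       niche_a = sp_a, niche_b = sp_b)
}

#' Write a synthetic landscape to the formats the ingest modules read
#'
#' One ESRI ASCII raster per variable plus a mask raster.
#'
#' @param landscape A `synthetic_landscape`.
#' @param dir Output directory (created if absent).
#' @return Named list of written paths, invisibly.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- landscape$grid
  south <- g$origin["north"] - g$n_rows * g$cell_size
  paths <- character(0)
  for (v in colnames(g$values)) {
    m <- matrix(g$values[, v], g$n_rows, g$n_cols, byrow = TRUE)
    p <- file.path(dir, paste0(v, ".asc"))
    write_ascii_grid(m, p, west = g$origin["west"], south = south,
                     cell_size = g$cell_size)
    paths[v] <- p
  }
  mask_m <- matrix(as.numeric(landscape$mask), g$n_rows, g$n_cols,
                   byrow = TRUE)
  mask_p <- file.path(dir, "mask.asc")
  write_ascii_grid(mask_m, mask_p, west = g$origin["west"], south = south,
                   cell_size = g$cell_size)
  invisible(list(variables = paths, mask = mask_p))
}
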