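# Gridded climate container and the background (available climate) subset.
#
# A climate_grid stores V aligned variables on one lattice. Cells are indexed
# row-major with row 1 at the northern edge; a cell is valid only when every
# variable is non-missing there (no imputation).

#' Construct a climate grid
#'
#' @param values Numeric matrix, one row per cell (row-major, row 1 = north),
#'   one named column per climate variable.
#' @param west,north Coordinates of the grid's north-west corner, degrees.
#' @param cell_size Cell width in degrees.
#' @param n_rows,n_cols Lattice dimensions.
#' @return An object of class `climate_grid`.
#' @export
climate_grid <- function(values, west, north, cell_size, n_rows, n_cols) {
  values <- as.matrix(values)
  if (nrow(values) != n_rows * n_cols) {
    stop("values must have one row per grid cell")
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("variables must carry unique names")
  }
  structure(
    list(origin = c(west = west, north = north), cell_size = cell_size,
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         values = values, valid = stats::complete.cases(values)),
    class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat("Climate grid:", x$n_rows, "x", x$n_cols, "cells,",
      ncol(x$values), "variables\n")
  cat("  origin (W, N):", x$origin["west"], x$origin["north"],
      " cell size:", x$cell_size, "deg\n")
  cat("  valid cells:", sum(x$valid), "of", length(x$valid), "\n")
  invisible(x)
}

cell_rowcol <- function(grid, cells) {
  cbind(row = (cells - 1L) %/% grid$n_cols + 1L,
        col = (cells - 1L) %% grid$n_cols + 1L)
}

cell_index <- function(grid, row, col) {
  (as.integer(row) - 1L) * grid$n_cols + as.integer(col)
}

#' Cell-centre coordinates
#'
#' @param grid A `climate_grid`.
#' @param cells Integer cell indices (row-major).
#' @return Matrix with columns `lon`, `lat`.
#' @export
cell_centers <- function(grid, cells) {
  rc <- cell_rowcol(grid, cells)
  cbind(lon = grid$origin["west"] + (rc[, "col"] - 0.5) * grid$cell_size,
        lat = grid$origin["north"] - (rc[, "row"] - 0.5) * grid$cell_size)
}

# Half-open cell membership: lon in [west_edge, east_edge), lat in
# (south_edge, north_edge]. Returns NA for points outside the lattice.
locate_cells <- function(grid, lon, lat) {
  cs <- grid$cell_size
  col <- floor((lon - grid$origin["west"]) / cs) + 1
  row <- floor((grid$origin["north"] - lat) / cs) + 1
  row[grid$origin["north"] - lat == 0] <- 1  # northern edge belongs to row 1
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows |
    !is.finite(lon) | !is.finite(lat)
  out <- cell_index(grid, row, col)
  out[bad] <- NA_integer_
  out
}

#' Read aligned single-variable rasters into a climate grid
#'
#' Each file holds one variable; all files must share an identical geometry
#' (a mismatch is an error, never silent resampling). A cell missing any
#' variable is marked invalid everywhere.
#'
#' @param paths Character vector of ESRI ASCII grid paths, one per variable.
#' @param var_names Variable names; defaults to the file base names.
#' @return A `climate_grid`.
#' @export
read_climate_grid <- function(paths, var_names = NULL) {
  if (length(paths) < 1) stop("at least one raster required")
  var_names <- var_names %||% sub("\\.[^.]*$", "", basename(paths))
  if (anyDuplicated(var_names)) stop("duplicate variable name")
  ref <- read_ascii_grid(paths[1])
  tol <- ref$cell_size * 1e-6
  layers <- vector("list", length(paths))
  layers[[1]] <- ref
  for (i in seq_along(paths)[-1]) {
    g <- read_ascii_grid(paths[i])
    if (nrow(g$values) != nrow(ref$values) ||
        ncol(g$values) != ncol(ref$values) ||
        abs(g$west - ref$west) > tol || abs(g$south - ref$south) > tol ||
        abs(g$cell_size - ref$cell_size) > tol) {
      stop("raster geometry mismatch: ", paths[i])
    }
    layers[[i]] <- g
  }
  vals <- vapply(layers, function(g) as.vector(t(g$values)),
                 numeric(length(ref$values)))
  colnames(vals) <- var_names
  n_rows <- nrow(ref$values)
  climate_grid(vals,
               west = ref$west,
               north = ref$south + n_rows * ref$cell_size,
               cell_size = ref$cell_size,
               n_rows = n_rows, n_cols = ncol(ref$values))
}

#' Restrict a climate grid to the available (background) climate space
#'
#' The background is the set of valid cells for which the mask is true; it
#' delimits the climate space regarded as available to the taxa (in the
#' motivating study, temperate-to-tropical zones of a Koppen-Geiger map).
#'
#' @param grid A `climate_grid`.
#' @param mask Logical vector (length = number of cells), logical/numeric
#'   matrix in grid layout, or path to an ESRI ASCII raster (> 0 means
#'   inside; nodata means outside).
#' @return An object of class `background_set` with elements `cells`
#'   (integer indices) and `values` (climate matrix for those cells).
#' @export
apply_background_mask <- function(grid, mask) {
  if (is.character(mask)) {
    m <- read_ascii_grid(mask)
    if (nrow(m$values) != grid$n_rows || ncol(m$values) != grid$n_cols) {
      stop("mask geometry does not match the climate grid")
    }
    mask <- as.vector(t(m$values)) > 0
    mask[is.na(mask)] <- FALSE
  } else if (is.matrix(mask)) {
    if (nrow(mask) != grid$n_rows || ncol(mask) != grid$n_cols) {
      stop("mask geometry does not match the climate grid")
    }
    mask <- as.vector(t(mask)) > 0
  }
  mask <- as.logical(mask)
  if (length(mask) != length(grid$valid)) {
    stop("mask length does not match the number of grid cells")
  }
  keep <- which(grid$valid & !is.na(mask) & mask)
  if (length(keep) == 0) stop("background is empty after masking")
  structure(list(cells = keep,
                 values = grid$values[keep, , drop = FALSE],
                 n_grid_cells = length(grid$valid)),
            class = "background_set")
}

#' @export
print.background_set <- function(x, ...) {
  cat("Background set:", length(x$cells), "cells of", x$n_grid_cells,
      "(", ncol(x$values), "variables )\n")
  invisible(x)
}
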