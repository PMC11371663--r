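# Kernel-smoothed occupancy surfaces in the PC1 x PC2 niche space.
#
# The availability density e is a 2D Gaussian KDE of the background cells'
# scores; the occurrence density o is a KDE of the occupied cells' scores on
# the same grid. The corrected occupancy z divides o by e (restricting to
# cells where climate is actually available) and renormalizes, so z reflects
# climatic preference rather than climate-space abundance. Densities are
# evaluated at cell centres and treated as discrete masses, matching the
# discrete Schoener's D downstream. Bandwidths follow the per-axis Silverman
# reference rule on the sample being smoothed.

kde_grid <- function(scores, R, lims) {
  if (stats::sd(scores[, 1]) == 0 || stats::sd(scores[, 2]) == 0) {
    stop("degenerate score cloud: no spread along an axis")
  }
  h <- c(stats::bw.nrd0(scores[, 1]), stats::bw.nrd0(scores[, 2]))
  if (any(h <= 0)) stop("degenerate score cloud: zero Silverman bandwidth")
  k <- MASS::kde2d(scores[, 1], scores[, 2], h = 4 * h, n = R, lims = lims)
  list(x = k$x, y = k$y, z = k$z / sum(k$z), bw = h)
}

#' Build the availability density over the background climate space
#'
#' @param scores Background scores, a two-column matrix (PC1, PC2).
#' @param R Grid resolution per axis (>= 10; default 100).
#' @param margin Fractional range expansion per side (default 0.05).
#' @return Object of class `availability_density`: grid centres `x`, `y`,
#'   normalized availability mass `e` (sums to 1), the Silverman
#'   bandwidths, the axis `lims`, and the background `scores` (retained for
#'   resampling nulls).
#' @export
build_availability_density <- function(scores, R = 100, margin = 0.05) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2) stop("scores must have two columns (PC1, PC2)")
  if (nrow(scores) < 2) stop("need at least 2 background cells")
  if (!is_count(R, 10)) stop("grid resolution R below 10 is rejected")
  rx <- range(scores[, 1])
  ry <- range(scores[, 2])
  if (diff(rx) == 0 || diff(ry) == 0) {
    stop("degenerate background score range")
  }
  lims <- c(rx[1] - margin * diff(rx), rx[2] + margin * diff(rx),
            ry[1] - margin * diff(ry), ry[2] + margin * diff(ry))
  k <- kde_grid(scores, R, lims)
  structure(list(R = as.integer(R), x = k$x, y = k$y, e = k$z, bw = k$bw,
                 lims = lims, margin = margin, scores = scores),
            class = "availability_density")
}

#' Build the availability-corrected occupancy surface for one taxon
#'
#' @param scores Occupied-cell scores, a two-column matrix (>= 5 rows; the
#'   overlap statistics are meaningless for fewer occupied cells).
#' @param avail An `availability_density` (defines the grid and e).
#' @param availability_floor Fraction of `max(e)` below which availability
#'   is treated as zero; keeps the correction from blowing up at the
#'   climate-space fringe (default 1e-6).
#' @return Object of class `niche_density_grid` with occurrence density `o`,
#'   availability `e`, corrected occupancy `z` (sums to 1, zero off the
#'   availability support), the support mask, `n_occ`, bandwidths, and the
#'   inputs needed by the randomization tests.
#' @export
build_occupancy <- function(scores, avail, availability_floor = 1e-6) {
  stopifnot(inherits(avail, "availability_density"))
  scores <- as.matrix(scores)
  if (ncol(scores) != 2) stop("scores must have two columns (PC1, PC2)")
  if (nrow(scores) < 5) {
    stop("at least 5 occupied cells are required to build an occupancy ",
         "surface")
  }
  l <- avail$lims
  inside <- scores[, 1] >= l[1] & scores[, 1] <= l[2] &
    scores[, 2] >= l[3] & scores[, 2] <= l[4]
  if (!any(inside)) {
    stop("all occurrence scores fall outside the availability axis ranges")
  }
  k <- kde_grid(scores, avail$R, l)
  support <- avail$e >= availability_floor * max(avail$e)
  r <- matrix(0, avail$R, avail$R)
  r[support] <- k$z[support] / avail$e[support]
  s <- sum(r)
  if (s == 0) stop("occupancy has no mass on the availability support")
  structure(list(R = avail$R, x = avail$x, y = avail$y,
                 o = k$z, e = avail$e, z = r / s,
                 support = support, n_occ = nrow(scores), bw = k$bw,
                 availability_floor = availability_floor,
                 scores = scores, avail = avail),
            class = "niche_density_grid")
}

#' @export
print.niche_density_grid <- function(x, ...) {
  cat("Niche density grid:", x$R, "x", x$R, "cells,",
      x$n_occ, "occupied climate cells\n")
  cat("  bandwidths (PC1, PC2):", signif(x$bw, 4), "\n")
  cat("  availability support:", sum(x$support), "grid cells\n")
  invisible(x)
}

#' Image of the corrected occupancy surface
#'
#' @param x A `niche_density_grid`.
#' @param which `"z"` (corrected occupancy, default), `"o"` or `"e"`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.niche_density_grid <- function(x, which = c("z", "o", "e"), ...) {
  which <- match.arg(which)
  graphics::image(x$x, x$y, x[[which]], xlab = "PC1", ylab = "PC2",
                  main = paste("niche surface:", which), ...)
  invisible(x)
}

#' Serialize a niche density grid to a text matrix plus JSON sidecar
#'
#' @param grid A `niche_density_grid`.
#' @param stem Output path stem; writes `<stem>.tsv` (z matrix) and
#'   `<stem>.json` (axis ranges, R, bandwidths).
#' @return The stem, invisibly.
#' @export
write_niche_grid <- function(grid, stem) {
  utils::write.table(grid$z, paste0(stem, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(R = grid$R, lims = grid$avail$lims,
                            bw = grid$bw, n_occ = grid$n_occ,
                            availability_floor = grid$availability_floor),
                       paste0(stem, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(stem)
}
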