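# Niche volume: how much of the available climate space a taxon occupies,
# by two estimators -- Schoener's D against the availability surface, and
# the area ratio of 95% highest-density regions.

#' Niche volume as Schoener's D against the availability surface
#'
#' @param z A taxon's corrected occupancy: a `niche_density_grid` (its `e`
#'   and floor are then used) or a normalized matrix.
#' @param e Availability mass matrix on the same grid (ignored when `z` is
#'   a `niche_density_grid` and `e` is missing).
#' @param availability_floor Support floor applied to `e` before
#'   renormalizing (default taken from the grid, else 1e-6).
#' @return Volume in `[0, 1]`; exactly 1 when the occupancy equals the
#'   renormalized availability.
#' @export
schoener_volume <- function(z, e = NULL, availability_floor = NULL) {
  if (inherits(z, "niche_density_grid")) {
    e <- e %||% z$e
    availability_floor <- availability_floor %||% z$availability_floor
    zm <- z$z
  } else {
    zm <- as.matrix(z)
    if (is.null(e)) stop("availability surface e is required")
  }
  availability_floor <- availability_floor %||% 1e-6
  e <- occupancy_matrix(e)
  if (!identical(dim(zm), dim(e))) stop("occupancy grids do not match")
  support <- e >= availability_floor * max(e)
  en <- matrix(0, nrow(e), ncol(e))
  en[support] <- e[support]
  en <- en / sum(en)
  schoeners_d(zm, en)
}

# Highest-density region of a discrete mass surface: the smallest set of
# cells whose summed mass reaches `level`. Cells are ranked by mass and
# accumulated; ties at the threshold mass are all included.
hdr_region <- function(mass, level = 0.95) {
  m <- mass / sum(mass)
  ord <- order(m, decreasing = TRUE)
  cum <- cumsum(m[ord])
  k <- which(cum >= level)[1]
  if (is.na(k)) k <- length(ord)
  thresh <- m[ord[k]]
  m >= thresh
}

#' Niche volume from 95% highest-density regions
#'
#' Fits 2D KDEs for the taxon and the background on a shared grid spanning
#' the background score ranges, delimits each surface's highest-density
#' region at `level`, and reports the fraction of the background HDR that
#' the taxon HDR covers.
#'
#' @param taxon_scores Two-column score matrix for the taxon (>= 5 rows).
#' @param background Background scores (two-column matrix) or an
#'   `availability_density` whose grid and KDE are reused.
#' @param level HDR probability level (default 0.95).
#' @param R Grid resolution per axis (used when `background` is a raw
#'   score matrix).
#' @param margin Range expansion per side (idem).
#' @return Volume in `[0, 1]`.
#' @export
hdr_volume <- function(taxon_scores, background, level = 0.95, R = 100,
                       margin = 0.05) {
  stopifnot(is_number(level), level > 0, level < 1)
  avail <- if (inherits(background, "availability_density")) background
           else build_availability_density(as.matrix(background), R, margin)
  taxon_scores <- as.matrix(taxon_scores)
  if (nrow(taxon_scores) < 5) stop("at least 5 taxon scores are required")
  kt <- kde_grid(taxon_scores, avail$R, avail$lims)
  hdr_t <- hdr_region(kt$z, level)
  hdr_b <- hdr_region(avail$e, level)
  sum(hdr_t & hdr_b) / sum(hdr_b)
}

#' Compare niche volumes between the extinct and extant groups
#'
#' Report plumbing around standard procedures: group medians, a two-tailed
#' paired t-test on the within-pair differences, and an ordinary
#' least-squares regression of extinct on extant volumes.
#'
#' @param extinct,extant Equal-length numeric vectors of per-pair volumes
#'   (>= 3 pairs).
#' @return Object of class `volume_group_comparison`: medians, mean paired
#'   difference, `t_p` (p = 1 with `degenerate = TRUE` when all
#'   differences are zero), regression `slope`, `r_squared` and `slope_p`.
#' @export
compare_volume_groups <- function(extinct, extant) {
  extinct <- as.numeric(extinct)
  extant <- as.numeric(extant)
  if (length(extinct) != length(extant)) {
    stop("extinct and extant volume vectors must pair up")
  }
  if (length(extinct) < 3) stop("at least 3 pairs are required")
  d <- extinct - extant
  degenerate <- stats::sd(d) == 0
  t_p <- if (degenerate) 1 else {
    stats::t.test(extinct, extant, paired = TRUE)$p.value
  }
  if (stats::sd(extant) == 0) {
    slope <- NA_real_
    r2 <- NA_real_
    slope_p <- NA_real_
  } else {
    fit <- stats::lm(extinct ~ extant)
    # a perfect pair correlation (identical volumes) is a legitimate
    # degenerate input; silence the perfect-fit warning
    sm <- suppressWarnings(summary(fit))
    slope <- unname(stats::coef(fit)[2])
    r2 <- sm$r.squared
    slope_p <- unname(sm$coefficients[2, 4])
  }
  structure(list(median_extinct = stats::median(extinct),
                 median_extant = stats::median(extant),
                 mean_difference = mean(d), t_p = t_p,
                 degenerate = degenerate, slope = slope,
                 r_squared = r2, slope_p = slope_p,
                 n_pairs = length(extinct)),
            class = "volume_group_comparison")
}

#' @export
print.volume_group_comparison <- function(x, ...) {
  cat("Niche volume comparison over", x$n_pairs, "pairs\n")
  cat("  medians (extinct, extant):", signif(x$median_extinct, 3), ",",
      signif(x$median_extant, 3), "\n")
  cat("  paired t-test p:", signif(x$t_p, 3),
      if (x$degenerate) "(degenerate: zero differences)", "\n")
  cat("  pair regression: slope", signif(x$slope, 3), " r2",
      signif(x$r_squared, 3), " p", signif(x$slope_p, 3), "\n")
  invisible(x)
}
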