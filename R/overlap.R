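# Schoener's D overlap and the directional niche similarity / difference
# randomization tests.

occupancy_matrix <- function(z) {
  if (inherits(z, "niche_density_grid")) z$z else as.matrix(z)
}

#' Schoener's D between two occupancy surfaces
#'
#' `D = 1 - 0.5 * sum(|z1 - z2|)` over the discrete occupancy masses: 0 for
#' disjoint niches, 1 for identical niches.
#'
#' @param z1,z2 `niche_density_grid` objects or normalized matrices on
#'   identical grids, each summing to 1.
#' @param tol Normalization tolerance (default 1e-6).
#' @return D in `[0, 1]`.
#' @export
schoeners_d <- function(z1, z2, tol = 1e-6) {
  m1 <- occupancy_matrix(z1)
  m2 <- occupancy_matrix(z2)
  if (!identical(dim(m1), dim(m2))) stop("occupancy grids do not match")
  if (abs(sum(m1) - 1) > tol || abs(sum(m2) - 1) > tol) {
    stop("occupancy surfaces must each sum to 1")
  }
  1 - 0.5 * sum(abs(m1 - m2))
}

# Translate a matrix by integer offsets, zero-filling vacated cells.
translate_matrix <- function(z, dr, dc) {
  R <- nrow(z)
  C <- ncol(z)
  out <- matrix(0, R, C)
  rs <- seq_len(R)
  cs <- seq_len(C)
  rk <- rs + dr >= 1 & rs + dr <= R
  ck <- cs + dc >= 1 & cs + dc <= C
  if (any(rk) && any(ck)) {
    out[rs[rk] + dr, cs[ck] + dc] <- z[rs[rk], cs[ck], drop = FALSE]
  }
  out
}

# One centroid-shift null surface: relocate the observed occupancy to a
# centroid drawn uniformly from availability-support cells, clip to the
# grid, zero outside the support, renormalize. Preserves the observed niche
# shape. Uses the caller's RNG stream.
shift_null <- function(grid) {
  z <- grid$z
  sup <- grid$support
  idx <- which(sup)
  wr <- round(sum(row(z) * z))
  wc <- round(sum(col(z) * z))
  for (try in 1:100) {
    t <- idx[sample.int(length(idx), 1)]
    tr <- (t - 1) %% nrow(z) + 1
    tc <- (t - 1) %/% nrow(z) + 1
    zs <- translate_matrix(z, tr - wr, tc - wc)
    zs[!sup] <- 0
    s <- sum(zs)
    if (s > 0) return(zs / s)
  }
  stop("failed to relocate the occupancy surface onto the availability ",
       "support")
}

# One resampling null surface: redraw n_occ cells from the background score
# cloud and rebuild the corrected occupancy. Matches a null in which the
# taxon uses available climate at random.
resample_null <- function(grid) {
  bg <- grid$avail$scores
  idx <- sample.int(nrow(bg), grid$n_occ, replace = TRUE)
  build_occupancy(bg[idx, , drop = FALSE], grid$avail,
                  availability_floor = grid$availability_floor)$z
}

#' Directional niche similarity / difference randomization test
#'
#' Randomizes one taxon's niche within the available climate space B times
#' and compares the observed Schoener's D against the null distribution.
#' `p_similarity` is the add-one permutation estimate of
#' `P(null D >= observed D)` (small when the pair is more similar than
#' random); `p_difference` uses the opposite tail. The default null
#' relocates the observed occupancy surface to a random availability-
#' support centroid, preserving its shape; `null = "resample"` instead
#' redraws the taxon's occupied cells from the background cloud.
#'
#' @param grid_a,grid_b `niche_density_grid`s sharing the same axes and
#'   availability surface.
#' @param B Number of null replicates (>= 99; the motivating design used
#'   1000).
#' @param seed RNG seed recorded in the result.
#' @param randomize Which taxon's surface is randomized: `"a"` or `"b"`.
#' @param null Null strategy: `"shift"` (default) or `"resample"`.
#' @return Object of class `niche_similarity_test`.
#' @export
similarity_test <- function(grid_a, grid_b, B = 1000, seed = 1L,
                            randomize = c("a", "b"),
                            null = c("shift", "resample")) {
  randomize <- match.arg(randomize)
  null <- match.arg(null)
  stopifnot(inherits(grid_a, "niche_density_grid"),
            inherits(grid_b, "niche_density_grid"))
  if (!is_count(B, 99)) stop("B must be an integer >= 99")
  if (!isTRUE(all.equal(grid_a$x, grid_b$x)) ||
      !isTRUE(all.equal(grid_a$y, grid_b$y)) ||
      !isTRUE(all.equal(grid_a$e, grid_b$e))) {
    stop("grids must share axes and availability surface")
  }
  if (!any(grid_a$support)) stop("availability support is empty")
  rnd <- if (randomize == "a") grid_a else grid_b
  fixed <- if (randomize == "a") grid_b$z else grid_a$z
  d_obs <- schoeners_d(grid_a, grid_b)
  null_d <- numeric(B)
  with_seed(seed, {
    for (b in seq_len(B)) {
      zn <- if (null == "shift") shift_null(rnd) else resample_null(rnd)
      null_d[b] <- 1 - 0.5 * sum(abs(zn - fixed))
    }
  })
  structure(list(d_obs = d_obs, null_d = null_d,
                 p_similarity = (1 + sum(null_d >= d_obs)) / (B + 1),
                 p_difference = (1 + sum(null_d <= d_obs)) / (B + 1),
                 direction = randomize, null = null, B = B,
                 seed = as.integer(seed)),
            class = "niche_similarity_test")
}

#' @export
print.niche_similarity_test <- function(x, ...) {
  cat("Niche similarity randomization test (", x$null,
      " null, taxon ", x$direction, " randomized, B = ", x$B, ")\n",
      sep = "")
  cat("  observed Schoener's D:", signif(x$d_obs, 4), "\n")
  cat("  p (similarity):", signif(x$p_similarity, 4),
      "  p (difference):", signif(x$p_difference, 4), "\n")
  invisible(x)
}

#' Histogram of the null overlap distribution
#'
#' @param x A `niche_similarity_test`.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.niche_similarity_test <- function(x, ...) {
  graphics::hist(x$null_d, breaks = 30, xlab = "null Schoener's D",
                 main = "similarity-test null distribution", ...)
  graphics::abline(v = x$d_obs, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Multiple-comparison adjustment of randomization p-values
#'
#' @param p Numeric vector of raw p-values in `(0, 1]`.
#' @param method Any method of [stats::p.adjust()] (default `"holm"`).
#' @return Adjusted p-values (attribute `method` records the adjustment).
#' @export
adjust_pvalues <- function(p, method = "holm") {
  if (!method %in% stats::p.adjust.methods) {
    stop("unknown adjustment method: ", method)
  }
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  out <- stats::p.adjust(p, method = method)
  attr(out, "method") <- method
  out
}

#' Classify a pair from its two directional tests
#'
#' Applies the dagger scheme: both directions significant, one direction,
#' or neither, independently for the similarity and difference families. A
#' pair that is neither similar nor different in either direction is the
#' candidate "climate legacy" pattern.
#'
#' @param p_similarity,p_difference Length-2 vectors of (adjusted)
#'   directional p-values.
#' @param alpha Significance level (default 0.05).
#' @return List with `similarity`, `difference` categories and the
#'   corresponding report symbols (`-`, dagger, double dagger).
#' @export
classify_pair <- function(p_similarity, p_difference, alpha = 0.05) {
  stopifnot(length(p_similarity) == 2, length(p_difference) == 2)
  sym <- c("-", "†", "‡")
  ns <- sum(p_similarity < alpha)
  nd <- sum(p_difference < alpha)
  list(similarity = c("non_similar", "similar_one", "similar_both")[ns + 1],
       difference = c("not_different", "different_one",
                      "different_both")[nd + 1],
       similarity_symbol = sym[ns + 1],
       difference_symbol = sym[nd + 1])
}
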