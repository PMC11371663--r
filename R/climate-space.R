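# Environmental PCA over the background climate space.
#
# Follows the PCA-env convention: the ordination is calibrated on background
# cells only (each valid background cell weighted once, variables centred and
# scaled to unit variance so degrees Celsius and millimetres are
# commensurable), and occurrences are projected into it afterwards. An
# optional switch also admits calibration on background plus occurrence cells.

#' Fit the environmental PCA over background cells
#'
#' Correlation-matrix PCA of the background climate table. Components are
#' ordered by decreasing variance and each axis sign is fixed so that its
#' largest-magnitude loading is positive, making axes deterministic across
#' runs and platforms.
#'
#' @param background A `background_set`, or a numeric matrix of climate
#'   values (rows = cells).
#' @param extra_cells Optional additional climate rows (e.g. occurrence
#'   cells) appended to the calibration table; the default (NULL) is the
#'   background-only convention.
#' @return An object of class `environmental_space` with per-variable
#'   `center` and `scale`, the orthonormal `loadings` (V x K),
#'   `var_fraction` per component, the background `scores`, and the PC1/PC2
#'   score ranges.
#' @export
fit_environmental_pca <- function(background, extra_cells = NULL) {
  x <- if (inherits(background, "background_set")) background$values
       else as.matrix(background)
  if (!is.null(extra_cells)) x <- rbind(x, as.matrix(extra_cells))
  if (is.null(colnames(x))) stop("climate variables must be named")
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    warning("dropping zero-variance variable(s): ",
            paste(colnames(x)[v == 0], collapse = ", "))
    x <- x[, v > 0, drop = FALSE]
  }
  if (ncol(x) < 2) stop("fewer than 2 informative variables after masking")
  if (nrow(x) < ncol(x) + 1) {
    stop("need at least V + 1 background cells to calibrate the PCA")
  }
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  for (k in seq_len(ncol(p$rotation))) {
    j <- which.max(abs(p$rotation[, k]))
    if (p$rotation[j, k] < 0) {
      p$rotation[, k] <- -p$rotation[, k]
      p$x[, k] <- -p$x[, k]
    }
  }
  ev <- p$sdev^2
  n_bg <- if (inherits(background, "background_set")) nrow(background$values)
          else nrow(as.matrix(background))
  scores <- p$x[seq_len(n_bg), , drop = FALSE]
  structure(
    list(center = p$center, scale = p$scale, loadings = p$rotation,
         sdev = p$sdev, var_fraction = ev / sum(ev),
         scores = scores,
         pc_ranges = apply(scores[, 1:2, drop = FALSE], 2, range)),
    class = "environmental_space")
}

#' Project climate vectors into the environmental space
#'
#' @param object An `environmental_space`.
#' @param newdata Matrix or data frame carrying every retained climate
#'   variable (extra columns are ignored).
#' @param ... Unused.
#' @return Score matrix (rows = input cells, columns = components); the
#'   first two columns are the niche-space axes used downstream.
#' @export
predict.environmental_space <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  vars <- names(object$center)
  missing <- setdiff(vars, colnames(x))
  if (length(missing) > 0) {
    stop("input lacks retained variable(s): ", paste(missing, collapse = ", "))
  }
  x <- x[, vars, drop = FALSE]
  scale(x, center = object$center, scale = object$scale) %*% object$loadings
}

#' @export
print.environmental_space <- function(x, ...) {
  cat("Environmental PCA:", length(x$center), "variables,",
      ncol(x$loadings), "components\n")
  vf <- round(100 * x$var_fraction[1:min(2, length(x$var_fraction))], 1)
  cat("  PC1:", vf[1], "% of variance")
  if (length(vf) > 1) cat("  PC2:", vf[2], "%")
  cat("\n")
  invisible(x)
}

#' Serialize an environmental space to JSON
#'
#' @param space An `environmental_space`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_environmental_space <- function(space, path) {
  obj <- list(center = as.list(space$center), scale = as.list(space$scale),
              loadings = space$loadings, sdev = space$sdev,
              var_fraction = space$var_fraction, pc_ranges = space$pc_ranges)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
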