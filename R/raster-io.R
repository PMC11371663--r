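# Plain-text raster input/output in the ESRI ASCII grid dialect.
# One file carries one variable; rows run north to south.

#' Read an ESRI ASCII grid
#'
#' @param path Path to a `.asc` file.
#' @return A list with `values` (numeric matrix, row 1 = northernmost row),
#'   `west`, `south`, `cell_size` and `nodata`.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ESRI ASCII header in ", path)
  }
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  n_rows <- as.integer(hdr$nrows)
  n_cols <- as.integer(hdr$ncols)
  if (length(vals) != n_rows * n_cols) {
    stop("raster body of ", path, " has ", length(vals), " values, expected ",
         n_rows * n_cols)
  }
  m <- matrix(vals, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  list(values = m, west = hdr$xllcorner, south = hdr$yllcorner,
       cell_size = hdr$cellsize, nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param values Numeric matrix, row 1 = northernmost row; `NA` written as the
#'   nodata value.
#' @param path Output path.
#' @param west,south Coordinates of the lower-left corner, degrees.
#' @param cell_size Cell width in degrees.
#' @param nodata Value used to encode missing cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(values, path, west, south, cell_size,
                             nodata = -9999) {
  values <- as.matrix(values)
  hdr <- c(
    paste("ncols", ncol(values)),
    paste("nrows", nrow(values)),
    paste("xllcorner", format(west, digits = 15)),
    paste("yllcorner", format(south, digits = 15)),
    paste("cellsize", format(cell_size, digits = 15)),
    paste("NODATA_value", format(nodata, digits = 15))
  )
  body <- apply(values, 1, function(r) {
    r[is.na(r)] <- nodata
    paste(format(r, digits = 10, trim = TRUE, scientific = FALSE),
          collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}
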