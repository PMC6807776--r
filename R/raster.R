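#' Multi-band raster stack
#'
#' A lightweight georeferenced raster container: a list of equally-sized
#' numeric matrices on a shared regular grid. Row 1 is the north edge.
#' Cell centers follow the lower-left-corner convention:
#' `x = xll + (col - 0.5) res`, `y = yll + (nrow - row + 0.5) res`.
#' Cells that are NA in any band are treated as nodata in all bands.
#'
#' @param bands a matrix or list of matrices (same dimensions).
#' @param res cell size in m (default 5).
#' @param xll,yll coordinates of the grid's lower-left corner in projected m.
#' @param band_names optional character vector of band names.
#' @return object of class `raster_stack`.
#' @export
raster_stack <- function(bands, res = 5, xll = 0, yll = 0, band_names = NULL) {
  if (is.matrix(bands)) bands <- list(bands)
  if (res <= 0) stop("resolution must be > 0", call. = FALSE)
  dims <- unique(lapply(bands, dim))
  if (length(dims) != 1) stop("all bands must share dimensions", call. = FALSE)
  if (!is.null(band_names)) names(bands) <- band_names
  structure(list(bands = bands, res = res, xll = xll, yll = yll,
                 nrow = nrow(bands[[1]]), ncol = ncol(bands[[1]])),
            class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("raster_stack: %d x %d cells, %d band(s), %g m resolution\n",
              x$nrow, x$ncol, length(x$bands), x$res))
  cat(sprintf("  lower-left corner (%g, %g); %d valid cells\n",
              x$xll, x$yll, sum(valid_mask(x))))
  invisible(x)
}

valid_mask <- function(stack) {
  m <- !is.na(stack$bands[[1]])
  for (b in stack$bands[-1]) m <- m & !is.na(b)
  m
}

cell_centers <- function(stack) {
  xs <- stack$xll + (seq_len(stack$ncol) - 0.5) * stack$res
  ys <- stack$yll + (stack$nrow - seq_len(stack$nrow) + 0.5) * stack$res
  list(x = xs, y = ys)
}

# (row, col) of the cell containing each point; NA when off-grid
point_to_cell <- function(stack, x, y) {
  col <- floor((x - stack$xll) / stack$res) + 1
  row <- stack$nrow - floor((y - stack$yll) / stack$res)
  off <- col < 1 | col > stack$ncol | row < 1 | row > stack$nrow
  col[off] <- NA_integer_
  row[off] <- NA_integer_
  data.frame(row = row, col = col)
}

#' Binary class map
#'
#' Boolean grid on the same georeferencing model as [raster_stack()]:
#' TRUE = target class (e.g. alder shrubland), FALSE = other, NA = nodata.
#'
#' @param values logical matrix.
#' @param res cell size (m); `xll`, `yll` lower-left corner.
#' @return object of class `binary_class_map`.
#' @export
binary_class_map <- function(values, res = 5, xll = 0, yll = 0) {
  if (res <= 0) stop("resolution must be > 0", call. = FALSE)
  storage.mode(values) <- "logical"
  structure(list(values = values, res = res, xll = xll, yll = yll,
                 nrow = nrow(values), ncol = ncol(values)),
            class = "binary_class_map")
}

#' @export
print.binary_class_map <- function(x, ...) {
  cat(sprintf("binary_class_map: %d x %d cells at %g m; %d positive (%.1f%%)\n",
              x$nrow, x$ncol, x$res, sum(x$values, na.rm = TRUE),
              100 * mean(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Read/write a single-band ESRI ASCII grid
#'
#' Plain-text grid exchange format (`ncols`/`nrows`/`xllcorner`/`yllcorner`/
#' `cellsize`/`NODATA_value` header followed by rows north to south).
#' Multi-band stacks are stored as one file per band.
#'
#' @param path file path.
#' @return `read_ascii_grid`: a one-band [raster_stack()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  raster_stack(m, res = hdr$cellsize, xll = hdr$xllcorner, yll = hdr$yllcorner)
}

#' @rdname read_ascii_grid
#' @param x a one-band `raster_stack`, a `binary_class_map`, or a matrix.
#' @param res,xll,yll georeferencing, used only when `x` is a bare matrix.
#' @param nodata value written for NA cells.
#' @export
write_ascii_grid <- function(x, path, res = 5, xll = 0, yll = 0,
                             nodata = -9999) {
  if (inherits(x, "raster_stack")) {
    m <- x$bands[[1]]; res <- x$res; xll <- x$xll; yll <- x$yll
  } else if (inherits(x, "binary_class_map")) {
    m <- x$values + 0; res <- x$res; xll <- x$xll; yll <- x$yll
  } else m <- x
  m[is.na(m)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.10g", xll), sprintf("yllcorner %.10g", yll),
           sprintf("cellsize %.10g", res), sprintf("NODATA_value %g", nodata))
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}
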