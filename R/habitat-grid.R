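#' Construct a binary habitat grid
#'
#' The elementary spatial container: a rectangular lattice of square cells in
#' which `1` marks habitat and `0` everything else (non-habitat and no-data
#' alike, which is conservative for connectivity). With the default
#' `cell_size_km = 1` each cell covers 1 km^2, the resolution at which
#' regional forest-cover maps are typically analysed.
#'
#' Cells are addressed `(row, col)` with row 1 at the top of the map, the
#' common raster convention. `origin` is the projected-km coordinate of the
#' lower-left corner of the grid and only matters for exported centroids;
#' all inter-patch distances are translation invariant.
#'
#' @param cells A matrix (or object coercible to one) whose entries are all
#'   0 or 1, or logical.
#' @param cell_size_km Edge length of one square cell, in km. Must be > 0.
#' @param origin Length-2 numeric, projected km of the lower-left corner.
#' @param crs_note Free-text note on the coordinate reference system.
#' @return An object of class `habitat_grid`.
#' @examples
#' g <- habitat_grid(rbind(c(1, 1, 0), c(0, 0, 0), c(0, 1, 1)))
#' habitat_area_km2(g)
#' @export
habitat_grid <- function(cells, cell_size_km = 1, origin = c(0, 0),
                         crs_note = "projected km, unspecified CRS") {
  cells <- as.matrix(cells)
  if (is.logical(cells)) storage.mode(cells) <- "integer"
  if (length(cells) > 0 && !all(cells %in% c(0L, 1L))) {
    abort("`cells` must contain only 0/1 (use `habitat_values` in `read_habitat_grid()` to recode).")
  }
  storage.mode(cells) <- "integer"
  if (!is.numeric(cell_size_km) || length(cell_size_km) != 1 || cell_size_km <= 0) {
    abort("`cell_size_km` must be a single positive number.")
  }
  structure(
    list(cells = cells, cell_size_km = as.numeric(cell_size_km),
         origin = as.numeric(origin), crs_note = crs_note),
    class = "habitat_grid"
  )
}

#' @export
print.habitat_grid <- function(x, ...) {
  cat(sprintf(
    "<habitat_grid> %d x %d cells of %.3g km (%d habitat cells, %.6g km^2)\n",
    nrow(x$cells), ncol(x$cells), x$cell_size_km,
    sum(x$cells), habitat_area_km2(x)
  ))
  invisible(x)
}

#' Total habitat area of a grid
#'
#' @param grid A [habitat_grid].
#' @return Habitat-cell count times the cell area, in km^2.
#' @export
habitat_area_km2 <- function(grid) {
  stopifnot(inherits(grid, "habitat_grid"))
  sum(grid$cells) * grid$cell_size_km^2
}

#' Read a habitat map into a binary grid
#'
#' Accepts an in-memory matrix, an ESRI ASCII grid (`.asc`, cell size taken
#' from the `cellsize` header), or a single-band TIFF raster (cell size must
#' then be supplied explicitly, since plain TIFF carries no georeferencing).
#' Cells whose value falls in `habitat_values` become 1; everything else,
#' including no-data, becomes 0.
#'
#' @param source A matrix, or path to an `.asc` / `.tif` file.
#' @param habitat_values Raster values coded as habitat (default `1`).
#' @param cell_size_km Cell edge length in km; required for TIFF sources,
#'   optional override otherwise.
#' @inheritParams habitat_grid
#' @return A [habitat_grid].
#' @export
read_habitat_grid <- function(source, habitat_values = 1, cell_size_km = NULL,
                              origin = NULL, crs_note = NULL) {
  if (is.matrix(source) || is.data.frame(source)) {
    vals <- as.matrix(source)
    cs <- cell_size_km %||% 1
    org <- origin %||% c(0, 0)
    note <- crs_note %||% "in-memory lattice"
  } else if (is.character(source) && length(source) == 1) {
    if (!file.exists(source)) abort(sprintf("Cannot read raster: '%s' does not exist.", source))
    ext <- tolower(tools::file_ext(source))
    if (ext %in% c("asc", "grd", "txt")) {
      parsed <- read_esri_ascii(source)
      vals <- parsed$values
      cs <- cell_size_km %||% parsed$cell_size_km
      org <- origin %||% parsed$origin
      note <- crs_note %||% "ESRI ASCII grid (projected km assumed)"
    } else if (ext %in% c("tif", "tiff")) {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        abort("Reading TIFF requires the 'tiff' package.")
      }
      if (is.null(cell_size_km)) {
        abort("TIFF rasters carry no cell size here; supply `cell_size_km` explicitly.")
      }
      img <- tiff::readTIFF(source, as.is = TRUE)
      if (length(dim(img)) == 3) {
        if (dim(img)[3] != 1) abort("Raster must be single-band.")
        img <- img[, , 1]
      }
      vals <- img
      cs <- cell_size_km
      org <- origin %||% c(0, 0)
      note <- crs_note %||% "TIFF raster, explicit cell size"
    } else {
      abort(sprintf("Unsupported raster format '.%s' (use .asc or .tif).", ext))
    }
  } else {
    abort("`source` must be a matrix or a file path.")
  }
  if (length(vals) == 0) abort("Empty raster.")
  bin <- matrix(as.integer(vals %in% habitat_values), nrow(vals), ncol(vals))
  habitat_grid(bin, cell_size_km = cs, origin = org, crs_note = note)
}

# ESRI ASCII grid: 5-6 header lines (ncols, nrows, xllcorner, yllcorner,
# cellsize, optional nodata_value) then nrows lines of ncols values,
# top row first.
read_esri_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  for (key in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[key]])) abort(sprintf("ESRI ASCII header lacks '%s'.", key))
  }
  body <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(body) != nr * nc) {
    abort(sprintf("ESRI ASCII body has %d values, expected %d.", length(body), nr * nc))
  }
  vals <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- hdr$nodata_value
  if (!is.null(nodata)) vals[vals == nodata] <- NA
  list(values = vals, cell_size_km = hdr$cellsize,
       origin = c(hdr$xllcorner %||% 0, hdr$yllcorner %||% 0))
}

#' Write a habitat grid as an ESRI ASCII raster
#'
#' @param grid A [habitat_grid].
#' @param path Output file path (`.asc`).
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(grid, path) {
  stopifnot(inherits(grid, "habitat_grid"))
  hdr <- c(
    sprintf("ncols %d", ncol(grid$cells)),
    sprintf("nrows %d", nrow(grid$cells)),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2]),
    sprintf("cellsize %.10g", grid$cell_size_km),
    "nodata_value -9999"
  )
  body <- apply(grid$cells, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a habitat grid as a single-band TIFF raster
#'
#' Pixel values are written as 8-bit 0/1; the cell size is not embedded
#' (plain TIFF), so supply it again on read.
#'
#' @inheritParams write_esri_ascii
#' @export
write_habitat_tiff <- function(grid, path) {
  stopifnot(inherits(grid, "habitat_grid"))
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("Writing TIFF requires the 'tiff' package.")
  }
  tiff::writeTIFF(grid$cells / 255, path, bits.per.sample = 8)
  invisible(path)
}
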