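#' Label habitat patches by connected-component analysis
#'
#' Decomposes the habitat cells of a grid into maximal connected components
#' ("patches") under 4- or 8-connectivity, the unit of analysis for every
#' downstream fragmentation metric: patch areas enter the metapopulation
#' matrix as \eqn{A_i}, and patch boundaries define the minimum edge-to-edge
#' distances \eqn{D_{ij}}.
#'
#' Patch ids are consecutive integers `1..n` assigned in decreasing area
#' order; ties are broken by the earliest patch cell in a row-major scan of
#' the grid, so labeling is fully deterministic. A cell is a boundary cell
#' when at least one of its neighbors (under the same connectivity) is
#' non-habitat or off the grid; single-cell patches are their own boundary.
#'
#' @param grid A [habitat_grid].
#' @param connectivity 4 (rook: edge-sharing neighbors) or 8 (queen:
#'   diagonal cells also touch, the default).
#' @return A `patch_set`: a list with a `patches` tibble (`patch_id`,
#'   `area_km2`, `n_cells`, `centroid_x_km`, `centroid_y_km`), a `labels`
#'   integer matrix (0 = non-habitat), a `boundary` tibble of boundary-cell
#'   positions and center coordinates, plus the connectivity and cell size.
#' @examples
#' g <- habitat_grid(rbind(c(1, 1, 0), c(0, 0, 0), c(0, 1, 1)))
#' label_patches(g, connectivity = 4)$patches
#' @export
label_patches <- function(grid, connectivity = 8) {
  stopifnot(inherits(grid, "habitat_grid"))
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  cells <- grid$cells
  nr <- nrow(cells); nc <- ncol(cells)
  hab <- which(cells == 1L)               # column-major linear indices
  n_hab <- length(hab)

  if (n_hab == 0) {
    return(new_patch_set(
      patches = tibble::tibble(patch_id = integer(), area_km2 = numeric(),
                               n_cells = integer(), centroid_x_km = numeric(),
                               centroid_y_km = numeric()),
      labels = matrix(0L, nr, nc),
      boundary = tibble::tibble(patch_id = integer(), row = integer(),
                                col = integer(), x_km = numeric(),
                                y_km = numeric()),
      connectivity = connectivity, grid = grid
    ))
  }

  rows <- ((hab - 1L) %% nr) + 1L
  cols <- ((hab - 1L) %/% nr) + 1L
  pos <- rep(0L, nr * nc)                 # linear index -> habitat-cell rank
  pos[hab] <- seq_len(n_hab)

  offsets <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  edges <- lapply(offsets, function(off) {
    r2 <- rows + off[1]; c2 <- cols + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) return(NULL)
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- cells[nb] == 1L
    cbind(pos[hab[ok][keep]], pos[nb[keep]])
  })
  edges <- do.call(rbind, edges)

  g <- igraph::make_empty_graph(n = n_hab, directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges))
  }
  memb <- igraph::components(g)$membership

  # deterministic ids: decreasing area, ties by first cell in row-major scan
  sizes <- tabulate(memb)
  rowmajor <- (rows - 1L) * nc + cols
  first_cell <- vapply(split(rowmajor, memb), min, numeric(1))
  ord <- order(-sizes, first_cell)
  relabel <- integer(length(sizes)); relabel[ord] <- seq_along(ord)
  patch_of_cell <- relabel[memb]

  labels <- matrix(0L, nr, nc)
  labels[hab] <- patch_of_cell

  cs <- grid$cell_size_km
  x_km <- grid$origin[1] + (cols - 0.5) * cs
  y_km <- grid$origin[2] + (nr - rows + 0.5) * cs
  patches <- tibble::tibble(patch_id = patch_of_cell, x_km = x_km, y_km = y_km) |>
    dplyr::group_by(.data$patch_id) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     centroid_x_km = mean(.data$x_km),
                     centroid_y_km = mean(.data$y_km), .groups = "drop") |>
    dplyr::arrange(.data$patch_id) |>
    dplyr::mutate(area_km2 = .data$n_cells * cs^2) |>
    dplyr::select("patch_id", "area_km2", "n_cells",
                  "centroid_x_km", "centroid_y_km")

  # boundary: habitat cell with any non-habitat or off-grid neighbor
  full_offsets <- list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L))
  if (connectivity == 8) {
    full_offsets <- c(full_offsets, list(c(1L, 1L), c(1L, -1L),
                                         c(-1L, 1L), c(-1L, -1L)))
  }
  is_boundary <- rep(FALSE, n_hab)
  for (off in full_offsets) {
    r2 <- rows + off[1]; c2 <- cols + off[2]
    outside <- r2 < 1L | r2 > nr | c2 < 1L | c2 > nc
    inside <- !outside
    nb_val <- rep(0L, n_hab)
    nb_val[inside] <- cells[(c2[inside] - 1L) * nr + r2[inside]]
    is_boundary <- is_boundary | outside | nb_val == 0L
  }
  boundary <- tibble::tibble(
    patch_id = patch_of_cell[is_boundary],
    row = rows[is_boundary], col = cols[is_boundary],
    x_km = x_km[is_boundary], y_km = y_km[is_boundary]
  ) |> dplyr::arrange(.data$patch_id, .data$row, .data$col)

  new_patch_set(patches, labels, boundary, connectivity, grid)
}

new_patch_set <- function(patches, labels, boundary, connectivity, grid) {
  structure(
    list(patches = patches, labels = labels, boundary = boundary,
         connectivity = connectivity, cell_size_km = grid$cell_size_km,
         origin = grid$origin),
    class = "patch_set"
  )
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches, %.6g km^2 total (connectivity %s)\n",
              nrow(x$patches), sum(x$patches$area_km2),
              x$connectivity %||% "n/a"))
  if (nrow(x$patches) > 0) print(x$patches, n = 5)
  invisible(x)
}

#' @rdname label_patches
#' @param x A `patch_set`.
#' @param ... Unused.
#' @export
tidy.patch_set <- function(x, ...) x$patches

#' Build a patch set from a pre-computed patch table
#'
#' For workflows that start from a tabular patch inventory rather than a
#' raster: each patch is reduced to one representative point, so inter-patch
#' distances are point-to-point rather than edge-to-edge.
#'
#' @param df Data frame with columns `patch_id`, `area_km2`, `x_km`, `y_km`.
#' @param cell_size_km Nominal source resolution (km), recorded only.
#' @return A `patch_set`.
#' @export
patch_set_from_table <- function(df, cell_size_km = 1) {
  req <- c("patch_id", "area_km2", "x_km", "y_km")
  if (!all(req %in% names(df))) {
    abort(paste0("Patch table needs columns: ", paste(req, collapse = ", ")))
  }
  if (any(df$area_km2 <= 0)) abort("All patch areas must be > 0.")
  df <- dplyr::arrange(tibble::as_tibble(df),
                       dplyr::desc(.data$area_km2), .data$patch_id)
  df$patch_id <- seq_len(nrow(df))
  patches <- tibble::tibble(
    patch_id = df$patch_id, area_km2 = as.numeric(df$area_km2),
    n_cells = NA_integer_,
    centroid_x_km = df$x_km, centroid_y_km = df$y_km
  )
  boundary <- tibble::tibble(patch_id = df$patch_id,
                             row = NA_integer_, col = NA_integer_,
                             x_km = df$x_km, y_km = df$y_km)
  structure(
    list(patches = patches, labels = NULL, boundary = boundary,
         connectivity = NA, cell_size_km = cell_size_km, origin = c(0, 0)),
    class = "patch_set"
  )
}

#' Drop patches below a minimum area
#'
#' A screening option motivated by minimum-viable-fragment recommendations;
#' off by default since even single-cell patches are legal.
#'
#' @param patches A `patch_set`.
#' @param min_area_km2 Patches strictly smaller than this are removed.
#' @return A `patch_set` with ids renumbered consecutively.
#' @export
filter_patches <- function(patches, min_area_km2) {
  stopifnot(inherits(patches, "patch_set"))
  keep <- patches$patches$patch_id[patches$patches$area_km2 >= min_area_km2]
  remap <- setNames(seq_along(keep), keep)
  out <- patches
  out$patches <- patches$patches |>
    dplyr::filter(.data$patch_id %in% keep) |>
    dplyr::mutate(patch_id = as.integer(remap[as.character(.data$patch_id)]))
  out$boundary <- patches$boundary |>
    dplyr::filter(.data$patch_id %in% keep) |>
    dplyr::mutate(patch_id = as.integer(remap[as.character(.data$patch_id)]))
  if (!is.null(patches$labels)) {
    lab <- patches$labels
    new_lab <- matrix(0L, nrow(lab), ncol(lab))
    for (old in keep) new_lab[lab == old] <- remap[[as.character(old)]]
    out$labels <- new_lab
  }
  out
}

#' Minimum edge-to-edge distance matrix between patches
#'
#' For every patch pair the minimum Euclidean distance between the centers
#' of their boundary cells, in projected km; the diagonal is zero by
#' definition (self-distance, supporting self-colonization). Distances are
#' computed per patch pair on the boundary cells only, with each pair
#' evaluated as one vectorized cross-distance block.
#'
#' @param patches A `patch_set` with at least one patch.
#' @return A symmetric `n x n` numeric matrix with patch ids as dimnames.
#' @export
min_edge_distances <- function(patches) {
  stopifnot(inherits(patches, "patch_set"))
  n <- nrow(patches$patches)
  if (n == 0) abort("Need at least one patch.")
  ids <- patches$patches$patch_id
  coords <- split.data.frame(
    cbind(patches$boundary$x_km, patches$boundary$y_km),
    factor(patches$boundary$patch_id, levels = ids)
  )
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      a <- coords[[i]]
      for (j in (i + 1):n) {
        b <- coords[[j]]
        d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
        D[i, j] <- D[j, i] <- sqrt(min(d2))
      }
    }
  }
  D
}

#' Export patch table / distance matrix as CSV
#'
#' @param patches A `patch_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_patch_table <- function(patches, path) {
  stopifnot(inherits(patches, "patch_set"))
  utils::write.csv(patches$patches, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patch_table
#' @param dists A distance matrix from [min_edge_distances()].
#' @export
write_distance_csv <- function(dists, path) {
  df <- as.data.frame(dists)
  names(df) <- colnames(dists)
  utils::write.csv(cbind(patch_id = rownames(dists), df), path,
                   row.names = FALSE)
  invisible(path)
}

#' Write the patch-label raster as a 16-bit TIFF
#'
#' @inheritParams write_patch_table
#' @export
write_patch_labels_tiff <- function(patches, path) {
  stopifnot(inherits(patches, "patch_set"))
  if (is.null(patches$labels)) abort("This patch_set has no label raster.")
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("Writing TIFF requires the 'tiff' package.")
  }
  tiff::writeTIFF(patches$labels / 65535, path, bits.per.sample = 16)
  invisible(path)
}
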