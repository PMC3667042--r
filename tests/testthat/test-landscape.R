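test_that("habitat grids encode rasters as binary lattices", {
  g <- read_habitat_grid(rbind(c(1, 1, 0), c(0, 0, 0), c(0, 1, 1)))
  expect_s3_class(g, "habitat_grid")
  expect_equal(sum(g$cells), 4)
  expect_equal(habitat_area_km2(g), 4)

  # all-zero grid is legal, not an error
  empty <- read_habitat_grid(matrix(0, 3, 3))
  expect_equal(sum(empty$cells), 0)

  # recoding: habitat_values picks out the habitat class
  coded <- read_habitat_grid(rbind(c(5, 2), c(2, 5)), habitat_values = 5)
  expect_equal(coded$cells, rbind(c(1L, 0L), c(0L, 1L)))

  expect_error(habitat_grid(matrix(2, 2, 2)), "0/1")
  expect_error(habitat_grid(matrix(1, 2, 2), cell_size_km = 0), "positive")
  expect_error(read_habitat_grid("no/such/file.asc"), "does not exist")
})

test_that("ESRI ASCII and TIFF rasters round-trip cell-for-cell", {
  grid <- generate_landscape(landscape_spec(c(20, 25), n_seeds = 6,
                                            growth_steps = 4, seed = 42))
  asc <- tempfile(fileext = ".asc")
  write_esri_ascii(grid, asc)
  back <- read_habitat_grid(asc)
  expect_identical(back$cells, grid$cells)
  expect_equal(back$cell_size_km, grid$cell_size_km)

  tif <- tempfile(fileext = ".tif")
  write_habitat_tiff(grid, tif)
  back2 <- read_habitat_grid(tif, cell_size_km = 1)
  expect_identical(back2$cells, grid$cells)
  expect_error(read_habitat_grid(tif), "cell_size_km")
})

test_that("patch labeling matches hand counts and respects connectivity", {
  g <- habitat_grid(rbind(c(1, 1, 0), c(0, 0, 0), c(0, 1, 1)))
  ps <- label_patches(g, connectivity = 4)
  expect_equal(nrow(ps$patches), 2)
  expect_equal(ps$patches$area_km2, c(2, 2))

  diagonal <- habitat_grid(rbind(c(1, 0), c(0, 1)))
  expect_equal(nrow(label_patches(diagonal, 4)$patches), 2)
  ps8 <- label_patches(diagonal, 8)
  expect_equal(nrow(ps8$patches), 1)
  expect_equal(ps8$patches$area_km2, 2)

  expect_error(label_patches(g, connectivity = 6), "4 or 8")
})

test_that("labeling partition equals an independent flood fill on random grids", {
  for (seed in 1:8) {
    g <- random_grid(50, 50, 0.4, seed = seed)
    for (conn in c(4, 8)) {
      ps <- label_patches(g, connectivity = conn)
      oracle <- flood_fill_labels(g$cells, conn)
      expect_true(same_partition(ps$labels, oracle))
      expect_equal(nrow(ps$patches), max(oracle))
    }
  }
})

test_that("patch set invariants hold: area accounting, id order, boundaries", {
  g <- random_grid(40, 40, 0.35, seed = 11)
  ps <- label_patches(g)
  # areas sum exactly to habitat area
  expect_identical(sum(ps$patches$area_km2), habitat_area_km2(g))
  # ids in decreasing area order
  expect_true(all(diff(ps$patches$area_km2) <= 0))
  expect_identical(ps$patches$patch_id, seq_len(nrow(ps$patches)))
  # every habitat cell labeled exactly once
  expect_identical(ps$labels > 0, g$cells == 1L)
  # single-cell patches are their own boundary
  singles <- ps$patches$patch_id[ps$patches$n_cells == 1]
  expect_true(all(singles %in% ps$boundary$patch_id))
  # labeling is idempotent: relabel the reconstructed mask
  mask <- habitat_grid((ps$labels > 0) + 0L)
  expect_true(same_partition(label_patches(mask)$labels, ps$labels))
})

test_that("tie-break rule: equal-area patches ordered by first row-major cell", {
  g <- habitat_grid(rbind(c(0, 0, 1), c(1, 0, 1), c(1, 0, 0)))
  ps <- label_patches(g, connectivity = 4)
  # both patches have 2 cells; the one whose first cell appears first in a
  # row-major scan (row 1, col 3) must get id 1
  expect_equal(ps$patches$area_km2, c(2, 2))
  expect_equal(ps$labels[1, 3], 1L)
  expect_equal(ps$labels[2, 1], 2L)
})

test_that("edge-to-edge distances follow the boundary-cell-center convention", {
  # two single-cell patches three columns apart
  g <- habitat_grid(matrix(c(1, 0, 0, 1), 1, 4))
  D <- min_edge_distances(label_patches(g, 4))
  expect_equal(D[1, 2], 3.0)
  expect_equal(diag(D), c(0, 0), ignore_attr = TRUE)

  # diagonal neighbors are distinct under 4-connectivity, sqrt(2) apart
  gd <- habitat_grid(rbind(c(1, 0), c(0, 1)))
  Dd <- min_edge_distances(label_patches(gd, 4))
  expect_equal(Dd[1, 2], sqrt(2))
})

test_that("distance matrix equals all-pairs brute force over boundary cells", {
  for (seed in c(3, 17, 29)) {
    g <- random_grid(40, 40, 0.25, seed = seed)
    ps <- label_patches(g)
    D <- min_edge_distances(ps)
    expect_true(isSymmetric(unname(D)))
    expect_true(all(D[upper.tri(D)] > 0))
    expect_equal(unname(D), brute_min_dist(ps), tolerance = 1e-12)
    # any single boundary-cell pair is an upper bound on the minimum
    first_bd <- ps$boundary[!duplicated(ps$boundary$patch_id), ]
    Db <- as.matrix(dist(first_bd[, c("x_km", "y_km")]))
    expect_true(all(D <= Db + 1e-9))
  }
})

test_that("bridging two patches never increases distance to third parties", {
  set.seed(21)
  g <- random_grid(30, 30, 0.2, seed = 77)
  ps <- label_patches(g)
  expect_gte(nrow(ps$patches), 3) # fixed seed guarantees third parties exist
  D0 <- min_edge_distances(ps)
  # bridge patches 1 and 2 along an L-shaped path between boundary cells
  b1 <- ps$boundary[ps$boundary$patch_id == 1, ][1, ]
  b2 <- ps$boundary[ps$boundary$patch_id == 2, ][1, ]
  cells <- g$cells
  cells[b1$row, min(b1$col, b2$col):max(b1$col, b2$col)] <- 1L
  cells[min(b1$row, b2$row):max(b1$row, b2$row), b2$col] <- 1L
  ps2 <- label_patches(habitat_grid(cells))
  D2 <- min_edge_distances(ps2)
  # map old patches to new ones via a shared cell
  old_to_new <- function(old_id) {
    cell <- which(ps$labels == old_id)[1]
    ps2$labels[cell]
  }
  merged <- old_to_new(1)
  expect_equal(merged, old_to_new(2)) # the bridge really merged them
  for (k in 3:nrow(ps$patches)) {
    nk <- old_to_new(k)
    if (nk == merged) next # bridge swallowed this patch too
    expect_lte(D2[merged, nk], min(D0[1, k], D0[2, k]) + 1e-9)
  }
})

test_that("minimum-patch-size filter drops and renumbers patches", {
  g <- habitat_grid(rbind(c(1, 1, 1, 0, 1), c(1, 1, 0, 0, 0),
                          c(0, 0, 0, 1, 1)))
  ps <- label_patches(g, 4)
  expect_equal(nrow(ps$patches), 3)
  f <- filter_patches(ps, min_area_km2 = 2)
  expect_equal(nrow(f$patches), 2)
  expect_equal(f$patches$patch_id, 1:2)
  expect_true(all(f$patches$area_km2 >= 2))
  expect_false(any(f$labels == 3))
})

test_that("patch tables and distance matrices export to CSV", {
  ps <- label_patches(random_grid(15, 15, 0.3, seed = 5))
  csv <- tempfile(fileext = ".csv")
  write_patch_table(ps, csv)
  tab <- read.csv(csv)
  expect_equal(tab$area_km2, ps$patches$area_km2)

  D <- min_edge_distances(ps)
  dcsv <- tempfile(fileext = ".csv")
  write_distance_csv(D, dcsv)
  back <- read.csv(dcsv)
  expect_equal(as.matrix(back[, -1]), unname(D), ignore_attr = TRUE)

  # round-trip through a representative-point patch table
  pt <- patch_set_from_table(data.frame(
    patch_id = 1:3, area_km2 = c(5, 1, 9),
    x_km = c(0, 10, 20), y_km = c(0, 0, 0)))
  expect_equal(pt$patches$area_km2, c(9, 5, 1)) # re-sorted by area
  expect_equal(min_edge_distances(pt)[1, 3], 10)
})
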