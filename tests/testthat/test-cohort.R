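# two landscapes of equal total habitat: one contiguous block vs a grid of
# scattered single cells
contiguous_grid <- function(n_cells = 30) {
  m <- matrix(0L, 12, 40)
  m[4:6, 3:12] <- 1L
  habitat_grid(m)
}

scattered_grid <- function(n_cells = 30) {
  m <- matrix(0L, 12, 40)
  pos <- expand.grid(row = seq(2, 11, by = 3), col = seq(2, 39, by = 3))
  pos <- pos[seq_len(n_cells), ]
  m[cbind(pos$row, pos$col)] <- 1L
  habitat_grid(m)
}

test_that("equal-area ranges differ by 10x in capacity when fragmented", {
  tbl <- tibble::tibble(
    species = c("one_big", "thirty_tiny"),
    iucn = c("LC", "LC"),
    grid = list(contiguous_grid(), scattered_grid())
  )
  out <- assess_cohort(tbl, kernel = dispersal_kernel("logsech", 2, 0.5),
                       cluster = FALSE)
  expect_equal(out$range_km2[1], out$range_km2[2])
  expect_gte(out$lambda_self[1] / out$lambda_self[2], 10)
})

test_that("cohorts are order-invariant, isolate failures, handle empties", {
  tbl <- tibble::tibble(
    species = c("a", "b", "c"),
    iucn = c("CR", "LC", "EN"),
    grid = list(contiguous_grid(), scattered_grid(),
                habitat_grid(matrix(0L, 5, 5)))
  )
  out1 <- assess_cohort(tbl)
  # zero-habitat species: range 0, lambda 0, no cluster
  expect_equal(out1$range_km2[3], 0)
  expect_equal(out1$lambda_self[3], 0)
  expect_true(is.na(out1$cluster[3]))

  # permuted input gives identical per-species records
  perm <- c(2, 3, 1)
  out2 <- assess_cohort(tbl[perm, ])
  expect_equal(
    dplyr::arrange(out2, species),
    dplyr::arrange(out1, species),
    ignore_attr = TRUE
  )

  # empty cohort: empty tibble, no error
  empty <- assess_cohort(tbl[0, ])
  expect_equal(nrow(empty), 0)

  # a failing species does not poison the rest
  bad <- tibble::tibble(species = c("ok", "broken"), iucn = c("LC", "LC"),
                        raster_path = c(tempfile(), "missing.asc"))
  write_esri_ascii(contiguous_grid(), bad$raster_path[1])
  # (give the real file an .asc name)
  asc <- paste0(bad$raster_path[1], ".asc")
  file.rename(bad$raster_path[1], asc); bad$raster_path[1] <- asc
  out3 <- assess_cohort(bad)
  expect_gt(out3$lambda_self[1], 0)
  expect_true(is.na(out3$lambda_self[2]))
  expect_match(out3$note[2], "does not exist")
})

test_that("unknown Red List codes map to NA and threatened is CR/EN/VU", {
  tbl <- tibble::tibble(
    species = letters[1:4],
    iucn = c("CR", "lc", "DD", "VU"),
    areas = list(4, 9, 16, 25)
  )
  out <- assess_cohort(tbl, cluster = FALSE)
  expect_equal(as.character(out$iucn), c("CR", "LC", NA, "VU"))
  expect_equal(out$threatened, c(TRUE, FALSE, FALSE, TRUE))
  # single-patch species via bare areas: lambda = A^(1+x)
  expect_equal(out$lambda_self, c(16, 81, 256, 625))
})

test_that("two-group split matches exhaustive enumeration of sorted splits", {
  cl <- cluster_capacities(c(-3.1, -3.0, -2.9, 1.9, 2.0, 2.1))
  expect_equal(as.character(cl$labels),
               c("low", "low", "low", "high", "high", "high"))
  expect_gt(cl$bimodality, 0.99)

  # brute-force oracle over all order-respecting 2-partitions
  set.seed(19)
  for (i in 1:10) {
    v <- rnorm(sample(4:12, 1))
    cl <- cluster_capacities(v)
    s <- sort(v)
    n <- length(s)
    wss <- sapply(seq_len(n - 1), function(k) {
      sum((s[1:k] - mean(s[1:k]))^2) +
        sum((s[(k + 1):n] - mean(s[(k + 1):n]))^2)
    })
    k_best <- which.min(wss)
    expect_equal(sum(cl$labels == "low"), k_best)
    expect_true(all(v[cl$labels == "low"] <= min(v[cl$labels == "high"])))
    expect_equal(cl$bimodality,
                 1 - min(wss) / sum((v - mean(v))^2), tolerance = 1e-12)
  }
})

test_that("cluster labels survive monotone transforms and degenerate input", {
  set.seed(23)
  v <- c(rnorm(10, -3, 0.4), rnorm(10, 2, 0.4))
  cl1 <- cluster_capacities(v)
  cl2 <- cluster_capacities(exp(v))     # strictly increasing transform
  expect_identical(cl1$labels, cl2$labels)

  deg <- cluster_capacities(c(5, 5, 5))
  expect_true(all(is.na(deg$labels)))
  expect_equal(deg$bimodality, 0)

  thr <- cluster_capacities(c(-2, -1, 3, 4), threshold = 0)
  expect_equal(as.character(thr$labels), c("low", "low", "high", "high"))
  expect_error(cluster_capacities(1), ">= 2")
  expect_error(cluster_capacities(c(1, NA)), "finite")
})

test_that("a strongly bimodal mixture is recovered almost perfectly", {
  set.seed(101)
  truth <- rep(c("low", "high"), each = 100)
  v <- c(rnorm(100, -3, 0.3), rnorm(100, 2, 0.3))
  cl <- cluster_capacities(v)
  expect_gte(mean(as.character(cl$labels) == truth), 0.99)
  expect_gt(cl$bimodality, 0.9)
})

test_that("omission rate arithmetic counts non-threatened cluster members", {
  rec <- tibble::tibble(
    species = paste0("s", 1:12),
    iucn = factor(c(rep("NT", 3), rep("LC", 2), rep("CR", 5), rep("EN", 2)),
                  levels = c("CR", "EN", "VU", "NT", "LC")),
    cluster = factor(c(rep("low", 10), "high", "high"),
                     levels = c("low", "high"))
  )
  om <- omission_rate(rec)
  expect_equal(om$n_group, 10)
  expect_equal(om$omission_rate, 0.5)
  expect_equal(om$n_nonthreatened + om$n_threatened, om$n_group)

  all_cr <- dplyr::mutate(rec, iucn = factor("CR", levels = levels(rec$iucn)))
  expect_equal(omission_rate(all_cr)$omission_rate, 0)
  expect_error(omission_rate(dplyr::mutate(rec, cluster = factor(NA, levels = c("low", "high")))),
               "empty")
})

test_that("slopegraph ranks agree with an independent sort oracle", {
  rec <- tibble::tibble(species = c("x", "y", "z"),
                        range_km2 = c(1, 2, 3),
                        lambda_self = c(3, 2, 1))
  rk <- slopegraph_ranks(rec)
  expect_equal(rk$rank_left, c(1, 2, 3))
  expect_equal(rk$rank_right, c(3, 2, 1))

  same <- tibble::tibble(species = c("x", "y"), range_km2 = c(5, 7),
                         lambda_self = c(5, 7))
  rk2 <- slopegraph_ranks(same)
  expect_equal(rk2$rank_left, rk2$rank_right)

  set.seed(29)
  rec3 <- tibble::tibble(species = paste0("s", 1:40),
                         range_km2 = rlnorm(40, 3, 2),
                         lambda_self = rlnorm(40, 1, 3))
  rk3 <- slopegraph_ranks(rec3)
  sort_rank <- function(v) { # independent: position in sorted order
    o <- order(v)
    r <- numeric(length(v)); r[o] <- seq_along(v); r
  }
  expect_equal(rk3$rank_left, sort_rank(rec3$range_km2))
  expect_equal(rk3$rank_right, sort_rank(rec3$lambda_self))
})

test_that("cohort plots build without evaluation errors", {
  tbl <- tibble::tibble(
    species = c("a", "b", "c"),
    iucn = c("CR", "LC", "EN"),
    grid = list(contiguous_grid(), scattered_grid(), contiguous_grid())
  )
  out <- assess_cohort(tbl)
  expect_s3_class(plot_capacity_histogram(out), "ggplot")
  expect_s3_class(plot_slopegraph(slopegraph_ranks(out)), "ggplot")
})
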