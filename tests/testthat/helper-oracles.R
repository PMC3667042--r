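# Independent oracles used across the suite. These deliberately re-derive
# results by the most literal method available (flood fill, all-pairs loops,
# plain power iteration) and stay independent of the package's code paths.

# stack-based flood fill over habitat cells
flood_fill_labels <- function(cells, connectivity) {
  nr <- nrow(cells); nc <- ncol(cells)
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8) {
    offs <- c(offs, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  }
  lab <- matrix(0L, nr, nc); cur <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (cells[r0, c0] == 1L && lab[r0, c0] == 0L) {
      cur <- cur + 1L
      stack <- list(c(r0, c0)); lab[r0, c0] <- cur
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (o in offs) {
          rr <- p[1] + o[1]; cc <- p[2] + o[2]
          if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
              cells[rr, cc] == 1L && lab[rr, cc] == 0L) {
            lab[rr, cc] <- cur
            stack[[length(stack) + 1]] <- c(rr, cc)
          }
        }
      }
    }
  }
  lab
}

# two labelings induce the same partition of habitat cells
same_partition <- function(lab_a, lab_b) {
  ha <- lab_a[lab_a > 0]; hb <- lab_b[lab_b > 0]
  if (length(ha) != length(hb)) return(FALSE)
  if (any((lab_a > 0) != (lab_b > 0))) return(FALSE)
  pairs <- unique(paste(ha, hb))
  length(pairs) == length(unique(ha)) &&
    length(pairs) == length(unique(hb))
}

# all-pairs minimum distance over every boundary-cell pair
brute_min_dist <- function(ps) {
  n <- nrow(ps$patches)
  bd <- split(ps$boundary[, c("x_km", "y_km")], ps$boundary$patch_id)
  D <- matrix(0, n, n)
  if (n < 2) return(D)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- bd[[as.character(i)]]; b <- bd[[as.character(j)]]
    best <- Inf
    for (u in seq_len(nrow(a))) {
      d2 <- (a$x_km[u] - b$x_km)^2 + (a$y_km[u] - b$y_km)^2
      best <- min(best, min(d2))
    }
    D[i, j] <- D[j, i] <- sqrt(best)
  }
  D
}

# plain normalized power iteration, Rayleigh-quotient estimate
power_oracle <- function(M, steps = 10000) {
  v <- rep(1, nrow(M)) + seq_len(nrow(M)) / nrow(M)
  for (k in seq_len(steps)) {
    w <- drop(M %*% v)
    nv <- sqrt(sum(w^2))
    if (nv == 0) return(list(lambda = 0, vector = v / sum(v)))
    v <- w / nv
  }
  list(lambda = sum(v * drop(M %*% v)) / sum(v * v),
       vector = abs(v) / sum(abs(v)))
}

random_grid <- function(nr, nc, p, seed) {
  set.seed(seed)
  habitat_grid(matrix(rbinom(nr * nc, 1, p), nr, nc))
}

# panel of synthetic landscapes reduced to (areas, dists), for the
# eigen-structure property suites
landscape_panel <- function(n, seed0 = 100, grid_shape = c(40, 40)) {
  fracs <- rep(c(0, 0.2, 0.5, 0.8, 0.95), length.out = n)
  growth <- rep(c(0L, 2L, 5L, 9L), length.out = n)
  lapply(seq_len(n), function(i) {
    spec <- landscape_spec(grid_shape, n_seeds = 10, growth_steps = growth[i],
                           big_patch_fraction = fracs[i], seed = seed0 + i)
    ps <- label_patches(generate_landscape(spec))
    list(areas = ps$patches$area_km2, dists = min_edge_distances(ps))
  })
}

# patch areas whose tie-merged cumulative points lie exactly on a log-log
# line of the requested slope: m equal smallest patches fix the intercept,
# then each further area solves C a^s = cum + a on the increasing branch
powerlaw_areas <- function(slope = 0.7, m = 10, n_extra = 5, a1 = 1) {
  C <- m * a1^(1 - slope)
  areas <- rep(a1, m)
  cum <- m * a1
  last <- a1
  for (k in seq_len(n_extra)) {
    f <- function(a) C * a^slope - a - cum
    hi <- if (slope < 1) {
      (slope * C)^(1 / (1 - slope)) # maximum of C a^s - a
    } else {
      h <- last * 2
      while (f(h) < 0) h <- h * 2
      h
    }
    a <- uniroot(f, c(last * (1 + 1e-12), hi), tol = 1e-12)$root
    for (it in 1:5) a <- a - f(a) / (slope * C * a^(slope - 1) - 1)
    areas <- c(areas, a)
    cum <- cum + a
    last <- a
  }
  areas
}
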