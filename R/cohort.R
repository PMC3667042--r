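IUCN_LEVELS <- c("CR", "EN", "VU", "NT", "LC")
IUCN_THREATENED <- c("CR", "EN", "VU")

normalize_iucn <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[!x %in% IUCN_LEVELS] <- NA_character_   # DD/NE/unknown -> NA, excluded
  factor(x, levels = IUCN_LEVELS)
}

#' Assess a cohort of species for fragmentation risk
#'
#' Runs the full per-species pipeline — patch extraction (when given grids),
#' range area, risk-threshold flags, cumulative-curve slope, and modified
#' metapopulation capacity — then clusters the cohort's log10 capacities
#' into low/high groups. Species failures are isolated: a species whose
#' input cannot be processed gets an `NA` row and a diagnostic message, and
#' the rest of the cohort is unaffected. A species with zero habitat gets
#' range 0, capacity 0 and no cluster label.
#'
#' @param species_tbl A data frame with a `species` column, optionally an
#'   `iucn` column (CR/EN/VU/NT/LC; anything else, e.g. DD/NE, becomes
#'   `NA`), and exactly one input column: `grid` (list of [habitat_grid]
#'   objects), `patches` (list of `patch_set` objects), `areas` (list of
#'   numeric patch-area vectors; capacity then needs `dists` too, so this
#'   form suits single-patch or precomputed cases), or `raster_path`
#'   (character paths readable by [read_habitat_grid()]).
#' @param x Extinction-area exponent (see [metapop_matrix()]).
#' @param kernel A [dispersal_kernel()].
#' @param connectivity Patch-labeling connectivity for raster inputs.
#' @param min_patch_km2 Optional minimum patch size filter (km^2).
#' @param thresholds Risk thresholds passed to [area_risk_flags()].
#' @param cluster Cluster the cohort's log10 capacities? Default `TRUE`.
#' @param cluster_threshold Optional fixed log10-capacity split; when given
#'   it replaces the data-driven two-group split.
#' @return A tibble with one row per species: `species`, `iucn`,
#'   `threatened`, `n_patches`, `range_km2`, `largest_patch_km2`,
#'   `lambda_self`, `lambda_classic`, `log10_lambda`, `loglog_slope`,
#'   `below_*` flags, `cluster` (`"low"`/`"high"`/`NA`) and `note`.
#'   Clustering diagnostics (split value, bimodality ratio) are attached as
#'   the `"cluster_info"` attribute.
#' @export
assess_cohort <- function(species_tbl, x = 1, kernel = dispersal_kernel(),
                          connectivity = 8, min_patch_km2 = NULL,
                          thresholds = c(harris_pimm = 11000, iucn_eoo = 20000),
                          cluster = TRUE, cluster_threshold = NULL) {
  species_tbl <- tibble::as_tibble(species_tbl)
  if (nrow(species_tbl) == 0) {
    out <- empty_cohort_row()[0, ]
    attr(out, "cluster_info") <- NULL
    return(out)
  }
  if (!"species" %in% names(species_tbl)) abort("`species_tbl` needs a `species` column.")
  input_col <- intersect(c("grid", "patches", "areas", "raster_path"),
                         names(species_tbl))
  if (length(input_col) != 1) {
    abort("`species_tbl` needs exactly one of: grid, patches, areas, raster_path.")
  }

  one <- function(i) {
    tryCatch({
      ps <- switch(input_col,
        grid = label_patches(species_tbl$grid[[i]], connectivity = connectivity),
        patches = species_tbl$patches[[i]],
        areas = NULL,
        raster_path = label_patches(
          read_habitat_grid(species_tbl$raster_path[[i]]),
          connectivity = connectivity)
      )
      if (!is.null(ps) && !is.null(min_patch_km2)) {
        ps <- filter_patches(ps, min_patch_km2)
      }
      areas <- if (is.null(ps)) as.numeric(species_tbl$areas[[i]]) else ps$patches$area_km2
      n <- length(areas)
      if (n == 0) {
        row <- empty_cohort_row()
      } else {
        cap <- if (is.null(ps)) {
          if (n > 1) abort("`areas` input supports single-patch species only; use `patches`.")
          metapop_capacity(areas, x = x, kernel = kernel)
        } else {
          metapop_capacity(ps, x = x, kernel = kernel)
        }
        curve <- cumulative_area_curve(areas)
        row <- tibble::tibble(
          n_patches = n,
          range_km2 = sum(areas),
          largest_patch_km2 = max(areas),
          lambda_self = cap$lambda_self,
          lambda_classic = cap$lambda_classic,
          log10_lambda = log10(cap$lambda_self),
          loglog_slope = curve$loglog_slope,
          note = NA_character_
        )
      }
      row
    }, error = function(e) {
      dplyr::mutate(empty_cohort_row(),
                    dplyr::across(dplyr::everything(), \(v) v[NA]),
                    note = conditionMessage(e))
    })
  }
  metrics <- purrr::map_dfr(seq_len(nrow(species_tbl)), one)

  out <- tibble::tibble(
    species = species_tbl$species,
    iucn = if ("iucn" %in% names(species_tbl)) {
      normalize_iucn(species_tbl$iucn)
    } else factor(NA_character_, levels = IUCN_LEVELS)
  )
  out$threatened <- out$iucn %in% IUCN_THREATENED
  out <- dplyr::bind_cols(out, metrics)
  flags <- area_risk_flags(dplyr::coalesce(out$range_km2, 0), thresholds)
  out <- dplyr::bind_cols(out, flags[, -1, drop = FALSE])

  out$cluster <- factor(NA_character_, levels = c("low", "high"))
  info <- NULL
  if (cluster) {
    ok <- is.finite(out$log10_lambda)
    if (sum(ok) >= 2) {
      cl <- cluster_capacities(out$log10_lambda[ok],
                               threshold = cluster_threshold)
      out$cluster[ok] <- cl$labels
      info <- cl[c("split_value", "bimodality")]
    }
  }
  attr(out, "cluster_info") <- info
  out
}

empty_cohort_row <- function() {
  tibble::tibble(
    n_patches = 0L, range_km2 = 0, largest_patch_km2 = 0,
    lambda_self = 0, lambda_classic = 0, log10_lambda = -Inf,
    loglog_slope = NA_real_, note = NA_character_
  )
}

#' Two-group split of log10 metapopulation capacities
#'
#' Partitions a cohort's capacities into "low" and "high" groups by the
#' exact, deterministic 1-D two-means split: every split point of the
#' sorted values is enumerated and the one minimizing the within-group sum
#' of squares wins. A bimodality diagnostic — the between-group share of
#' total sum of squares — is reported so callers can reject cohorts that
#' are not meaningfully bimodal (values near 1 mean two tight, well
#' separated modes; values near 0 mean the split is arbitrary). Because the
#' split respects sorted order, labels are invariant to any strictly
#' increasing transform of the values.
#'
#' @param values Numeric vector (log10 capacities; >= 2 finite values).
#' @param threshold Optional fixed split value: labels become
#'   `low` iff `values < threshold`, and the diagnostic still reflects the
#'   resulting grouping.
#' @return List: `labels` (factor `low`/`high`, same length/order as
#'   `values`; all `NA` when the values are all identical), `split_value`
#'   (midpoint between the groups), `bimodality` (between-SS / total-SS).
#' @examples
#' cluster_capacities(c(-3.1, -3, -2.9, 1.9, 2, 2.1))
#' @export
cluster_capacities <- function(values, threshold = NULL) {
  v <- as.numeric(values)
  if (length(v) < 2 || any(!is.finite(v))) {
    abort("Need >= 2 finite values to cluster.")
  }
  labels <- factor(rep(NA_character_, length(v)), levels = c("low", "high"))
  if (max(v) == min(v)) {
    return(list(labels = labels, split_value = NA_real_, bimodality = 0))
  }
  if (!is.null(threshold)) {
    low <- v < threshold
    if (all(low) || !any(low)) {
      return(list(labels = labels, split_value = threshold, bimodality = 0))
    }
    labels[] <- ifelse(low, "low", "high")
    tss <- sum((v - mean(v))^2)
    bss <- sum(low) * (mean(v[low]) - mean(v))^2 +
      sum(!low) * (mean(v[!low]) - mean(v))^2
    return(list(labels = labels, split_value = threshold,
                bimodality = bss / tss))
  }
  ord <- order(v)
  s <- sort(v)
  n <- length(s)
  cs <- cumsum(s); cs2 <- cumsum(s^2)
  k <- seq_len(n - 1)
  wss_left <- cs2[k] - cs[k]^2 / k
  wss_right <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  wss <- wss_left + wss_right
  best <- which.min(wss)
  labels[ord] <- rep(c("low", "high"), c(best, n - best))
  tss <- cs2[n] - cs[n]^2 / n
  list(labels = labels,
       split_value = (s[best] + s[best + 1]) / 2,
       bimodality = 1 - wss[best] / tss)
}

#' Omission rate of a capacity cluster
#'
#' Among the species in a cluster (typically the low-capacity, high-risk
#' group), the fraction that current Red List assessments class as
#' non-threatened (NT or LC) — the potential omission rate — together with
#' the complementary count of threatened species (CR/EN/VU) the cluster
#' captures. Species with no usable category are excluded from the
#' arithmetic.
#'
#' @param records A cohort tibble from [assess_cohort()] (needs `iucn` and
#'   `cluster` columns).
#' @param group Which cluster to evaluate (default `"low"`).
#' @return A one-row tibble: `group`, `n_group`, `n_nonthreatened`,
#'   `n_threatened`, `omission_rate`.
#' @export
omission_rate <- function(records, group = "low") {
  stopifnot(all(c("iucn", "cluster") %in% names(records)))
  g <- records[!is.na(records$cluster) & records$cluster == group &
                 !is.na(records$iucn), ]
  if (nrow(g) == 0) abort(sprintf("Cluster '%s' is empty (or has no Red List categories).", group))
  n_non <- sum(as.character(g$iucn) %in% c("NT", "LC"))
  n_thr <- sum(as.character(g$iucn) %in% IUCN_THREATENED)
  tibble::tibble(
    group = group, n_group = nrow(g),
    n_nonthreatened = n_non, n_threatened = n_thr,
    omission_rate = n_non / nrow(g)
  )
}

#' Slopegraph-ready paired ranks
#'
#' Ranks every species on two metrics — by default remaining range area on
#' the left and modified metapopulation capacity on the right — ascending,
#' so the species at greatest risk (smallest values) get rank 1 and sit at
#' the top of a slopegraph. Ties share their mean rank. Comparing the two
#' rank columns shows how accounting for fragmentation reorders a
#' fragmentation-blind area ranking.
#'
#' @param records A cohort tibble (>= 2 rows).
#' @param metric_left,metric_right Column names of the two metrics.
#' @return A tibble: `species`, `iucn`, the two metric values, `rank_left`,
#'   `rank_right`, `rank_shift` (`rank_right - rank_left`).
#' @export
slopegraph_ranks <- function(records, metric_left = "range_km2",
                             metric_right = "lambda_self") {
  stopifnot(nrow(records) >= 2,
            all(c(metric_left, metric_right) %in% names(records)))
  tibble::tibble(
    species = records$species,
    iucn = if ("iucn" %in% names(records)) records$iucn else NA,
    left_value = records[[metric_left]],
    right_value = records[[metric_right]],
    rank_left = rank(records[[metric_left]], ties.method = "average"),
    rank_right = rank(records[[metric_right]], ties.method = "average")
  ) |>
    dplyr::mutate(rank_shift = .data$rank_right - .data$rank_left)
}

#' Capacity histogram for a cohort, colored by Red List category
#'
#' @param records A cohort tibble from [assess_cohort()].
#' @param bins Histogram bin count.
#' @return A ggplot: distribution of log10 capacity, filled by category.
#' @export
plot_capacity_histogram <- function(records, bins = 20) {
  dat <- records[is.finite(records$log10_lambda), ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$log10_lambda, fill = .data$iucn)) +
    ggplot2::geom_histogram(bins = bins, colour = "grey30", linewidth = 0.2) +
    ggplot2::scale_fill_manual(
      values = c(CR = "#d73027", EN = "#fc8d59", VU = "#91cf60",
                 NT = "#4575b4", LC = "#bdbdbd"),
      na.value = "white", drop = FALSE, name = "Red List") +
    ggplot2::labs(x = expression(log[10] ~ "metapopulation capacity"),
                  y = "Species") +
    ggplot2::theme_minimal()
}

#' Slopegraph of range-area rank vs capacity rank
#'
#' @param ranks A tibble from [slopegraph_ranks()].
#' @return A ggplot slopegraph; species at greater risk at the top.
#' @export
plot_slopegraph <- function(ranks) {
  long <- tidyr::pivot_longer(ranks, c("rank_left", "rank_right"),
                              names_to = "side", values_to = "rank")
  long$side <- factor(long$side, levels = c("rank_left", "rank_right"),
                      labels = c("Range area", "Metapop. capacity"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$side, y = .data$rank,
                                     group = .data$species,
                                     colour = .data$iucn)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_manual(
      values = c(CR = "#d73027", EN = "#fc8d59", VU = "#91cf60",
                 NT = "#4575b4", LC = "#bdbdbd"),
      na.value = "grey70", drop = FALSE, name = "Red List") +
    ggplot2::labs(x = NULL, y = "Rank (1 = highest risk)") +
    ggplot2::theme_minimal()
}
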