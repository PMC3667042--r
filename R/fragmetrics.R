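#' Total remaining range area
#'
#' The simplest fragmentation-blind metric: the summed area of all habitat
#' patches in a species' range.
#'
#' @param patches A `patch_set`, or a numeric vector of patch areas (km^2).
#' @return Total area in km^2 (0 for an empty patch set).
#' @export
total_range_area <- function(patches) {
  areas <- if (inherits(patches, "patch_set")) patches$patches$area_km2 else as.numeric(patches)
  sum(areas)
}

#' Flag a range area against risk thresholds
#'
#' Compares a (habitat-trimmed) range area against two screening thresholds
#' used in extinction-risk assessment: 11,000 km^2, below which species with
#' habitat-trimmed ranges were proposed to be at particular risk, and the
#' 20,000 km^2 Extent-of-Occurrence threshold below which the IUCN regards a
#' species as likely threatened. Flags use a strict `<`, so a species
#' exactly at a threshold is not flagged; thresholds are configurable.
#'
#' @param area_km2 Range areas (km^2), >= 0. Vectorized.
#' @param thresholds Named list/vector of thresholds in km^2.
#' @return A tibble with `area_km2` and one logical column per threshold
#'   (`below_<name>`).
#' @examples
#' area_risk_flags(c(10999, 11000, 15000))
#' @export
area_risk_flags <- function(area_km2,
                            thresholds = c(harris_pimm = 11000, iucn_eoo = 20000)) {
  if (any(area_km2 < 0)) abort("Areas must be >= 0.")
  out <- tibble::tibble(area_km2 = as.numeric(area_km2))
  for (nm in names(thresholds)) {
    out[[paste0("below_", nm)]] <- area_km2 < thresholds[[nm]]
  }
  out
}

#' Cumulative size-ranked fragment-area curve
#'
#' For patches sorted by increasing area, plots the cumulative total area
#' contained in patches up to a given size against that size. Patches of
#' identical area are merged into a single point at the cumulative total
#' through that area, keeping the curve a function of area. The right-most
#' point is always (largest fragment, total area). On log-log axes the
#' curve is typically near-linear and an ordinary least-squares fit of
#' log10(cumulative area) on log10(area) summarizes it: the shallower the
#' slope, the more of the range sits in small fragments — but note that
#' adding tiny patches *raises* the curve's left end and *lowers* the
#' slope, which is why this metric can misleadingly rank the most
#' fragmented ranges as least at risk.
#'
#' @param areas Patch areas in km^2 (all > 0, n >= 1), or a `patch_set`.
#' @return A `cum_area_curve`: list with `points` (tibble `area_km2`,
#'   `cum_area_km2`), `loglog_slope`, `loglog_intercept`, `r_squared`
#'   (all `NA` when fewer than 2 distinct areas), `largest_patch_km2`,
#'   `total_area_km2`.
#' @examples
#' cumulative_area_curve(c(1, 2, 3, 10))$points
#' @export
cumulative_area_curve <- function(areas) {
  if (inherits(areas, "patch_set")) areas <- areas$patches$area_km2
  areas <- as.numeric(areas)
  if (length(areas) == 0) abort("Need at least one patch area.")
  if (any(areas <= 0)) abort("All areas must be > 0.")
  a <- sort(areas)
  cum <- cumsum(a)
  pts <- tibble::tibble(area_km2 = a, cum_area_km2 = cum) |>
    dplyr::group_by(.data$area_km2) |>
    dplyr::summarise(cum_area_km2 = max(.data$cum_area_km2), .groups = "drop")
  slope <- intercept <- r2 <- NA_real_
  if (nrow(pts) >= 2) {
    fit <- lm(log10(cum_area_km2) ~ log10(area_km2), data = pts)
    slope <- unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
    y <- log10(pts$cum_area_km2)
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }
  structure(
    list(points = pts, loglog_slope = slope, loglog_intercept = intercept,
         r_squared = r2, largest_patch_km2 = max(a), total_area_km2 = sum(a),
         n_patches = length(a)),
    class = "cum_area_curve"
  )
}

#' @export
print.cum_area_curve <- function(x, ...) {
  cat(sprintf(
    "<cum_area_curve> %d patches, total %.6g km^2, largest %.6g km^2\n",
    x$n_patches, x$total_area_km2, x$largest_patch_km2))
  if (is.finite(x$loglog_slope)) {
    cat(sprintf("  log-log slope %.4f (R^2 = %.4f)\n", x$loglog_slope, x$r_squared))
  } else {
    cat("  log-log slope undefined (< 2 distinct areas)\n")
  }
  invisible(x)
}

#' @rdname cumulative_area_curve
#' @param x A `cum_area_curve`.
#' @param ... Unused.
#' @export
tidy.cum_area_curve <- function(x, ...) x$points

#' @rdname cumulative_area_curve
#' @export
glance.cum_area_curve <- function(x, ...) {
  tibble::tibble(
    n_patches = x$n_patches,
    total_area_km2 = x$total_area_km2,
    largest_patch_km2 = x$largest_patch_km2,
    loglog_slope = x$loglog_slope,
    loglog_intercept = x$loglog_intercept,
    r_squared = x$r_squared
  )
}

#' Plot a cumulative fragment-area curve on log-log axes
#'
#' @param object A `cum_area_curve`.
#' @param ... Unused.
#' @return A ggplot of cumulative area vs patch area (log10 axes) with the
#'   fitted line when defined.
#' @export
autoplot.cum_area_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object$points,
                       ggplot2::aes(x = .data$area_km2, y = .data$cum_area_km2)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Fragment area (km²)",
                  y = "Cumulative area in fragments this size or smaller (km²)") +
    ggplot2::theme_minimal()
  if (is.finite(object$loglog_slope)) {
    p <- p + ggplot2::geom_abline(slope = object$loglog_slope,
                                  intercept = object$loglog_intercept,
                                  linetype = 2, colour = "grey40")
  }
  p
}

#' Export a cumulative curve as CSV / JSON summary
#'
#' @param curve A `cum_area_curve`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_curve <- function(curve, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(curve, "cum_area_curve"))
  if (!is.null(csv_path)) {
    utils::write.csv(curve$points, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      abort("JSON export requires the 'jsonlite' package.")
    }
    jsonlite::write_json(as.list(glance(curve)), json_path,
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(c(csv_path, json_path))
}
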