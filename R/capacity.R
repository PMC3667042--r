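#' Build the metapopulation matrix M
#'
#' Elementwise \eqn{m_{ij} = A_i^x \, f(D_{ij}) \, A_j}, where \eqn{A} is
#' patch area (km^2), \eqn{x} scales extinction probability to area and
#' \eqn{f} is the dispersal survival function. With `self_colonization =
#' TRUE` the diagonal is retained as \eqn{m_{ii} = A_i^{x+1}} (since
#' \eqn{f(0) = 1}), so a patch contributes to its own recolonization — the
#' within-patch rescue effect that large patches enjoy. With it off the
#' diagonal is zeroed, recovering the classical capacity matrix.
#'
#' The alternative exponent placement \eqn{A_j^x f(D_{ij}) A_i} is the
#' transpose of this matrix and therefore has the same spectrum; the choice
#' is immaterial for the capacity.
#'
#' @param areas_km2 Strictly positive patch areas.
#' @param dists Symmetric distance matrix (km), zero diagonal, conformable
#'   with `areas_km2`.
#' @param x Extinction-area scaling exponent, >= 0. Default 1 (extinction
#'   risk proportional to 1/area).
#' @param kernel A [dispersal_kernel()], or any function mapping distances
#'   to survival probabilities with `f(0) = 1`.
#' @param self_colonization Keep the diagonal? Default `TRUE`.
#' @return An `n x n` nonnegative matrix.
#' @export
metapop_matrix <- function(areas_km2, dists, x = 1,
                           kernel = dispersal_kernel(),
                           self_colonization = TRUE) {
  areas_km2 <- as.numeric(areas_km2)
  n <- length(areas_km2)
  if (any(areas_km2 <= 0)) abort("All patch areas must be > 0.")
  if (!is.numeric(x) || length(x) != 1 || x < 0) abort("`x` must be a single number >= 0.")
  dists <- as.matrix(dists)
  if (!all(dim(dists) == n)) abort("`dists` must be n x n, conformable with `areas_km2`.")
  f <- if (is.function(kernel)) kernel(dists) else survival_kernel(dists, kernel)
  M <- (areas_km2^x) * f * rep(areas_km2, each = n)
  dim(M) <- c(n, n)
  if (!self_colonization) diag(M) <- 0
  M
}

#' Leading eigenvalue and eigenvector of a nonnegative matrix
#'
#' The spectral radius and its Perron eigenvector (entrywise nonnegative,
#' normalized to sum 1). The metapopulation matrix is diagonally similar to
#' a symmetric matrix, so the `"dense"` method detects that structure and
#' solves the symmetric problem exactly; `"power"` is an independent
#' power-iteration route kept for cross-validation and for very large
#' sparse-feeling problems.
#'
#' @param M Nonnegative square matrix (may be `0 x 0`).
#' @param method `"dense"` (base `eigen`) or `"power"` (power iteration).
#' @param tol,max_iter Convergence control for the power method.
#' @return List with `lambda` (spectral radius; 0 for an empty matrix) and
#'   `vector` (nonnegative, sums to 1; empty for an empty matrix).
#' @export
leading_eigen <- function(M, method = c("dense", "power"),
                          tol = 1e-13, max_iter = 100000L) {
  method <- match.arg(method)
  M <- as.matrix(M)
  n <- nrow(M)
  if (n == 0) return(list(lambda = 0, vector = numeric(0)))
  if (any(!is.finite(M))) abort("Matrix entries must be finite.")
  if (any(M < 0)) abort("Matrix entries must be nonnegative.")
  if (ncol(M) != n) abort("Matrix must be square.")
  if (all(M == 0)) return(list(lambda = 0, vector = rep(1 / n, n)))

  if (method == "power") {
    # shift by sigma so the Perron root of M + sigma*I is strictly largest
    # in modulus; without it, zero-diagonal two-patch matrices oscillate
    sigma <- max(rowSums(M))
    v <- rep(1 / n, n)
    lambda <- 0
    for (i in seq_len(max_iter)) {
      w <- drop(M %*% v) + sigma * v
      s <- sum(w)
      if (s == 0) return(list(lambda = 0, vector = rep(1 / n, n)))
      w <- w / s
      if (max(abs(w - v)) < tol && i > 5) {
        v <- w; lambda <- s - sigma; break
      }
      v <- w; lambda <- s - sigma
    }
    return(list(lambda = lambda, vector = v / sum(v)))
  }

  if (isSymmetric(M, tol = 1e-10)) {
    e <- eigen((M + t(M)) / 2, symmetric = TRUE)
    lambda <- e$values[1]
    v <- e$vectors[, 1]
  } else {
    e <- eigen(M)
    k <- which.max(Mod(e$values))
    lambda <- Re(e$values[k])
    v <- Re(e$vectors[, k])
  }
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)
  list(lambda = lambda, vector = v / sum(v))
}

#' Metapopulation capacity of a patch network
#'
#' The headline metric: the leading eigenvalue \eqn{\lambda} of the
#' metapopulation matrix built from patch areas and inter-patch dispersal
#' survival. With self-colonization on (the default) this is the modified
#' capacity \eqn{\lambda_{self}}; with it off, the classical capacity.
#' Units are relative ("Levins patch equivalents"), so the value is most
#' useful as a peer-group comparison across species or landscapes, not an
#' absolute persistence probability.
#'
#' The leading eigenvector gives each patch's relative contribution to
#' capacity. Degenerate inputs behave sensibly: zero patches give
#' \eqn{\lambda = 0}; a single patch with self-colonization gives exactly
#' \eqn{A^{1+x}}.
#'
#' @param patches A `patch_set` (from [label_patches()] or
#'   [patch_set_from_table()]), or a numeric vector of patch areas in km^2
#'   (then `dists` is required unless there is at most one patch).
#' @param dists Optional precomputed distance matrix (km); computed with
#'   [min_edge_distances()] from a `patch_set` when missing.
#' @inheritParams metapop_matrix
#' @param both_variants Also compute the other diagonal variant so the
#'   result carries `lambda_self` and `lambda_classic` side by side.
#' @return A `capacity_result`: list with `lambda`, `variant`, `vector`
#'   (per-patch contributions, sums to 1), `n_patches`, `areas_km2`,
#'   `lambda_self`/`lambda_classic` (when `both_variants`), and the
#'   parameters used.
#' @examples
#' metapop_capacity(4, x = 0.5)$lambda # single 4 km^2 patch: 4^1.5 = 8
#' @export
metapop_capacity <- function(patches, dists = NULL, x = 1,
                             kernel = dispersal_kernel(),
                             self_colonization = TRUE,
                             both_variants = TRUE) {
  if (inherits(patches, "patch_set")) {
    areas <- patches$patches$area_km2
    if (is.null(dists) && length(areas) > 0) dists <- min_edge_distances(patches)
  } else {
    areas <- as.numeric(patches)
  }
  n <- length(areas)
  if (n == 0) {
    res <- list(lambda = 0, variant = if (self_colonization) "self" else "classic",
                vector = numeric(0), n_patches = 0L, areas_km2 = numeric(0),
                lambda_self = 0, lambda_classic = 0,
                x = x, kernel = kernel, self_colonization = self_colonization)
    return(structure(res, class = "capacity_result"))
  }
  if (is.null(dists)) {
    if (n > 1) abort("Supply `dists` when giving bare areas for > 1 patch.")
    dists <- matrix(0, 1, 1)
  }
  solve_variant <- function(self) {
    M <- metapop_matrix(areas, dists, x = x, kernel = kernel,
                        self_colonization = self)
    leading_eigen(M)
  }
  main <- solve_variant(self_colonization)
  res <- list(
    lambda = main$lambda,
    variant = if (self_colonization) "self" else "classic",
    vector = main$vector,
    n_patches = n,
    areas_km2 = areas,
    x = x, kernel = kernel, self_colonization = self_colonization
  )
  if (both_variants) {
    other <- solve_variant(!self_colonization)
    if (self_colonization) {
      res$lambda_self <- main$lambda; res$lambda_classic <- other$lambda
    } else {
      res$lambda_self <- other$lambda; res$lambda_classic <- main$lambda
    }
  }
  structure(res, class = "capacity_result")
}

#' @export
print.capacity_result <- function(x, ...) {
  cat(sprintf("<capacity_result> lambda_%s = %.6g over %d patches\n",
              x$variant, x$lambda, x$n_patches))
  if (!is.null(x$lambda_classic) && x$variant == "self") {
    cat(sprintf("  (classic lambda = %.6g)\n", x$lambda_classic))
  }
  invisible(x)
}

#' Tidy a capacity result into per-patch contributions
#'
#' @param x A `capacity_result`.
#' @param ... Unused.
#' @return A tibble with one row per patch: `patch_id`, `area_km2`,
#'   `contribution` (leading-eigenvector weight, sums to 1).
#' @export
tidy.capacity_result <- function(x, ...) {
  tibble::tibble(
    patch_id = seq_len(x$n_patches),
    area_km2 = x$areas_km2,
    contribution = x$vector
  )
}

#' One-row summary of a capacity result
#'
#' @inheritParams tidy.capacity_result
#' @return A one-row tibble: `n_patches`, `range_km2`, `largest_patch_km2`,
#'   `lambda_self`, `lambda_classic`, `log10_lambda_self`, `x`.
#' @export
glance.capacity_result <- function(x, ...) {
  tibble::tibble(
    n_patches = x$n_patches,
    range_km2 = sum(x$areas_km2),
    largest_patch_km2 = if (x$n_patches) max(x$areas_km2) else 0,
    lambda_self = x$lambda_self %||% if (x$variant == "self") x$lambda else NA_real_,
    lambda_classic = x$lambda_classic %||% if (x$variant == "classic") x$lambda else NA_real_,
    log10_lambda_self = log10(x$lambda_self %||% x$lambda),
    x = x$x
  )
}

#' Plot per-patch contributions to metapopulation capacity
#'
#' @param object A `capacity_result`.
#' @param ... Unused.
#' @return A ggplot: patch area vs contribution to the leading eigenvector.
#' @export
autoplot.capacity_result <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$area_km2, y = .data$contribution)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Patch area (km², log scale)",
                  y = "Contribution to leading eigenvector",
                  title = sprintf("Metapopulation capacity λ = %.4g (%s)",
                                  object$lambda, object$variant)) +
    ggplot2::theme_minimal()
}
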