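#' Penalized spline smooth of alr cover against an environmental gradient
#'
#' Fits a thin-plate regression spline with the smoothing penalty selected
#' by generalized cross-validation (mgcv, `method = "GCV.Cp"`), normal
#' errors and identity link — the standard smooth for alr-transformed cover
#' against depth, substrate slope or light. The basis dimension defaults to
#' `k = 10`; surveys with few distinct covariate levels cap it (e.g. `k = 7`
#' when only seven sampling depths exist). If `x` has fewer distinct values
#' than `k`, the basis is reduced with a warning.
#'
#' @param x Covariate vector (depth in m, slope in degrees, light, ...).
#' @param y alr-transformed cover vector.
#' @param k Basis dimension (number of knots) of the thin-plate spline.
#' @return Object of class `smooth_fit`: the mgcv fit plus `edf`,
#'   `gcv`, `sp` (selected penalty) and the data range.
#' @export
fit_smooth <- function(x, y, k = 10) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n_distinct <- length(unique(x))
  if (n_distinct < 3) abort("Need at least 3 distinct covariate values")
  if (n_distinct < k) {
    warn(sprintf("Only %d distinct covariate values: reducing basis dimension from %d",
                 n_distinct, k))
    k <- n_distinct
  }
  if (length(x) <= k) abort("Need more observations than basis functions")
  df <- data.frame(x = x, y = y)
  g <- mgcv::gam(y ~ s(x, k = k, bs = "tp"), data = df, method = "GCV.Cp")
  structure(list(
    gam = g,
    k = k,
    edf = sum(summary(g)$edf),
    gcv = g$gcv.ubre,
    sp = g$sp,
    x_range = range(x),
    n = length(x)
  ), class = "smooth_fit")
}

#' @export
print.smooth_fit <- function(x, ...) {
  cat(sprintf("Thin-plate smooth: n = %d, k = %d, EDF = %.2f, GCV = %.4f\n",
              x$n, x$k, x$edf, x$gcv))
  invisible(x)
}

#' @rdname fit_smooth
#' @param x,object A `smooth_fit`.
#' @param ... Unused.
#' @method glance smooth_fit
#' @export
glance.smooth_fit <- function(x, ...) {
  tibble(n = x$n, k = x$k, edf = x$edf, gcv = unname(x$gcv),
         sp = unname(x$sp))
}

#' Evaluate a fitted smooth with 95% confidence band
#'
#' Pointwise fitted values plus/minus 1.96 standard errors from the
#' penalized-fit covariance, on the alr scale. Grid points outside the
#' observed covariate range are flagged as extrapolation.
#'
#' @param fit A `smooth_fit`.
#' @param grid Covariate values at which to evaluate.
#' @return Tibble: `x`, `fit`, `se`, `ci_lower`, `ci_upper`,
#'   `extrapolated`.
#' @export
predict_curve <- function(fit, grid) {
  stopifnot(inherits(fit, "smooth_fit"))
  pr <- predict(fit$gam, newdata = data.frame(x = grid), se.fit = TRUE)
  outside <- grid < fit$x_range[1] | grid > fit$x_range[2]
  tibble(
    x = grid,
    fit = as.numeric(pr$fit),
    se = as.numeric(pr$se.fit),
    ci_lower = as.numeric(pr$fit - 1.96 * pr$se.fit),
    ci_upper = as.numeric(pr$fit + 1.96 * pr$se.fit),
    extrapolated = outside
  )
}

#' Back-transform fitted alr curves to percent-cover curves
#'
#' Evaluates each per-taxon smooth (and optionally the total-cover smooth)
#' on a shared grid, applies the inverse alr across taxa plus the coral-free
#' base, normalizes each grid point to 100%, and zeroes covers below 0.25%
#' (half the recording error) without re-normalizing. The total fit is
#' back-transformed as the two-part total/other case.
#'
#' @param taxon_fits Named list of `smooth_fit` objects, one per taxon in
#'   [reef_taxa()].
#' @param grid Shared covariate grid.
#' @param total_fit Optional `smooth_fit` for alr total cover.
#' @param floor_percent Zeroing threshold after normalization.
#' @return Long tibble: `x`, `part` (taxa, `other_benthic`, optionally
#'   `total`), `percent`.
#' @export
back_transform_curves <- function(taxon_fits, grid, total_fit = NULL,
                                  floor_percent = 0.25) {
  taxa <- reef_taxa()
  miss <- setdiff(taxa, names(taxon_fits))
  if (length(miss)) {
    abort(sprintf("Missing smooth fit for taxa: %s", paste(miss, collapse = ", ")))
  }
  alr_mat <- vapply(taxa, function(t) predict_curve(taxon_fits[[t]], grid)$fit,
                    numeric(length(grid)))
  pct <- inverse_alr(alr_mat, floor_percent = floor_percent)
  out <- as_tibble(pct) |>
    mutate(x = grid) |>
    tidyr::pivot_longer(-"x", names_to = "part", values_to = "percent")
  if (!is.null(total_fit)) {
    tot_alr <- predict_curve(total_fit, grid)$fit
    tot_pct <- inverse_alr(cbind(total = tot_alr), floor_percent = floor_percent)
    out <- bind_rows(out, tibble(x = grid, part = "total",
                                 percent = tot_pct[, "total"]))
  }
  out
}
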