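#' Multiplicative zero replacement for closed compositions
#'
#' Percent cover is recorded to the nearest 1%, so a recorded zero is known
#' only to be below half the rounding error. Zeros are replaced by
#' `delta = 0.0025` (0.25% on the proportion scale) and, under the
#' multiplicative variant, the nonzero parts are shrunk by `(1 - k * delta)`
#' (`k` = number of zeros replaced) so the composition stays closed and the
#' ratios among nonzero parts are preserved. A naive variant that substitutes
#' without rescaling is available for comparison.
#'
#' @param parts Numeric vector (a single composition summing to 1) or a
#'   samples-by-parts matrix of row compositions.
#' @param delta Replacement value on the proportion scale.
#' @param method `"multiplicative"` (default) or `"naive"`.
#' @return Object of the same shape with strictly positive parts.
#' @examples
#' replace_zeros(c(0.5, 0.5, 0))
#' @export
replace_zeros <- function(parts, delta = 0.0025,
                          method = c("multiplicative", "naive")) {
  method <- match.arg(method)
  if (is.matrix(parts) || is.data.frame(parts)) {
    m <- as.matrix(parts)
    out <- t(apply(m, 1, replace_zeros, delta = delta, method = method))
    dimnames(out) <- dimnames(m)
    return(out)
  }
  if (any(parts < 0)) abort("Composition parts must be nonnegative")
  z <- parts == 0
  if (!any(z)) return(parts)
  nz_min <- min(parts[!z])
  if (delta >= nz_min) {
    abort(sprintf(
      "delta (%g) must be below the smallest nonzero part (%g): replacement would invert ordering",
      delta, nz_min))
  }
  out <- parts
  out[z] <- delta
  if (method == "multiplicative") {
    out[!z] <- parts[!z] * (1 - sum(z) * delta)
  }
  out
}

#' Close percent covers into a strictly positive composition
#'
#' Divides percent covers by 100 and appends the coral-free base
#' (`other_benthic`) as `1 - sum(parts)`; zeros (including a zero base when
#' the taxa already sum to 100%) are then replaced via [replace_zeros()].
#' Pass the seven taxon covers for the per-taxon composition, or a single
#' `total` cover for the two-part total/other composition.
#'
#' @param taxon_percents Named numeric vector of percent covers in
#'   `[0, 100]` (any subset naming; a single unnamed value is labelled
#'   `total`).
#' @param delta,method Passed to [replace_zeros()].
#' @return Named numeric composition summing to 1, last part
#'   `other_benthic`.
#' @examples
#' close_composition(c(acropora = 25))
#' @export
close_composition <- function(taxon_percents, delta = 0.0025,
                              method = c("multiplicative", "naive")) {
  method <- match.arg(method)
  x <- taxon_percents
  if (is.null(names(x))) {
    names(x) <- if (length(x) == 1) "total" else
      reef_taxa()[seq_along(x)]
  }
  if (anyNA(x)) abort("Cannot close a composition with missing covers")
  if (any(x < 0 | x > 100)) abort("Percent covers must lie in [0, 100]")
  s <- sum(x)
  if (s > 100 + 1e-9) {
    abort(sprintf("Covers sum to %.4f%% > 100%%", s))
  }
  parts <- c(x, other_benthic = max(0, 100 - s)) / 100
  parts <- parts / sum(parts)
  replace_zeros(parts, delta = delta, method = method)
}

#' Additive log-ratio transform against the coral-free base
#'
#' `alr(t) = log(part(t) / part(other_benthic))`, removing the constant-sum
#' constraint so cover can be modelled on an unconstrained scale.
#'
#' @param comp Named composition from [close_composition()] (denominator
#'   part named by `denom`), or a matrix of row compositions.
#' @param denom Name of the denominator part.
#' @return Named numeric vector (or matrix) of log ratios, denominator
#'   dropped.
#' @export
alr_transform <- function(comp, denom = "other_benthic") {
  if (is.matrix(comp) || is.data.frame(comp)) {
    m <- as.matrix(comp)
    out <- t(apply(m, 1, alr_transform, denom = denom))
    rownames(out) <- rownames(m)
    return(out)
  }
  if (!denom %in% names(comp)) {
    abort(sprintf("Denominator part '%s' not found", denom))
  }
  if (any(comp <= 0)) {
    abort("All parts must be strictly positive; apply replace_zeros() first")
  }
  log(comp[setdiff(names(comp), denom)] / comp[[denom]])
}

#' Inverse additive log-ratio back to percent cover
#'
#' Parts are proportional to `exp(coord)` with the denominator part
#' proportional to 1; all parts are normalized to sum to 100%. Optionally,
#' any normalized cover below half the recording error (0.25%) is set to 0%
#' with no re-normalization — the flooring used when back-transforming
#' fitted response curves.
#'
#' @param coords Named numeric vector of alr coordinates (or matrix with one
#'   row per observation).
#' @param floor_percent Covers below this are zeroed after normalization;
#'   `NULL` disables flooring (exact round-trip of [alr_transform()]).
#' @param denom Name given to the denominator part in the output.
#' @return Named numeric vector (or matrix) of percents summing to 100
#'   before flooring.
#' @export
inverse_alr <- function(coords, floor_percent = NULL, denom = "other_benthic") {
  if (is.matrix(coords) || is.data.frame(coords)) {
    m <- as.matrix(coords)
    out <- t(apply(m, 1, inverse_alr, floor_percent = floor_percent, denom = denom))
    rownames(out) <- rownames(m)
    return(out)
  }
  if (any(!is.finite(coords))) abort("alr coordinates must be finite")
  e <- c(exp(coords), 1)
  names(e) <- c(names(coords), denom)
  pct <- 100 * e / sum(e)
  if (!is.null(floor_percent)) {
    pct[pct < floor_percent] <- 0
  }
  pct
}

#' Robust centred log-ratio transform of a cover matrix
#'
#' Each row (sample) is log-transformed and centred by its row mean of logs.
#' Zero replacement is assumed to have been applied already, so every part
#' is strictly positive and all parts enter the centring. Euclidean distance
#' between rclr rows is the robust Aitchison distance used for ordination.
#'
#' @param cover_matrix Samples-by-parts matrix or data frame of nonnegative
#'   covers (any constant row scale; log-ratios are scale invariant).
#' @return Matrix of the same shape; rows sum to zero.
#' @export
rclr_transform <- function(cover_matrix) {
  m <- as.matrix(cover_matrix)
  if (any(rowSums(m) == 0)) {
    abort("Row(s) of all zeros cannot be log-ratio transformed")
  }
  if (any(m <= 0)) {
    abort("All parts must be strictly positive; apply replace_zeros() first")
  }
  lm_ <- log(m)
  sweep(lm_, 1, rowMeans(lm_))
}

#' Close and alr-transform a resolved survey table
#'
#' Convenience pipeline step: for each record with complete covers, closes
#' the seven-taxon composition (and the two-part total/other composition),
#' applies zero replacement, and returns the alr coordinates alongside the
#' record metadata.
#'
#' @param resolved Tibble from [resolve_survey()].
#' @param delta,method Passed to [replace_zeros()].
#' @return Tibble with one row per complete record: metadata columns,
#'   `alr_<taxon>` coordinates and `alr_total`.
#' @export
cover_to_alr <- function(resolved, delta = 0.0025,
                         method = c("multiplicative", "naive")) {
  method <- match.arg(method)
  taxa <- reef_taxa()
  keep <- complete.cases(resolved[, c("total", taxa)])
  df <- resolved[keep, , drop = FALSE]
  alr_taxa <- t(vapply(seq_len(nrow(df)), function(i) {
    comp <- close_composition(setNames(as.numeric(df[i, taxa]), taxa),
                              delta = delta, method = method)
    alr_transform(comp)
  }, numeric(length(taxa))))
  colnames(alr_taxa) <- paste0("alr_", taxa)
  alr_total <- vapply(seq_len(nrow(df)), function(i) {
    comp <- close_composition(c(total = df$total[i]), delta = delta, method = method)
    as.numeric(alr_transform(comp))
  }, numeric(1))
  bind_cols(df |> select(-dplyr::all_of(c(taxa, "total"))),
            tibble(total = df$total), as_tibble(alr_taxa),
            tibble(alr_total = alr_total))
}
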