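#' Robust Aitchison distance between cover samples
#'
#' Euclidean distance between the rows of the robust centred log-ratio
#' transform ([rclr_transform()]) of the cover matrix. Zero replacement is
#' expected to have been applied upstream (composition pipeline), so all
#' parts are strictly positive.
#'
#' @param cover_matrix Samples-by-parts matrix/data frame of strictly
#'   positive covers; row names are sample ids.
#' @return A `dist` object with sample labels.
#' @export
robust_aitchison_dist <- function(cover_matrix) {
  dist(rclr_transform(cover_matrix))
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Kruskal stress-1 nMDS via monotone (isotonic) regression with random
#' restarts, keeping the lowest-stress configuration, centred and rotated to
#' principal axes. Implemented with `vegan::metaMDS()` on the supplied
#' distances.
#'
#' @param d A `dist` object (e.g. [robust_aitchison_dist()]).
#' @param dims Number of ordination dimensions.
#' @param restarts Random-restart budget (`trymax`); the search stops early
#'   once convergent repeated solutions are found.
#' @param seed Seed for the restart randomization.
#' @return Object of class `reef_nmds`: `points` tibble (`sample`, `NMDS1`,
#'   `NMDS2`, ...), `stress` (0-1), `converged` flag, and the underlying
#'   vegan object.
#' @export
nmds <- function(d, dims = 2, restarts = 999, seed = 1) {
  stopifnot(inherits(d, "dist"))
  if (attr(d, "Size") < 4) abort("nMDS needs at least 4 samples")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  fit <- vegan::metaMDS(d, k = dims, trymax = restarts, trace = 0,
                        autotransform = FALSE, wascores = FALSE)
  pts <- as_tibble(vegan::scores(fit, display = "sites"))
  labs <- attr(d, "Labels") %||% as.character(seq_len(attr(d, "Size")))
  structure(list(
    points = bind_cols(tibble(sample = labs), pts),
    stress = fit$stress,
    converged = isTRUE(fit$converged) || (is.numeric(fit$converged) && fit$converged > 0),
    vegan_fit = fit
  ), class = "reef_nmds")
}

#' @export
print.reef_nmds <- function(x, ...) {
  cat(sprintf("nMDS ordination: %d samples, stress = %.4f, converged = %s\n",
              nrow(x$points), x$stress, x$converged))
  invisible(x)
}

#' Fit environmental/taxon correlation vectors onto an ordination
#'
#' For each numeric variable, finds the direction in ordination space whose
#' projection best correlates with the variable (least squares), with a
#' permutation test of the squared correlation (`vegan::envfit()`).
#' Constant variables are skipped with a warning.
#'
#' @param ord A `reef_nmds` object.
#' @param variables Data frame of numeric variables aligned to the ordination
#'   samples.
#' @param perms Number of permutations.
#' @param seed Permutation seed.
#' @return Tibble: `variable`, unit direction components (`NMDS1`, `NMDS2`,
#'   ...), `r2`, `p_value`.
#' @export
fit_env_vectors <- function(ord, variables, perms = 999, seed = 1) {
  stopifnot(inherits(ord, "reef_nmds"))
  num <- variables[vapply(variables, is.numeric, logical(1))]
  const <- vapply(num, function(x) sd(x) == 0, logical(1))
  if (any(const)) {
    warn(sprintf("Skipping constant variable(s): %s",
                 paste(names(num)[const], collapse = ", ")))
    num <- num[!const]
  }
  if (!ncol(num)) abort("No usable (non-constant numeric) variables")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  coords <- as.matrix(ord$points[, -1])
  ef <- vegan::envfit(coords, num, permutations = perms)
  arrows <- ef$vectors$arrows
  arrows <- matrix(as.numeric(arrows / sqrt(rowSums(arrows^2))),
                   nrow = nrow(arrows), dimnames = dimnames(arrows))
  bind_cols(
    tibble(variable = rownames(arrows)),
    as_tibble(arrows),
    tibble(r2 = unname(ef$vectors$r), p_value = unname(ef$vectors$pvals))
  )
}

#' Permutational multivariate analysis of variance
#'
#' Partitions the squared distances by the model terms with sequential
#' (order-of-entry) sums of squares and tests each term's pseudo-F by free
#' permutation of sample rows (`vegan::adonis2()`). The default design
#' follows the community analysis: substrate, year (numeric covariate),
#' depth, then the substrate interactions.
#'
#' @param d A `dist` object.
#' @param design Data frame of factors/covariates aligned to samples.
#' @param formula RHS formula of terms in entry order; default
#'   `~ substrate + year + depth_m + substrate:year + substrate:depth_m`
#'   restricted to columns present in `design`.
#' @param perms Number of permutations.
#' @param seed Permutation seed.
#' @return Tibble: `term`, `df`, `sum_of_squares`, `r_squared`, `pseudo_f`,
#'   `p_value`, including Residual and Total rows.
#' @export
permanova <- function(d, design, formula = NULL, perms = 9999, seed = 1) {
  stopifnot(inherits(d, "dist"))
  if (is.null(formula)) {
    base_terms <- c("substrate", "year", "depth_m")
    present <- intersect(base_terms, names(design))
    if (!length(present)) abort("No default design columns present; supply `formula`")
    inter <- if ("substrate" %in% present) {
      paste0("substrate:", setdiff(present, "substrate"))
    } else character(0)
    formula <- as.formula(paste("d ~", paste(c(present, inter), collapse = " + ")))
  } else {
    formula <- as.formula(paste("d ~", paste(deparse(formula[[length(formula)]]), collapse = "")))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  res <- vegan::adonis2(formula, data = design, permutations = perms,
                        by = "terms")
  tibble(
    term = rownames(res),
    df = res$Df,
    sum_of_squares = res$SumOfSqs,
    r_squared = res$R2,
    pseudo_f = res$`F`,
    p_value = res$`Pr(>F)`
  )
}

#' Pairwise PERMANOVA with Bonferroni correction
#'
#' One-factor PERMANOVA on the sub-distance-matrix of every group pair;
#' p-values are Bonferroni-adjusted (`min(1, p * n_pairs)`). Pairs involving
#' a group with fewer than 2 samples are skipped with a warning.
#'
#' @param d A `dist` object.
#' @param group Grouping vector aligned to samples.
#' @param perms Number of permutations per pair.
#' @param seed Permutation seed.
#' @return Tibble: `group1`, `group2`, `df`, `pseudo_f`, `r_squared`,
#'   `p_value`, `p_adjusted`.
#' @export
pairwise_permanova <- function(d, group, perms = 9999, seed = 1) {
  stopifnot(inherits(d, "dist"))
  group <- as.character(group)
  m <- as.matrix(d)
  sizes <- table(group)
  usable <- names(sizes)[sizes >= 2]
  if (length(usable) < length(sizes)) {
    warn(sprintf("Skipping group(s) with < 2 samples: %s",
                 paste(setdiff(names(sizes), usable), collapse = ", ")))
  }
  if (length(usable) < 2) abort("Need at least 2 groups with >= 2 samples")
  pairs <- utils::combn(sort(usable), 2)
  n_pairs <- ncol(pairs)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  purrr::map_dfr(seq_len(n_pairs), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    keep <- group %in% c(g1, g2)
    sub_d <- stats::as.dist(m[keep, keep])
    sub_design <- data.frame(g = factor(group[keep]))
    res <- vegan::adonis2(sub_d ~ g, data = sub_design, permutations = perms,
                          by = "terms")
    tibble(group1 = g1, group2 = g2, df = res$Df[1],
           pseudo_f = res$`F`[1], r_squared = res$R2[1],
           p_value = res$`Pr(>F)`[1],
           p_adjusted = min(1, res$`Pr(>F)`[1] * n_pairs))
  })
}
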