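#' Standardize model covariates by twice their standard deviation
#'
#' Each covariate (binary indicators included) is mapped to
#' `(x - mean(x)) / (2 * sd(x))` with the sample SD (`n - 1` denominator),
#' putting binary and continuous effect sizes on a comparable scale: a
#' standardized column has mean 0 and SD 0.5. Interaction columns should be
#' formed *after* standardization as products of the standardized main
#' effects.
#'
#' @param data Data frame of covariates.
#' @param cols Character vector of columns to standardize (default: all
#'   numeric columns).
#' @return The data with the named columns standardized; the
#'   `"scaling"` attribute holds a tibble of per-column means and SDs for
#'   back-transformation.
#' @examples
#' standardize_design(data.frame(x = c(1, 2, 3)))
#' @export
standardize_design <- function(data, cols = NULL) {
  cols <- cols %||% names(data)[vapply(data, is.numeric, logical(1))]
  scaling <- purrr::map_dfr(cols, function(cl) {
    x <- data[[cl]]
    s <- sd(x)
    if (!is.finite(s) || s == 0) {
      abort(sprintf("Covariate '%s' is constant: cannot standardize", cl))
    }
    tibble(column = cl, mean = mean(x), sd = s)
  })
  for (i in seq_len(nrow(scaling))) {
    cl <- scaling$column[i]
    data[[cl]] <- (data[[cl]] - scaling$mean[i]) / (2 * scaling$sd[i])
  }
  attr(data, "scaling") <- scaling
  data
}

#' Highest density interval of a sample
#'
#' Shortest contiguous interval containing `ceiling(mass * n)` of the sorted
#' draws.
#'
#' @param draws Numeric vector of posterior draws.
#' @param mass Probability mass in (0, 1).
#' @return Numeric vector `c(lower, upper)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  stopifnot(mass > 0, mass < 1)
  x <- sort(draws[is.finite(draws)])
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m])
}

#' Classify an effect from its 80% highest density interval
#'
#' An effect is called credible when its 80% HDI excludes zero; an interval
#' endpoint exactly at zero counts as overlapping (conservative).
#'
#' @param interval Numeric `c(lower, upper)`.
#' @return One of `"credible_negative"`, `"credible_positive"`,
#'   `"not_credible"`.
#' @export
classify_trend <- function(interval) {
  lo <- interval[[1]]; hi <- interval[[2]]
  if (hi < 0) "credible_negative"
  else if (lo > 0) "credible_positive"
  else "not_credible"
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classical (non-split) PSRF computed across independent sampler runs:
#' with `W` the mean within-run variance and `B/n` the variance of the run
#' means, `Rhat = sqrt(((n-1)/n * W + B/n) / W)`.
#'
#' @param chains A runs-by-draws numeric matrix for one parameter, or a list
#'   of equal-size draw matrices (draws-by-parameters, one per run) for many.
#' @return A single `rhat`, or a named vector per parameter. Parameters with
#'   zero within-run variance are flagged `NA` with a warning.
#' @export
gelman_rubin <- function(chains) {
  psrf1 <- function(m) { # k x n matrix
    k <- nrow(m); n <- ncol(m)
    stopifnot(k >= 2)
    W <- mean(apply(m, 1, var))
    if (!is.finite(W) || W == 0) {
      warn("Zero within-chain variance: rhat undefined")
      return(NA_real_)
    }
    B_over_n <- var(rowMeans(m))
    sqrt(((n - 1) / n * W + B_over_n) / W)
  }
  if (is.list(chains) && !is.data.frame(chains)) {
    mats <- lapply(chains, as.matrix)
    params <- colnames(mats[[1]]) %||% paste0("p", seq_len(ncol(mats[[1]])))
    vapply(seq_along(params), function(j) {
      psrf1(do.call(rbind, lapply(mats, function(m) m[, j])))
    }, numeric(1)) |> setNames(params)
  } else {
    psrf1(as.matrix(chains))
  }
}

#' Variance inflation factors and pairwise correlations
#'
#' Reports the VIF of each covariate from auxiliary least-squares
#' regressions on the remaining covariates, together with the full Pearson
#' correlation matrix, as a pre-fit multicollinearity screen (report only;
#' no hard failure).
#'
#' @param data Data frame with at least two numeric covariate columns.
#' @return List with `vif` (tibble: covariate, vif) and `correlations`
#'   (long tibble: var1, var2, r). Singular designs yield infinite VIF.
#' @export
screen_collinearity <- function(data) {
  num <- data[vapply(data, is.numeric, logical(1))]
  if (ncol(num) < 2) abort("Need at least 2 numeric covariates")
  X <- as.matrix(num)
  vifs <- vapply(seq_len(ncol(X)), function(j) {
    fit <- lm(X[, j] ~ X[, -j, drop = FALSE])
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  cm <- cor(X)
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  list(
    vif = tibble(covariate = colnames(X), vif = vifs),
    correlations = tibble(
      var1 = colnames(X)[idx[, 1]],
      var2 = colnames(X)[idx[, 2]],
      r = cm[idx]
    )
  )
}

#' Specify a hierarchical Bayesian cover or colony model
#'
#' Three model equations are supported, sharing one sampling protocol:
#' \describe{
#'   \item{`reef_cover`}{alr cover ~ substrate + depth + year +
#'     substrate:depth + substrate:year, with survey-site and survey-method
#'     random intercepts; normal errors, identity link.}
#'   \item{`block_cover`}{alr cover on wave-dissipating blocks ~
#'     surface processing + depth + years since installation + both
#'     interactions; normal errors.}
#'   \item{`block_colony`}{colony density ~ the same block design; gamma
#'     errors parameterized by mean and variance, log link.}
#' }
#' Coefficient priors are Uniform(-10, 10) (Uniform(-20, 20) for
#' `block_colony`); every SD scale parameter has a Half-Cauchy prior with
#' scale 0.01. Sampling: 1000 discarded tuning iterations then 2000 retained
#' draws, repeated in 5 independent runs (10,000 pooled draws).
#'
#' @param equation Model equation.
#' @param beta_bounds Optional length-2 override of the uniform coefficient
#'   prior bounds.
#' @param halfcauchy_scale Scale of the Half-Cauchy prior on SD parameters.
#' @param tune,draws,runs Sampler protocol overrides.
#' @return An object of class `hbm_spec`.
#' @export
hbm_spec <- function(equation = c("reef_cover", "block_cover", "block_colony"),
                     beta_bounds = NULL, halfcauchy_scale = 1e-2,
                     tune = 1000, draws = 2000, runs = 5) {
  equation <- match.arg(equation)
  stopifnot(tune > 0, draws > 0, runs > 0, halfcauchy_scale > 0)
  beta_bounds <- beta_bounds %||%
    if (equation == "block_colony") c(-20, 20) else c(-10, 10)
  stopifnot(length(beta_bounds) == 2, beta_bounds[1] < beta_bounds[2])
  terms <- if (equation == "reef_cover") {
    c("intercept", "substrate", "depth", "year",
      "substrate:depth", "substrate:year")
  } else {
    c("intercept", "processing", "depth", "years",
      "processing:depth", "processing:years")
  }
  structure(list(
    equation = equation,
    family = if (equation == "block_colony") "gamma_log" else "normal_identity",
    terms = terms,
    random = if (equation == "reef_cover") c("site_id", "method") else character(0),
    beta_bounds = beta_bounds,
    halfcauchy_scale = halfcauchy_scale,
    tune = tune, draws = draws, runs = runs
  ), class = "hbm_spec")
}

# deterministic expansion of one master seed into per-run sampler seeds
derive_run_seeds <- function(seed, runs) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  sample.int(2147483646L, runs)
}

# design matrix shared by all three equations: standardized mains, products
hbm_design <- function(data, spec) {
  if (spec$equation == "reef_cover") {
    need <- c("substrate", "depth_m", "year")
    if (!all(need %in% names(data))) {
      abort(sprintf("reef_cover needs columns: %s", paste(need, collapse = ", ")))
    }
    raw <- tibble(
      substrate = as.numeric(data$substrate == "natural"),
      depth = data$depth_m,
      year = data$year
    )
  } else {
    need <- c("processed", "depth_m", "years")
    if (!all(need %in% names(data))) {
      abort(sprintf("%s needs columns: %s", spec$equation, paste(need, collapse = ", ")))
    }
    raw <- tibble(
      processing = as.numeric(data$processed %in% c(1, TRUE, "processed")),
      depth = data$depth_m,
      years = data$years
    )
  }
  std <- standardize_design(raw)
  f <- std[[1]]
  X <- cbind(
    intercept = 1,
    as.matrix(std),
    inter1 = f * std$depth,
    inter2 = f * std[[3]]
  )
  colnames(X) <- spec$terms
  list(X = X, scaling = attr(std, "scaling"))
}

hbm_model_string <- function(spec) {
  ranef_mu <- if (length(spec$random)) " + r_site[site[i]] + r_method[method[i]]" else ""
  ranef_block <- if (length(spec$random)) "
  for (s in 1:n_site) { r_site[s] ~ dnorm(0, pow(s_site, -2)) }
  for (m in 1:n_method) { r_method[m] ~ dnorm(0, pow(s_method, -2)) }
  s_site ~ dt(0, pow(hc_scale, -2), 1) T(0,)
  s_method ~ dt(0, pow(hc_scale, -2), 1) T(0,)" else ""
  lik <- if (spec$family == "normal_identity") "
    mu[i] <- inprod(X[i,], beta)RANEF
    y[i] ~ dnorm(mu[i], pow(eps, -2))" else "
    log(mu[i]) <- inprod(X[i,], beta)RANEF
    sh[i] <- pow(mu[i], 2) / pow(eps, 2)
    ra[i] <- mu[i] / pow(eps, 2)
    y[i] ~ dgamma(sh[i], ra[i])"
  lik <- sub("RANEF", ranef_mu, lik)
  paste0("model {
  for (i in 1:n) {", lik, "
  }
  for (j in 1:p) { beta[j] ~ dunif(lb, ub) }
  eps ~ dt(0, pow(hc_scale, -2), 1) T(0,)", ranef_block, "
}")
}

#' Fit a hierarchical Bayesian effect-size model
#'
#' Builds the standardized design for the chosen equation, then samples the
#' posterior with the fixed protocol: `runs` independent MCMC runs (distinct
#' seeds derived from `seed`), each discarding `tune` adaptation iterations
#' and retaining `draws`, pooled into `runs * draws` posterior draws.
#' Summaries report posterior medians, 80% and 95% HDIs, the
#' credible-trend classification from the 80% HDI, the Gelman-Rubin
#' statistic across runs, and Bayesian R-squared.
#'
#' @param data Data frame. `reef_cover` needs `substrate`
#'   (artificial/natural), `depth_m`, `year`, `site_id`, `method`;
#'   `block_cover`/`block_colony` need `processed` (0/1), `depth_m`,
#'   `years`.
#' @param response Name of the response column (alr cover, or strictly
#'   positive colony density for `block_colony`).
#' @param spec An [hbm_spec()].
#' @param seed Master seed; expanded deterministically into one seed per
#'   run.
#' @param quiet Suppress progress messages.
#' @return An object of class `hbm_fit`: list with `summary` (tibble),
#'   `draws` (pooled matrix), `run_draws` (per-run matrices), `bayes_r2`
#'   draws, `scaling`, `spec`, and metadata. Methods: [tidy()], [glance()],
#'   [autoplot()].
#' @export
fit_hbm <- function(data, response, spec = hbm_spec(), seed = 1, quiet = TRUE) {
  y <- data[[response]]
  if (is.null(y)) abort(sprintf("Response column '%s' not found", response))
  if (anyNA(y) || any(!is.finite(y))) abort("Response must be finite and complete")
  if (spec$family == "gamma_log" && any(y <= 0)) {
    abort(paste("block_colony requires strictly positive colony densities",
                "(the gamma distribution excludes 0); drop or offset zero counts"))
  }
  des <- hbm_design(data, spec)
  X <- des$X
  n <- nrow(X); p <- ncol(X)
  jd <- list(n = n, p = p, X = X, y = y,
             lb = spec$beta_bounds[1], ub = spec$beta_bounds[2],
             hc_scale = spec$halfcauchy_scale)
  monitors <- c("beta", "eps")
  if (length(spec$random)) {
    site <- as.integer(factor(data$site_id))
    method <- as.integer(factor(data$method))
    jd$site <- site; jd$method <- method
    jd$n_site <- max(site); jd$n_method <- max(method)
    monitors <- c(monitors, "s_site", "s_method", "r_site", "r_method")
  }
  beta0 <- rep(0, p)
  if (spec$family == "gamma_log") beta0[1] <- min(max(log(mean(y)), jd$lb + 0.1), jd$ub - 0.1)
  eps0 <- if (spec$family == "gamma_log") max(sd(y), 0.1) else max(sd(y - mean(y)), 0.1)

  run_seeds <- derive_run_seeds(seed, spec$runs)
  model_str <- hbm_model_string(spec)
  run_draws <- vector("list", spec$runs)
  for (r in seq_len(spec$runs)) {
    inits <- list(beta = beta0, eps = eps0,
                  .RNG.name = "base::Mersenne-Twister",
                  .RNG.seed = run_seeds[r])
    if (length(spec$random)) {
      inits$r_site <- rep(0, jd$n_site); inits$r_method <- rep(0, jd$n_method)
      inits$s_site <- 0.1; inits$s_method <- 0.1
    }
    jm <- rjags::jags.model(textConnection(model_str), data = jd, inits = inits,
                            n.chains = 1, n.adapt = spec$tune, quiet = TRUE)
    sm <- rjags::coda.samples(jm, monitors, n.iter = spec$draws, progress.bar = "none")
    run_draws[[r]] <- as.matrix(sm[[1]])
    if (!quiet) message(sprintf("run %d/%d done", r, spec$runs))
  }
  pooled <- do.call(rbind, run_draws)

  beta_cols <- paste0("beta[", seq_len(p), "]")
  param_names <- c(setNames(beta_cols, spec$terms),
                   eps = "eps",
                   if (length(spec$random)) c(s_site = "s_site", s_method = "s_method"))
  rhats <- gelman_rubin(run_draws)

  summary_tbl <- purrr::imap_dfr(param_names, function(col, nm) {
    d <- pooled[, col]
    h80 <- hdi(d, 0.80); h95 <- hdi(d, 0.95)
    tibble(term = nm, median = median(d),
           hdi80_lower = h80[1], hdi80_upper = h80[2],
           hdi95_lower = h95[1], hdi95_upper = h95[2],
           credible = classify_trend(h80),
           rhat = unname(rhats[col]))
  })
  # scale parameters are variance components, not trends
  summary_tbl$credible[!summary_tbl$term %in% spec$terms] <- NA_character_

  # linear-predictor draws for Bayesian R2 (reconstructed from the design)
  eta <- pooled[, beta_cols, drop = FALSE] %*% t(X)
  if (length(spec$random)) {
    eta <- eta + pooled[, paste0("r_site[", jd$site, "]"), drop = FALSE] +
      pooled[, paste0("r_method[", jd$method, "]"), drop = FALSE]
  }
  if (spec$family == "gamma_log") eta <- exp(eta)
  var_fit <- apply(eta, 1, var)
  var_res <- pooled[, "eps"]^2
  r2 <- var_fit / (var_fit + var_res)

  structure(list(
    summary = summary_tbl, draws = pooled, run_draws = run_draws,
    bayes_r2 = r2, scaling = des$scaling, spec = spec,
    n = n, run_seeds = run_seeds, seed = seed, response = response,
    param_names = param_names
  ), class = "hbm_fit")
}

#' Bayesian R-squared of a fitted model
#'
#' Per-draw `var(fitted) / (var(fitted) + var(residual))`, where the
#' residual variance is the model's error-scale draw squared.
#'
#' @param fit An `hbm_fit`.
#' @param mass HDI mass for the interval summary.
#' @return Tibble with the median and HDI of the R-squared distribution.
#' @export
bayes_r2 <- function(fit, mass = 0.95) {
  stopifnot(inherits(fit, "hbm_fit"))
  h <- hdi(fit$bayes_r2, mass)
  tibble(median = median(fit$bayes_r2), hdi_lower = h[1], hdi_upper = h[2],
         mass = mass)
}

#' @export
print.hbm_fit <- function(x, ...) {
  cat(sprintf("Hierarchical Bayesian fit (%s): n = %d, %d runs x %d draws = %d pooled\n",
              x$spec$equation, x$n, x$spec$runs, x$spec$draws, nrow(x$draws)))
  print(x$summary, n = nrow(x$summary))
  cat(sprintf("Bayesian R2 (median): %.3f; max rhat: %.3f\n",
              median(x$bayes_r2), max(x$summary$rhat, na.rm = TRUE)))
  invisible(x)
}

#' @rdname fit_hbm
#' @param x,object An `hbm_fit`.
#' @param ... Unused.
#' @method tidy hbm_fit
#' @export
tidy.hbm_fit <- function(x, ...) x$summary

#' @rdname fit_hbm
#' @method glance hbm_fit
#' @export
glance.hbm_fit <- function(x, ...) {
  tibble(n = x$n, n_draws = nrow(x$draws), runs = x$spec$runs,
         draws_per_run = x$spec$draws,
         bayes_r2 = median(x$bayes_r2),
         max_rhat = max(x$summary$rhat, na.rm = TRUE))
}
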