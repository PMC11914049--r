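test_that("2SD standardization yields mean 0, SD 0.5, and handles indicators", {
  out <- standardize_design(data.frame(x = c(1, 2, 3)))
  expect_equal(out$x, c(-0.5, 0, 0.5))
  set.seed(1)
  df <- data.frame(a = rnorm(100, 5, 3), b = rep(c(0, 1), 50))
  std <- standardize_design(df)
  expect_equal(colMeans(std), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(vapply(std, sd, numeric(1)), c(a = 0.5, b = 0.5), tolerance = 1e-12)
  # balanced indicator maps to +/- 0.4975 with the n-1 SD at n = 100
  expect_equal(max(std$b), 0.5 / (2 * sqrt(25 / 99)) / 1, tolerance = 1e-9)
  expect_equal(sort(unique(round(std$b, 4))), c(-0.4975, 0.4975))
  expect_error(standardize_design(data.frame(x = rep(2, 5))), "constant")
  sc <- attr(std, "scaling")
  expect_equal(sc$mean[sc$column == "b"], 0.5)
})

test_that("hdi finds the shortest mass interval", {
  set.seed(2)
  z <- rnorm(10000)
  h95 <- hdi(z, 0.95)
  expect_equal(unname(h95), c(-1.96, 1.96), tolerance = 0.05)
  h80 <- hdi(runif(10000), 0.80)
  expect_equal(unname(diff(h80)), 0.80, tolerance = 0.02)
  expect_equal(unname(hdi(rep(3, 500), 0.9)), c(3, 3))
  # HDI80 nested in HDI95
  expect_true(hdi(z, 0.8)[1] >= h95[1] && hdi(z, 0.8)[2] <= h95[2])
})

test_that("credible-trend classification uses strict zero exclusion", {
  expect_equal(classify_trend(c(-0.5, -0.1)), "credible_negative")
  expect_equal(classify_trend(c(0.1, 0.5)), "credible_positive")
  expect_equal(classify_trend(c(-0.1, 0.2)), "not_credible")
  expect_equal(classify_trend(c(0, 0.3)), "not_credible")
  expect_equal(classify_trend(c(-0.3, 0)), "not_credible")
})

test_that("gelman-rubin matches its defining formula and coda on references", {
  set.seed(3)
  m <- matrix(rnorm(4000), nrow = 4)
  # near-identical well-mixed chains: rounds to 1.00
  expect_equal(round(gelman_rubin(m), 2), 1)
  # hand-oracle on a small case
  m2 <- rbind(rnorm(200), rnorm(200))
  W <- mean(c(var(m2[1, ]), var(m2[2, ])))
  B_n <- var(rowMeans(m2))
  expect_equal(gelman_rubin(m2), sqrt((199 / 200 * W + B_n) / W), tolerance = 1e-12)
  # chains offset by 10 SD diverge
  m3 <- rbind(rnorm(500), rnorm(500) + 10)
  expect_gt(gelman_rubin(m3), 1.1)
  # coda agreement on well-mixed chains (independent implementation)
  ch <- lapply(1:4, function(i) matrix(rnorm(1000), ncol = 1,
                                       dimnames = list(NULL, "b")))
  ours <- gelman_rubin(ch)
  codas <- coda::gelman.diag(coda::as.mcmc.list(lapply(ch, coda::as.mcmc)),
                             autoburnin = FALSE)$psrf[1, 1]
  expect_equal(unname(ours["b"]), codas, tolerance = 0.01)
  expect_warning(gelman_rubin(rbind(rep(1, 50), rep(1, 50))), "undefined")
})

test_that("collinearity screen reproduces closed-form VIFs", {
  set.seed(4)
  n <- 200
  x <- rnorm(n); y_ind <- rnorm(n)
  scr <- screen_collinearity(data.frame(a = x, b = y_ind))
  expect_equal(scr$vif$vif, c(1, 1), tolerance = 0.05)
  # two predictors with correlation r have VIF 1/(1-r^2)
  r <- 0.6
  b <- r * x + sqrt(1 - r^2) * rnorm(n)
  scr2 <- screen_collinearity(data.frame(a = x, b = b))
  r_emp <- cor(x, b)
  expect_equal(scr2$vif$vif, rep(1 / (1 - r_emp^2), 2), tolerance = 1e-8)
  scr3 <- screen_collinearity(data.frame(a = x, b = x))
  expect_true(all(is.infinite(scr3$vif$vif)))
})

test_that("model specs encode the printed priors and protocol", {
  s1 <- hbm_spec("reef_cover")
  expect_equal(s1$beta_bounds, c(-10, 10))
  expect_equal(s1$halfcauchy_scale, 1e-2)
  expect_equal(c(s1$tune, s1$draws, s1$runs), c(1000, 2000, 5))
  expect_equal(length(s1$terms), 6)
  expect_equal(s1$random, c("site_id", "method"))
  s3 <- hbm_spec("block_colony")
  expect_equal(s3$beta_bounds, c(-20, 20))
  expect_equal(s3$family, "gamma_log")
  # overrides
  expect_equal(hbm_spec("reef_cover", beta_bounds = c(-5, 5))$beta_bounds, c(-5, 5))
})

test_that("a fitted model is reproducible and keeps exact draw bookkeeping", {
  sim <- simulate_block_survey(small_block_cfg(seed = 21))
  spec <- hbm_spec("block_cover")
  fit <- fit_hbm(sim$data, "alr_cover", spec, seed = 99)
  expect_equal(nrow(fit$draws), spec$runs * spec$draws)
  expect_equal(length(fit$run_draws), 5)
  expect_equal(unique(vapply(fit$run_draws, nrow, integer(1))), 2000)
  expect_equal(length(fit$run_seeds), 5)
  # HDI nesting per coefficient
  expect_true(all(fit$summary$hdi80_lower >= fit$summary$hdi95_lower - 1e-12))
  expect_true(all(fit$summary$hdi80_upper <= fit$summary$hdi95_upper + 1e-12))
  expect_true(all(fit$summary$rhat >= 1 - 0.01, na.rm = TRUE))
  # bit-for-bit reproducibility under the same master seed
  fit2 <- fit_hbm(sim$data, "alr_cover", spec, seed = 99)
  expect_identical(fit$draws, fit2$draws)
  expect_equal(tidy(fit), tidy(fit2))
  # tidiers
  expect_s3_class(tidy(fit), "tbl_df")
  g <- glance(fit)
  expect_equal(g$n_draws, 10000)
  r2 <- bayes_r2(fit)
  expect_true(r2$median >= 0 && r2$median <= 1)
  expect_true(all(fit$bayes_r2 >= 0 & fit$bayes_r2 <= 1))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("gamma colony model rejects zero counts and keeps positive means", {
  sim <- simulate_block_survey(small_block_cfg(seed = 22))
  bad <- sim$data
  bad$colony_density[1] <- 0
  expect_error(fit_hbm(bad, "colony_density", hbm_spec("block_colony")),
               "strictly positive")
})
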