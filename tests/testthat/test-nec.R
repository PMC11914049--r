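test_that("seawater density matches the standard equation of state", {
  expect_equal(seawater_density(25, 35), 1023.3, tolerance = 0.5)
  # fresh water at 4 C is ~1000
  expect_equal(seawater_density(4, 0), 1000, tolerance = 0.1)
  # monotone increasing in salinity at fixed temperature
  s <- seq(20, 40, 2)
  expect_true(all(diff(seawater_density(rep(25, length(s)), s)) > 0))
  expect_equal(seawater_density(25, 35, constant = 1023), 1023)
  expect_error(seawater_density(60, 35), "temperature")
  expect_error(seawater_density(25, 80), "salinity")
})

test_that("window NEC reproduces the TA-anomaly arithmetic and unit chain", {
  # TA falling at exactly 0.2 mmol/kg/h in a 0.5 m pool of density 1023:
  # NEC = -1/2 * (-0.2) * 0.5 * 1023 = 51.15 mmol m^-2 h^-1
  w <- tibble::tibble(time_h = c(0, 0.3, 0.6),
                      ta_mmol_kg = 2.3 - 0.2 * c(0, 0.3, 0.6),
                      depth_m = 0.5, temp_c = 25, salinity = 35,
                      photon_flux = 800, stagnant = TRUE)
  est <- window_nec(w, density = 1023)
  expect_equal(est$nec, 51.15, tolerance = 1e-10)
  expect_equal(est$ta_slope, -0.2, tolerance = 1e-12)
  # exact line: regression SE is zero, so the NEC SE is too
  expect_equal(est$nec_se, 0, tolerance = 1e-8)
  # zero slope gives zero NEC; rising TA gives negative NEC (dissolution)
  w0 <- w; w0$ta_mmol_kg <- rep(2.3, 3)
  expect_equal(window_nec(w0, density = 1023)$nec, 0, tolerance = 1e-12)
  wr <- w; wr$ta_mmol_kg <- 2.3 + 0.1 * w$time_h
  expect_lt(window_nec(wr, density = 1023)$nec, 0)
  # contract violations
  wbad <- w; wbad$stagnant[2] <- FALSE
  expect_error(window_nec(wbad), "advection")
  expect_error(window_nec(w[1:2, ]), "3 samples")
  wshort <- w; wshort$time_h <- c(0, 0.1, 0.2)
  expect_error(window_nec(wshort), "span")
})

test_that("noisy series with known dissolution recovers truth within 2 SE", {
  # true flux: constant NEC of -8 (TA rising) in a 0.4 m pool
  rho <- seawater_density(28, 34)
  true_nec <- -8
  t <- seq(0, 3, by = 0.2)
  hits <- vapply(1:10, function(r) {
    set.seed(400 + r)
    ta <- 2.3 - 2 * true_nec * t / (0.4 * rho) + rnorm(length(t), 0, 0.002)
    w <- tibble::tibble(time_h = t, ta_mmol_kg = ta, depth_m = 0.4,
                        temp_c = 28, salinity = 34, photon_flux = 0,
                        stagnant = TRUE)
    est <- window_nec(w)
    expect_lt(est$nec, 0)
    abs(est$nec - true_nec) < 2 * est$nec_se
  }, logical(1))
  expect_gte(sum(hits), 8)
})

test_that("light-response fitting selects the generating form", {
  set.seed(18)
  I <- c(0, 0, 50, 100, 200, 400, 600, 900, 1200, 1500, 300, 700)
  # linear truth
  nec_lin <- 0.004 * I - 1 + rnorm(length(I), 0, 0.2)
  f_lin <- fit_light_response(nec_lin, I)
  expect_equal(f_lin$form, "linear")
  se_b <- tidy(f_lin)$std_error[tidy(f_lin)$term == "b"]
  expect_lt(abs(f_lin$coef[["b"]] - 0.004), 2 * se_b)
  # saturating truth (a = 6, Ik = 500, c = -1)
  ok <- 0
  for (s in 1:5) {
    set.seed(100 + s)
    nec_tanh <- 6 * tanh(I / 500) - 1 + rnorm(length(I), 0, 0.3)
    f_tanh <- fit_light_response(nec_tanh, I)
    if (f_tanh$form == "tanh" &&
        abs(f_tanh$coef[["a"]] - 6) < 2 * sqrt(f_tanh$vcov["a", "a"]) &&
        abs(f_tanh$coef[["c"]] - (-1)) < 2 * sqrt(f_tanh$vcov["c", "c"])) {
      ok <- ok + 1
    }
  }
  expect_gte(ok, 4)
  expect_error(fit_light_response(rnorm(5), rep(300, 5)), "identifiable")
})

test_that("daily integration is exact for closed forms and propagates error", {
  lin <- structure(list(form = "linear", coef = c(b = 0.004, c = -1),
                        vcov = matrix(0, 2, 2, dimnames = list(c("b", "c"), c("b", "c")))),
                   class = "light_response")
  day_const <- tibble::tibble(time_h = seq(0, 24, by = 0.25), light = 500)
  out <- integrate_daily_nec(lin, day_const)
  expect_equal(out$daily_nec, 24 * (0.004 * 500 - 1), tolerance = 1e-10)
  expect_equal(out$daily_nec_sd, 0)
  # zero function integrates to zero with zero sd
  zero <- structure(list(form = "linear", coef = c(b = 0, c = 0),
                         vcov = matrix(0, 2, 2, dimnames = list(c("b", "c"), c("b", "c")))),
                    class = "light_response")
  expect_equal(unlist(integrate_daily_nec(zero, day_const)),
               c(daily_nec = 0, daily_nec_sd = 0))
  # gap and coverage contracts
  expect_error(integrate_daily_nec(lin, tibble::tibble(time_h = c(0, 5, 24),
                                                       light = 0)), "Gap")
  expect_error(integrate_daily_nec(lin, tibble::tibble(time_h = seq(2, 24, 0.5),
                                                       light = 0)), "24 h")
})

test_that("delta-method daily sd agrees with a Monte-Carlo oracle", {
  set.seed(19)
  I <- c(0, 0, 100, 250, 400, 600, 800, 1100, 1400, 300, 50, 700)
  nec <- 6 * tanh(I / 500) - 1 + rnorm(length(I), 0, 0.3)
  fit <- fit_light_response(nec, I, form = "tanh")
  day <- tibble::tibble(time_h = seq(0, 24, by = 0.1),
                        light = ifelse(time_h >= 6 & time_h <= 18,
                                       1500 * sin(pi * (time_h - 6) / 12)^2, 0))
  out <- integrate_daily_nec(fit, day)
  draws <- MASS::mvrnorm(10000, fit$coef, fit$vcov)
  mc <- apply(draws, 1, function(p) {
    pracma::trapz(day$time_h, p["a"] * tanh(day$light / p["Ik"]) + p["c"])
  })
  expect_equal(out$daily_nec_sd, sd(mc), tolerance = 0.1 * sd(mc))
})

test_that("station slope comparison detects heterogeneous drawdown", {
  set.seed(20)
  mk <- function(st, rate) {
    t <- seq(0, 3, by = 0.2)
    tibble::tibble(station_id = st, date = "d1", time_h = t,
                   ta_mmol_kg = 2.3 + rate * t + rnorm(length(t), 0, 0.003),
                   depth_m = 0.5, temp_c = 28, salinity = 34,
                   photon_flux = 500, stagnant = TRUE)
  }
  ser <- tidepool_series(dplyr::bind_rows(mk("s1", -0.05), mk("s2", -0.10),
                                          mk("s3", -0.05)))
  cmp <- compare_station_slopes(ser)
  expect_equal(nrow(cmp$slopes), 3)
  expect_equal(cmp$slopes$slope, c(-0.05, -0.10, -0.05), tolerance = 0.01)
  expect_lt(cmp$homogeneity$p_value, 0.01)
  # slope table consistent with window_nec on the same samples
  w1 <- window_nec(ser[ser$station_id == "s1", ])
  expect_equal(cmp$slopes$slope[1], w1$ta_slope, tolerance = 1e-12)
  if (!is.null(cmp$pairwise)) {
    expect_equal(nrow(cmp$pairwise), 3)
  }
  # null: identical stations rarely flagged
  pvals <- vapply(1:20, function(r) {
    set.seed(300 + r)
    s <- tidepool_series(dplyr::bind_rows(mk("s1", -0.05), mk("s2", -0.05)))
    compare_station_slopes(s)$homogeneity$p_value
  }, numeric(1))
  expect_lte(mean(pvals < 0.05), 0.25)
})
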