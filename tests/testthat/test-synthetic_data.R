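test_that("survey generator is deterministic and honours injection rates", {
  cfg <- survey_sim_config(seed = 31, records_per_year = 4, years = 2001:2005)
  s1 <- simulate_survey(cfg)
  s2 <- simulate_survey(cfg)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$truth$r_site, s2$truth$r_site)
  # zero injection rates produce a fully numeric table
  cfg0 <- survey_sim_config(seed = 31, records_per_year = 4, years = 2001:2005,
                            rate_rare = 0, rate_plus = 0, rate_range = 0)
  s0 <- simulate_survey(cfg0)
  toks <- unlist(s0$data[reef_taxa()])
  expect_true(all(grepl("^[0-9.]+$", toks)))
  # symbols only appear where their definition allows
  s <- simulate_survey(survey_sim_config(seed = 32, records_per_year = 6,
                                         years = 2001:2008, rate_rare = 1,
                                         rate_plus = 1, rate_range = 1))
  for (tx in reef_taxa()) {
    tok <- s$data[[tx]]
    truthv <- s$percent[[tx]]
    expect_true(all(truthv[tok == "R"] < 1))
    expect_true(all(truthv[tok == "+"] >= 1 & truthv[tok == "+"] < 5))
  }
  # generated covers are valid percents closing to 100
  pct <- as.matrix(s$percent[reef_taxa()])
  expect_true(all(pct >= 0 & pct <= 100))
  expect_true(all(rowSums(pct) <= 100 + 1e-9))
})

test_that("simulated tables survive the parse-resolve pipeline", {
  sim <- simulate_survey(survey_sim_config(seed = 33, records_per_year = 5,
                                           years = 2000:2009))
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(sim$data, f)
  res <- resolve_survey(read_survey_table(f, quiet = TRUE), tolerance = 1)
  expect_equal(nrow(res), nrow(sim$data))
  # resolved numeric cells agree with the generating percents
  num_mask <- grepl("^[0-9.]+$", sim$data$acropora)
  expect_equal(res$acropora[num_mask],
               round(sim$percent$acropora[num_mask], 1), tolerance = 0.051)
})

test_that("pre-bleaching spans show the disturbance drop and recovery", {
  cfg <- survey_sim_config(seed = 34, years = 1989:2018, records_per_year = 8,
                           rate_rare = 0, rate_plus = 0, rate_range = 0)
  sim <- simulate_survey(cfg)
  tot <- dplyr::bind_cols(sim$percent["total"], year = sim$data$year,
                          substrate = sim$data$substrate)
  mean_by <- function(yrs) mean(tot$total[tot$year %in% yrs])
  # cover collapses right after the bleaching year then recovers
  expect_lt(mean_by(1998:1999), mean_by(1995:1997))
  expect_gt(mean_by(2014:2018), mean_by(1998:2000))
})

test_that("block generator reproduces the quadrat design and gamma counts", {
  sim <- simulate_block_survey(block_sim_config(seed = 35))
  d <- sim$data
  # 18 quadrats per year: 2 processing x 3 sections x 3 depths
  expect_equal(nrow(d), 18 * 18)
  expect_equal(as.integer(table(d$years)), rep(18L, 18))
  expect_setequal(unique(d$depth_m), c(2, 5, 8))
  expect_true(all(d$colony_density > 0))
  expect_true(all(d$cover_percent >= 0 & d$cover_percent <= 100))
  expect_identical(simulate_block_survey(block_sim_config(seed = 35))$data, d)
})

test_that("tide-pool generator inverts exactly at zero noise", {
  cfg <- tidepool_sim_config(seed = 36, ta_noise_sd = 0)
  sim <- simulate_tidepool_day(cfg)
  w <- nec_windows(sim$series)
  # windows exceed 30 min with at least 3 samples
  expect_true(all(w$n >= 3))
  expect_true(all(w$end_h - w$start_h > 0.5))
  # noiseless: window NEC matches the true response at the window's light
  p <- sim$truth$params
  pred_true <- p$a * tanh(w$mean_light / p$Ik) + p$c0
  expect_equal(w$nec, pred_true, tolerance = 0.15)
  # night windows carry the dark rate
  night <- w[w$mean_light == 0, ]
  expect_equal(night$nec, rep(p$c0, nrow(night)), tolerance = 0.02)
  expect_identical(simulate_tidepool_day(cfg)$series$ta_mmol_kg,
                   sim$series$ta_mmol_kg)
})

test_that("truth sidecars serialize with the generated tables", {
  sim <- simulate_block_survey(small_block_cfg(seed = 37))
  dir <- withr::local_tempdir()
  files <- write_simulation(sim, dir, stem = "block")
  expect_true(file.exists(files[["data"]]))
  expect_true(file.exists(files[["truth"]]))
  truth <- jsonlite::read_json(files[["truth"]])
  expect_equal(unname(unlist(truth$beta_cover)),
               unname(sim$truth$beta_cover), tolerance = 1e-12)
})
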