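#' Configuration for the synthetic benthic survey generator
#'
#' Encodes the generative structure every downstream module assumes: an
#' 11-site, 5-method survey design split across artificial structures and
#' natural reefs; per-taxon linear models of alr cover with substrate,
#' depth and survey-year effects plus their substrate interactions;
#' site and method random intercepts; and optional degradation of small
#' covers into the semi-quantitative symbols "R", "+" and ranges.
#'
#' True coefficients are expressed on the standardized-covariate scale
#' (the 2SD scale the models estimate on); the generator standardizes its
#' own design by the same rule before applying them, so recovery tests are
#' exact contrasts. The default year span is the post-bleaching recovery
#' window (2000-2018); spans reaching back before `bleaching_year` add a
#' pre-bleaching plateau and a disturbance drop with substrate-dependent
#' linear recovery, for descriptive (ordination/plot) use.
#'
#' @param seed Master seed.
#' @param n_sites,n_methods Random-effect group counts (first
#'   `ceiling(n_sites/2)` sites are artificial, the rest natural).
#' @param years Survey years.
#' @param records_per_year Records drawn each year.
#' @param depth_range Depth-below-LWL range (m) sampled uniformly.
#' @param beta Named 6-vector of true standardized coefficients
#'   (`intercept`, `substrate`, `depth`, `year`, `substrate:depth`,
#'   `substrate:year`) shared across taxa; per-taxon offsets separate the
#'   seven taxa on the alr scale.
#' @param taxon_offsets Named 7-vector of per-taxon intercept offsets.
#' @param s_site,s_method,eps Random-effect and residual SDs (alr scale).
#' @param bleaching_year,bleach_drop,recovery_years Disturbance trajectory
#'   for spans that include pre-bleaching years: alr cover drops by
#'   `bleach_drop` at `bleaching_year` and relaxes back linearly over
#'   `recovery_years` (named: artificial, natural; artificial recovers
#'   faster).
#' @param rate_rare,rate_plus,rate_range Probabilities of emitting a cell
#'   as "R" (true cover < 1%), "+" (1-5%), or a range (>= 5%).
#' @return A list of class `survey_sim_config`.
#' @export
survey_sim_config <- function(seed = 1, n_sites = 11, n_methods = 5,
                              years = 2000:2018, records_per_year = 12,
                              depth_range = c(0.5, 10),
                              beta = c(intercept = -1.0, substrate = -1.0,
                                       depth = -0.3, year = 1.2,
                                       `substrate:depth` = 0.1,
                                       `substrate:year` = -0.8),
                              taxon_offsets = c(acropora = 0.8, pocillopora = -0.5,
                                                montipora = -0.2, porites = -0.4,
                                                faviidae = -1.0, millepora = -1.5,
                                                other_hard = -0.8),
                              s_site = 0.4, s_method = 0.25, eps = 0.5,
                              bleaching_year = 1998, bleach_drop = 2.0,
                              recovery_years = c(artificial = 6, natural = 14),
                              rate_rare = 0.3, rate_plus = 0.3, rate_range = 0.2) {
  stopifnot(s_site > 0, s_method > 0, eps > 0, length(beta) == 6,
            all(c(rate_rare, rate_plus, rate_range) >= 0),
            all(c(rate_rare, rate_plus, rate_range) <= 1))
  structure(as.list(environment()), class = "survey_sim_config")
}

# degrade a numeric percent cell to a survey token per the symbol rules
degrade_cell <- function(x, cfg) {
  if (x < 1 && stats::runif(1) < cfg$rate_rare) return("R")
  if (x >= 1 && x < 5 && stats::runif(1) < cfg$rate_plus) return("+")
  if (x >= 5 && stats::runif(1) < cfg$rate_range) {
    lo <- max(0, floor(x) - 5); hi <- min(100, floor(x) + 5)
    return(sprintf("%d-%d", lo, hi))
  }
  format(round(x, 1), trim = TRUE)
}

#' Simulate a semi-quantitative benthic survey table
#'
#' Draws site and method random intercepts, builds per-taxon alr means from
#' the standardized design of [survey_sim_config()], adds normal residual
#' noise, maps through the inverse alr to percent cover, and (optionally)
#' degrades cells to the symbolic tokens used in historical records.
#'
#' @param cfg A [survey_sim_config()].
#' @return List: `data` (raw survey tibble in the [read_survey_table()]
#'   schema, symbolic tokens included), `percent` (the exact numeric covers
#'   before degradation), `alr` (the noiseless-free alr draws actually
#'   used), and `truth` (every generative parameter, the standardization
#'   record and the random-effect draws).
#' @export
simulate_survey <- function(cfg = survey_sim_config()) {
  stopifnot(inherits(cfg, "survey_sim_config"))
  set.seed(cfg$seed)
  taxa <- reef_taxa()
  sites <- sprintf("site%02d", seq_len(cfg$n_sites))
  site_substrate <- setNames(
    rep(c("artificial", "natural"),
        c(ceiling(cfg$n_sites / 2), floor(cfg$n_sites / 2))), sites)
  methods <- reef_methods()[seq_len(cfg$n_methods)]
  r_site <- rnorm(cfg$n_sites, 0, cfg$s_site)
  r_method <- rnorm(cfg$n_methods, 0, cfg$s_method)

  n <- length(cfg$years) * cfg$records_per_year
  recs <- tibble(
    record_id = sprintf("rec%04d", seq_len(n)),
    year = rep(cfg$years, each = cfg$records_per_year),
    site_id = sample(sites, n, replace = TRUE),
    method = sample(methods, n, replace = TRUE),
    depth_m = round(runif(n, cfg$depth_range[1], cfg$depth_range[2]), 1)
  ) |>
    mutate(substrate = unname(site_substrate[.data$site_id]),
           elevation_lwl_m = -.data$depth_m,
           slope_deg = round(runif(n, 0, 90)))

  raw <- tibble(substrate = as.numeric(recs$substrate == "natural"),
                depth = recs$depth_m, year = as.numeric(recs$year))
  std <- standardize_design(raw)
  X <- cbind(intercept = 1, as.matrix(std),
             std$substrate * std$depth, std$substrate * std$year)

  # substrate-dependent disturbance trajectory for pre-bleaching spans
  bleach <- rep(0, n)
  if (min(cfg$years) < cfg$bleaching_year) {
    post <- recs$year >= cfg$bleaching_year
    rec_yrs <- cfg$recovery_years[recs$substrate]
    frac <- pmin(1, (recs$year - cfg$bleaching_year) / rec_yrs)
    bleach[post] <- -cfg$bleach_drop * (1 - frac[post])
  }

  alr <- vapply(taxa, function(tx) {
    mu <- drop(X %*% cfg$beta) + cfg$taxon_offsets[[tx]] +
      r_site[match(recs$site_id, sites)] + r_method[match(recs$method, methods)] +
      bleach
    mu + rnorm(n, 0, cfg$eps)
  }, numeric(n))

  pct <- inverse_alr(alr)  # n x 8, includes other_benthic
  percent <- as_tibble(pct[, taxa]) |>
    mutate(total = 100 - pct[, "other_benthic"])

  cells <- percent[taxa]
  for (tx in taxa) {
    cells[[tx]] <- vapply(percent[[tx]], degrade_cell, character(1), cfg = cfg)
  }
  data <- bind_cols(
    recs |> select("record_id", "site_id", "substrate", "year",
                   "elevation_lwl_m", "slope_deg", "method"),
    tibble(total = format(round(percent$total, 1), trim = TRUE)),
    cells
  )
  list(
    data = data,
    percent = bind_cols(recs["record_id"], percent),
    alr = bind_cols(recs["record_id"], as_tibble(alr) |>
                      stats::setNames(paste0("alr_", taxa))),
    truth = list(config = cfg, beta = cfg$beta, taxon_offsets = cfg$taxon_offsets,
                 r_site = setNames(r_site, sites),
                 r_method = setNames(r_method, methods),
                 eps = cfg$eps, scaling = attr(std, "scaling"),
                 site_substrate = site_substrate)
  )
}

#' Configuration for the wave-dissipating-block survey generator
#'
#' Emulates the block monitoring design: three surface-processed and three
#' unprocessed sections, each surveyed with one 50 x 50 cm quadrat at three
#' depths (2, 5 and 8 m below LWL) — 18 quadrats per year — over 18 years
#' since installation. Cover follows a normal alr model and colony density
#' a gamma model (mean-variance parameterization, log link); coefficients
#' are on the standardized scale as in [survey_sim_config()].
#'
#' @param seed Master seed.
#' @param years Years since installation surveyed.
#' @param beta_cover Named true coefficients for the alr-cover model.
#' @param beta_colony Named true coefficients for the log colony-density
#'   model.
#' @param eps_cover Residual SD of alr cover.
#' @param eps_colony Gamma SD of colony density (same units as the
#'   response, colonies per m^2).
#' @return A list of class `block_sim_config`.
#' @export
block_sim_config <- function(seed = 1, years = 1:18,
                             beta_cover = c(intercept = -1.5, processing = 0.8,
                                            depth = -0.4, years = 1.0,
                                            `processing:depth` = 0.0,
                                            `processing:years` = 0.5),
                             beta_colony = c(intercept = 2.0, processing = 0.6,
                                             depth = -0.3, years = 0.8,
                                             `processing:depth` = 0.0,
                                             `processing:years` = 0.4),
                             eps_cover = 0.5, eps_colony = 2.0) {
  stopifnot(eps_cover > 0, eps_colony > 0,
            length(beta_cover) == 6, length(beta_colony) == 6)
  structure(as.list(environment()), class = "block_sim_config")
}

#' Simulate a wave-dissipating-block monitoring survey
#'
#' @param cfg A [block_sim_config()].
#' @return List: `data` (tibble: `record_id`, `years`, `processed`,
#'   `section`, `depth_m`, `alr_cover`, `cover_percent`, `colony_density`)
#'   and `truth`.
#' @export
simulate_block_survey <- function(cfg = block_sim_config()) {
  stopifnot(inherits(cfg, "block_sim_config"))
  set.seed(cfg$seed)
  design <- tidyr::expand_grid(
    years = cfg$years,
    processed = c(0L, 1L),
    section = 1:3,
    depth_m = c(2, 5, 8)
  ) |>
    mutate(record_id = sprintf("blk%04d", row_number()))

  raw <- tibble(processing = as.numeric(design$processed),
                depth = design$depth_m, years = as.numeric(design$years))
  std <- standardize_design(raw)
  X <- cbind(intercept = 1, as.matrix(std),
             std$processing * std$depth, std$processing * std$years)
  n <- nrow(X)

  alr_cover <- drop(X %*% cfg$beta_cover) + rnorm(n, 0, cfg$eps_cover)
  cover_percent <- inverse_alr(cbind(total = alr_cover))[, "total"]

  mu <- exp(drop(X %*% cfg$beta_colony))
  shape <- mu^2 / cfg$eps_colony^2
  rate <- mu / cfg$eps_colony^2
  colony <- rgamma(n, shape = shape, rate = rate)
  # gamma support is (0, inf); guard against numerical underflow to 0
  colony <- pmax(colony, .Machine$double.eps)

  list(
    data = bind_cols(design["record_id"],
                     design |> select("years", "processed", "section", "depth_m"),
                     tibble(alr_cover = alr_cover,
                            cover_percent = unname(cover_percent),
                            colony_density = colony)),
    truth = list(config = cfg, beta_cover = cfg$beta_cover,
                 beta_colony = cfg$beta_colony, eps_cover = cfg$eps_cover,
                 eps_colony = cfg$eps_colony, scaling = attr(std, "scaling"))
  )
}

#' Configuration for the tide-pool chemistry generator
#'
#' One artificial-tide-pool day: a sinusoidal daytime light curve (zero at
#' night), a 3-4 h stagnant low-tide span during which total alkalinity is
#' drawn down by calcification following a known tanh light response, and
#' TA measurement noise at the titration accuracy (~3 umol kg^-1).
#'
#' @param seed Master seed.
#' @param station_ids Stations to simulate (each gets the same truth unless
#'   `a` etc. are vectors recycled across stations).
#' @param date Label for the sampling day.
#' @param a,Ik,c0 True tanh light response `NEC(I) = a * tanh(I / Ik) + c0`
#'   (mmol m^-2 h^-1; `Ik` in light units).
#' @param light_max Midday peak photon flux (umol m^-2 s^-1 scale).
#' @param sunrise_h,sunset_h Daylight window (h).
#' @param stagnant_spans List of `c(start_h, end_h)` stagnant low-tide
#'   spans, each treated as a separate sampling occasion (TA restarts at
#'   `ta0`). The default pairs a morning span (light rising from low to
#'   near-saturating) with a night span (zero light), emulating the pooling
#'   of daytime and night-time sampling days that identifies both the
#'   light-saturated and dark ends of the response.
#' @param sample_interval_min Chemistry sampling interval (10-12 min in the
#'   field design).
#' @param depth_m Mean pool water depth during stagnation (m).
#' @param ta0 TA at the start of the stagnant span (mmol kg^-1).
#' @param temp_c,salinity Pool temperature and salinity.
#' @param ta_noise_sd TA measurement noise SD (mmol kg^-1).
#' @return A list of class `tidepool_sim_config`.
#' @export
tidepool_sim_config <- function(seed = 1, station_ids = "st1", date = "day1",
                                a = 6, Ik = 500, c0 = -1,
                                light_max = 1500, sunrise_h = 6, sunset_h = 18,
                                stagnant_spans = list(c(7.5, 11), c(21, 24)),
                                sample_interval_min = 12, depth_m = 0.5,
                                ta0 = 2.3, temp_c = 28, salinity = 34,
                                ta_noise_sd = 0.003) {
  stopifnot(sample_interval_min > 0, depth_m > 0, ta0 > 0,
            all(vapply(stagnant_spans, function(s) s[2] > s[1], logical(1))))
  structure(as.list(environment()), class = "tidepool_sim_config")
}

# sinusoidal daytime light curve, zero at night
daylight_curve <- function(t, cfg) {
  ifelse(t >= cfg$sunrise_h & t <= cfg$sunset_h,
         cfg$light_max * sin(pi * (t - cfg$sunrise_h) / (cfg$sunset_h - cfg$sunrise_h))^2,
         0)
}

#' Simulate a tide-pool sampling day
#'
#' Evolves TA through the stagnant span with
#' `dTA/dt = -2 * NEC(I(t)) / (Zbar * rho)` (the TA-anomaly relation run
#' forward), samples it at the configured interval with measurement noise,
#' and returns the full-day light record plus the analytic truth (including
#' the exact daily integral of the true light response).
#'
#' @param cfg A [tidepool_sim_config()].
#' @return List: `series` (a [tidepool_series()]), `light_day`
#'   (tibble `time_h`, `light` over 0-24 h), `truth` (parameters, density
#'   used and `daily_nec_true`, the fine-grid integral of the true
#'   response over the day).
#' @export
simulate_tidepool_day <- function(cfg = tidepool_sim_config()) {
  stopifnot(inherits(cfg, "tidepool_sim_config"))
  set.seed(cfg$seed)
  rho <- seawater_density(cfg$temp_c, cfg$salinity)
  k <- length(cfg$station_ids)
  pars <- tibble(station_id = cfg$station_ids,
                 a = rep(cfg$a, length.out = k),
                 Ik = rep(cfg$Ik, length.out = k),
                 c0 = rep(cfg$c0, length.out = k))
  nec_true <- function(I, p) p$a * tanh(I / p$Ik) + p$c0

  series <- purrr::map_dfr(seq_len(k), function(s) {
    p <- pars[s, ]
    purrr::map_dfr(seq_along(cfg$stagnant_spans), function(sp) {
      span <- cfg$stagnant_spans[[sp]]
      t_samp <- seq(span[1], span[2], by = cfg$sample_interval_min / 60)
      # fine forward integration of the TA drawdown between samples
      t_fine <- seq(span[1], max(t_samp), by = 1 / 600)
      dta <- -2 * nec_true(daylight_curve(t_fine, cfg), p) / (cfg$depth_m * rho)
      ta_fine <- cfg$ta0 + c(0, cumsum(0.5 * (dta[-1] + dta[-length(dta)]) * diff(t_fine)))
      ta <- stats::approx(t_fine, ta_fine, xout = t_samp)$y +
        rnorm(length(t_samp), 0, cfg$ta_noise_sd)
      tibble(station_id = p$station_id,
             date = sprintf("%s_span%d", cfg$date, sp), time_h = t_samp,
             ta_mmol_kg = ta, depth_m = cfg$depth_m, temp_c = cfg$temp_c,
             salinity = cfg$salinity,
             photon_flux = daylight_curve(t_samp, cfg), stagnant = TRUE)
    })
  })

  t_day <- seq(0, 24, by = 1 / 6)
  light_day <- tibble(time_h = t_day, light = daylight_curve(t_day, cfg))
  t_grid <- seq(0, 24, by = 1 / 600)
  daily_true <- vapply(seq_len(k), function(s) {
    pracma::trapz(t_grid, nec_true(daylight_curve(t_grid, cfg), pars[s, ]))
  }, numeric(1))

  list(
    series = tidepool_series(series),
    light_day = light_day,
    truth = list(config = cfg, params = pars, density = rho,
                 daily_nec_true = setNames(daily_true, cfg$station_ids))
  )
}

#' Write a simulated survey and its truth sidecar
#'
#' @param sim Output of [simulate_survey()], [simulate_block_survey()] or
#'   [simulate_tidepool_day()].
#' @param dir Output directory.
#' @param stem File stem.
#' @return Named character vector of the files written, invisibly.
#' @export
write_simulation <- function(sim, dir, stem = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  tabular <- sim[setdiff(names(sim)[vapply(sim, is.data.frame, logical(1))], "series")]
  for (nm in names(tabular)) {
    f <- file.path(dir, sprintf("%s_%s.csv", stem, nm))
    readr::write_csv(tabular[[nm]], f, progress = FALSE)
    files[nm] <- f
  }
  if ("series" %in% names(sim)) {
    f <- file.path(dir, sprintf("%s_series.csv", stem))
    readr::write_csv(as_tibble(sim$series), f, progress = FALSE)
    files["series"] <- f
  }
  truth_file <- file.path(dir, sprintf("%s_truth.json", stem))
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, truth_file, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  files["truth"] <- truth_file
  invisible(files)
}
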