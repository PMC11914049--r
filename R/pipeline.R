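#' Run one analysis stage with a reproducible manifest
#'
#' Orchestrates the package's stages over files in an output directory,
#' recording a JSON run manifest (config snapshot, master seed, input/output
#' digests, package version) sufficient to reproduce each stage
#' bit-for-bit. All randomness flows from the single `seed`.
#'
#' Stages and their main outputs:
#' \describe{
#'   \item{`simulate`}{`config$what` one of `"survey"`, `"block"`,
#'     `"tidepool"`; writes the simulated tables + truth sidecar.}
#'   \item{`resolve`}{reads `survey_data.csv`, writes `resolved.csv` and
#'     `alr.csv`.}
#'   \item{`fit-hbm`}{fits `config$equation` (`"reef_cover"`,
#'     `"block_cover"`, `"block_colony"`) to `config$response`, with an
#'     optional `config$year_range` subset; writes `hbm_summary.json` and
#'     `hbm_draws.csv`.}
#'   \item{`ordinate`}{robust Aitchison distances, nMDS and PERMANOVA on
#'     the resolved covers; writes coordinates and the partition table.}
#'   \item{`curves`}{per-taxon depth smooths and back-transformed percent
#'     curves; writes `curves.csv`.}
#'   \item{`nec`}{window NEC, light-response fit and daily NEC from the
#'     tide-pool series; writes `nec_windows.csv`, `light_response.json`,
#'     `daily_nec.csv`.}
#'   \item{`report`}{collates the stage manifests into `run_manifest.json`.}
#' }
#'
#' @param stage Stage name.
#' @param config Named list of stage options (see Details).
#' @param outdir Directory for inputs/outputs.
#' @param seed Master seed.
#' @return Named list of outputs (stage-dependent), invisibly for
#'   file-only stages; the manifest is always written alongside.
#' @export
run_stage <- function(stage = c("simulate", "resolve", "fit-hbm", "ordinate",
                                "curves", "nec", "report"),
                      config = list(), outdir = ".", seed = 1) {
  stage <- match.arg(stage)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character(0)
  outputs <- character(0)
  result <- NULL

  need_input <- function(f, producer) {
    path <- file.path(outdir, f)
    if (!file.exists(path)) {
      abort(sprintf("Stage '%s' needs %s; run the '%s' stage first",
                    stage, f, producer))
    }
    path
  }

  if (stage == "simulate") {
    what <- config$what %||% "survey"
    sim <- switch(what,
      survey = simulate_survey(modify_config(survey_sim_config(seed = seed), config)),
      block = simulate_block_survey(modify_config(block_sim_config(seed = seed), config)),
      tidepool = simulate_tidepool_day(modify_config(tidepool_sim_config(seed = seed), config)),
      abort(sprintf("Unknown simulation '%s'", what)))
    outputs <- write_simulation(sim, outdir, stem = what)
    result <- sim
  } else if (stage == "resolve") {
    inputs <- need_input("survey_data.csv", "simulate")
    tbl <- read_survey_table(inputs, quiet = TRUE)
    resolved <- resolve_survey(tbl, tolerance = config$tolerance %||% 1)
    alr <- cover_to_alr(resolved)
    outputs <- c(resolved = file.path(outdir, "resolved.csv"),
                 alr = file.path(outdir, "alr.csv"))
    readr::write_csv(resolved, outputs["resolved"], progress = FALSE)
    readr::write_csv(alr, outputs["alr"], progress = FALSE)
    result <- list(resolved = resolved, alr = alr)
  } else if (stage == "fit-hbm") {
    equation <- config$equation %||% "reef_cover"
    input_file <- if (equation == "reef_cover") "alr.csv" else "block_data.csv"
    producer <- if (equation == "reef_cover") "resolve" else "simulate"
    inputs <- need_input(input_file, producer)
    data <- readr::read_csv(inputs, show_col_types = FALSE, progress = FALSE)
    if (!is.null(config$year_range)) {
      yr_col <- if (equation == "reef_cover") "year" else "years"
      data <- data[data[[yr_col]] >= config$year_range[1] &
                     data[[yr_col]] <= config$year_range[2], ]
    }
    response <- config$response %||%
      if (equation == "reef_cover") "alr_total" else
        if (equation == "block_colony") "colony_density" else "alr_cover"
    spec <- hbm_spec(equation,
                     beta_bounds = config$beta_bounds,
                     halfcauchy_scale = config$halfcauchy_scale %||% 1e-2)
    fit <- fit_hbm(data, response, spec, seed = seed)
    outputs <- c(summary = file.path(outdir, "hbm_summary.json"),
                 draws = file.path(outdir, "hbm_draws.csv"))
    jsonlite::write_json(list(summary = tidy(fit), glance = glance(fit),
                              run_seeds = fit$run_seeds),
                         outputs["summary"], auto_unbox = TRUE, digits = NA)
    readr::write_csv(as_tibble(fit$draws), outputs["draws"], progress = FALSE)
    result <- fit
  } else if (stage == "ordinate") {
    inputs <- need_input("resolved.csv", "resolve")
    resolved <- readr::read_csv(inputs, show_col_types = FALSE, progress = FALSE)
    taxa <- reef_taxa()
    keep <- complete.cases(resolved[, c("total", taxa)])
    df <- resolved[keep, ]
    comp <- t(apply(df[taxa], 1, function(p) {
      close_composition(setNames(as.numeric(p), taxa))
    }))
    rownames(comp) <- df$record_id
    d <- robust_aitchison_dist(comp)
    ord <- nmds(d, restarts = config$restarts %||% 50, seed = seed)
    perm <- permanova(d, df, perms = config$perms %||% 999, seed = seed)
    outputs <- c(coords = file.path(outdir, "nmds_coords.csv"),
                 permanova = file.path(outdir, "permanova.csv"))
    readr::write_csv(ord$points, outputs["coords"], progress = FALSE)
    readr::write_csv(perm, outputs["permanova"], progress = FALSE)
    result <- list(ordination = ord, permanova = perm)
  } else if (stage == "curves") {
    inputs <- need_input("alr.csv", "resolve")
    alr <- readr::read_csv(inputs, show_col_types = FALSE, progress = FALSE)
    k <- config$k %||% 10
    grid <- seq(min(alr$depth_m), max(alr$depth_m), length.out = 50)
    fits <- lapply(setNames(reef_taxa(), reef_taxa()), function(tx) {
      fit_smooth(alr$depth_m, alr[[paste0("alr_", tx)]], k = k)
    })
    total_fit <- fit_smooth(alr$depth_m, alr$alr_total, k = k)
    curves <- back_transform_curves(fits, grid, total_fit = total_fit)
    outputs <- c(curves = file.path(outdir, "curves.csv"))
    readr::write_csv(curves, outputs["curves"], progress = FALSE)
    result <- list(fits = fits, total_fit = total_fit, curves = curves)
  } else if (stage == "nec") {
    inputs <- need_input("tidepool_series.csv", "simulate")
    series <- tidepool_series(readr::read_csv(inputs, show_col_types = FALSE,
                                              progress = FALSE))
    windows <- nec_windows(series)
    lr <- fit_light_response(windows$nec, windows$mean_light)
    light_file <- file.path(outdir, "tidepool_light_day.csv")
    daily <- if (file.exists(light_file)) {
      ld <- readr::read_csv(light_file, show_col_types = FALSE, progress = FALSE)
      integrate_daily_nec(lr, ld)
    } else NULL
    outputs <- c(windows = file.path(outdir, "nec_windows.csv"),
                 light = file.path(outdir, "light_response.json"))
    readr::write_csv(windows, outputs["windows"], progress = FALSE)
    jsonlite::write_json(list(form = lr$form, coef = as.list(lr$coef),
                              aicc = as.list(lr$aicc)),
                         outputs["light"], auto_unbox = TRUE, digits = NA)
    if (!is.null(daily)) {
      outputs["daily"] <- file.path(outdir, "daily_nec.csv")
      readr::write_csv(daily, outputs["daily"], progress = FALSE)
    }
    result <- list(windows = windows, light_response = lr, daily = daily)
  } else if (stage == "report") {
    mf <- list.files(outdir, pattern = "^manifest_.*\\.json$", full.names = TRUE)
    collated <- lapply(mf, jsonlite::read_json)
    out <- file.path(outdir, "run_manifest.json")
    jsonlite::write_json(collated, out, auto_unbox = TRUE, digits = NA)
    outputs <- c(run_manifest = out)
    result <- collated
  }

  manifest <- list(
    stage = stage,
    config = config,
    seed = seed,
    package_version = as.character(utils::packageVersion("reefstats")),
    inputs = as.list(tools::md5sum(inputs)),
    outputs = as.list(tools::md5sum(unname(outputs[file.exists(unname(outputs))])))
  )
  jsonlite::write_json(manifest, file.path(outdir, sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, digits = NA)
  invisible(result)
}

# override default config fields with user-supplied values (shared keys only)
modify_config <- function(cfg, overrides) {
  for (nm in intersect(names(overrides), names(cfg))) cfg[[nm]] <- overrides[[nm]]
  cfg
}

#' Run a chain of stages with one master seed
#'
#' @param stages Character vector of stage names, run in order.
#' @param config Named list of per-stage configs (keyed by stage name) or a
#'   single shared config list.
#' @param outdir Shared output directory.
#' @param seed Master seed used by every stage.
#' @return Named list of stage results, invisibly.
#' @export
run_pipeline <- function(stages, config = list(), outdir = ".", seed = 1) {
  per_stage <- all(names(config) %in% stages) && length(config) > 0
  results <- lapply(setNames(stages, stages), function(st) {
    cfg <- if (per_stage) config[[st]] %||% list() else config
    run_stage(st, config = cfg, outdir = outdir, seed = seed)
  })
  invisible(results)
}
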