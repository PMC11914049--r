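#' Seawater density at atmospheric pressure
#'
#' One-atmosphere international equation of state of seawater (EOS-80;
#' Millero & Poisson 1981 polynomial in temperature and practical
#' salinity). A constant override is available for sensitivity checks or
#' when no sonde record exists.
#'
#' @param temperature_c Temperature in degrees C, within `[-2, 40]`.
#' @param salinity Practical salinity, within `[0, 42]`.
#' @param constant Optional constant density (kg m^-3) returned verbatim.
#' @return Density in kg m^-3.
#' @examples
#' seawater_density(25, 35) # ~1023.3
#' @export
seawater_density <- function(temperature_c, salinity, constant = NULL) {
  if (!is.null(constant)) return(rep(constant, length.out = max(length(temperature_c), 1)))
  t <- temperature_c; s <- salinity
  if (any(t < -2 | t > 40)) abort("temperature_c outside [-2, 40]")
  if (any(s < 0 | s > 42)) abort("salinity outside [0, 42]")
  rho_w <- 999.842594 + 6.793952e-2 * t - 9.095290e-3 * t^2 +
    1.001685e-4 * t^3 - 1.120083e-6 * t^4 + 6.536332e-9 * t^5
  A <- 0.824493 - 4.0899e-3 * t + 7.6438e-5 * t^2 - 8.2467e-7 * t^3 +
    5.3875e-9 * t^4
  B <- -5.72466e-3 + 1.0227e-4 * t - 1.6546e-6 * t^2
  C <- 4.8314e-4
  rho_w + A * s + B * s^1.5 + C * s^2
}

#' Assemble and validate a tide-pool chemistry series
#'
#' @param data Data frame with columns `station_id`, `date`, `time_h`
#'   (hours), `ta_mmol_kg` (total alkalinity, mmol kg^-1), `depth_m` (mean
#'   water depth), `temp_c`, `salinity`, `photon_flux`, and logical
#'   `stagnant` flagging spans when the pool rim is exposed and the pool is
#'   isolated from the surrounding sea.
#' @return The validated tibble (class `tidepool_series`), ordered by
#'   station and time.
#' @export
tidepool_series <- function(data) {
  need <- c("station_id", "date", "time_h", "ta_mmol_kg", "depth_m",
            "temp_c", "salinity", "photon_flux", "stagnant")
  miss <- setdiff(need, names(data))
  if (length(miss)) abort(sprintf("Missing column(s): %s", paste(miss, collapse = ", ")))
  out <- as_tibble(data) |> arrange(.data$station_id, .data$date, .data$time_h)
  by <- paste(out$station_id, out$date)
  for (g in unique(by)) {
    tt <- out$time_h[by == g]
    if (any(diff(tt) <= 0)) abort(sprintf("Times not strictly increasing for %s", g))
  }
  if (any(out$ta_mmol_kg <= 0)) abort("TA must be positive")
  if (any(out$ta_mmol_kg > 10)) {
    warn("TA > 10 mmol kg^-1: check units (values look like umol kg^-1)")
  }
  if (any(out$stagnant & out$depth_m <= 0)) abort("Depth must be positive during stagnant spans")
  class(out) <- c("tidepool_series", class(out))
  out
}

#' Net ecosystem calcification over one sampling window
#'
#' Total-alkalinity-anomaly estimate for a short window inside a stagnant
#' span: `NEC = -1/2 * dTA/dt * Zbar * rho_water` (mmol CaCO3 m^-2 h^-1),
#' two moles of TA being consumed per mole of CaCO3 precipitated. The TA
#' trend `dTA/dt` is the least-squares slope of TA against time over the
#' window (using every sample, not just the endpoints); its standard error
#' propagates directly to the NEC standard error. A TA decrease gives
#' positive NEC (net calcification); a TA rise gives negative NEC (net
#' dissolution).
#'
#' @param window Data frame of at least 3 consecutive samples from a
#'   stagnant span (columns as in [tidepool_series()]).
#' @param density Optional constant seawater density (kg m^-3); otherwise
#'   computed from mean window temperature and salinity.
#' @param min_span_h Minimum window time span in hours.
#' @return One-row tibble: `start_h`, `end_h`, `n`, `nec`, `nec_se`
#'   (mmol m^-2 h^-1), `ta_slope`, `ta_slope_se` (mmol kg^-1 h^-1),
#'   `mean_depth_m`, `density`, `mean_light`.
#' @export
window_nec <- function(window, density = NULL, min_span_h = 0.5) {
  if (nrow(window) < 3) abort("A NEC window needs at least 3 samples")
  if (!all(window$stagnant)) {
    abort("Window extends outside a stagnant span: the TA-anomaly method assumes no advection")
  }
  span <- diff(range(window$time_h))
  if (span <= min_span_h) {
    abort(sprintf("Window spans %.2f h; must exceed %.2f h", span, min_span_h))
  }
  sl <- lm(ta_mmol_kg ~ time_h, data = window)
  slope <- coef(sl)[["time_h"]]
  slope_se <- sqrt(vcov(sl)["time_h", "time_h"])
  zbar <- mean(window$depth_m)
  rho <- density %||% seawater_density(mean(window$temp_c), mean(window$salinity))
  tibble(
    start_h = min(window$time_h), end_h = max(window$time_h), n = nrow(window),
    nec = -0.5 * slope * zbar * rho,
    nec_se = 0.5 * slope_se * zbar * rho,
    ta_slope = slope, ta_slope_se = slope_se,
    mean_depth_m = zbar, density = rho,
    mean_light = mean(window$photon_flux)
  )
}

#' Sliding NEC windows over the stagnant spans of a series
#'
#' Builds consecutive-sample windows within each stagnant span and estimates
#' NEC in each with [window_nec()]. Windows start at `min_samples` samples
#' and are widened until they span more than `min_span_h` hours (with a
#' 10-12 min sampling interval this typically takes 4 samples to exceed
#' 30 min).
#'
#' @param series A [tidepool_series()].
#' @param min_samples Minimum samples per window.
#' @param min_span_h Minimum window span (hours).
#' @param density Optional constant density override.
#' @return Tibble of window estimates with `station_id` and `date`.
#' @export
nec_windows <- function(series, min_samples = 3, min_span_h = 0.5, density = NULL) {
  series |>
    filter(.data$stagnant) |>
    group_by(.data$station_id, .data$date) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      out <- list()
      i <- 1
      while (i <= n - min_samples + 1) {
        j <- i + min_samples - 1
        while (j <= n && df$time_h[j] - df$time_h[i] <= min_span_h) j <- j + 1
        if (j > n) break
        out[[length(out) + 1]] <-
          window_nec(df[i:j, ], density = density, min_span_h = min_span_h)
        i <- i + 1
      }
      if (!length(out)) return(tibble())
      bind_rows(out)
    }) |>
    ungroup()
}

#' Fit a light response of net ecosystem calcification
#'
#' Regresses window NEC against light as either a saturating hyperbolic
#' tangent, `NEC(I) = a * tanh(I / I_k) + c` (photosynthesis-irradiance
#' analogue: `a` the light-saturated amplitude, `I_k` the saturation onset,
#' `c` the dark rate), or a straight line `NEC(I) = b * I + c`. Both are
#' fitted (nonlinear and ordinary least squares) and the form with the
#' lower small-sample AIC (AICc) is selected; a non-converging tanh fit
#' falls back to linear with a warning.
#'
#' @param nec Numeric vector of window NEC values (mmol m^-2 h^-1).
#' @param light Matching light intensities.
#' @param form `"auto"` (AICc selection), `"tanh"`, or `"linear"`.
#' @return Object of class `light_response`: `form`, `coef`, `vcov`,
#'   `aicc` (both forms where available), and the model object.
#' @export
fit_light_response <- function(nec, light, form = c("auto", "tanh", "linear")) {
  form <- match.arg(form)
  stopifnot(length(nec) == length(light))
  if (sd(light) == 0) abort("All light values equal: light dependence not identifiable")
  df <- data.frame(nec = nec, light = light)
  aicc <- function(fit, k) {
    n <- length(nec)
    AIC(fit) + 2 * k * (k + 1) / max(n - k - 1, 0.5)
  }
  lin <- lm(nec ~ light, data = df)
  lin_vcov <- vcov(lin)[c(2, 1), c(2, 1)]
  dimnames(lin_vcov) <- list(c("b", "c"), c("b", "c"))
  lin_out <- list(form = "linear",
                  coef = c(b = unname(coef(lin)[2]), c = unname(coef(lin)[1])),
                  vcov = lin_vcov,
                  model = lin, aicc_linear = aicc(lin, 3))
  tanh_out <- NULL
  if (form != "linear" && length(nec) >= 4) {
    start <- list(a = max(nec) - min(nec),
                  Ik = max(stats::median(light[light > 0], na.rm = TRUE), 1),
                  c = min(nec))
    tanh_fit <- tryCatch(
      minpack.lm::nlsLM(nec ~ a * tanh(light / Ik) + c, data = df, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(tanh_fit)) {
      tanh_vcov <- vcov(tanh_fit)
      dimnames(tanh_vcov) <- list(names(coef(tanh_fit)), names(coef(tanh_fit)))
      tanh_out <- list(form = "tanh", coef = coef(tanh_fit),
                       vcov = tanh_vcov, model = tanh_fit,
                       aicc_tanh = aicc(tanh_fit, 4))
    }
  }
  sel <- if (form == "linear" || is.null(tanh_out)) {
    if (form == "tanh") warn("tanh fit failed to converge: falling back to linear")
    lin_out
  } else if (form == "tanh") {
    tanh_out
  } else {
    if (tanh_out$aicc_tanh < lin_out$aicc_linear) tanh_out else lin_out
  }
  sel$aicc <- c(linear = lin_out$aicc_linear,
                tanh = if (!is.null(tanh_out)) tanh_out$aicc_tanh else NA_real_)
  sel$data <- as_tibble(df)
  structure(sel, class = "light_response")
}

#' Evaluate a light-response fit
#'
#' @param object A `light_response`.
#' @param light Light intensities.
#' @param ... Unused.
#' @return Predicted NEC.
#' @export
predict.light_response <- function(object, light, ...) {
  p <- object$coef
  if (object$form == "tanh") p[["a"]] * tanh(light / p[["Ik"]]) + p[["c"]]
  else p[["b"]] * light + p[["c"]]
}

#' @rdname fit_light_response
#' @param x,object A `light_response`.
#' @param ... Unused.
#' @method tidy light_response
#' @export
tidy.light_response <- function(x, ...) {
  tibble(term = names(x$coef), estimate = unname(x$coef),
         std_error = sqrt(diag(x$vcov)))
}

#' @export
print.light_response <- function(x, ...) {
  cat(sprintf("Light response (%s): %s\n", x$form,
              paste(sprintf("%s = %.4g", names(x$coef), x$coef), collapse = ", ")))
  invisible(x)
}

#' Daily net ecosystem calcification by integrating the light response
#'
#' Integrates the fitted NEC-light response over a 24-h light series
#' (trapezoid rule; night-time zeros included) to obtain daily NEC in
#' mmol CaCO3 m^-2 day^-1. The SD is first-order (delta-method) error
#' propagation: the gradient of the integral with respect to the regression
#' parameters, through the parameter covariance.
#'
#' @param fit A `light_response`.
#' @param light_day Data frame with `time_h` covering `[0, 24]` and `light`.
#' @param max_gap_h Largest tolerated gap between light samples.
#' @return One-row tibble: `daily_nec`, `daily_nec_sd`.
#' @export
integrate_daily_nec <- function(fit, light_day, max_gap_h = 2) {
  stopifnot(inherits(fit, "light_response"))
  t <- light_day$time_h; I <- light_day$light
  if (min(t) > 0 + 1e-9 || max(t) < 24 - 1e-9) {
    abort("Light series must cover the full 24 h day")
  }
  if (any(diff(t) > max_gap_h)) {
    abort(sprintf("Gap in light series exceeds %.1f h", max_gap_h))
  }
  value <- pracma::trapz(t, predict(fit, I))
  # gradient of the integral w.r.t. the regression parameters
  g <- if (fit$form == "tanh") {
    a <- fit$coef[["a"]]; Ik <- fit$coef[["Ik"]]
    c(a = pracma::trapz(t, tanh(I / Ik)),
      Ik = pracma::trapz(t, -a * I / (Ik^2 * cosh(I / Ik)^2)),
      c = pracma::trapz(t, rep(1, length(t))))
  } else {
    c(b = pracma::trapz(t, I),
      c = pracma::trapz(t, rep(1, length(t))))
  }
  V <- fit$vcov[names(g), names(g)]
  tibble(daily_nec = value, daily_nec_sd = sqrt(max(0, drop(t(g) %*% V %*% g))))
}

#' Compare TA drawdown slopes among tide-pool stations
#'
#' Analysis of covariance of total alkalinity against time by station over
#' stagnant spans: per-station slopes (hence average NEC), an F-test of
#' slope homogeneity (time-by-station interaction), and Tukey-style pairwise
#' slope contrasts (via emmeans when available).
#'
#' @param series A [tidepool_series()] covering 2 or more stations.
#' @param min_samples Minimum stagnant samples for a station to enter.
#' @return List: `slopes` (tibble: station, slope, se, n),
#'   `homogeneity` (tibble: F statistic, df, p for the interaction),
#'   `pairwise` (tibble of slope contrasts, or NULL if emmeans is absent).
#' @export
compare_station_slopes <- function(series, min_samples = 3) {
  df <- series |> filter(.data$stagnant)
  counts <- table(df$station_id)
  keep <- names(counts)[counts >= min_samples]
  if (length(keep) < length(counts)) {
    warn(sprintf("Skipping station(s) with < %d stagnant samples: %s",
                 min_samples, paste(setdiff(names(counts), keep), collapse = ", ")))
  }
  if (length(keep) < 2) abort("Need at least 2 stations with enough samples")
  df <- df |> filter(.data$station_id %in% keep) |>
    mutate(station_id = factor(.data$station_id))
  m_int <- lm(ta_mmol_kg ~ time_h * station_id, data = df)
  m_add <- lm(ta_mmol_kg ~ time_h + station_id, data = df)
  an <- anova(m_add, m_int)
  slopes <- df |>
    group_by(.data$station_id) |>
    dplyr::group_modify(function(d, key) {
      sl <- lm(ta_mmol_kg ~ time_h, data = d)
      tibble(slope = coef(sl)[["time_h"]],
             se = sqrt(vcov(sl)["time_h", "time_h"]), n = nrow(d))
    }) |>
    ungroup() |>
    dplyr::rename(station = "station_id")
  pairwise <- NULL
  if (requireNamespace("emmeans", quietly = TRUE)) {
    tr <- emmeans::emtrends(m_int, "station_id", var = "time_h")
    pw <- summary(graphics::pairs(tr), adjust = "tukey")
    pairwise <- tibble(contrast = as.character(pw$contrast),
                       estimate = pw$estimate, se = pw$SE,
                       t_ratio = pw$t.ratio, p_value = pw$p.value)
  }
  list(
    slopes = slopes,
    homogeneity = tibble(f = an$F[2], df1 = an$Df[2], df2 = an$Res.Df[2],
                         p_value = an$`Pr(>F)`[2]),
    pairwise = pairwise
  )
}
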