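#' Configuration for the synthetic LTE panel generator
#'
#' Describes a multi-year, multi-treatment yield panel with known
#' stability structure. Observed yields follow the Finlay-Wilkinson model
#' `y_ij = beta_i + alpha_i * omega_j + eps_ij` with environment (year)
#' effects `omega_j ~ N(env_mean, env_sd)` and treatment noise whose SD
#' follows a Taylor power law, `sd(eps_i) = sqrt(taylor_c *
#' mean_i^taylor_b)`. The predicted series shares the environmental signal
#' but has its interannual SD multiplied by `prediction_shrinkage` and its
#' level shifted by `prediction_bias`, emulating crop-model output that is
#' less variable than the field data.
#'
#' Either treatment `means` (then slopes default to 1) or explicit
#' `fw_slopes`/`fw_intercepts` must be given; in the latter case means are
#' implied by `mean_i = beta_i + alpha_i * env_mean`.
#'
#' @param means Treatment base mean yields (Mg/ha), all positive.
#' @param fw_slopes,fw_intercepts Per-treatment Finlay-Wilkinson
#'   coefficients.
#' @param n_environments Number of environments (years).
#' @param env_mean,env_sd Mean and SD of the environment effects (Mg/ha).
#' @param taylor_b,taylor_c Exponent and scale of the mean-variance power
#'   law for the treatment noise; `taylor_c = 0` gives a noise-free panel.
#' @param prediction_shrinkage Ratio of predicted to observed interannual
#'   SD, in (0, 1].
#' @param prediction_bias Level shift of the predicted series (Mg/ha).
#' @param treatment_ids Optional labels; default T01, T02, ...
#' @param dataset_id Dataset label for the generated panel.
#' @param factors Optional tibble of per-treatment factor columns
#'   (row-matched to treatments) copied onto the records.
#' @param seed Integer seed; the generator is reproducible given the seed.
#' @return A list of class `panel_config`.
#' @export
panel_config <- function(means = NULL, fw_slopes = NULL,
                         fw_intercepts = NULL, n_environments = 8,
                         env_mean = NULL, env_sd = 0.5, taylor_b = 2,
                         taylor_c = 0.01, prediction_shrinkage = 1,
                         prediction_bias = 0, treatment_ids = NULL,
                         dataset_id = "synthetic", factors = NULL,
                         seed = 1L) {
  if (is.null(means) && (is.null(fw_slopes) || is.null(fw_intercepts))) {
    stop("give either `means` or both `fw_slopes` and `fw_intercepts`",
         call. = FALSE)
  }
  if (is.null(fw_slopes)) fw_slopes <- rep(1, length(means))
  if (is.null(env_mean)) {
    env_mean <- if (!is.null(means)) mean(means) else 1
  }
  if (is.null(fw_intercepts)) fw_intercepts <- means - fw_slopes * env_mean
  if (is.null(means)) means <- fw_intercepts + fw_slopes * env_mean
  if (any(means <= 0)) stop("treatment means must be positive", call. = FALSE)
  if (prediction_shrinkage <= 0 || prediction_shrinkage > 1) {
    stop("prediction_shrinkage must be in (0, 1]", call. = FALSE)
  }
  if (env_sd < 0 || taylor_c < 0) {
    stop("env_sd and taylor_c must be non-negative", call. = FALSE)
  }
  n_t <- length(means)
  stopifnot(length(fw_slopes) == n_t, length(fw_intercepts) == n_t,
            n_environments >= 2)
  treatment_ids <- treatment_ids %||% sprintf("T%02d", seq_len(n_t))
  structure(list(
    means = means, fw_slopes = fw_slopes, fw_intercepts = fw_intercepts,
    n_treatments = n_t, n_environments = as.integer(n_environments),
    env_mean = env_mean, env_sd = env_sd, taylor_b = taylor_b,
    taylor_c = taylor_c, prediction_shrinkage = prediction_shrinkage,
    prediction_bias = prediction_bias, treatment_ids = treatment_ids,
    dataset_id = dataset_id, factors = factors, seed = as.integer(seed)
  ), class = "panel_config")
}

#' Generate a synthetic observed/predicted LTE yield panel
#'
#' Draws one panel realization from a [panel_config()]. Negative yield
#' draws are truncated at 0; a truncation rate above 10% raises a warning
#' (an error under `strict = TRUE`), since heavy truncation distorts the
#' configured moment structure.
#'
#' @param config A `panel_config`.
#' @param strict Escalate the high-truncation warning to an error.
#' @return A `yield_panel` holding both sources.
#' @export
generate_lte_panel <- function(config, strict = FALSE) {
  stopifnot(inherits(config, "panel_config"))
  with_seed(config$seed, {
    n_t <- config$n_treatments
    n_e <- config$n_environments
    omega <- rnorm(n_e, config$env_mean, config$env_sd)
    eps_sd <- sqrt(config$taylor_c * config$means^config$taylor_b)
    signal <- outer(config$fw_slopes, omega) + config$fw_intercepts
    eps_obs <- matrix(rnorm(n_t * n_e), n_t, n_e) * eps_sd
    eps_prd <- matrix(rnorm(n_t * n_e), n_t, n_e) * eps_sd
    obs <- signal + eps_obs
    shr <- config$prediction_shrinkage
    prd <- config$means + config$prediction_bias +
      shr * (signal - config$means) + shr * eps_prd

    n_neg <- sum(obs < 0) + sum(prd < 0)
    trunc_rate <- n_neg / (2 * n_t * n_e)
    if (trunc_rate > 0.10) {
      msg <- sprintf("%.1f%% of yield draws truncated at zero", 100 * trunc_rate)
      if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    }
    obs[obs < 0] <- 0
    prd[prd < 0] <- 0

    env_ids <- sprintf("E%02d", seq_len(n_e))
    grid <- expand.grid(t = seq_len(n_t), e = seq_len(n_e))
    rec <- function(mat, src) {
      tibble::tibble(
        dataset_id = config$dataset_id, source = src,
        treatment_id = config$treatment_ids[grid$t],
        environment_id = env_ids[grid$e],
        grain_yield = mat[cbind(grid$t, grid$e)])
    }
    df <- dplyr::bind_rows(rec(obs, "observed"), rec(prd, "predicted"))
    if (!is.null(config$factors)) {
      fac <- tibble::as_tibble(config$factors)
      fac$treatment_id <- config$treatment_ids
      df <- dplyr::left_join(df, fac, by = "treatment_id")
    }
    yield_panel(df)
  })
}

#' Preset panel configurations emulating the two LTE panels
#'
#' Returns a [panel_config()] whose treatment means match the observed
#' means of the bundled stability summaries: `"sadore_millet"` (12
#' fertilizer-by-density-by-residue treatments over 8 years, yields about
#' 0.26-0.55 Mg/ha) or `"ndiaye_rice"` (4 N rates by 2 seasons over 8
#' years, 1.6-6.6 Mg/ha). The Taylor noise law is fitted to the published
#' (mean, SD) pairs after setting aside a common environment-effect
#' variance, and the prediction shrinkage/bias are set from the published
#' predicted-to-observed SD ratios and mean offsets.
#'
#' @param name `"sadore_millet"` or `"ndiaye_rice"`.
#' @param seed Seed stored in the config.
#' @return A `panel_config`.
#' @export
preset_panel_config <- function(name = c("sadore_millet", "ndiaye_rice"),
                                seed = 1L) {
  name <- match.arg(name)
  fx <- load_lte_stability(name)
  env_sd <- 0.5 * min(fx$sd_obs)
  resid_var <- pmax(fx$sd_obs^2 - env_sd^2, 1e-6)
  tf <- lm(log10(resid_var) ~ log10(fx$mean_obs))
  b <- unname(coef(tf)[2])
  c_ <- 10^unname(coef(tf)[1])
  shrink <- min(1, mean(fx$sd_pred / fx$sd_obs))
  fac_cols <- setdiff(names(fx), c("dataset_id", "treatment_id", "n",
                                   "mean_obs", "sd_obs", "mean_pred",
                                   "sd_pred", "acv_obs", "acv_pred",
                                   "syi_obs", "syi_pred"))
  panel_config(
    means = fx$mean_obs, n_environments = 8, env_sd = env_sd,
    taylor_b = b, taylor_c = c_, prediction_shrinkage = shrink,
    prediction_bias = mean(fx$mean_pred - fx$mean_obs),
    treatment_ids = fx$treatment_id, dataset_id = name,
    factors = fx[fac_cols], seed = seed)
}

#' Parameter ranges of the toy crop-response function
#'
#' @return A `param_ranges` table with the five parameters of
#'   [toy_crop_model()].
#' @export
toy_crop_ranges <- function() {
  parameter_ranges(tibble::tibble(
    name = c("tt_emerg", "tt_grainfill", "rue", "grain_rate",
             "stress_sens"),
    min = c(100, 200, 1.3, 0.001, 0.1),
    max = c(500, 800, 2.0, 0.05, 0.9),
    unit = c("degC d", "degC d", "g MJ-1", "mg degC d-1", "-")))
}

#' Toy crop-response function for sensitivity testing
#'
#' A deterministic, smooth response surface standing in for a crop
#' simulator in sensitivity-analysis tests. By construction it has (a)
#' strong main effects on the phenology-like thermal-time parameters, (b)
#' a designated pairwise interaction between `rue` and `tt_grainfill`
#' (a centered product term carrying no main-effect variance, so their
#' total-effect indices exceed their main effects detectably), (c) a
#' documented failure region -- points with
#' `tt_emerg + tt_grainfill > 1150` do not reach maturity and return
#' `NA` -- and (d) a year context that perturbs the response coefficients
#' reproducibly.
#'
#' @param point Named numeric vector with entries `tt_emerg`,
#'   `tt_grainfill`, `rue`, `grain_rate`, `stress_sens`, within
#'   [toy_crop_ranges()].
#' @param context Year label (any string/number); identical
#'   (point, context) pairs give identical outputs.
#' @return Named numeric vector `c(yield = , biomass = )` in Mg/ha, or
#'   `NA` in the failure region.
#' @export
toy_crop_model <- function(point, context = "year1") {
  rng <- toy_crop_ranges()
  p <- point[rng$name]
  if (anyNA(p)) {
    stop("point must name all of: ", paste(rng$name, collapse = ", "),
         call. = FALSE)
  }
  if (any(p < rng$min | p > rng$max)) {
    stop("parameter(s) out of range: ",
         paste(rng$name[p < rng$min | p > rng$max], collapse = ", "),
         call. = FALSE)
  }
  # failure region: combined pre- and post-flowering thermal time too long
  # for the season; crop does not reach maturity
  if (p[["tt_emerg"]] + p[["tt_grainfill"]] > 1150) {
    return(c(yield = NA_real_, biomass = NA_real_))
  }
  # deterministic year-effect coefficients from the context label
  h <- sum(utf8ToInt(as.character(context)))
  yf1 <- 1 + 0.12 * sin(h)
  yf2 <- 0.2 * sin(2 * h)

  g <- plogis((p[["tt_grainfill"]] - 500) / 120)      # grain-fill response
  e <- sin(pi * (p[["tt_emerg"]] - 100) / 400)        # establishment window
  ru <- (p[["rue"]] - 1.3) / 0.7                      # rue on [0, 1]
  rc <- (p[["rue"]] - 1.65) / 0.7                     # centered rue
  yield <- 1.2 + yf1 * 2.2 * g + 0.9 * ru +
    3 * rc * (g - 0.5) +                              # pure interaction
    0.5 * e + 6 * p[["grain_rate"]] +
    0.3 * (1 - p[["stress_sens"]]) + yf2
  biomass <- yield * (1.8 + 0.8 * p[["stress_sens"]])
  c(yield = unname(yield), biomass = unname(biomass))
}

#' Blackman thermal-time increment
#'
#' Daily thermal-time accumulation above a base temperature with an
#' optimum cutoff: `max(0, t_mean - tbd)` for `t_mean < tod`. Above the
#' optimum the increment is capped at `tod - tbd` by default (linear-
#' with-plateau reading); `above_tod = "zero"` switches to a zero
#' increment above the optimum.
#'
#' @param t_mean Daily mean air temperature (degrees C), vectorized.
#' @param tbd Base temperature for development (default 15 C).
#' @param tod Optimum temperature for development (default 34 C).
#' @param above_tod Behavior at or above `tod`: `"cap"` (default) or
#'   `"zero"`.
#' @return Thermal-time increments (degree-days).
#' @export
thermal_time <- function(t_mean, tbd = 15, tod = 34,
                         above_tod = c("cap", "zero")) {
  above_tod <- match.arg(above_tod)
  stopifnot(tbd < tod)
  ti <- pmax(0, t_mean - tbd)
  hot <- !is.na(t_mean) & t_mean >= tod
  ti[hot] <- if (above_tod == "cap") tod - tbd else 0
  ti
}

#' @rdname thermal_time
#' @param weather A data frame with `tmin` and `tmax` columns (daily); the
#'   mean of the two drives accumulation.
#' @return `thermal_time_accumulate()`: cumulative thermal time
#'   (degree-days) over the series.
#' @export
thermal_time_accumulate <- function(weather, tbd = 15, tod = 34,
                                    above_tod = c("cap", "zero")) {
  cumsum(thermal_time((weather$tmin + weather$tmax) / 2, tbd = tbd,
                      tod = tod, above_tod = above_tod))
}

#' Generate synthetic daily weather
#'
#' Sinusoidal seasonal temperature cycles with day-to-day noise, a
#' seasonally modulated rainfall occurrence/intensity process tuned so the
#' long-run annual rainfall matches the site preset (Sudano-Sahelian
#' Sadore: 565 mm with a June-October rainy season; Sahelian coastal
#' Ndiaye: 277 mm concentrated in July-October), and a radiation cycle.
#' Deterministic for a fixed seed.
#'
#' @param site `"sadore"` or `"ndiaye"`.
#' @param n_years Number of years (365-day days sequence from 2001-01-01).
#' @param seed Integer seed.
#' @return A tibble with columns `date`, `tmin`, `tmax`, `rain`,
#'   `radiation` (MJ m-2 d-1); `tmin <= tmax` and `rain >= 0` on every
#'   day.
#' @export
generate_weather <- function(site = c("sadore", "ndiaye"), n_years,
                             seed = 1L) {
  site <- match.arg(site)
  stopifnot(n_years >= 1)
  preset <- switch(site,
    sadore = list(rain_total = 565, rain_peak = 225, rain_width = 40,
                  p_max = 0.55, tmin_mean = 22, tmin_amp = 6,
                  tmax_mean = 36, tmax_amp = 5, rad_mean = 21,
                  rad_amp = 3),
    ndiaye = list(rain_total = 277, rain_peak = 240, rain_width = 30,
                  p_max = 0.45, tmin_mean = 19, tmin_amp = 5,
                  tmax_mean = 32, tmax_amp = 4, rad_mean = 20,
                  rad_amp = 4))
  with_seed(seed, {
    dates <- seq(as.Date("2001-01-01"), by = "day",
                 length.out = 365 * n_years)
    doy <- as.POSIXlt(dates)$yday + 1
    p_wet <- preset$p_max *
      exp(-0.5 * ((doy - preset$rain_peak) / preset$rain_width)^2)
    # mean intensity solved so the expected annual total hits the preset
    mu <- preset$rain_total /
      sum(preset$p_max *
            exp(-0.5 * ((1:365 - preset$rain_peak) / preset$rain_width)^2))
    wet <- rbinom(length(doy), 1, p_wet)
    rain <- wet * rgamma(length(doy), shape = 0.8, scale = mu / 0.8)
    seas <- cos(2 * pi * (doy - 135) / 365)  # warm season peak in May
    tmin <- preset$tmin_mean + preset$tmin_amp * seas +
      rnorm(length(doy), 0, 1.2)
    dtr <- pmax(1, (preset$tmax_mean - preset$tmin_mean) +
                  (preset$tmax_amp - preset$tmin_amp) * seas +
                  rnorm(length(doy), 0, 1.5) - 4 * wet)
    radiation <- pmax(5, preset$rad_mean + preset$rad_amp * seas +
                        rnorm(length(doy), 0, 1.5) - 3 * wet)
    tibble::tibble(date = dates, tmin = tmin, tmax = tmin + dtr,
                   rain = rain, radiation = radiation)
  })
}
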