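# Shared daily driver for the chickpea and wheat engines.
#
# Daily order of operations (modify-then-advance): thermal time from the
# cardinal response -> daylength -> water-balance step (demand from the
# current stage) -> FASW -> crop-specific TT factor (wheat photoperiod /
# vernalisation) -> soil-water modification -> stage advance. The water
# balance runs from the first weather day (fallow accumulation before
# sowing); crop development starts the day after sowing.
simulate_crop <- function(weather, profile, sowing_date, sowing_depth,
                          sw_params, init, targets_fun, factor_fun,
                          flowering_stage, terminal_stage, kc,
                          root_rate = 0.7, cardinals = cardinal_temps(),
                          twilight_angle = -2.2, runoff_fraction = 0,
                          crop = "crop", cultivar_name = "") {
  stopifnot(inherits(weather, "weather_series"),
            inherits(profile, "soil_profile"))
  sowing_date <- as.Date(sowing_date)
  if (sowing_date < weather$date[1] || sowing_date > weather$date[nrow(weather)]) {
    stop("sowing date ", format(sowing_date), " outside the weather range")
  }
  if (sowing_depth < 0) stop("sowing depth must be >= 0 (mm)")
  sw_on <- !is.null(sw_params)
  zone <- if (sw_on) sw_params$zone_depth else 60

  state <- if (inherits(init, "soil_water_state")) {
    init
  } else {
    initialize_soil_water(profile,
                          starting_water = init$fraction,
                          mode = if (is.null(init$mode)) "uniform" else init$mode)
  }

  lat <- ws_latitude(weather)
  profile_depth <- max(profile$layers$bottom)
  doy_all <- as.integer(format(weather$date, "%j"))
  tt_all <- daily_thermal_time(weather$tmax, weather$tmin, cardinals)
  pp_all <- daylength(lat, doy_all, twilight_angle)
  et0_all <- et0_hargreaves(lat, doy_all, weather$tmax, weather$tmin)

  sow_i <- which(weather$date == sowing_date)
  n_all <- nrow(weather)

  # fallow water balance up to and including the sowing day
  for (i in seq_len(sow_i)) {
    state <- step_water_balance(profile, state, weather[i, ],
                                transpiration_demand = 0, root_depth = 0,
                                evap_demand = 0.6 * et0_all[i],
                                runoff_fraction = runoff_fraction)
  }

  dev <- list(stage = stage_codes()[["sowing"]], phase_cum = 0)
  cum_tt <- 0          # unadjusted TT from sowing
  cum_ttm <- 0
  flowering_date <- as.Date(NA)
  maturity_date <- as.Date(NA)
  cum_tt_at_flowering <- NA_real_

  n_days <- n_all - sow_i
  trace <- list(date = weather$date[sow_i + seq_len(n_days)],
                stage = integer(n_days), tt = numeric(n_days),
                ttm = numeric(n_days), fasw = numeric(n_days),
                daylength = numeric(n_days), cum_tt = numeric(n_days))

  ll15_top <- profile$layers$ll15[1]
  for (k in seq_len(n_days)) {
    i <- sow_i + k
    tt <- tt_all[i]
    pp <- pp_all[i]

    # root front grows with unadjusted cumulative TT, capped at the profile
    root_cm <- min((sowing_depth + root_rate * cum_tt) / 10, profile_depth)
    demand <- kc[min(dev$stage, length(kc))] * et0_all[i]
    state <- step_water_balance(profile, state, weather[i, ],
                                transpiration_demand = demand,
                                root_depth = root_cm,
                                evap_demand = 0.6 * et0_all[i],
                                runoff_fraction = runoff_fraction)
    fasw <- compute_fasw(profile, state, zone)

    if (dev$stage == stage_codes()[["sowing"]]) {
      # germination needs moist seed-zone soil; waits in dry seedbeds
      if (state$sw[1] > ll15_top) dev$stage <- stage_codes()[["germination"]]
      ttm <- 0
    } else if (dev$stage >= terminal_stage) {
      ttm <- 0
    } else {
      f <- factor_fun(dev$stage, weather$tmax[i], weather$tmin[i], pp)
      tt_dev <- tt * f
      ttm <- if (sw_on) modify_tt(tt_dev, fasw, dev$stage, sw_params) else tt_dev
      dev <- advance_stage(dev, ttm, targets_fun(pp))
      if (flowering_stage %in% dev$entered) {
        flowering_date <- weather$date[i]
        cum_tt_at_flowering <- cum_tt + tt
      }
      if (terminal_stage %in% dev$entered) maturity_date <- weather$date[i]
    }
    cum_tt <- cum_tt + tt
    cum_ttm <- cum_ttm + ttm

    trace$stage[k] <- dev$stage
    trace$tt[k] <- tt
    trace$ttm[k] <- ttm
    trace$fasw[k] <- fasw
    trace$daylength[k] <- pp
    trace$cum_tt[k] <- cum_tt
    if (!is.na(maturity_date)) {
      trace <- lapply(trace, function(v) v[seq_len(k)])
      break
    }
  }

  structure(list(
    trace = as.data.frame(trace),
    crop = crop, cultivar = cultivar_name,
    sowing_date = sowing_date,
    did_flower = !is.na(flowering_date),
    flowering_date = flowering_date,
    days_to_flowering = if (!is.na(flowering_date)) {
      as.integer(flowering_date - sowing_date)
    } else NA_integer_,
    maturity_date = maturity_date,
    days_to_maturity = if (!is.na(maturity_date)) {
      as.integer(maturity_date - sowing_date)
    } else NA_integer_,
    cum_tt_at_flowering = cum_tt_at_flowering,
    soil_water_modification = sw_on
  ), class = "phenology_trace")
}

#' @export
print.phenology_trace <- function(x, ...) {
  cat(sprintf("<phenology_trace> %s '%s', sown %s, soil-water modification %s\n",
              x$crop, x$cultivar, format(x$sowing_date),
              if (x$soil_water_modification) "on" else "off"))
  if (x$did_flower) {
    cat(sprintf("  flowering: %s (%d days after sowing; %.0f degCd unadjusted TT)\n",
                format(x$flowering_date), x$days_to_flowering,
                x$cum_tt_at_flowering))
  } else {
    cat("  did not flower within the weather series\n")
  }
  if (!is.na(x$days_to_maturity)) {
    cat(sprintf("  maturity: %s (%d days after sowing)\n",
                format(x$maturity_date), x$days_to_maturity))
  }
  invisible(x)
}

#' Write the per-day trace and run summary of a simulation
#'
#' @param result a `phenology_trace` from [simulate_chickpea()] or
#'   [simulate_wheat()].
#' @param trace_path CSV path for the per-day trace (date, stage, TT, TTm,
#'   FASW, daylength), or `NULL` to skip.
#' @param summary_path JSON path for the run summary, or `NULL` to skip.
#' @return `result`, invisibly.
#' @export
write_trace <- function(result, trace_path = NULL, summary_path = NULL) {
  stopifnot(inherits(result, "phenology_trace"))
  if (!is.null(trace_path)) {
    utils::write.csv(result$trace, trace_path, row.names = FALSE)
  }
  if (!is.null(summary_path)) {
    s <- result[c("crop", "cultivar", "did_flower", "days_to_flowering",
                  "days_to_maturity", "cum_tt_at_flowering",
                  "soil_water_modification")]
    s$sowing_date <- format(result$sowing_date)
    s$flowering_date <- if (result$did_flower) format(result$flowering_date) else NA
    jsonlite::write_json(s, summary_path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, na = "null")
  }
  invisible(result)
}
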