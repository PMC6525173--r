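#' Wheat photoperiod factor
#'
#' Development-rate reduction for short days, on the APSIM-Wheat convention
#' `f_p = 1 - 0.002 * Rp * (20 - pp)^2` for daylength `pp` below 20 h,
#' clamped to `[0, 1]`. `Rp` is the cultivar photoperiod sensitivity on a
#' 0-5 scale; an insensitive cultivar (`Rp = 0`) always develops at full
#' rate.
#'
#' @param pp photoperiod, hours in `[0, 24]`; vectorised.
#' @param Rp photoperiod sensitivity (>= 0).
#' @return factor in `[0, 1]`.
#' @export
photoperiod_factor <- function(pp, Rp) {
  if (any(pp < 0 | pp > 24)) stop("pp must be in [0, 24]")
  if (Rp < 0) stop("Rp must be >= 0")
  f <- 1 - 0.002 * Rp * pmax(20 - pp, 0)^2
  pmin(pmax(f, 0), 1)
}

#' Wheat vernalisation state and daily step
#'
#' Accrues vernal days on cool days and devernalises on hot days while the
#' requirement is still reversible, on the APSIM-Wheat convention: with
#' crown temperature approximated by the air mean `Tm`, a day with
#' `tmax < 30` and `tmin < 15` adds
#' `max(min(1.4 - 0.0778 Tm, 0.5 + 13.44 Tm / (tmax - tmin + 3)^2), 0)`
#' vernal days; a day with `tmax > 30` while cumulative vernal days `V < 10`
#' removes `min(0.5 (tmax - 30), V)`. The development factor is
#' `f_v = 1 - 0.0054545 * Rv * (50 - V)`, clamped to `[0, 1]`, so `f_v = 1`
#' once `V >= 50` or for an insensitive cultivar (`Rv = 0`).
#'
#' @param state list with `V` (cumulative vernal days) and `deverned`
#'   (devernalisation tally); start from [vernalisation_state()].
#' @param tmax,tmin daily extremes, degrees C.
#' @param Rv vernalisation sensitivity (>= 0).
#' @return list with the updated `state` and the day's factor `f_v`.
#' @export
vernalisation_step <- function(state, tmax, tmin, Rv) {
  if (tmax < tmin) stop("tmax must be >= tmin")
  if (Rv < 0) stop("Rv must be >= 0")
  tm <- (tmax + tmin) / 2
  if (tmax < 30 && tmin < 15) {
    dv <- max(min(1.4 - 0.0778 * tm,
                  0.5 + 13.44 * tm / (tmax - tmin + 3)^2), 0)
    state$V <- state$V + dv
  } else if (tmax > 30 && state$V < 10) {
    dd <- min(0.5 * (tmax - 30), state$V)
    state$V <- state$V - dd
    state$deverned <- state$deverned + dd
  }
  f_v <- if (Rv == 0 || state$V >= 50) 1 else {
    min(max(1 - 0.0054545 * Rv * (50 - state$V), 0), 1)
  }
  list(state = state, f_v = f_v)
}

#' @rdname vernalisation_step
#' @export
vernalisation_state <- function() list(V = 0, deverned = 0)

#' Wheat cultivar parameter set
#'
#' @param name cultivar name.
#' @param Rp photoperiod sensitivity, 0-5 scale.
#' @param Rv vernalisation sensitivity.
#' @param tt_to_floral_init thermal time from emergence to floral
#'   initiation, °Cd (555 for cv. Gregory; 715 in the gene-based
#'   re-parameterisation).
#' @param tt_init_to_flower thermal time from floral initiation to
#'   flowering, °Cd.
#' @param emergence_lag,emergence_rate emergence target is
#'   `emergence_lag + emergence_rate * sowing depth (mm)`, °Cd.
#' @return a `wheat_cultivar` list.
#' @export
wheat_cultivar <- function(name, Rp, Rv, tt_to_floral_init,
                           tt_init_to_flower = 650,
                           emergence_lag = 40, emergence_rate = 1.5) {
  if (Rp < 0 || Rv < 0) stop("Rp and Rv must be >= 0")
  if (any(c(tt_to_floral_init, tt_init_to_flower,
            emergence_lag, emergence_rate) < 0)) {
    stop("all thermal-time targets must be >= 0")
  }
  structure(list(name = name, Rp = Rp, Rv = Rv,
                 tt_to_floral_init = tt_to_floral_init,
                 tt_init_to_flower = tt_init_to_flower,
                 emergence_lag = emergence_lag,
                 emergence_rate = emergence_rate),
            class = "wheat_cultivar")
}

#' Named wheat model variants for cv. Gregory
#'
#' Four configurations: `original` (Rp 3.2, Rv 2.7, 555 °Cd to initiation),
#' `zheng` (gene-based re-parameterisation: Rp 2.6, Rv 0.9, 715 °Cd),
#' `reduced` (Rp 2.6, Rv 1.98, 555 °Cd) and `reduced_sw` (the `reduced`
#' parameters run with the soil-water thermal-time modification).
#'
#' @return named list; each element has `cultivar` (a [wheat_cultivar()])
#'   and `sw_params` (an [sw_modification()] or `NULL`).
#' @export
wheat_presets <- function() {
  list(
    original = list(cultivar = wheat_cultivar("Gregory (original)",
                                              Rp = 3.2, Rv = 2.7,
                                              tt_to_floral_init = 555),
                    sw_params = NULL),
    zheng = list(cultivar = wheat_cultivar("Gregory (gene-based)",
                                           Rp = 2.6, Rv = 0.9,
                                           tt_to_floral_init = 715),
                 sw_params = NULL),
    reduced = list(cultivar = wheat_cultivar("Gregory (reduced)",
                                             Rp = 2.6, Rv = 1.98,
                                             tt_to_floral_init = 555),
                   sw_params = NULL),
    reduced_sw = list(cultivar = wheat_cultivar("Gregory (reduced)",
                                                Rp = 2.6, Rv = 1.98,
                                                tt_to_floral_init = 555),
                      sw_params = sw_modification())
  )
}

#' Simulate wheat development to flowering
#'
#' As [simulate_chickpea()], but between emergence and floral initiation the
#' daily thermal time is first reduced by `min(f_p, f_v)` — the photoperiod
#' and vernalisation factors — before the soil-water modification is
#' applied. Wheat stages: 1 sowing, 2 germination, 3 emergence, 4 floral
#' initiation, 5 flowering (terminal here; grain phases are out of scope).
#' The soil-water gate "stage >= 3" again means emergence onward.
#'
#' @inheritParams simulate_chickpea
#' @param cultivar a [wheat_cultivar()]; see [wheat_presets()].
#' @return a `phenology_trace` (flowering is the terminal stage, so
#'   `days_to_maturity` is `NA`).
#' @export
simulate_wheat <- function(weather, profile,
                           cultivar = wheat_presets()$reduced$cultivar,
                           sowing_date, sowing_depth = 50,
                           sw_params = NULL,
                           init = list(fraction = 0.2, mode = "uniform"),
                           cardinals = cardinal_temps(),
                           twilight_angle = -2.2, root_rate = 0.7) {
  stopifnot(inherits(cultivar, "wheat_cultivar"))
  emergence_target <- cultivar$emergence_lag +
    cultivar$emergence_rate * sowing_depth
  targets_fun <- function(pp) {
    c(Inf, emergence_target, cultivar$tt_to_floral_init,
      cultivar$tt_init_to_flower)
  }
  vern <- vernalisation_state()
  # photoperiod/vernalisation limit development only up to floral initiation
  factor_fun <- function(stage, tmax, tmin, pp) {
    step <- vernalisation_step(vern, tmax, tmin, cultivar$Rv)
    vern <<- step$state
    if (stage == 3L) {
      min(photoperiod_factor(pp, cultivar$Rp), step$f_v)
    } else 1
  }
  kc <- c(0, 0, 0.4, 0.8, 1.0)
  res <- simulate_crop(weather, profile, sowing_date, sowing_depth,
                       sw_params = sw_params, init = init,
                       targets_fun = targets_fun, factor_fun = factor_fun,
                       flowering_stage = 5L, terminal_stage = 5L,
                       kc = kc, root_rate = root_rate, cardinals = cardinals,
                       twilight_angle = twilight_angle,
                       crop = "wheat", cultivar_name = cultivar$name)
  # flowering is terminal for wheat here; no grain phases are simulated
  res$maturity_date <- as.Date(NA)
  res$days_to_maturity <- NA_integer_
  res$vernalisation <- vern
  res
}
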