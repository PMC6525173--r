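#' Cardinal temperatures
#'
#' Base, optimum and ceiling temperatures of the daily thermal-time response.
#' Defaults (0, 30, 40 degrees C) are the chickpea values; the same response
#' is used for wheat.
#'
#' @param base,optimum,ceiling degrees C with `base < optimum < ceiling`.
#' @return a `cardinal_temps` list.
#' @export
cardinal_temps <- function(base = 0, optimum = 30, ceiling = 40) {
  if (!(base < optimum && optimum < ceiling)) {
    stop("cardinal temperatures must satisfy base < optimum < ceiling")
  }
  structure(list(base = base, optimum = optimum, ceiling = ceiling),
            class = "cardinal_temps")
}

#' Daily thermal time
#'
#' Degree-days accrued in one day from the daily mean temperature
#' `m = (tmax + tmin) / 2`: zero at or below `base`, `m - base` up to the
#' optimum (so TT equals the mean temperature with a 0 degree base), then a
#' linear decline from `optimum - base` at the optimum to zero at the
#' ceiling.
#'
#' @param tmax,tmin daily extremes, degrees C (`tmax >= tmin`); vectorised.
#' @param cardinals a [cardinal_temps()] set.
#' @return thermal time in degree-days (°Cd).
#' @export
daily_thermal_time <- function(tmax, tmin, cardinals = cardinal_temps()) {
  if (any(tmax < tmin)) stop("tmax must be >= tmin")
  m <- (tmax + tmin) / 2
  b <- cardinals$base; o <- cardinals$optimum; cl <- cardinals$ceiling
  tt <- ifelse(m <= b, 0,
        ifelse(m <= o, m - b,
        ifelse(m < cl, (o - b) * (cl - m) / (cl - o), 0)))
  pmax(tt, 0)
}

#' Photoperiod-interpolated phase target
#'
#' Piecewise-linear interpolation of a thermal-time target against
#' photoperiod, flat beyond the end knots (APSIM lookup-table semantics).
#'
#' @param pp photoperiod, hours.
#' @param knots ascending photoperiod knots, hours.
#' @param targets thermal-time targets at the knots, °Cd (same length).
#' @return interpolated target, °Cd.
#' @export
phase_target <- function(pp, knots, targets) {
  if (length(knots) != length(targets)) {
    stop("knots and targets must have the same length")
  }
  if (length(knots) == 1) return(rep(targets, length(pp)))
  if (is.unsorted(knots, strictly = TRUE)) stop("knots must be strictly ascending")
  stats::approx(knots, targets, xout = pp, rule = 2)$y
}

#' Chickpea / crop development stage codes
#'
#' Integer stage codes used throughout: 1 sowing, 2 germination,
#' 3 emergence, 4 end of juvenile phase, 5 floral initiation, 6 flowering,
#' 7 start of grain fill, 8 end of grain fill, 9 maturity, 10 harvest ripe.
#' The soil-water gate "stage >= 3" therefore means emergence onward.
#'
#' @return a named integer vector of stage codes.
#' @export
stage_codes <- function() {
  c(sowing = 1L, germination = 2L, emergence = 3L, end_juvenile = 4L,
    floral_initiation = 5L, flowering = 6L, start_grain_fill = 7L,
    end_grain_fill = 8L, maturity = 9L, harvest_ripe = 10L)
}

#' Soil-water thermal-time modification parameters
#'
#' The modification multiplies daily thermal time by
#' `constant - min(FASW, 1)` whenever `FASW >= threshold` and the crop stage
#' lies in `[min_stage, max_stage]`. With the defaults (constant 1.65,
#' threshold 0.65) the multiplier is exactly 1 at the threshold and declines
#' to 0.65 at or above field capacity, delaying development in wet topsoil.
#'
#' @param constant additive constant of the modification (default 1.65).
#' @param threshold FASW gate in `(0, 1]` (default 0.65, the readily
#'   available water limit); must be below `constant` so the multiplier
#'   never exceeds 1 inside the gate.
#' @param min_stage first stage the modification applies to (default 3,
#'   emergence).
#' @param max_stage last stage it applies to (default 6, flowering;
#'   configurable to 9 to run it through grain fill).
#' @param zone_depth FASW zone bottom, cm (default 60).
#' @return an `sw_modification` list.
#' @export
sw_modification <- function(constant = 1.65, threshold = 0.65,
                            min_stage = 3L, max_stage = 6L, zone_depth = 60) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (constant <= threshold) {
    stop("constant must exceed threshold (multiplier <= 1 inside the gate)")
  }
  if (min_stage > max_stage) stop("min_stage must be <= max_stage")
  structure(list(constant = constant, threshold = threshold,
                 min_stage = as.integer(min_stage),
                 max_stage = as.integer(max_stage), zone_depth = zone_depth),
            class = "sw_modification")
}

#' Soil-water modification of daily thermal time
#'
#' `TTm = TT * (constant - min(FASW, 1))` when `FASW >= threshold` and
#' `min_stage <= stage <= max_stage`; otherwise `TTm = TT`. FASW above 1
#' (topsoil wetter than DUL) clamps the multiplier at its minimum,
#' `constant - 1`.
#'
#' @param tt daily thermal time, °Cd (>= 0); vectorised over `tt` and `fasw`.
#' @param fasw fractional available soil water (unclamped).
#' @param stage integer crop stage code (see [stage_codes()]).
#' @param params an [sw_modification()] parameter set.
#' @return modified thermal time TTm, °Cd (TTm <= TT always).
#' @export
modify_tt <- function(tt, fasw, stage, params = sw_modification()) {
  if (any(tt < 0)) stop("tt must be >= 0")
  gated <- stage >= params$min_stage & stage <= params$max_stage &
    fasw >= params$threshold
  mult <- ifelse(gated, params$constant - pmin(fasw, 1), 1)
  tt * mult
}

#' Advance the development stage with one day's thermal time
#'
#' Accumulates the day's (modified) thermal time into the current phase;
#' whenever the phase target is met, the surplus rolls into the next phase
#' and the stage increments, possibly several times in one day. Zero-target
#' phases are crossed as soon as any positive thermal time arrives.
#'
#' @param state list with `stage` (integer code) and `phase_cum` (°Cd
#'   accumulated in the current phase).
#' @param ttm_today the day's thermal time, °Cd.
#' @param targets numeric vector of phase targets, °Cd: `targets[s]` is the
#'   target of the phase that starts at stage `s`. Stages beyond
#'   `length(targets)` are terminal.
#' @return the updated state; `state$entered` lists stages entered today.
#' @export
advance_stage <- function(state, ttm_today, targets) {
  entered <- integer(0)
  if (ttm_today > 0) {
    while (state$stage <= length(targets) &&
           state$phase_cum + ttm_today >= targets[state$stage]) {
      ttm_today <- ttm_today - (targets[state$stage] - state$phase_cum)
      state$phase_cum <- 0
      state$stage <- state$stage + 1L
      entered <- c(entered, state$stage)
    }
    state$phase_cum <- state$phase_cum + ttm_today
  }
  state$entered <- entered
  state
}
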