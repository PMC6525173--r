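#' Layered soil profile
#'
#' A `soil_profile` holds an ordered, contiguous stack of layers and the
#' two-stage soil evaporation parameters. Per layer: `top`/`bottom` depths
#' (cm), volumetric water contents `air_dry`, `ll15` (lower limit at
#' 1.5 MPa), `dul` (drained upper limit, 0.03 MPa), `sat` (saturation), the
#' drainage coefficient `swcon` (fraction of water above DUL drained per day)
#' and the root uptake coefficient `kl` (fraction of extractable water a
#' fully rooted layer can supply per day).
#'
#' @param layers data frame with columns `top`, `bottom`, `air_dry`, `ll15`,
#'   `dul`, `sat`, `swcon`, `kl`; layers must be contiguous from the surface
#'   with `air_dry <= ll15 < dul <= sat` in each.
#' @param u stage-1 cumulative soil evaporation limit, mm (default 6).
#' @param cona stage-2 evaporation coefficient, mm per sqrt(day) (default 3.5).
#' @return a `soil_profile` object.
#' @export
soil_profile <- function(layers, u = 6, cona = 3.5) {
  stopifnot(is.data.frame(layers))
  needed <- c("top", "bottom", "air_dry", "ll15", "dul", "sat", "swcon", "kl")
  missing_cols <- setdiff(needed, names(layers))
  if (length(missing_cols) > 0) {
    stop("soil layers missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  layers <- layers[, needed]
  n <- nrow(layers)
  if (n == 0) stop("soil profile needs at least one layer")
  if (layers$top[1] != 0) stop("first layer must start at the surface (top = 0)")
  if (any(layers$bottom <= layers$top)) stop("each layer must have bottom > top")
  if (n > 1 && any(abs(layers$top[-1] - layers$bottom[-n]) > 1e-9)) {
    stop("layers must be contiguous (each top equals the previous bottom)")
  }
  ok <- layers$air_dry <= layers$ll15 & layers$ll15 < layers$dul &
    layers$dul <= layers$sat
  if (!all(ok)) {
    stop("layer ", which(!ok)[1],
         " violates air_dry <= ll15 < dul <= sat")
  }
  if (any(layers$swcon < 0 | layers$swcon > 1)) stop("swcon must be in [0, 1]")
  if (any(layers$kl < 0 | layers$kl > 1)) stop("kl must be in [0, 1]")
  if (u <= 0 || cona < 0) stop("u must be > 0 and cona >= 0")
  prof <- structure(list(layers = layers, u = u, cona = cona),
                    class = "soil_profile")
  if (pawc(prof) <= 0) stop("profile PAWC must be positive")
  prof
}

#' @export
print.soil_profile <- function(x, ...) {
  cat(sprintf("<soil_profile> %d layers to %g cm, PAWC %.1f mm\n",
              nrow(x$layers), max(x$layers$bottom), pawc(x)))
  invisible(x)
}

layer_thickness_mm <- function(profile) {
  (profile$layers$bottom - profile$layers$top) * 10
}

#' Plant available water holding capacity
#'
#' `PAWC = sum((dul - ll15) * thickness)` in mm, over the whole profile or
#' the part of it above `zone_depth`, prorating a straddling layer by
#' thickness fraction.
#'
#' @param profile a [soil_profile()].
#' @param zone_depth optional zone bottom, cm; `NULL` for the whole profile.
#' @return PAWC in mm.
#' @export
pawc <- function(profile, zone_depth = NULL) {
  ly <- profile$layers
  frac <- if (is.null(zone_depth)) {
    rep(1, nrow(ly))
  } else {
    zone_fractions(profile, zone_depth)
  }
  sum((ly$dul - ly$ll15) * (ly$bottom - ly$top) * 10 * frac)
}

# fraction of each layer's thickness lying within [0, zone_depth]
zone_fractions <- function(profile, zone_depth) {
  ly <- profile$layers
  if (zone_depth <= 0) stop("zone_depth must be positive")
  if (zone_depth > max(ly$bottom) + 1e-9) {
    stop("zone_depth (", zone_depth, " cm) exceeds profile depth (",
         max(ly$bottom), " cm)")
  }
  pmin(pmax((zone_depth - ly$top) / (ly$bottom - ly$top), 0), 1)
}

#' Initialise the soil water state
#'
#' @param profile a [soil_profile()].
#' @param starting_water available water as a fraction of PAWC in `[0, 1]`.
#' @param mode `"uniform"` sets every layer to `ll15 + f * (dul - ll15)`;
#'   `"fill_from_top"` fills layers to DUL from the surface down until the
#'   target total is allocated, leaving deeper layers at LL15.
#' @return a `soil_water_state`: per-layer volumetric water `sw`, the
#'   two-stage evaporation trackers, and the previous day's flux ledger
#'   (infiltration, runoff, drainage, evaporation, uptake, all mm).
#' @export
initialize_soil_water <- function(profile, starting_water,
                                  mode = c("uniform", "fill_from_top")) {
  mode <- match.arg(mode)
  if (starting_water < 0 || starting_water > 1) {
    stop("starting_water must be a fraction of PAWC in [0, 1]")
  }
  ly <- profile$layers
  thick <- layer_thickness_mm(profile)
  if (mode == "uniform") {
    sw <- ly$ll15 + starting_water * (ly$dul - ly$ll15)
  } else {
    target <- starting_water * pawc(profile)
    cap <- (ly$dul - ly$ll15) * thick
    sw_mm <- numeric(nrow(ly))
    for (i in seq_len(nrow(ly))) {
      take <- min(cap[i], target)
      sw_mm[i] <- take
      target <- target - take
    }
    sw <- ly$ll15 + sw_mm / thick
  }
  structure(list(sw = sw, sumes = profile$u, t2 = 1,
                 fluxes = c(infiltration = 0, runoff = 0, drainage = 0,
                            evaporation = 0, uptake = 0)),
            class = "soil_water_state")
}

#' Total stored water
#' @param profile a [soil_profile()].
#' @param state a soil water state.
#' @return stored water over the whole profile, mm.
#' @export
soil_water_mm <- function(profile, state) {
  sum(state$sw * layer_thickness_mm(profile))
}

#' Advance the water balance one day
#'
#' A cascading ("tipping bucket") daily water balance. Order of operations:
#' infiltration of rain + irrigation into the top layer (runoff optional via
#' `runoff_fraction`, default 0); instantaneous cascade of any water above
#' saturation; gravitational drainage `swcon * (sw - dul)` per layer passed
#' to the layer below (below the profile it becomes deep drainage); two-stage
#' soil evaporation from the top layer (stage 1 up to `u` mm since last
#' rewetting, stage 2 at `cona * (sqrt(t) - sqrt(t - 1))`), floored at
#' air-dry; and root uptake `kl * (sw - ll15) * thickness` per rooted layer,
#' scaled so the day's total never exceeds `transpiration_demand`. All fluxes
#' are clipped to physical bounds rather than erroring, and the returned flux
#' ledger closes the mass balance to numerical precision.
#'
#' @param profile a [soil_profile()].
#' @param state the current `soil_water_state`.
#' @param weather_day a one-row [weather_series()] slice or list with `rain`
#'   and `irrigation` (mm).
#' @param transpiration_demand crop water demand, mm (>= 0).
#' @param root_depth rooting depth, cm (>= 0).
#' @param evap_demand potential soil evaporation, mm (atmospheric cap on
#'   stage-1 evaporation).
#' @param runoff_fraction fraction of rain + irrigation lost to runoff
#'   (simple hook; default 0).
#' @return the updated `soil_water_state` with its `fluxes` ledger.
#' @export
step_water_balance <- function(profile, state, weather_day,
                               transpiration_demand = 0, root_depth = 0,
                               evap_demand = 4, runoff_fraction = 0) {
  if (transpiration_demand < 0) stop("transpiration_demand must be >= 0")
  if (root_depth < 0) stop("root_depth must be >= 0")
  ly <- profile$layers
  thick <- layer_thickness_mm(profile)
  sw_mm <- state$sw * thick
  ll15_mm <- ly$ll15 * thick
  dul_mm <- ly$dul * thick
  sat_mm <- ly$sat * thick
  ad_mm <- ly$air_dry * thick
  n <- nrow(ly)

  water_in <- weather_day$rain + weather_day$irrigation
  runoff <- runoff_fraction * water_in
  infil <- water_in - runoff

  # infiltration + saturation cascade + gravitational drainage, top down
  flow <- infil
  for (i in seq_len(n)) {
    sw_mm[i] <- sw_mm[i] + flow
    flow <- 0
    if (sw_mm[i] > sat_mm[i]) {
      flow <- sw_mm[i] - sat_mm[i]
      sw_mm[i] <- sat_mm[i]
    }
    if (sw_mm[i] > dul_mm[i]) {
      dr <- ly$swcon[i] * (sw_mm[i] - dul_mm[i])
      sw_mm[i] <- sw_mm[i] - dr
      flow <- flow + dr
    }
  }
  drainage <- flow

  # two-stage evaporation from the top layer; rewetting winds the stage-1
  # accumulator back by the day's infiltration
  sumes <- max(state$sumes - infil, 0)
  t2 <- if (sumes < profile$u) 0 else state$t2
  avail1 <- max(sw_mm[1] - ad_mm[1], 0)
  if (sumes < profile$u) {
    es <- min(evap_demand, profile$u - sumes, avail1)
  } else {
    t2 <- t2 + 1
    es <- min(profile$cona * (sqrt(t2) - sqrt(t2 - 1)), evap_demand, avail1)
  }
  es <- max(es, 0)
  sumes <- sumes + es
  sw_mm[1] <- sw_mm[1] - es

  # root uptake within root_depth, proportionally rationed to demand
  uptake <- 0
  if (transpiration_demand > 0 && root_depth > 0) {
    rooted <- pmin(pmax((root_depth - ly$top) / (ly$bottom - ly$top), 0), 1)
    pot <- ly$kl * rooted * pmax(sw_mm - ll15_mm, 0)
    tot <- sum(pot)
    if (tot > 0) {
      scale <- min(1, transpiration_demand / tot)
      sw_mm <- sw_mm - pot * scale
      uptake <- tot * scale
    }
  }

  state$sw <- sw_mm / thick
  state$sumes <- sumes
  state$t2 <- t2
  state$fluxes <- c(infiltration = infil, runoff = runoff, drainage = drainage,
                    evaporation = es, uptake = uptake)
  state
}

#' Fractional available soil water
#'
#' `FASW = sum(sw_dep - ll15_dep) / sum(dul_dep - ll15_dep)` over the layers
#' intersecting `[0, zone_depth]`, with a straddling layer prorated by
#' thickness fraction. The value is *not* clamped: it exceeds 1 when water is
#' held between DUL and saturation (consumers clamp where the thermal-time
#' modification requires it), and can be slightly negative if the surface
#' layer has evaporated below LL15.
#'
#' @param profile a [soil_profile()].
#' @param state a `soil_water_state`.
#' @param zone_depth zone bottom, cm (default 60, the effective root zone).
#' @return FASW (dimensionless fraction, unclamped).
#' @export
compute_fasw <- function(profile, state, zone_depth = 60) {
  ly <- profile$layers
  frac <- zone_fractions(profile, zone_depth)
  thick <- (ly$bottom - ly$top) * 10
  num <- sum((state$sw - ly$ll15) * thick * frac)
  den <- sum((ly$dul - ly$ll15) * thick * frac)
  num / den
}

#' Hargreaves reference evapotranspiration
#'
#' Temperature-based daily ET0 (mm/day): `0.0023 * Ra * (Tmean + 17.8) *
#' sqrt(Tmax - Tmin)` with extraterrestrial radiation `Ra` from standard
#' solar geometry, expressed in evaporation-equivalent mm. Used to supply
#' transpiration and soil evaporation demand without requiring measured
#' radiation.
#'
#' @param latitude degrees (south negative).
#' @param day_of_year 1-366.
#' @param tmax,tmin daily extremes, degrees C.
#' @return ET0 in mm/day (>= 0); vectorised.
#' @export
et0_hargreaves <- function(latitude, day_of_year, tmax, tmin) {
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * day_of_year / 365.25)
  decl <- 0.409 * sin(2 * pi * day_of_year / 365.25 - 1.39)
  ws <- acos(pmin(pmax(-tan(phi) * tan(decl), -1), 1))
  ra_mj <- 24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(ws))
  ra_mm <- 0.408 * ra_mj
  tmean <- (tmax + tmin) / 2
  pmax(0.0023 * ra_mm * (tmean + 17.8) * sqrt(pmax(tmax - tmin, 0)), 0)
}
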