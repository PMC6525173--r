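# fixtures built in code: a minimal two-layer profile and simple weather

two_layer_profile <- function(thick_cm = c(30, 30), ll15 = 0.20, dul = 0.30,
                              sat = 0.40, air_dry = 0.10, swcon = 0.3,
                              kl = 0.06, u = 6, cona = 3.5) {
  n <- length(thick_cm)
  bottom <- cumsum(thick_cm)
  soil_profile(data.frame(
    top = c(0, bottom[-n]), bottom = bottom,
    air_dry = air_dry, ll15 = ll15, dul = dul, sat = sat,
    swcon = swcon, kl = kl
  ), u = u, cona = cona)
}

const_weather <- function(n, tmax = 20, tmin = 10, rain = 0,
                          latitude = -27, start = "2015-05-01",
                          irrigation = 0) {
  weather_series(data.frame(
    date = as.Date(start) + seq_len(n) - 1,
    tmax = tmax, tmin = tmin, rain = rain, irrigation = irrigation
  ), latitude = latitude)
}

# a flat-photoperiod chickpea cultivar for closed-form accumulation checks
flat_cultivar <- function(emergence = 90, emerg_endjuv = 660,
                          endjuv_init = 0, init_flower = 33) {
  chickpea_cultivar("test-flat", pp_knots = c(1, 24),
                    tt_endjuv_to_init = c(endjuv_init, endjuv_init),
                    tt_emerg_to_endjuv = emerg_endjuv,
                    tt_init_to_flower = init_flower,
                    emergence_lag = emergence, emergence_rate = 0)
}

# state with every layer at a given volumetric content
state_at <- function(profile, sw) {
  st <- initialize_soil_water(profile, 0)
  st$sw <- rep(sw, length.out = nrow(profile$layers))
  st
}

mass_balance_residual <- function(profile, before, after) {
  f <- after$fluxes
  (soil_water_mm(profile, after) - soil_water_mm(profile, before)) -
    (f[["infiltration"]] - f[["drainage"]] - f[["evaporation"]] - f[["uptake"]])
}
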