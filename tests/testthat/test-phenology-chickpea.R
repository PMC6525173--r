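test_that("daily thermal time follows the cardinal response", {
  # TT equals the daily mean temperature up to the 30 C optimum
  expect_equal(daily_thermal_time(20, 10), 15)
  expect_equal(daily_thermal_time(0, -10), 0)
  expect_equal(daily_thermal_time(40, 40), 0)   # ceiling
  expect_equal(daily_thermal_time(35, 35), 15)  # linear decline 30 -> 40
  expect_equal(daily_thermal_time(30, 30), 30)  # maximum at the optimum
  expect_error(daily_thermal_time(5, 10), "tmax")
  expect_error(cardinal_temps(30, 20, 40), "base < optimum < ceiling")
})

test_that("photoperiod interpolation reproduces the cultivar table", {
  orig <- chickpea_cultivars("original")$hattrick
  expect_equal(phase_target(10.7, orig$pp_knots, orig$tt_endjuv_to_init), 446)
  expect_equal(phase_target(17, orig$pp_knots, orig$tt_endjuv_to_init), 0)
  # flat extrapolation beyond the end knots
  expect_equal(phase_target(9, orig$pp_knots, orig$tt_endjuv_to_init), 446)
  new <- chickpea_cultivars("soilwater")$hattrick
  expect_equal(phase_target(13, new$pp_knots, new$tt_endjuv_to_init), 0)
  expect_equal(new$tt_emerg_to_endjuv, 660)
  ty <- chickpea_cultivars("soilwater")$tyson
  expect_equal(ty$pp_knots[1], 10.1)
  expect_equal(ty$tt_endjuv_to_init[1], 468.3)
  expect_equal(ty$tt_emerg_to_endjuv, 690)
  expect_error(phase_target(12, c(10, 17), c(446, 0, 1)), "same length")
})

test_that("the soil-water modification gates and clamps as specified", {
  expect_equal(modify_tt(20, 0.65, 3), 20)   # multiplier exactly 1 at gate
  expect_equal(modify_tt(20, 1.0, 3), 13)    # 20 * (1.65 - 1)
  expect_equal(modify_tt(20, 1.2, 3), 13)    # FASW > 1 clamps the multiplier
  expect_equal(modify_tt(20, 0.5, 3), 20)    # gate closed below threshold
  expect_equal(modify_tt(20, 0.9, 2), 20)    # pre-emergence stage exempt
  expect_equal(modify_tt(20, 0.9, 7), 20)    # beyond flowering by default
  expect_equal(modify_tt(20, 0.9, 7,
                         sw_modification(max_stage = 9)), 15)
  expect_error(sw_modification(constant = 0.5), "constant must exceed")
  expect_error(modify_tt(-1, 0.9, 3), "tt must be")

  # TTm <= TT and multiplier in [0.65, 1] over the whole FASW range
  set.seed(7)
  f <- runif(200, -0.1, 1.4)
  tt <- runif(200, 0, 30)
  ttm <- modify_tt(tt, f, 4)
  expect_true(all(ttm <= tt + 1e-12))
  mult <- ifelse(tt > 0, ttm / tt, 1)
  expect_true(all(mult >= 0.65 - 1e-12 & mult <= 1 + 1e-12))
})

test_that("stage advance accumulates, carries surplus, and ignores zero days", {
  st <- list(stage = 6L, phase_cum = 449)
  out <- advance_stage(st, 2, c(Inf, 90, 660, 446, 33, 450, 690, 60, 1))
  expect_equal(out$stage, 7L)
  expect_equal(out$phase_cum, 1)
  expect_equal(out$entered, 7L)

  same <- advance_stage(st, 0, c(Inf, 90, 660, 446, 33, 450, 690, 60, 1))
  expect_equal(same$stage, 6L)
  expect_equal(same$phase_cum, 449)

  # zero-target phases are crossed in the same day, surplus rolling on
  multi <- advance_stage(list(stage = 4L, phase_cum = 0), 40,
                         c(Inf, 90, 660, 0, 33, 450, 690, 60, 1))
  expect_equal(multi$stage, 6L)
  expect_equal(multi$entered, c(5L, 6L))
  expect_equal(multi$phase_cum, 7)
})

test_that("flowering day matches the closed-form division oracle", {
  # constant 10 degCd/day; targets 90 + 660 + 0 + 33 = 783 degCd; germination
  # on day 1, accumulation from day 2 -> flowering 1 + ceil(783/10) days
  ws <- const_weather(120, tmax = 10, tmin = 10, rain = 0)
  p <- two_layer_profile()
  res <- simulate_chickpea(ws, p, flat_cultivar(), sowing_date = "2015-05-01",
                           sw_params = NULL, init = list(fraction = 0.5))
  expect_true(res$did_flower)
  expect_equal(res$days_to_flowering, 1 + ceiling(783 / 10))
})

test_that("germination waits for seed-zone moisture", {
  ws <- const_weather(150, tmax = 10, tmin = 10,
                      rain = c(rep(0, 20), 30, rep(0, 129)))
  p <- two_layer_profile()
  res <- simulate_chickpea(ws, p, flat_cultivar(), sowing_date = "2015-05-01",
                           sw_params = NULL, init = list(fraction = 0))
  # dry seedbed at LL15: germination only after the day-21 rain
  expect_equal(res$trace$stage[1:19], rep(1L, 19))
  expect_true(res$did_flower)
})

test_that("the gate never opening leaves flowering dates identical", {
  ws <- const_weather(150, tmax = 22, tmin = 8, rain = 0)
  p <- two_layer_profile()
  on <- simulate_chickpea(ws, p, flat_cultivar(), sowing_date = "2015-05-01",
                          sw_params = sw_modification(),
                          init = list(fraction = 0.3))
  off <- simulate_chickpea(ws, p, flat_cultivar(), sowing_date = "2015-05-01",
                           sw_params = NULL, init = list(fraction = 0.3))
  expect_true(all(on$trace$fasw < 0.65))
  expect_equal(on$days_to_flowering, off$days_to_flowering)
})

test_that("saturated topsoil stretches the gated phases by exactly 1/0.65", {
  # daily 30 mm rain holds the top 60 cm at or above DUL, so the multiplier
  # clamps at 0.65 throughout the gated (emergence onward) phases
  ws <- const_weather(250, tmax = 10, tmin = 10, rain = 30)
  p <- two_layer_profile()
  on <- simulate_chickpea(ws, p, flat_cultivar(), sowing_date = "2015-05-01",
                          sw_params = sw_modification(),
                          init = list(fraction = 1))
  off <- simulate_chickpea(ws, p, flat_cultivar(), sowing_date = "2015-05-01",
                           sw_params = NULL, init = list(fraction = 1))
  gated <- on$trace$stage >= 3 & on$trace$stage < 6
  expect_true(all(on$trace$fasw[gated] >= 1))
  # emergence phase (90 degCd at 10/day from day 2) ends day 10; the gated
  # 693 degCd then accrue at 6.5 vs 10 degCd/day
  expect_equal(off$days_to_flowering, 10 + ceiling(693 / 10))
  expect_equal(on$days_to_flowering, 10 + ceiling(693 / 6.5))
})

test_that("soil-water modification never brings flowering forward", {
  soils <- build_fixture_soils()
  for (i in 1:10) {
    ws <- generate_synthetic_weather(runif(1, -28.5, -23.4),
                                     "2015-02-01", 340, seed = 100 + i,
      climate = climate_params(p_wet = runif(1, 0.1, 0.5),
                               rain_mean = runif(1, 4, 12)))
    p <- soils[[sample(length(soils), 1)]]
    sow <- as.Date("2015-05-01") + sample(0:40, 1)
    f0 <- runif(1, 0.1, 0.6)
    on <- simulate_chickpea(ws, p, sowing_date = sow,
                            init = list(fraction = f0))
    off <- simulate_chickpea(ws, p, sowing_date = sow, sw_params = NULL,
                             init = list(fraction = f0))
    expect_true(all(on$trace$ttm <= on$trace$tt + 1e-12))
    if (on$did_flower && off$did_flower) {
      expect_gte(on$days_to_flowering, off$days_to_flowering)
    }
  }
})

test_that("raising the upper photoperiod knot never hastens winter flowering", {
  soils <- build_fixture_soils()
  base <- chickpea_cultivars("soilwater")$hattrick  # upper knot 12 h
  wide <- base
  wide$pp_knots <- c(10.7, 17)
  for (s in 1:3) {
    ws <- generate_synthetic_weather(-27, "2015-02-01", 340, seed = 200 + s)
    a <- simulate_chickpea(ws, soils$ferrosol_109, base,
                           sowing_date = "2015-05-20", sw_params = NULL)
    b <- simulate_chickpea(ws, soils$ferrosol_109, wide,
                           sowing_date = "2015-05-20", sw_params = NULL)
    expect_gte(b$days_to_flowering, a$days_to_flowering)
  }
})

test_that("exhausted weather reports did-not-flower rather than erroring", {
  ws <- const_weather(30, tmax = 10, tmin = 10, rain = 0)
  p <- two_layer_profile()
  res <- simulate_chickpea(ws, p, flat_cultivar(), sowing_date = "2015-05-01",
                           init = list(fraction = 0.5))
  expect_false(res$did_flower)
  expect_true(is.na(res$days_to_flowering))
  expect_error(simulate_chickpea(ws, p, flat_cultivar(),
                                 sowing_date = "2016-01-01"),
               "outside the weather range")
})

test_that("trace invariants hold on a realistic run", {
  soils <- build_fixture_soils()
  ws <- generate_synthetic_weather(-26.55, "2015-01-15", 380, seed = 42)
  res <- simulate_chickpea(ws, soils$vertisol_257, sowing_date = "2015-05-15",
                           init = list(fraction = 0.3))
  tr <- res$trace
  expect_true(all(diff(tr$stage) >= 0))
  expect_true(all(tr$ttm <= tr$tt + 1e-12))
  expect_true(all(tr$daylength > 9 & tr$daylength < 15))
  expect_equal(tr$cum_tt, cumsum(tr$tt))
  expect_true(res$did_flower)
  expect_equal(res$days_to_flowering,
               as.integer(res$flowering_date - res$sowing_date))
  expect_gt(res$days_to_maturity, res$days_to_flowering)
  expect_equal(res$cum_tt_at_flowering,
               tr$cum_tt[tr$date == res$flowering_date])
})
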