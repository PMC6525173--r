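#' Daily weather series
#'
#' A `weather_series` is a data frame with one row per calendar day and columns
#' `date` (Date), `tmax`, `tmin` (degrees C), `rain` and `irrigation` (mm),
#' carrying the site latitude (decimal degrees, south negative) as an
#' attribute. Dates must be strictly consecutive with no gaps; `tmax >= tmin`
#' and non-negative water inputs are enforced at construction.
#'
#' @param records data frame with columns `date`, `tmax`, `tmin`, `rain` and
#'   optionally `irrigation` (defaults to 0).
#' @param latitude site latitude in decimal degrees, in `[-90, 90]`;
#'   southern-hemisphere sites are negative.
#' @return a `weather_series` object (a validated data frame).
#' @examples
#' ws <- weather_series(data.frame(
#'   date = as.Date("2015-04-27") + 0:2,
#'   tmax = c(22, 21, 23), tmin = c(8, 7, 9), rain = c(0, 4, 0)
#' ), latitude = -28.21)
#' @export
weather_series <- function(records, latitude) {
  stopifnot(is.data.frame(records))
  needed <- c("date", "tmax", "tmin", "rain")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop("weather records missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!is.numeric(latitude) || length(latitude) != 1 || is.na(latitude) ||
      latitude < -90 || latitude > 90) {
    stop("latitude must be a single value in [-90, 90]")
  }
  records$date <- as.Date(records$date)
  if (!"irrigation" %in% names(records)) records$irrigation <- 0
  records <- records[, c("date", "tmax", "tmin", "rain", "irrigation")]
  if (nrow(records) == 0) stop("weather series must contain at least one day")
  if (anyNA(records)) {
    bad <- which(rowSums(is.na(records)) > 0)[1]
    stop("missing value in weather record at row ", bad)
  }
  bad <- which(records$tmax < records$tmin)
  if (length(bad) > 0) {
    stop("tmin exceeds tmax at row ", bad[1], " (", records$date[bad[1]], ")")
  }
  bad <- which(records$rain < 0 | records$irrigation < 0)
  if (length(bad) > 0) {
    stop("negative rain or irrigation at row ", bad[1], " (", records$date[bad[1]], ")")
  }
  dd <- diff(as.integer(records$date))
  if (any(dd != 1)) {
    i <- which(dd != 1)[1]
    stop("dates must be strictly consecutive; gap or disorder after ",
         records$date[i], " (row ", i, ")")
  }
  rownames(records) <- NULL
  structure(records, latitude = latitude,
            class = c("weather_series", "data.frame"))
}

#' @export
print.weather_series <- function(x, ...) {
  cat(sprintf("<weather_series> %d days, %s to %s, latitude %.2f\n",
              nrow(x), format(x$date[1]), format(x$date[nrow(x)]),
              attr(x, "latitude")))
  invisible(x)
}

#' Site latitude of a weather series
#' @param ws a [weather_series()].
#' @return latitude in decimal degrees.
#' @export
ws_latitude <- function(ws) attr(ws, "latitude")

#' Read a daily weather file
#'
#' Two dialects are supported: a CSV with columns `date` (ISO-8601), `maxt`,
#' `mint`, `rain` and optional `irrigation`; and an APSIM-style `.met` text
#' file (whitespace-delimited `year day maxt mint rain ...` table preceded by
#' a `latitude = <value>` header constant, a column-name line, and a units
#' line). Unknown columns are ignored. Gaps in the date sequence are an
#' error, never silently filled.
#'
#' @param path file path.
#' @param format `"csv"` or `"met"`.
#' @param latitude required for `format = "csv"` (the CSV carries no
#'   latitude); ignored for `.met`, whose header supplies it.
#' @return a [weather_series()].
#' @export
read_weather <- function(path, format = c("csv", "met"), latitude = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("weather file not found: ", path)
  if (format == "csv") {
    if (is.null(latitude)) stop("latitude must be supplied when reading CSV weather")
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    needed <- c("date", "maxt", "mint", "rain")
    missing_cols <- setdiff(needed, names(df))
    if (length(missing_cols) > 0) {
      stop("CSV weather file missing column(s): ", paste(missing_cols, collapse = ", "))
    }
    dates <- as.Date(df$date, format = "%Y-%m-%d")
    if (anyNA(dates)) {
      stop("unparseable date at data row ", which(is.na(dates))[1])
    }
    rec <- data.frame(date = dates, tmax = df$maxt, tmin = df$mint,
                      rain = df$rain,
                      irrigation = if ("irrigation" %in% names(df)) df$irrigation else 0)
    weather_series(rec, latitude)
  } else {
    read_met(path)
  }
}

read_met <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lat_line <- grep("^\\s*latitude\\s*=", lines, ignore.case = TRUE, value = TRUE)
  if (length(lat_line) == 0) stop("met file has no 'latitude =' header constant")
  lat <- suppressWarnings(as.numeric(sub(".*=\\s*(-?[0-9.]+).*", "\\1", lat_line[1])))
  if (is.na(lat)) stop("could not parse latitude from met header: ", lat_line[1])
  hdr_i <- grep("^\\s*year\\s+day\\s+", lines, ignore.case = TRUE)
  if (length(hdr_i) == 0) stop("met file has no 'year day ...' column header line")
  hdr_i <- hdr_i[1]
  cols <- strsplit(trimws(lines[hdr_i]), "\\s+")[[1]]
  # the line after the header holds units, e.g. "() () (oC) (oC) (mm)"
  data_lines <- lines[seq(hdr_i + 2, length(lines))]
  data_lines <- data_lines[!grepl("^\\s*(!.*)?$", data_lines)]
  if (length(data_lines) == 0) stop("met file contains no data rows")
  df <- utils::read.table(text = paste(data_lines, collapse = "\n"),
                          col.names = cols, check.names = FALSE)
  for (nm in c("year", "day", "maxt", "mint", "rain")) {
    if (!nm %in% cols) stop("met file missing required column: ", nm)
  }
  dates <- as.Date(df$day - 1, origin = as.Date(paste0(df$year, "-01-01")))
  rec <- data.frame(date = dates, tmax = df$maxt, tmin = df$mint,
                    rain = df$rain,
                    irrigation = if ("irrigation" %in% cols) df$irrigation else 0)
  weather_series(rec, lat)
}

#' Write a weather series to disk
#'
#' @param ws a [weather_series()].
#' @param path output file path.
#' @param format `"csv"` or `"met"`; both round-trip losslessly through
#'   [read_weather()].
#' @return `path`, invisibly.
#' @export
write_weather <- function(ws, path, format = c("csv", "met")) {
  format <- match.arg(format)
  stopifnot(inherits(ws, "weather_series"))
  if (format == "csv") {
    out <- data.frame(date = format(ws$date), maxt = ws$tmax, mint = ws$tmin,
                      rain = ws$rain, irrigation = ws$irrigation)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    yr <- as.integer(format(ws$date, "%Y"))
    doy <- as.integer(format(ws$date, "%j"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("[weather.met.weather]",
                 "!written by phenoflow",
                 sprintf("latitude = %.4f  (DECIMAL DEGREES)", ws_latitude(ws)),
                 "year day maxt mint rain irrigation",
                 "()   ()  (oC) (oC) (mm) (mm)"), con)
    writeLines(sprintf("%d %d %.10g %.10g %.10g %.10g",
                       yr, doy, ws$tmax, ws$tmin, ws$rain, ws$irrigation), con)
  }
  invisible(path)
}

#' Synthetic climate parameter set
#'
#' Parameters for [generate_synthetic_weather()]. Temperature follows an
#' annual sinusoid (warmest around `phase_doy`, i.e. mid-January for
#' southern-hemisphere sites) plus Gaussian noise on the daily mean; rainfall
#' follows a two-state wet/dry Markov chain with gamma-distributed wet-day
#' amounts. Defaults emulate an inland southern-Queensland winter-cropping
#' climate: mild subtropical temperatures with winter minima that can dip
#' below zero, and modest, moderately persistent rainfall.
#'
#' @param tmean annual mean of the daily mean temperature, degrees C.
#' @param amplitude annual half-range of the sinusoid, degrees C (> 0 allowed
#'   to be 0 for a flat climate; negative is an error).
#' @param diurnal_range mean tmax - tmin spread, degrees C.
#' @param noise_sd standard deviation of the Gaussian noise on the daily mean
#'   temperature, degrees C.
#' @param phase_doy day of year of the warmest day (default 15, mid-January:
#'   southern-hemisphere winter minimum in July).
#' @param p_wet stationary wet-day probability in `[0, 1]`.
#' @param wet_persistence lag-1 autocorrelation of the wet/dry chain in
#'   `[0, 1)`; `p11 = p_wet + (1 - p_wet) * wet_persistence`.
#' @param rain_mean mean wet-day rainfall amount, mm.
#' @param rain_shape gamma shape of wet-day amounts.
#' @return a named list of class `climate_params`.
#' @export
climate_params <- function(tmean = 17, amplitude = 8, diurnal_range = 14,
                           noise_sd = 2.5, phase_doy = 15,
                           p_wet = 0.25, wet_persistence = 0.45,
                           rain_mean = 8, rain_shape = 0.75) {
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (diurnal_range < 0) stop("diurnal_range must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (p_wet < 0 || p_wet > 1) stop("p_wet must be in [0, 1]")
  if (wet_persistence < 0 || wet_persistence >= 1) {
    stop("wet_persistence must be in [0, 1)")
  }
  if (rain_mean < 0) stop("rain_mean must be non-negative")
  if (rain_shape <= 0) stop("rain_shape must be positive")
  structure(list(tmean = tmean, amplitude = amplitude,
                 diurnal_range = diurnal_range, noise_sd = noise_sd,
                 phase_doy = phase_doy, p_wet = p_wet,
                 wet_persistence = wet_persistence, rain_mean = rain_mean,
                 rain_shape = rain_shape),
            class = "climate_params")
}

#' Generate a synthetic daily weather series
#'
#' Stands in for downloaded station records: a seasonal temperature sinusoid
#' with Gaussian noise and Markov-chain rainfall (see [climate_params()]).
#' Deterministic for a fixed seed.
#'
#' @param latitude site latitude, decimal degrees (south negative).
#' @param start first date of the series.
#' @param n_days number of days (>= 1).
#' @param seed integer RNG seed.
#' @param climate a [climate_params()] object.
#' @return a [weather_series()].
#' @export
generate_synthetic_weather <- function(latitude, start, n_days, seed,
                                       climate = climate_params()) {
  if (!inherits(climate, "climate_params")) {
    climate <- do.call(climate_params, climate)
  }
  if (n_days < 1) stop("n_days must be >= 1")
  start <- as.Date(start)
  dates <- start + seq_len(n_days) - 1
  doy <- as.integer(format(dates, "%j"))
  set.seed(as.integer(seed))
  seasonal <- climate$tmean +
    climate$amplitude * cos(2 * pi * (doy - climate$phase_doy) / 365.25)
  tmean_d <- seasonal + stats::rnorm(n_days, 0, climate$noise_sd)
  range_d <- pmax(climate$diurnal_range +
                    stats::rnorm(n_days, 0, climate$noise_sd / 2), 0.5)
  tmax <- tmean_d + range_d / 2
  tmin <- tmean_d - range_d / 2
  # two-state Markov chain with stationary probability p_wet
  p <- climate$p_wet
  rho <- climate$wet_persistence
  p11 <- p + (1 - p) * rho
  p01 <- p * (1 - rho)
  wet <- logical(n_days)
  u <- stats::runif(n_days)
  wet[1] <- u[1] < p
  if (n_days > 1) {
    for (i in 2:n_days) {
      wet[i] <- u[i] < (if (wet[i - 1]) p11 else p01)
    }
  }
  rain <- numeric(n_days)
  nwet <- sum(wet)
  if (nwet > 0 && climate$rain_mean > 0) {
    rain[wet] <- stats::rgamma(nwet, shape = climate$rain_shape,
                               scale = climate$rain_mean / climate$rain_shape)
  }
  weather_series(data.frame(date = dates, tmax = tmax, tmin = tmin,
                            rain = rain, irrigation = 0),
                 latitude)
}

#' Astronomical daylength
#'
#' Daylength in hours from standard solar geometry: solar declination from
#' the day of year and the hour angle at a configurable sun altitude. The
#' default twilight angle of -2.2 degrees (sun centre below the horizon) is
#' the crop-modelling convention for photoperiod, which extends daylength by
#' roughly 20-30 minutes relative to geometric sunrise/sunset.
#'
#' @param latitude degrees in `[-90, 90]` (south negative).
#' @param day_of_year 1-366; vectorised.
#' @param twilight_angle sun altitude in degrees defining day/night; negative
#'   values place the sun below the horizon (twilight included).
#' @return daylength in hours, in `[0, 24]`.
#' @export
daylength <- function(latitude, day_of_year, twilight_angle = -2.2) {
  if (any(latitude < -90 | latitude > 90)) stop("latitude must be in [-90, 90]")
  phi <- latitude * pi / 180
  decl <- -23.44 * pi / 180 * cos(2 * pi * (day_of_year + 10) / 365.25)
  alt <- twilight_angle * pi / 180
  cosh0 <- (sin(alt) - sin(phi) * sin(decl)) / (cos(phi) * cos(decl))
  cosh0 <- pmin(pmax(cosh0, -1), 1)
  24 / pi * acos(cosh0)
}
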