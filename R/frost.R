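#' Count post-flowering frost events
#'
#' A frost event is a day with minimum temperature at or below `threshold`
#' (default 0 degrees C). Days are counted in the window strictly after
#' flowering up to and including `end`; consecutive frost days count
#' individually.
#'
#' @param weather a [weather_series()].
#' @param flowering flowering date.
#' @param end end of the assessment window (e.g. simulated maturity).
#' @param threshold frost threshold, degrees C (default 0; a day counts when
#'   `tmin <= threshold`).
#' @return integer count of frost days.
#' @export
count_post_flowering_frosts <- function(weather, flowering, end,
                                        threshold = 0) {
  stopifnot(inherits(weather, "weather_series"))
  flowering <- as.Date(flowering)
  end <- as.Date(end)
  if (flowering > end) stop("flowering must be on or before end")
  rng <- range(weather$date)
  if (flowering < rng[1] || end > rng[2]) {
    stop("frost window [", format(flowering), ", ", format(end),
         "] outside the weather range")
  }
  sel <- weather$date > flowering & weather$date <= end
  sum(weather$tmin[sel] <= threshold)
}

#' Apply the per-event frost yield penalty
#'
#' Each post-flowering frost event removes a fixed fraction (default 5%) of
#' the potential yield: `YieldL = YieldW * n * loss_per_event`, capped at
#' `YieldW` so the harvestable yield `YieldGM = YieldW - YieldL` never goes
#' negative.
#'
#' @param yield_w potential yield at 12% seed moisture, kg/ha (>= 0).
#' @param n_events number of post-flowering frost events (>= 0).
#' @param loss_per_event fractional loss per event (default 0.05).
#' @return a `frost_assessment` list with `n_events`, `yield_potential`,
#'   `yield_lost` and `yield_gm` (kg/ha).
#' @export
apply_frost_penalty <- function(yield_w, n_events, loss_per_event = 0.05) {
  if (yield_w < 0) stop("yield_w must be >= 0")
  if (n_events < 0) stop("n_events must be >= 0")
  if (loss_per_event < 0) stop("loss_per_event must be >= 0")
  yield_l <- min(yield_w * n_events * loss_per_event, yield_w)
  structure(list(n_events = as.integer(n_events),
                 yield_potential = yield_w,
                 yield_lost = yield_l,
                 yield_gm = yield_w - yield_l),
            class = "frost_assessment")
}

#' @export
print.frost_assessment <- function(x, ...) {
  cat(sprintf("<frost_assessment> %d frost events: potential %.0f, lost %.0f, harvestable %.0f kg/ha\n",
              x$n_events, x$yield_potential, x$yield_lost, x$yield_gm))
  invisible(x)
}

#' Frost assessment for a completed simulation
#'
#' Convenience wrapper: counts frosts from the simulated flowering date to
#' `end` (default the simulated maturity) and applies the penalty.
#'
#' @param result a `phenology_trace` that reached flowering.
#' @param weather the [weather_series()] the run used.
#' @param yield_w potential yield, kg/ha.
#' @param end window end; default the simulated maturity date, falling back
#'   to the last weather day if maturity was not reached.
#' @param threshold,loss_per_event see [count_post_flowering_frosts()] and
#'   [apply_frost_penalty()].
#' @return a `frost_assessment` with the window recorded.
#' @export
assess_frost <- function(result, weather, yield_w, end = NULL,
                         threshold = 0, loss_per_event = 0.05) {
  stopifnot(inherits(result, "phenology_trace"))
  if (!result$did_flower) stop("simulation did not reach flowering")
  if (is.null(end)) {
    end <- if (!is.na(result$maturity_date)) result$maturity_date else
      weather$date[nrow(weather)]
  }
  n <- count_post_flowering_frosts(weather, result$flowering_date, end,
                                   threshold)
  out <- apply_frost_penalty(yield_w, n, loss_per_event)
  out$window <- c(start = format(result$flowering_date), end = format(as.Date(end)))
  out
}
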