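#' Normalised root-mean-square error
#'
#' `NRMSE = sqrt(mean((observed - predicted)^2)) / mean(observed)` — the
#' RMSE of the predictions as a fraction of the mean observation.
#'
#' @param observed,predicted numeric vectors of equal length (>= 1).
#' @return NRMSE (dimensionless fraction).
#' @export
nrmse <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have the same length")
  }
  if (length(observed) < 1) stop("need at least one pair")
  m <- mean(observed)
  if (m == 0) stop("mean of observed is zero; NRMSE undefined")
  sqrt(mean((observed - predicted)^2)) / m
}

#' Lin's concordance correlation coefficient
#'
#' Measures agreement of predictions with observations against the 45-degree
#' line through the origin: `rho_c = rho * Cb` with Pearson correlation
#' `rho` and bias-correction factor `Cb = 2 / (v + 1/v + u^2)`, where
#' `v = s1/s2` is the scale ratio and `u = (m1 - m2) / sqrt(s1 * s2)` the
#' location shift (`m_i`, `s_i`: mean and standard deviation of the
#' observations, i = 1, and predictions, i = 2). Moments are population
#' (divide-by-n) by default, per Lin's original definition; set
#' `moments = "sample"` for the n-1 variant (rho_c is changed only through
#' u, and only slightly).
#'
#' @param observed,predicted numeric vectors, equal length >= 2, both
#'   non-constant.
#' @param moments `"population"` or `"sample"`.
#' @return an `agreement_stats` list: `rho_c`, `rho`, `Cb`, `v`, `u`,
#'   `m1`, `m2`, `s1`, `s2`, `n` and the McBride `category`.
#' @export
lins_ccc <- function(observed, predicted,
                     moments = c("population", "sample")) {
  moments <- match.arg(moments)
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have the same length")
  }
  n <- length(observed)
  if (n < 2) stop("need at least two pairs")
  denom <- if (moments == "population") n else n - 1
  m1 <- mean(observed); m2 <- mean(predicted)
  s1sq <- sum((observed - m1)^2) / denom
  s2sq <- sum((predicted - m2)^2) / denom
  if (s1sq == 0 || s2sq == 0) {
    stop("constant series: scale ratio and correlation undefined")
  }
  s12 <- sum((observed - m1) * (predicted - m2)) / denom
  s1 <- sqrt(s1sq); s2 <- sqrt(s2sq)
  rho <- s12 / (s1 * s2)
  v <- s1 / s2
  u <- (m1 - m2) / sqrt(s1 * s2)
  cb <- 2 / (v + 1 / v + u^2)
  rho_c <- rho * cb
  structure(list(rho_c = rho_c, rho = rho, Cb = cb, v = v, u = u,
                 m1 = m1, m2 = m2, s1 = s1, s2 = s2, n = n,
                 category = mcbride_category(rho_c)),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement_stats> n = %d: rho_c = %.4f (%s), rho = %.4f, Cb = %.4f\n",
              x$n, x$rho_c, x$category, x$rho, x$Cb))
  invisible(x)
}

#' McBride category of a concordance coefficient
#'
#' Cut-points: `rho_c <= 0.90` poor; `> 0.90` to `0.95` moderate; `> 0.95`
#' to `0.99` substantial; `> 0.99` almost perfect.
#'
#' @param rho_c concordance coefficient in `[-1, 1]`.
#' @return one of `"poor"`, `"moderate"`, `"substantial"`,
#'   `"almost perfect"`.
#' @export
mcbride_category <- function(rho_c) {
  if (is.na(rho_c) || rho_c < -1 || rho_c > 1) {
    stop("rho_c must be in [-1, 1]")
  }
  if (rho_c > 0.99) "almost perfect"
  else if (rho_c > 0.95) "substantial"
  else if (rho_c > 0.90) "moderate"
  else "poor"
}

#' Agreement statistics for an observed/predicted table
#'
#' @param table data frame with columns `observed` and `predicted` (or the
#'   column names given).
#' @param observed,predicted column names.
#' @return list with `nrmse` and the `lins_ccc` stats.
#' @export
evaluate_agreement <- function(table, observed = "observed",
                               predicted = "predicted") {
  o <- table[[observed]]
  p <- table[[predicted]]
  list(nrmse = nrmse(o, p), ccc = lins_ccc(o, p))
}
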