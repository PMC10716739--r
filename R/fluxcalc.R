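# Significance-gated H2 oxidation rates from static-headspace GC time series.

# ideal-gas constant, L atm K^-1 mol^-1
.R_GAS <- 0.082057366

# moles of gas in the headspace; 1 ppbv of headspace gas = n_head nanomoles
headspace_moles <- function(headspace_ml, temp_K, pressure_atm) {
  if (headspace_ml <= 0) stop("headspace volume must be positive")
  if (temp_K <= 0) stop("temperature must be positive")
  if (pressure_atm <= 0) stop("pressure must be positive")
  pressure_atm * (headspace_ml / 1000) / (.R_GAS * temp_K)
}

# ppbv min^-1 decay slope magnitude equivalent to a rate in nmol g^-1 h^-1
slope_for_rate <- function(rate, soil_dw_g, headspace_ml, temp_K, pressure_atm) {
  n_head <- headspace_moles(headspace_ml, temp_K, pressure_atm)
  rate * soil_dw_g / (60 * n_head)
}

#' Construct a headspace concentration time series
#'
#' One microcosm-day record of headspace H2 mixing ratio versus time, with the
#' physical constants needed to convert a decay slope into an oxidation rate.
#' The GC assay takes 5 to 6 observations within a window of at most 20
#' minutes; both constraints are enforced.
#'
#' @param sample_id,day identifiers.
#' @param t_min numeric vector of sampling times (minutes, non-negative,
#'   increasing).
#' @param c_ppbv matching vector of H2 mixing ratios (ppbv, non-negative).
#' @param soil_dw_g,headspace_ml,temp_K,pressure_atm physical constants.
#' @return list of class `headspace_series`.
#' @export
headspace_series <- function(sample_id, day, t_min, c_ppbv,
                             soil_dw_g = 10, headspace_ml = 117.5,
                             temp_K = 298.15, pressure_atm = 1) {
  if (length(t_min) != length(c_ppbv)) stop("t_min and c_ppbv lengths differ")
  n <- length(t_min)
  if (n < 5 || n > 6) {
    stop(sprintf("headspace series for %s day %s has %d observations; 5 or 6 required",
                 sample_id, day, n))
  }
  if (is.unsorted(t_min, strictly = TRUE)) stop("t_min must be strictly increasing")
  if (any(t_min < 0) || any(c_ppbv < 0)) stop("times and concentrations must be non-negative")
  if (max(t_min) - min(t_min) > 20) {
    stop("measurement window exceeds 20 minutes")
  }
  headspace_moles(headspace_ml, temp_K, pressure_atm)  # validates constants
  structure(list(sample_id = sample_id, day = as.integer(day),
                 t_min = as.numeric(t_min), c_ppbv = as.numeric(c_ppbv),
                 soil_dw_g = soil_dw_g, headspace_ml = headspace_ml,
                 temp_K = temp_K, pressure_atm = pressure_atm),
            class = "headspace_series")
}

#' Fit the linear headspace decay
#'
#' Ordinary least-squares fit of concentration on time; the slope's two-sided
#' t-test p-value feeds the significance gate of [rate_from_slope()]. A
#' perfectly constant series returns slope 0 with p = 1.
#'
#' @param series a [headspace_series()].
#' @return list with `slope` (ppbv per minute), `intercept` (ppbv), `p_slope`.
#' @export
fit_decay <- function(series) {
  stopifnot(inherits(series, "headspace_series"))
  t <- series$t_min
  c <- series$c_ppbv
  if (length(unique(t)) < 3) stop("fewer than 3 distinct time points; decay unfittable")
  if (all(c == c[1])) {
    # perfectly constant series: no decay, no evidence against the null
    return(list(slope = 0, intercept = c[1], p_slope = 1))
  }
  fit <- stats::lm(c ~ t)
  sm <- suppressWarnings(summary(fit))$coefficients  # noiseless series fit exactly
  slope <- unname(sm["t", "Estimate"])
  p <- unname(sm["t", "Pr(>|t|)"])
  if (is.nan(p)) p <- 1  # zero-variance series: no evidence of decay
  list(slope = slope, intercept = unname(sm["(Intercept)", "Estimate"]),
       p_slope = p)
}

#' Convert a decay slope to a significance-gated H2 oxidation rate
#'
#' The headspace contains `n = PV/RT` moles of gas, so a change of 1 ppbv
#' corresponds to `n` nanomoles of H2. A significant negative concentration
#' slope is net uptake (positive rate); a significant positive slope is net
#' emission (negative rate). A rate of 0 is assigned when the decay is not
#' significant at `alpha` (`gated = TRUE`).
#'
#' @param slope fitted slope in ppbv per minute.
#' @param p_slope two-sided p-value of the slope, from [fit_decay()].
#' @param series the [headspace_series()] providing the physical constants.
#' @param alpha significance level of the gate (default 0.05).
#' @return data.frame with one row: `sample_id`, `day`, `u` (nmol per g dry
#'   soil per hour), `slope_ppbv_per_min`, `p_slope`, `gated`.
#' @export
rate_from_slope <- function(slope, p_slope, series, alpha = 0.05) {
  stopifnot(inherits(series, "headspace_series"),
            is.numeric(slope), length(slope) == 1,
            p_slope >= 0, p_slope <= 1, alpha > 0, alpha <= 1)
  n_head <- headspace_moles(series$headspace_ml, series$temp_K, series$pressure_atm)
  gated <- p_slope >= alpha
  u <- if (gated) 0 else -slope * 60 * n_head / series$soil_dw_g
  data.frame(sample_id = series$sample_id, day = series$day, u = u,
             slope_ppbv_per_min = slope, p_slope = p_slope, gated = gated,
             stringsAsFactors = FALSE)
}

#' Estimate the H2 oxidation rate of one series
#'
#' Convenience wrapper: [fit_decay()] followed by [rate_from_slope()].
#'
#' @inheritParams rate_from_slope
#' @param series a [headspace_series()].
#' @return see [rate_from_slope()].
#' @export
estimate_rate <- function(series, alpha = 0.05) {
  f <- fit_decay(series)
  rate_from_slope(f$slope, f$p_slope, series, alpha = alpha)
}

#' Median oxidation rate of a microcosm
#'
#' The per-microcosm activity statistic: the median of the gated rates over all
#' measurement days available for the sample (even-length inputs use the usual
#' midpoint convention).
#'
#' @param u numeric vector of oxidation rates, or a data.frame of rates from
#'   [estimate_rate()] for a single sample.
#' @param sample_id identifier carried through.
#' @return data.frame with `sample_id`, `median_u`, `n_obs`.
#' @export
median_rate <- function(u, sample_id = NA_character_) {
  if (is.data.frame(u)) {
    sid <- unique(u$sample_id)
    if (length(sid) != 1) stop("median_rate() expects rates of a single sample; see summarize_rates()")
    sample_id <- sid
    u <- u$u
  }
  if (length(u) == 0) stop("no rates to summarize")
  data.frame(sample_id = sample_id, median_u = stats::median(u),
             n_obs = length(u), stringsAsFactors = FALSE)
}

#' Per-sample median rates for a full rate table
#'
#' @param rates data.frame of rates as returned by [estimate_rate()] (rows
#'   over samples and days).
#' @return data.frame with one row per sample: `sample_id`, `median_u`, `n_obs`.
#' @export
summarize_rates <- function(rates) {
  stopifnot(is.data.frame(rates), nrow(rates) > 0)
  out <- do.call(rbind, lapply(split(rates, rates$sample_id), median_rate))
  rownames(out) <- NULL
  out[order(out$sample_id), , drop = FALSE]
}

#' Percent change of activity relative to a control
#'
#' `100 * (1 - treatment / control)`: positive values are a loss of activity.
#'
#' @param treatment,control median rates (numbers, or single-row summaries from
#'   [median_rate()]).
#' @return percent change (numeric scalar).
#' @export
#' @examples
#' percent_change(0.06, 0.75)  # 92
percent_change <- function(treatment, control) {
  if (is.data.frame(treatment)) treatment <- treatment$median_u
  if (is.data.frame(control)) control <- control$median_u
  stopifnot(length(treatment) == 1, length(control) == 1)
  if (control == 0) stop("control median rate is zero; percent change undefined")
  100 * (1 - treatment / control)
}

#' Test the temporal trend of weekly oxidation rates
#'
#' Default model regresses the rate on the natural log of incubation day
#' (a logarithmic rise/decline; requires `t_day >= 1`). The alternative
#' `"log_rate"` model regresses `ln(u)` on day, excluding non-positive rates
#' and reporting how many were excluded.
#'
#' @param t_day incubation day of each observation.
#' @param u oxidation rate of each observation.
#' @param model `"log_time"` (default) or `"log_rate"`.
#' @return list with `coef` (slope), `p`, `r2`, `n_excluded`.
#' @export
trend_test <- function(t_day, u, model = c("log_time", "log_rate")) {
  model <- match.arg(model)
  stopifnot(length(t_day) == length(u))
  if (length(u) < 4) stop("at least 4 weekly observations required")
  n_excluded <- 0L
  if (model == "log_time") {
    if (any(t_day < 1)) stop("log_time model requires t_day >= 1")
    x <- log(t_day); y <- u
  } else {
    keep <- u > 0
    n_excluded <- sum(!keep)
    if (!any(keep)) stop("all rates are non-positive; log_rate model undefined")
    if (sum(keep) < 4) stop("fewer than 4 positive rates for log_rate model")
    x <- t_day[keep]; y <- log(u[keep])
  }
  if (all(y == y[1])) return(list(coef = 0, p = 1, r2 = 0, n_excluded = n_excluded))
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  p <- sm$coefficients["x", "Pr(>|t|)"]
  if (is.nan(p)) p <- 1
  list(coef = unname(stats::coef(fit)["x"]), p = unname(p),
       r2 = sm$r.squared, n_excluded = n_excluded)
}
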