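# Bioreactor physiology: specific growth rate, specific production/uptake
# rates, yields and the respiratory quotient, computed interval-wise between
# sampling points.

#' Specific growth rate by exponential regression
#'
#' Slope of the ordinary least-squares fit of ln(biomass) against time, the
#' standard semi-logarithmic estimate of mu (1/h) during exponential growth.
#' Requires at least 3 points, all with positive biomass.
#'
#' @param time time points (h).
#' @param biomass biomass proxy (OD600 or CDW g/L), strictly positive.
#' @return mu in 1/h.
#' @examples
#' growth_rate(0:3, 2^(0:3))  # ln 2
#' @export
growth_rate <- function(time, biomass) {
  if (length(time) < 3L) stop("growth rate needs at least 3 points")
  if (any(biomass <= 0)) stop("biomass must be positive for log regression")
  unname(stats::coef(stats::lm(log(biomass) ~ time))[2])
}

#' Time-averaged biomass under exponential growth
#'
#' The time average of x(t) = x1 * exp(mu t) between two sampling points is
#' (x2 - x1) / ln(x2 / x1), independent of mu. Used as the biomass
#' denominator for specific rates during the exponential (aerobic) phase;
#' returns x1 in the x1 = x2 limit. Always lies strictly between the two
#' endpoints and is symmetric in its arguments.
#'
#' @param x1,x2 biomass concentrations (g/L) at the interval endpoints, > 0.
#' @return g/L.
#' @export
exp_average_biomass <- function(x1, x2) {
  stopifnot(x1 > 0, x2 > 0)
  if (isTRUE(all.equal(x1, x2))) return(x1)
  (x2 - x1) / log(x2 / x1)
}

#' Specific production or uptake rate
#'
#' q = (delta_conc / delta_t) / biomass_avg, in g per g CDW per h. The
#' biomass average between the endpoints is the exponential time average
#' during exponential growth and the arithmetic mean during the linear
#' (oxygen-limited/anaerobic) growth regime. For uptake rates pass the
#' consumed amount as a positive \code{delta_conc}.
#'
#' @param delta_conc concentration change over the interval (g/L).
#' @param delta_t interval length (h), > 0.
#' @param x1,x2 biomass at the interval endpoints (g/L).
#' @param mode \code{"exponential"} or \code{"arithmetic"} biomass averaging.
#' @return g / (g CDW h).
#' @export
specific_rate <- function(delta_conc, delta_t, x1, x2,
                          mode = c("exponential", "arithmetic")) {
  mode <- match.arg(mode)
  stopifnot(delta_t > 0)
  xbar <- if (mode == "exponential") exp_average_biomass(x1, x2)
          else (x1 + x2) / 2
  if (xbar <= 0) stop("non-positive average biomass")
  (delta_conc / delta_t) / xbar
}

#' Product yield on glucose
#'
#' Grams of product formed per gram of glucose consumed between two sampling
#' points. A negative product change (net consumption) is clipped to 0 and
#' flagged; zero glucose consumption leaves the yield undefined (NA, with
#' flag).
#'
#' @param delta_product product formed over the interval (g/L).
#' @param delta_glucose_consumed glucose consumed over the interval (g/L, >0
#'   for a defined yield).
#' @return numeric yield with attribute \code{"flag"} (\code{""},
#'   \code{"product_decreased"} or \code{"no_glucose_consumed"}).
#' @export
product_yield <- function(delta_product, delta_glucose_consumed) {
  if (is.na(delta_glucose_consumed) || delta_glucose_consumed <= 0) {
    return(structure(NA_real_, flag = "no_glucose_consumed"))
  }
  if (delta_product < 0) {
    return(structure(0, flag = "product_decreased"))
  }
  structure(delta_product / delta_glucose_consumed, flag = "")
}

#' Respiratory quotient from off-gas fractions
#'
#' RQ = CER / OUR, the molar CO2 evolution rate over the molar O2 uptake
#' rate from the inlet-outlet balance. With the default equal in/out dry gas
#' flow assumption: OUR proportional to (yO2_in - yO2_out) and CER to
#' (yCO2_out - yCO2_in). The inert (N2) balance option corrects the outlet
#' flow by the ratio of inert fractions, appropriate when total moles change
#' appreciably. Undefined (NA, flagged) when O2 uptake is not positive, as
#' in the N2-sparged anaerobic phase.
#'
#' @param o2_in,o2_out,co2_in,co2_out volume (mole) fractions of O2 and CO2
#'   in the inlet and outlet gas.
#' @param balance \code{"equal_flow"} (default) or \code{"inert"}.
#' @return RQ (dimensionless), NA with attribute \code{"flag"} =
#'   \code{"no_o2_uptake"} when undefined.
#' @export
respiratory_quotient <- function(o2_in, o2_out, co2_in, co2_out,
                                 balance = c("equal_flow", "inert")) {
  balance <- match.arg(balance)
  if (balance == "inert") {
    inert_in <- 1 - o2_in - co2_in
    inert_out <- 1 - o2_out - co2_out
    if (inert_out <= 0) stop("outlet inert fraction must be positive")
    f <- inert_in / inert_out          # outlet/inlet flow ratio
    our <- o2_in - f * o2_out
    cer <- f * co2_out - co2_in
  } else {
    our <- o2_in - o2_out
    cer <- co2_out - co2_in
  }
  if (our <= 0) return(structure(NA_real_, flag = "no_o2_uptake"))
  structure(cer / our, flag = "")
}

#' Interval-wise culture kinetics
#'
#' Computes, for each consecutive pair of named sampling times, the specific
#' growth rate (exponential regression over the series points falling inside
#' the interval), the specific glucose uptake rate, and per-product specific
#' production rates and yields. Biomass averaging is exponential for
#' intervals labelled exponential-phase and arithmetic otherwise.
#'
#' @param ts data.frame time series with columns \code{time_h},
#'   \code{biomass_g_L}, \code{glucose_g_L} and one column per product
#'   (g/L), e.g. from [simulate_physiology()].
#' @param interval_times numeric vector of sampling times (h) delimiting the
#'   intervals, e.g. \code{c(0, 4.9, 6.8, 8, 9, 10)}.
#' @param interval_labels optional labels (default \code{"T0-T1"}, ...).
#' @param exponential_intervals indices of intervals in exponential growth
#'   (default: the first).
#' @param products names of product columns (default: every column other
#'   than time/biomass/glucose/off-gas).
#' @return data.frame with one row per interval x quantity.
#' @export
interval_kinetics <- function(ts, interval_times, interval_labels = NULL,
                              exponential_intervals = 1L,
                              products = NULL) {
  stopifnot(all(diff(ts$time_h) > 0), length(interval_times) >= 2L)
  if (is.null(products)) {
    products <- setdiff(names(ts),
                        c("time_h", "biomass_g_L", "glucose_g_L",
                          "o2_in", "o2_out", "co2_in", "co2_out"))
  }
  n_int <- length(interval_times) - 1L
  if (is.null(interval_labels)) {
    interval_labels <- paste0("T", seq_len(n_int) - 1L, "-T", seq_len(n_int))
  }
  at <- function(col, t) stats::approx(ts$time_h, ts[[col]], xout = t,
                                       rule = 2)$y
  out <- list()
  for (i in seq_len(n_int)) {
    t1 <- interval_times[i]; t2 <- interval_times[i + 1L]
    mode <- if (i %in% exponential_intervals) "exponential" else "arithmetic"
    inwin <- ts$time_h >= t1 - 1e-9 & ts$time_h <= t2 + 1e-9
    mu <- if (sum(inwin) >= 3L)
      growth_rate(ts$time_h[inwin], ts$biomass_g_L[inwin]) else NA_real_
    x1 <- at("biomass_g_L", t1); x2 <- at("biomass_g_L", t2)
    dglc <- at("glucose_g_L", t1) - at("glucose_g_L", t2)
    q_s <- if (dglc > 0) specific_rate(dglc, t2 - t1, x1, x2, mode) else NA_real_
    row <- data.frame(interval = interval_labels[i], t_start = t1, t_end = t2,
                      mu = mu, q_s = q_s, stringsAsFactors = FALSE)
    for (p in products) {
      dp <- at(p, t2) - at(p, t1)
      row[[paste0("q_", p)]] <-
        specific_rate(max(dp, 0), t2 - t1, x1, x2, mode)
      row[[paste0("yield_", p)]] <- as.numeric(product_yield(dp, dglc))
    }
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
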