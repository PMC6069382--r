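# First-order Arrhenius shelf-life kinetics.
# Rates are day^-1 throughout; temperatures are degrees Celsius at every
# user-facing interface and Kelvin internally. R = 8.314 J mol^-1 K^-1.

GAS_CONSTANT <- 8.314
ABS_ZERO_C <- -273.15

#' Kinetic parameter set for first-order quality decay
#'
#' Bundles the parameters of the Arrhenius rate law and the first-order
#' decay model: the rate constant at a reference temperature, the
#' activation energy, and the initial and equilibrium (failure) values of
#' the quality factor. For tomato firmness the quality factor is the
#' penetration force in newtons; decay stops being acceptable when the
#' firmness reaches `c_eq`.
#'
#' @param k_ref Rate constant at the reference temperature (day^-1), > 0.
#' @param T_ref_C Reference temperature (deg C).
#' @param Ea Activation energy (kJ/mol), > 0.
#' @param c0 Initial quality factor (N).
#' @param c_eq Equilibrium/failure quality factor (N); `c0 > c_eq >= 0`.
#' @param W Optional pre-exponential factor (day^-1). Redundant with
#'   `k_ref` under the ratio form of the rate law; kept for completeness.
#' @param product_label Free-text label for the product the parameters
#'   describe.
#'
#' @return An object of class `kinetic_params`.
#' @seealso [tomato_firmness_params()] for the built-in preset.
#' @export
#' @examples
#' p <- kinetic_params(k_ref = 0.2, T_ref_C = 20, Ea = 64.8,
#'                     c0 = 12.4, c_eq = 3)
#' arrhenius_rate(p, 20)  # k_ref recovered at the reference temperature
kinetic_params <- function(k_ref, T_ref_C, Ea, c0, c_eq, W = NULL,
                           product_label = "") {
  stopifnot(is.numeric(k_ref), is.numeric(T_ref_C), is.numeric(Ea),
            is.numeric(c0), is.numeric(c_eq))
  if (!is.finite(k_ref) || k_ref <= 0)
    stop("k_ref must be a positive finite rate (day^-1)")
  if (!is.finite(Ea) || Ea <= 0)
    stop("Ea must be a positive finite activation energy (kJ/mol)")
  if (!is.finite(T_ref_C) || T_ref_C <= ABS_ZERO_C)
    stop("T_ref_C must be above absolute zero")
  if (!is.finite(c0) || !is.finite(c_eq) || c_eq < 0 || c0 < c_eq)
    stop("quality factors must satisfy c0 >= c_eq >= 0")
  structure(
    list(k_ref = k_ref, T_ref_C = T_ref_C, Ea = Ea, c0 = c0, c_eq = c_eq,
         W = W, product_label = product_label),
    class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters",
      if (nzchar(x$product_label)) paste0("(", x$product_label, ")"), "\n")
  cat(sprintf("  k_ref = %g day^-1 @ %g degC, Ea = %g kJ/mol\n",
              x$k_ref, x$T_ref_C, x$Ea))
  cat(sprintf("  c0 = %g N, c_eq = %g N\n", x$c0, x$c_eq))
  invisible(x)
}

#' Built-in tomato-firmness kinetic preset
#'
#' The firmness-decay parameter set for fresh tomatoes used throughout the
#' package: k_ref = 0.2 day^-1 at 20 deg C, Ea = 64.8 kJ/mol, initial
#' firmness 12.4 N, failure firmness 3 N. The canonical rate unit is
#' day^-1: with these values the model yields a fresh shelf life of about
#' 7.1 days at 20 deg C, about 3 days at 30 deg C and about 1.3 days at
#' 40 deg C.
#'
#' @return A [kinetic_params()] object.
#' @export
tomato_firmness_params <- function() {
  kinetic_params(k_ref = 0.2, T_ref_C = 20, Ea = 64.8, c0 = 12.4,
                 c_eq = 3, product_label = "tomato firmness")
}

celsius_to_kelvin <- function(T_C) {
  if (any(!is.finite(T_C)) || any(T_C <= ABS_ZERO_C))
    stop("temperature must be finite and above absolute zero (-273.15 degC)")
  T_C + 273.15
}

#' Arrhenius rate constant at a given temperature
#'
#' Evaluates the ratio form of the Arrhenius law,
#' `k(T) = k_ref * exp(-(Ea/R) * (1/T - 1/T_ref))` with temperatures in
#' kelvin, `Ea` converted to J/mol and `R = 8.314 J mol^-1 K^-1`. The rate
#' is strictly increasing in temperature for positive activation energy.
#'
#' @param params A [kinetic_params()] object.
#' @param T_C Temperature (deg C); may be a vector.
#' @return Rate constant(s), day^-1.
#' @export
#' @examples
#' arrhenius_rate(tomato_firmness_params(), c(20, 30, 40))
arrhenius_rate <- function(params, T_C) {
  stopifnot(inherits(params, "kinetic_params"))
  T_K <- celsius_to_kelvin(T_C)
  T_ref_K <- celsius_to_kelvin(params$T_ref_C)
  Ea_J <- params$Ea * 1000
  params$k_ref * exp(-(Ea_J / GAS_CONSTANT) * (1 / T_K - 1 / T_ref_K))
}

#' Rate-constant interval induced by sensor accuracy
#'
#' A temperature sensor with accuracy `acc` leaves the true temperature
#' anywhere in `[T - acc, T + acc]`, so the decay rate lies between
#' `k(T - acc)` and `k(T + acc)`. Following the SL-/SL+ convention the
#' pessimistic (larger, from the warmer bound) rate is `k_minus` and the
#' optimistic one `k_plus`.
#'
#' @param params A [kinetic_params()] object.
#' @param T_C Measured temperature (deg C).
#' @param acc Sensor accuracy (deg C), >= 0.
#' @return Named numeric vector `c(k_minus=, k_plus=)` with
#'   `k_minus >= k(T) >= k_plus`.
#' @export
rate_bounds <- function(params, T_C, acc) {
  if (!is.numeric(acc) || !is.finite(acc) || acc < 0)
    stop("acc must be a non-negative finite accuracy (degC)")
  c(k_minus = arrhenius_rate(params, T_C + acc),
    k_plus = arrhenius_rate(params, T_C - acc))
}

#' Quality state of a monitored pallet
#'
#' Tracks elapsed storage time, the current quality factor, the rate in
#' effect and the predicted remaining shelf life with its sensor-accuracy
#' bounds.
#'
#' @param t Elapsed storage time (day).
#' @param c Current quality factor (N), >= 0.
#' @param k_current Rate in effect (day^-1).
#' @param SL Predicted remaining shelf life (day), >= 0.
#' @param SL_lo,SL_hi Shelf-life bounds from sensor accuracy (day),
#'   `SL_lo <= SL <= SL_hi`.
#' @return An object of class `quality_state`.
#' @export
quality_state <- function(t = 0, c, k_current = NA_real_, SL = NA_real_,
                          SL_lo = NA_real_, SL_hi = NA_real_) {
  if (!is.finite(c) || c < 0) stop("quality factor c must be >= 0")
  if (!is.finite(t) || t < 0) stop("time t must be >= 0")
  if (is.finite(SL) && SL < 0) stop("SL must be >= 0")
  if (is.finite(SL_lo) && is.finite(SL_hi) &&
      !(SL_lo <= SL + 1e-9 && SL <= SL_hi + 1e-9))
    stop("shelf-life bounds must satisfy SL_lo <= SL <= SL_hi")
  structure(list(t = t, c = c, k_current = k_current, SL = SL,
                 SL_lo = SL_lo, SL_hi = SL_hi),
            class = "quality_state")
}

#' @export
print.quality_state <- function(x, ...) {
  cat(sprintf("Quality state: t = %.3f d, c = %.3f N, SL = %.3f d [%.3f, %.3f]\n",
              x$t, x$c, x$SL, x$SL_lo, x$SL_hi))
  invisible(x)
}

#' Advance first-order quality decay over a time step
#'
#' Integrates the first-order decay model at constant rate `k` over `dt`
#' days. Two defensible forms are provided: `"exponential"`,
#' `c' = c * exp(-k dt)` (the form consistent with the logarithmic
#' shelf-life expression, and the default), and `"equilibrium"`,
#' `c' = c_eq + (c - c_eq) * exp(-k dt)`, which decays towards the failure
#' level instead of zero.
#'
#' @param state A [quality_state()] object (or a single numeric quality
#'   value).
#' @param k Decay rate (day^-1), >= 0.
#' @param dt Time step (day), >= 0.
#' @param form `"exponential"` (default) or `"equilibrium"`.
#' @param c_eq Equilibrium quality factor, required for the equilibrium
#'   form when `state` is bare numeric.
#' @return An updated `quality_state` (or numeric if `state` was numeric).
#' @export
decay_step <- function(state, k, dt, form = c("exponential", "equilibrium"),
                       c_eq = NULL) {
  form <- match.arg(form)
  if (!is.finite(dt) || dt < 0) stop("dt must be a non-negative time step")
  if (!is.finite(k) || k < 0) stop("k must be a non-negative rate")
  bare <- is.numeric(state)
  c_now <- if (bare) state else state$c
  c_new <- switch(form,
    exponential = c_now * exp(-k * dt),
    equilibrium = {
      if (is.null(c_eq)) stop("equilibrium form requires c_eq")
      c_eq + (c_now - c_eq) * exp(-k * dt)
    })
  c_new <- max(c_new, 0)
  if (bare) return(c_new)
  quality_state(t = state$t + dt, c = c_new, k_current = k,
                SL = state$SL, SL_lo = state$SL_lo, SL_hi = state$SL_hi)
}

#' Predicted shelf life from the current quality factor
#'
#' Remaining time until the quality factor decays from `c_prime` to the
#' failure level `c_eq` at constant rate `k`:
#' `SL = (1/k) * ln(c_prime / c_eq)`, clamped at zero once the failure
#' level is reached.
#'
#' @param c_prime Current quality factor (N), > 0.
#' @param params A [kinetic_params()] object (supplies `c_eq`).
#' @param k Decay rate in effect (day^-1), > 0.
#' @return Remaining shelf life (day), >= 0.
#' @export
#' @examples
#' p <- tomato_firmness_params()
#' shelf_life(p$c0, p, arrhenius_rate(p, 30))  # about 3 days
shelf_life <- function(c_prime, params, k) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!is.finite(k) || k <= 0) stop("k must be a positive rate")
  if (params$c_eq <= 0) stop("c_eq must be positive for the log form")
  if (!is.finite(c_prime) || c_prime < 0) stop("c_prime must be >= 0")
  if (c_prime <= params$c_eq) return(0)
  (1 / k) * log(c_prime / params$c_eq)
}

#' Shelf-life interval induced by sensor accuracy
#'
#' Propagates the temperature-sensor accuracy through the rate law into
#' shelf-life bounds: the lower bound uses the faster rate at `T + acc`,
#' the upper bound the slower rate at `T - acc`.
#'
#' @param c_prime Current quality factor (N).
#' @param params A [kinetic_params()] object.
#' @param T_C Measured temperature (deg C).
#' @param acc Sensor accuracy (deg C), >= 0.
#' @return Named vector `c(SL_lo=, SL=, SL_hi=)` (day).
#' @export
shelf_life_bounds <- function(c_prime, params, T_C, acc) {
  kb <- rate_bounds(params, T_C, acc)
  c(SL_lo = shelf_life(c_prime, params, kb[["k_minus"]]),
    SL = shelf_life(c_prime, params, arrhenius_rate(params, T_C)),
    SL_hi = shelf_life(c_prime, params, kb[["k_plus"]]))
}

#' Estimate a decay rate from an observed quality series
#'
#' Fits the exponential decay form by ordinary least squares on the
#' linearized model: the slope of `-ln(c/c[1])` against time estimates
#' `k`. Quality decay rates are conventionally determined by regression
#' of empirical firmness series; this is the linearized equivalent.
#'
#' @param t Observation times (day), strictly increasing, length >= 2.
#' @param c Observed quality factors (N), all > 0, same length as `t`.
#' @return A list with `k` (day^-1), `se` (its standard error; `NA` for a
#'   two-point series) and `n`.
#' @export
fit_rate <- function(t, c) {
  if (length(t) != length(c)) stop("t and c must have equal length")
  if (length(t) < 2) stop("need at least two observations")
  if (any(!is.finite(t)) || any(!is.finite(c))) stop("non-finite inputs")
  if (any(diff(t) <= 0)) stop("t must be strictly increasing")
  if (any(c <= 0)) stop("quality factors must be positive to linearize")
  y <- -log(c / c[1])
  if (length(t) == 2)
    return(list(k = (y[2] - y[1]) / (t[2] - t[1]), se = NA_real_, n = 2L))
  fit <- stats::lm(y ~ t)
  # a noiseless series is legal input; silence the perfect-fit warning
  sm <- suppressWarnings(summary(fit))$coefficients
  list(k = unname(sm["t", "Estimate"]), se = unname(sm["t", "Std. Error"]),
       n = length(t))
}
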