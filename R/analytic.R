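#' Closed-form total cell number under the PSCD model
#'
#' With the effective division rate `2/t`, the cell-number balance
#' `dN/dt = (2/t) N` integrates to quadratic growth `N(t) = N_bar0 * t^2`,
#' where `N_bar0 = N0 / t0^2` anchors the curve at the initial time.
#'
#' @param t Time(s) in days, `>= 0` (vectorized).
#' @param params A [pscd_params()] (or [iscd_params()]) with `N_bar0` set.
#' @return Total cell number(s).
#' @export
pscd_total_cells <- function(t, params) {
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  N_bar0 <- params$N_bar0
  if (is.null(N_bar0)) stop("`params` lacks N_bar0 (see convert_params)", call. = FALSE)
  N_bar0 * t^2
}

#' Closed-form total ALP activity under the PSCD model
#'
#' The ALP balance `dPhi/dt = (2/t) Phi - d0 Phi` integrates to the
#' rise-and-fall curve `Phi(t) = Phi_bar0 * t^2 * exp(-d0 * t)`:
#' division-driven quadratic growth eventually overwhelmed by exponential
#' intracellular degradation, peaking at `t = 2/d0`.
#'
#' @param t Time(s) in days, `>= 0` (vectorized).
#' @param params A [pscd_params()] with `Phi_bar0` and `d0 > 0`.
#' @return Total ALP activity value(s).
#' @export
pscd_total_alp <- function(t, params) {
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  if (is.null(params$Phi_bar0)) stop("`params` lacks Phi_bar0", call. = FALSE)
  if (is.null(params$d0) || params$d0 <= 0) {
    stop("`d0` must be positive for the ALP closed form", call. = FALSE)
  }
  params$Phi_bar0 * t^2 * exp(-params$d0 * t)
}

#' Peak time of the PSCD total ALP activity
#'
#' The unique stationary point of `t^2 * exp(-d0 * t)` on `t > 0` is
#' `t = 2 / d0`.
#'
#' @param params A [pscd_params()] with `d0 > 0`.
#' @return Peak time in days.
#' @export
pscd_peak_time <- function(params) {
  if (is.null(params$d0) || params$d0 <= 0) {
    stop("`d0` must be positive", call. = FALSE)
  }
  2 / params$d0
}

#' Closed-form moments under the ISCD model
#'
#' With the net rate `k_bar = k_d - k_f` chosen as `2/t`, both moments
#' grow quadratically: `N(t) = N_bar0 * t^2`, `Phi(t) = Phi_bar0 * t^2`.
#' Total ALP activity is therefore monotone increasing for all `t > 0`,
#' the property that makes the model inconsistent with an interior ALP
#' peak.
#'
#' @param t Time(s) in days, `>= 0` (vectorized).
#' @param params An [iscd_params()].
#' @return A data frame with columns `time`, `N`, `Phi`.
#' @export
iscd_moments <- function(t, params) {
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  data.frame(time = t, N = params$N_bar0 * t^2, Phi = params$Phi_bar0 * t^2)
}

#' Division rate as a function of cell number density
#'
#' Eliminating time between the fitted division rate `k_d = 2/t` and the
#' fitted growth law `N = N_bar0 * t^2`, with density `rho = N / V` at
#' fixed scaffold volume `V`, gives
#' `k_d(rho) = 2 * sqrt(N_bar0 / (rho * V))`: the division rate falls with
#' the square root of the density (log-log slope -1/2).  The elimination
#' is exact — the exponent is reported as derived, not forced to a `1/rho`
#' form.
#'
#' @param params Parameters with `N_bar0` set ([pscd_params()] or
#'   [iscd_params()]).
#' @param V Scaffold volume (fixed, arbitrary volume units), `> 0`.
#' @param rho_values Strictly positive cell number densities (cells per
#'   volume unit).
#' @return An object of class `density_rate_curve`: a data frame with
#'   columns `rho` and `k_d`, plus attributes `V` and `N_bar0`.
#' @export
density_rate_curve <- function(params, V, rho_values) {
  if (!is.numeric(V) || length(V) != 1L || V <= 0) {
    stop("`V` must be a single positive volume", call. = FALSE)
  }
  if (any(rho_values <= 0)) stop("`rho_values` must be positive", call. = FALSE)
  N_bar0 <- params$N_bar0
  if (is.null(N_bar0) || N_bar0 <= 0) stop("`N_bar0` must be positive", call. = FALSE)
  rho <- sort(as.numeric(rho_values))
  k_d <- 2 * sqrt(N_bar0 / (rho * V))
  structure(data.frame(rho = rho, k_d = k_d),
            V = V, N_bar0 = N_bar0,
            class = c("density_rate_curve", "data.frame"))
}
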