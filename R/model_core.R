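#' Model specification for the ALP-activity population balance
#'
#' A `model_spec` bundles the kernel functions of the population-balance
#' equation for the density `n(a, t)` of cells over per-cell ALP activity
#' `a`: a division kernel, a differentiation (loss) rate, and the
#' intracellular ALP synthesis and degradation fluxes, together with the
#' division bookkeeping mode.
#'
#' Two division modes are supported.  In `"conserved"` mode a mother cell
#' of activity `a + a'` is replaced by daughters of activities `a` and
#' `a'`, at rate `division_kernel(a, a')`; these events conserve total ALP
#' activity.  In `"non_conserved_symmetric"` mode both daughters inherit
#' the mother's activity; the kernel is then the singular
#' `k * delta(a - a')`, which is never discretized: it is represented
#' analytically by the scalar magnitude `division_rate` (`k`), and the
#' solver and the stochastic simulator use the equivalent local gain term
#' `g(t) * k * n(a, t)`.
#'
#' The dimensionless `division_time_factor` `g(t)` multiplies the division
#' kernel, so time-dependent division rates keep the kernels themselves
#' time-independent.  The factor `g(t) = 2/t` (with `k = 1`) gives the
#' effective division rate `2/t` used by both concrete differentiation
#' models; it diverges at `t = 0`, so solvers must start at a strictly
#' positive time.
#'
#' @param division_mode Either `"non_conserved_symmetric"` (default) or
#'   `"conserved"`.
#' @param division_rate Scalar magnitude `k` of the symmetric delta
#'   kernel; used only in `"non_conserved_symmetric"` mode.
#' @param division_kernel Function `k_d(a, a')` returning a non-negative
#'   rate (per day); used only in `"conserved"` mode.  Must be symmetric
#'   in its arguments and vectorized.
#' @param division_time_factor Function `g(t)` of time, a non-negative
#'   dimensionless multiplier of the division kernel.  Default: constant 1.
#' @param differentiation_rate Function `k_f(a)`, non-negative rate (per
#'   day) of instantaneous loss of a cell from the population.
#' @param synthesis_flux Function `s_i(a)`, ALP activity gained per cell
#'   per day by intracellular synthesis.
#' @param degradation_flux Function `d_o(a)`, ALP activity lost per cell
#'   per day by intracellular degradation.
#' @param label Free-text label for reports.
#'
#' @return An object of class `model_spec`.
#' @seealso [pscd_model()], [iscd_model()], [solve_population_balance()]
#' @export
model_spec <- function(division_mode = c("non_conserved_symmetric", "conserved"),
                       division_rate = 1,
                       division_kernel = NULL,
                       division_time_factor = function(t) rep(1, length(t)),
                       differentiation_rate = function(a) rep(0, length(a)),
                       synthesis_flux = function(a) rep(0, length(a)),
                       degradation_flux = function(a) rep(0, length(a)),
                       label = "custom") {
  division_mode <- match.arg(division_mode)
  if (division_mode == "non_conserved_symmetric") {
    if (!is.numeric(division_rate) || length(division_rate) != 1L ||
        !is.finite(division_rate) || division_rate < 0) {
      stop("`division_rate` must be a single finite non-negative number", call. = FALSE)
    }
  } else {
    if (!is.function(division_kernel)) {
      stop("conserved mode requires a `division_kernel` function k_d(a, a')", call. = FALSE)
    }
  }
  for (nm in c("division_time_factor", "differentiation_rate",
               "synthesis_flux", "degradation_flux")) {
    if (!is.function(get(nm))) stop("`", nm, "` must be a function", call. = FALSE)
  }
  obj <- structure(list(
    division_mode = division_mode,
    division_rate = division_rate,
    division_kernel = division_kernel,
    division_time_factor = division_time_factor,
    differentiation_rate = differentiation_rate,
    synthesis_flux = synthesis_flux,
    degradation_flux = degradation_flux,
    label = label
  ), class = "model_spec")
  validate_model_spec(obj)
  obj
}

# Spot-check that the rate/flux functions are finite and non-negative on a
# probe grid of activities (and g on a probe grid of times).  Cheap guard,
# not a proof for all a.
validate_model_spec <- function(x, a_probe = c(0, 0.1, 1, 10, 100),
                                t_probe = c(0.1, 1, 7, 28)) {
  for (nm in c("differentiation_rate", "synthesis_flux", "degradation_flux")) {
    v <- x[[nm]](a_probe)
    if (length(v) != length(a_probe) || any(!is.finite(v)) || any(v < 0)) {
      stop("`", nm, "` must evaluate to finite non-negative values for a >= 0",
           call. = FALSE)
    }
  }
  g <- x$division_time_factor(t_probe)
  if (any(!is.finite(g)) || any(g < 0)) {
    stop("`division_time_factor` must be finite and non-negative for t > 0",
         call. = FALSE)
  }
  invisible(x)
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$label, "\n", sep = "")
  cat("  division mode: ", x$division_mode, "\n", sep = "")
  if (x$division_mode == "non_conserved_symmetric") {
    cat("  delta-kernel magnitude k: ", x$division_rate, "\n", sep = "")
  }
  cat("  g(7) = ", signif(x$division_time_factor(7), 4),
      ", k_f(1) = ", signif(x$differentiation_rate(1), 4),
      ", s_i(1) = ", signif(x$synthesis_flux(1), 4),
      ", d_o(1) = ", signif(x$degradation_flux(1), 4), "\n", sep = "")
  invisible(x)
}

#' Progressive stem-cell differentiation (PSCD) model preset
#'
#' Symmetric non-conserved division at effective rate `2/t` (both daughters
#' inherit the mother's ALP activity), no instantaneous differentiation
#' loss, no ALP synthesis, and gradual intracellular ALP degradation
#' `d_o(a) = d0 * a`.  Differentiation proceeds via progressive decay of
#' per-cell ALP activity, passing through pre-osteoblast states.  The
#' moment closed forms are `N(t) = N_bar0 * t^2` and
#' `Phi(t) = Phi_bar0 * t^2 * exp(-d0 * t)`.
#'
#' @param d0 ALP degradation rate (per day), `>= 0`.
#' @return A [model_spec()] for the PSCD model.
#' @examples
#' m <- pscd_model(d0 = 1 / 5.84)
#' m$degradation_flux(5.84) # = 1 activity unit per day
#' @export
pscd_model <- function(d0) {
  if (!is.numeric(d0) || length(d0) != 1L || !is.finite(d0) || d0 < 0) {
    stop("`d0` must be a single finite non-negative rate (per day)", call. = FALSE)
  }
  force(d0)
  model_spec(
    division_mode = "non_conserved_symmetric",
    division_rate = 1,
    division_time_factor = function(t) 2 / t,
    differentiation_rate = function(a) rep(0, length(a)),
    synthesis_flux = function(a) rep(0, length(a)),
    degradation_flux = function(a) d0 * a,
    label = "pscd"
  )
}

#' Instantaneous stem-cell differentiation (ISCD) model preset
#'
#' Symmetric non-conserved division at effective rate `2/t`, constant
#' instantaneous differentiation rate `k_f` (a cell leaves the population
#' with all its ALP activity at once), and no intracellular ALP fluxes.
#' Both moments follow `t^2` growth: `N(t) = N_bar0 * t^2`,
#' `Phi(t) = Phi_bar0 * t^2` — total ALP activity is monotone in time,
#' which is the property that lets the model be rejected on data with an
#' interior ALP peak.
#'
#' @param k_f Differentiation rate (per day), `>= 0`.
#' @return A [model_spec()] for the ISCD model.
#' @export
iscd_model <- function(k_f) {
  if (!is.numeric(k_f) || length(k_f) != 1L || !is.finite(k_f) || k_f < 0) {
    stop("`k_f` must be a single finite non-negative rate (per day)", call. = FALSE)
  }
  force(k_f)
  model_spec(
    division_mode = "non_conserved_symmetric",
    division_rate = 1,
    division_time_factor = function(t) 2 / t,
    differentiation_rate = function(a) rep(k_f, length(a)),
    synthesis_flux = function(a) rep(0, length(a)),
    degradation_flux = function(a) rep(0, length(a)),
    label = "iscd"
  )
}

#' PSCD model parameters
#'
#' Holds the PSCD closed-form parameters in either or both of two
#' equivalent parameterizations: the growth amplitudes
#' (`N_bar0` in cells/day^2, `Phi_bar0` in activity units/day^2) or the
#' initial-time values (`N0` cells and `Phi0` activity units at time `t0`
#' days).  They are linked by `N_bar0 = N0 / t0^2` and
#' `Phi_bar0 = Phi0 * exp(d0 * t0) / t0^2`; [convert_params()] fills in
#' the missing half.  If both halves are supplied they must be consistent
#' to 1e-9 relative.
#'
#' @param N_bar0,Phi_bar0 Quadratic-growth amplitudes (optional).
#' @param d0 ALP degradation rate (per day), `> 0` for the ALP closed form.
#' @param N0,Phi0,t0 Initial-time parameterization (optional); `t0 > 0`.
#' @return An object of class `pscd_params`.
#' @export
pscd_params <- function(N_bar0 = NULL, Phi_bar0 = NULL, d0,
                        N0 = NULL, Phi0 = NULL, t0 = NULL) {
  chk_nonneg <- function(x, nm) {
    if (!is.null(x) && (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)) {
      stop("`", nm, "` must be a single finite non-negative number", call. = FALSE)
    }
  }
  chk_nonneg(N_bar0, "N_bar0"); chk_nonneg(Phi_bar0, "Phi_bar0")
  chk_nonneg(d0, "d0"); chk_nonneg(N0, "N0"); chk_nonneg(Phi0, "Phi0")
  if (!is.null(t0) && (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0) || t0 <= 0)) {
    stop("`t0` must be a single positive time (days)", call. = FALSE)
  }
  p <- structure(list(N_bar0 = N_bar0, Phi_bar0 = Phi_bar0, d0 = d0,
                      N0 = N0, Phi0 = Phi0, t0 = t0),
                 class = "pscd_params")
  # cross-check consistency when both parameterizations are present
  rel <- function(x, y) abs(x - y) / max(abs(x), abs(y), .Machine$double.eps)
  if (!is.null(N_bar0) && !is.null(N0) && !is.null(t0) &&
      rel(N_bar0, N0 / t0^2) > 1e-9) {
    stop("inconsistent parameters: N_bar0 != N0 / t0^2", call. = FALSE)
  }
  if (!is.null(Phi_bar0) && !is.null(Phi0) && !is.null(t0) &&
      rel(Phi_bar0, Phi0 * exp(d0 * t0) / t0^2) > 1e-9) {
    stop("inconsistent parameters: Phi_bar0 != Phi0 * exp(d0 t0) / t0^2", call. = FALSE)
  }
  p
}

#' ISCD model parameters
#'
#' @param N_bar0,Phi_bar0 Quadratic-growth amplitudes (`>= 0`).
#' @param k_bar Net rate `k_d - k_f` (per day); only needed for the
#'   general-rate (non-`2/t`) form, may be `NULL`.
#' @return An object of class `iscd_params`.
#' @export
iscd_params <- function(N_bar0, Phi_bar0, k_bar = NULL) {
  for (nm in c("N_bar0", "Phi_bar0")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
      stop("`", nm, "` must be a single finite non-negative number", call. = FALSE)
    }
  }
  structure(list(N_bar0 = N_bar0, Phi_bar0 = Phi_bar0, k_bar = k_bar),
            class = "iscd_params")
}

#' Convert PSCD parameters between amplitude and initial-time forms
#'
#' Applies `N_bar0 = N0 / t0^2` and `Phi_bar0 = Phi0 * exp(d0 * t0) / t0^2`
#' (or their inverses) to fill in the missing parameterization.  The
#' mapping is a bijection for `t0 > 0`, so a round trip returns the input.
#'
#' @param params A [pscd_params()] object.
#' @param direction `"to_amplitude"` (compute `N_bar0`, `Phi_bar0` from
#'   `N0`, `Phi0`, `t0`) or `"to_initial"` (the inverse).
#' @param t0 Reference time (days) used when `params$t0` is absent;
#'   defaults to 7, the first measurement day of the assay design.
#' @return A `pscd_params` object with both parameterizations populated.
#' @export
convert_params <- function(params, direction = c("to_amplitude", "to_initial"),
                           t0 = NULL) {
  if (!inherits(params, "pscd_params")) {
    stop("`params` must be a `pscd_params` object", call. = FALSE)
  }
  direction <- match.arg(direction)
  t0 <- t0 %||% params$t0 %||% 7
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0) || t0 <= 0) {
    stop("`t0` must be a single positive time (days)", call. = FALSE)
  }
  d0 <- params$d0
  if (direction == "to_amplitude") {
    if (is.null(params$N0) && is.null(params$Phi0)) {
      stop("no initial-time fields (N0, Phi0) to convert", call. = FALSE)
    }
    N_bar0 <- if (!is.null(params$N0)) params$N0 / t0^2 else params$N_bar0
    Phi_bar0 <- if (!is.null(params$Phi0)) params$Phi0 * exp(d0 * t0) / t0^2 else params$Phi_bar0
    pscd_params(N_bar0 = N_bar0, Phi_bar0 = Phi_bar0, d0 = d0,
                N0 = params$N0, Phi0 = params$Phi0, t0 = t0)
  } else {
    if (is.null(params$N_bar0) && is.null(params$Phi_bar0)) {
      stop("no amplitude fields (N_bar0, Phi_bar0) to convert", call. = FALSE)
    }
    N0 <- if (!is.null(params$N_bar0)) params$N_bar0 * t0^2 else params$N0
    Phi0 <- if (!is.null(params$Phi_bar0)) params$Phi_bar0 * t0^2 * exp(-d0 * t0) else params$Phi0
    pscd_params(N_bar0 = params$N_bar0, Phi_bar0 = params$Phi_bar0, d0 = d0,
                N0 = N0, Phi0 = Phi0, t0 = t0)
  }
}

#' Build a model preset from a configuration list or YAML/JSON file
#'
#' Accepts either a named list or a path to a YAML file with fields
#' `model` (`"pscd"` or `"iscd"`) and the corresponding numeric parameter
#' (`d0` or `k_f`).  Custom kernels must be supplied programmatically via
#' [model_spec()].
#'
#' @param config A named list or a file path.
#' @return A [model_spec()].
#' @export
model_from_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$model)) {
    stop("config must contain a `model` field (\"pscd\" or \"iscd\")", call. = FALSE)
  }
  switch(tolower(config$model),
    pscd = {
      if (is.null(config$d0)) stop("pscd config requires `d0`", call. = FALSE)
      pscd_model(as.numeric(config$d0))
    },
    iscd = {
      if (is.null(config$k_f)) stop("iscd config requires `k_f`", call. = FALSE)
      iscd_model(as.numeric(config$k_f))
    },
    stop("unknown model preset: ", config$model,
         " (custom kernels are supplied programmatically)", call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
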