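#' Ensemble of individual cells
#'
#' The state of the event-driven single-cell simulator: a vector of
#' per-cell ALP activities at a common time.  Extinction (an empty
#' ensemble) is a valid state.
#'
#' @param activities Numeric vector of per-cell ALP activities, `>= 0`.
#' @param time Time stamp in days.
#' @return An object of class `cell_ensemble`.
#' @export
cell_ensemble <- function(activities, time = 0) {
  activities <- as.numeric(activities)
  if (any(!is.finite(activities)) || any(activities < 0)) {
    stop("`activities` must be finite and non-negative", call. = FALSE)
  }
  structure(list(activities = activities, time = as.numeric(time)),
            class = "cell_ensemble")
}

#' @export
print.cell_ensemble <- function(x, ...) {
  cat("<cell_ensemble> ", length(x$activities), " cells at t = ", x$time,
      " d; total ALP = ", signif(sum(x$activities), 6), "\n", sep = "")
  invisible(x)
}

# Per-interval deterministic drift da/dt = s_i(a) - d_o(a).  Linear pure
# degradation (s_i == 0, d_o(a) = d0 * a) is detected by probing and
# integrated exactly as a * exp(-d0 * dt); anything else uses fixed Euler
# substeps with clamping at a = 0.
make_drift <- function(model, n_substeps = 20L) {
  a_probe <- c(0.5, 1, 2, 5, 17)
  si_p <- model$synthesis_flux(a_probe)
  do_p <- model$degradation_flux(a_probe)
  if (all(si_p == 0) && all(do_p == 0) &&
      model$synthesis_flux(0) == 0 && model$degradation_flux(0) == 0) {
    return(list(fn = function(a, dt) a, clamped = FALSE))
  }
  ratios <- do_p / a_probe
  if (all(si_p == 0) && model$degradation_flux(0) == 0 &&
      diff(range(ratios)) <= 1e-12 * max(ratios)) {
    d0 <- ratios[1]
    return(list(fn = function(a, dt) a * exp(-d0 * dt), clamped = FALSE))
  }
  list(fn = function(a, dt) {
    h <- dt / n_substeps
    for (i in seq_len(n_substeps)) {
      a <- pmax(a + h * (model$synthesis_flux(a) - model$degradation_flux(a)), 0)
    }
    a
  }, clamped = TRUE)
}

# Per-cell event rates at time t: list(div = ..., f = ...).
agent_rates <- function(model, a, t, n_quad = 33L) {
  g <- model$division_time_factor(t)
  kf <- model$differentiation_rate(a)
  if (model$division_mode == "non_conserved_symmetric") {
    div <- rep(g * model$division_rate, length(a))
  } else {
    # parent of activity a divides at rate g/2 * int_0^a k_d(a - u, u) du
    div <- vapply(a, function(ai) {
      if (ai <= 0) return(0)
      u <- seq(0, ai, length.out = n_quad)
      g * 0.5 * trapz(u, model$division_kernel(ai - u, u))
    }, numeric(1))
  }
  list(div = div, f = kf)
}

#' Event-driven stochastic simulation of single-cell dynamics
#'
#' Exact stochastic simulation of the processes underlying the mean-field
#' balance equation: division events (symmetric copies in
#' `non_conserved_symmetric` mode; a random split of the mother's activity
#' in `conserved` mode, uniform on `[0, a]` by default), instantaneous
#' differentiation removals at rate `k_f(a)`, and deterministic per-cell
#' drift `da/dt = s_i(a) - d_o(a)` between events.  Time-dependent
#' division rates (e.g. `g(t) = 2/t`) are handled by thinning: candidate
#' events are generated from a majorant evaluated at the interval start,
#' which is a valid bound whenever the rates do not increase along the
#' flow (the case for a decreasing `g` and pure degradation drift); a
#' safety factor can be supplied otherwise, and a detected majorant
#' violation is an error, never silent bias.
#'
#' @param model A [model_spec()].
#' @param initial A [cell_ensemble()]; its `time` is the start time and
#'   must precede `t_end` (strictly positive if `g` diverges at 0).
#' @param t_end End time (days).
#' @param seed Integer RNG seed; the same seed reproduces the trajectory
#'   exactly.
#' @param record_times Times (days) at which moments are recorded;
#'   default 8 evenly spaced points from start to `t_end`.
#' @param split_sampler Conserved mode only: function `(a, u)` mapping a
#'   uniform deviate `u` to the activity of one daughter; default uniform
#'   split `a * u` (matched to a constant division kernel).
#' @param bound_factor Multiplier `>= 1` on the thinning majorant, for
#'   models whose rates can increase between events.
#' @return A list with `ensemble` (final [cell_ensemble()]) and `moments`
#'   (a [moment_series()] with `N` = cell count, `Phi` = summed activity
#'   at `record_times`).
#' @export
simulate_agents <- function(model, initial, t_end, seed,
                            record_times = NULL,
                            split_sampler = function(a, u) a * u,
                            bound_factor = 1) {
  if (!inherits(model, "model_spec")) stop("`model` must be a `model_spec`", call. = FALSE)
  if (!inherits(initial, "cell_ensemble")) {
    stop("`initial` must be a `cell_ensemble`", call. = FALSE)
  }
  t0 <- initial$time
  if (t0 >= t_end) stop("`initial$time` must precede `t_end`", call. = FALSE)
  if (!is.finite(model$division_time_factor(t0))) {
    stop("division time factor singular at the start time", call. = FALSE)
  }
  if (bound_factor < 1) stop("`bound_factor` must be >= 1", call. = FALSE)
  record_times <- sort(record_times %||% seq(t0, t_end, length.out = 8))
  if (any(record_times < t0) || any(record_times > t_end)) {
    stop("`record_times` must lie in [start, t_end]", call. = FALSE)
  }
  set.seed(as.integer(seed))
  drift <- make_drift(model)

  a <- initial$activities
  t <- t0
  rec_N <- rec_Phi <- numeric(length(record_times))
  rec_i <- 1L
  record_upto <- function(limit) {
    while (rec_i <= length(record_times) && record_times[rec_i] <= limit) {
      ar <- drift$fn(a, record_times[rec_i] - t)
      rec_N[rec_i] <<- length(ar)
      rec_Phi[rec_i] <<- sum(ar)
      rec_i <<- rec_i + 1L
    }
  }

  repeat {
    rates <- agent_rates(model, a, t)
    R_true <- sum(rates$div) + sum(rates$f)
    R_bound <- bound_factor * R_true
    if (length(a) == 0L || R_bound <= 0) {
      # no further events possible beyond drift; record the remainder
      record_upto(t_end)
      a <- drift$fn(a, t_end - t); t <- t_end
      break
    }
    t_cand <- t + stats::rexp(1L, rate = R_bound)
    record_upto(min(t_cand, t_end))
    if (t_cand >= t_end) {
      a <- drift$fn(a, t_end - t); t <- t_end
      break
    }
    a <- drift$fn(a, t_cand - t)
    t <- t_cand
    rates_c <- agent_rates(model, a, t)
    R_c <- sum(rates_c$div) + sum(rates_c$f)
    if (R_c > R_bound * (1 + 1e-9)) {
      stop("thinning majorant violated: event rates increased between events; ",
           "supply a larger `bound_factor`", call. = FALSE)
    }
    if (stats::runif(1L) < R_c / R_bound) {
      w <- c(rates_c$div, rates_c$f)
      idx <- sample.int(2L * length(a), 1L, prob = w)
      if (idx <= length(a)) {
        if (model$division_mode == "non_conserved_symmetric") {
          a <- c(a, a[idx])                          # symmetric copy
        } else {
          s <- split_sampler(a[idx], stats::runif(1L))
          a <- c(a[-idx], a[idx] - s, s)             # conserving split
        }
      } else {
        a <- a[-(idx - length(a))]                   # differentiation removal
      }
    }
  }

  list(ensemble = cell_ensemble(a, t_end),
       moments = moment_series(record_times, rec_N, pmax(rec_Phi, 0)))
}

#' Run replicate agent simulations
#'
#' Convenience runner: replicate `r` uses seed `seed + r` and a freshly
#' drawn initial ensemble from `initial_fn` (or the fixed `initial`).
#'
#' @param model A [model_spec()].
#' @param initial A fixed [cell_ensemble()], or `NULL` if `initial_fn`
#'   given.
#' @param initial_fn Optional function of the replicate seed returning a
#'   [cell_ensemble()]; called after the replicate seed is set.
#' @param t_end,record_times,split_sampler,bound_factor Passed to
#'   [simulate_agents()].
#' @param n_replicates Number of replicates, `>= 2`.
#' @param seed Base integer seed.
#' @return List of [moment_series()], one per replicate.
#' @export
simulate_agent_replicates <- function(model, initial = NULL, t_end, seed,
                                      n_replicates, record_times = NULL,
                                      initial_fn = NULL,
                                      split_sampler = function(a, u) a * u,
                                      bound_factor = 1) {
  if (is.null(initial) && is.null(initial_fn)) {
    stop("supply `initial` or `initial_fn`", call. = FALSE)
  }
  lapply(seq_len(n_replicates), function(r) {
    if (!is.null(initial_fn)) {
      set.seed(as.integer(seed) + r)
      init <- initial_fn(as.integer(seed) + r)
    } else {
      init <- initial
    }
    simulate_agents(model, init, t_end, seed = as.integer(seed) + r,
                    record_times = record_times,
                    split_sampler = split_sampler,
                    bound_factor = bound_factor)$moments
  })
}

#' Pointwise mean and standard error over replicate moment series
#'
#' @param replicates List of at least two [moment_series()] on a common
#'   time grid.
#' @return A data frame with columns `time`, `N_mean`, `N_se`, `Phi_mean`,
#'   `Phi_se` (SE = sample SD / sqrt(R)).
#' @export
ensemble_moments <- function(replicates) {
  if (!is.list(replicates) || length(replicates) < 2L) {
    stop("need at least 2 replicate moment series", call. = FALSE)
  }
  times <- replicates[[1]]$time
  for (r in replicates) {
    if (length(r$time) != length(times) || any(abs(r$time - times) > 1e-9)) {
      stop("replicate moment series are not on a common time grid", call. = FALSE)
    }
  }
  R <- length(replicates)
  Nm <- vapply(replicates, function(r) r$N, numeric(length(times)))
  Pm <- vapply(replicates, function(r) r$Phi, numeric(length(times)))
  Nm <- matrix(Nm, nrow = length(times)); Pm <- matrix(Pm, nrow = length(times))
  data.frame(
    time = times,
    N_mean = rowMeans(Nm),
    N_se = apply(Nm, 1, stats::sd) / sqrt(R),
    Phi_mean = rowMeans(Pm),
    Phi_se = apply(Pm, 1, stats::sd) / sqrt(R)
  )
}
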