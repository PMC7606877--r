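#' Discretized ALP-activity distribution
#'
#' Represents the cell density `n(a)` over per-cell ALP activity `a` on a
#' strictly increasing grid at a single time.  `density[i]` has units of
#' cells per activity unit, so the zeroth and first moments (total cell
#' number `N` and total ALP activity `Phi`) are integrals over the grid.
#'
#' @param grid Strictly increasing numeric vector of activities, `a >= 0`,
#'   length `>= 3`.
#' @param density Non-negative numeric vector, same length as `grid`.
#'   Values in `[-1e-12, 0)` are treated as numerical noise and clipped
#'   to zero; anything more negative is an error.
#' @param time Time stamp in days.
#' @return An object of class `alp_distribution`.
#' @export
alp_distribution <- function(grid, density, time = 0) {
  grid <- as.numeric(grid); density <- as.numeric(density)
  if (length(grid) < 3L || length(grid) != length(density)) {
    stop("`grid` and `density` must have equal length >= 3", call. = FALSE)
  }
  if (any(!is.finite(grid)) || any(diff(grid) <= 0) || grid[1] < 0) {
    stop("`grid` must be finite, non-negative and strictly increasing", call. = FALSE)
  }
  if (any(is.na(density)) || any(!is.finite(density))) {
    stop("`density` contains non-finite values", call. = FALSE)
  }
  if (any(density < -1e-12)) {
    stop("`density` has entries below -1e-12; not a valid (noisy) non-negative density",
         call. = FALSE)
  }
  density[density < 0] <- 0
  structure(list(grid = grid, density = density, time = as.numeric(time)),
            class = "alp_distribution")
}

#' @export
print.alp_distribution <- function(x, ...) {
  m <- compute_moments(x)
  cat("<alp_distribution> t = ", x$time, " d, ", length(x$grid),
      " grid points on [", x$grid[1], ", ", x$grid[length(x$grid)], "]\n",
      "  N = ", signif(m[["N"]], 6), " cells, Phi = ", signif(m[["Phi"]], 6),
      " activity units\n", sep = "")
  invisible(x)
}

#' Time series of population moments
#'
#' A data frame with columns `time` (days), `N` (total cells) and `Phi`
#' (total ALP activity) carrying class `moment_series`.
#'
#' @param times,N,Phi Equal-length numeric vectors, finite and `>= 0`.
#' @return A `moment_series` data frame.
#' @export
moment_series <- function(times, N, Phi) {
  if (length(times) != length(N) || length(times) != length(Phi)) {
    stop("`times`, `N` and `Phi` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(c(times, N, Phi))) || any(N < 0) || any(Phi < 0)) {
    stop("moment series entries must be finite and non-negative", call. = FALSE)
  }
  structure(data.frame(time = times, N = N, Phi = Phi),
            class = c("moment_series", "data.frame"))
}

#' Zeroth and first moments of an ALP distribution
#'
#' `N = integral of n(a) da` and `Phi = integral of a * n(a) da`,
#' evaluated by the trapezoid rule on the distribution's grid.
#'
#' @param dist An [alp_distribution()].
#' @return Named numeric vector `c(N = ..., Phi = ...)`, both `>= 0`.
#' @export
compute_moments <- function(dist) {
  if (!inherits(dist, "alp_distribution")) {
    stop("`dist` must be an `alp_distribution`", call. = FALSE)
  }
  if (any(is.na(dist$density))) stop("NaN in density", call. = FALSE)
  c(N = trapz(dist$grid, dist$density),
    Phi = trapz(dist$grid, dist$grid * dist$density))
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2

#' Gamma-shaped initial ALP distribution
#'
#' Convenience constructor for demonstrations and solver runs: a gamma
#' density (default shape 2, scale 1) over activity, scaled so the zeroth
#' moment equals `N0`, on a uniform grid `[0, a_max]`.  By default `a_max`
#' is 10 times the gamma's 99th percentile, leaving ample headroom so that
#' numerical diffusion never reaches the upper boundary.
#'
#' @param N0 Total cell number (zeroth moment).
#' @param time Time stamp (days).
#' @param shape,scale Gamma parameters of the activity profile.
#' @param n_grid Number of grid points.
#' @param a_max Upper grid limit; default `10 * qgamma(0.99, shape, scale)`.
#' @return An [alp_distribution()].
#' @export
gamma_initial_distribution <- function(N0, time = 7, shape = 2, scale = 1,
                                       n_grid = 400, a_max = NULL) {
  a_max <- a_max %||% (10 * stats::qgamma(0.99, shape = shape, scale = scale))
  grid <- seq(0, a_max, length.out = n_grid)
  dens <- stats::dgamma(grid, shape = shape, scale = scale)
  dens <- dens * N0 / trapz(grid, dens)
  alp_distribution(grid, dens, time)
}

# Right-hand side of the population-balance equation on a uniform grid.
# `aux` carries precomputed grid quantities; returns list(dn, outflow_a0,
# outflow_amax) where outflows are cell-number fluxes (cells/day).
balance_rhs <- function(n, t, model, aux) {
  g <- model$division_time_factor(t)
  dn <- numeric(aux$G)

  if (model$division_mode == "non_conserved_symmetric") {
    # delta kernel handled analytically: local gain g(t) * k * n
    dn <- dn + g * model$division_rate * n
  } else {
    npad <- c(n, numeric(aux$G - 1L))
    H <- matrix(npad[aux$hankel_idx], aux$G, aux$G)
    gain <- aux$da * rowSums(aux$K * H)
    loss <- 0.5 * aux$da * aux$Kdiag_sum * n
    dn <- dn + g * (gain - loss)
  }

  # differentiation loss
  dn <- dn - aux$kf * n

  out0 <- 0; outmax <- 0
  # synthesis: rightward advection, conservative upwind, zero inflow at a=0
  if (aux$has_si) {
    Fr <- aux$si * n                       # flux through the interface above i
    dn <- dn - (Fr - c(0, Fr[-aux$G])) / aux$da
    outmax <- Fr[aux$G]                    # leaves through a = a_max
  }
  # degradation: leftward advection, conservative upwind, zero inflow at a_max.
  # The bottom node is a half-width finite-volume cell (the trapezoid rule
  # gives a = 0 half weight), so the scheme conserves the trapezoid zeroth
  # moment exactly as density accumulates near a = 0.
  if (aux$has_do) {
    Fl <- aux$do_ * n                      # flux through the interface below i
    upd <- (c(Fl[-1], 0) - Fl) / aux$da
    upd[1] <- 2 * upd[1]
    dn <- dn + upd
    out0 <- Fl[1]                          # leaves through a = 0 iff d_o(0) > 0
  }
  list(dn = dn, outflow_a0 = out0, outflow_amax = outmax)
}

#' Numerically integrate the population-balance equation
#'
#' Marches the full balance equation for `n(a, t)` forward in time on the
#' initial distribution's (uniform) activity grid with fixed explicit
#' steps.  Conserved division is evaluated by direct quadrature of the
#' gain/loss integrals (O(G^2) per step, with the discretization chosen so
#' that total ALP activity is conserved exactly by the division terms);
#' symmetric non-conserved division uses the analytic local gain
#' `g(t) * k * n`; synthesis and degradation enter as conservative
#' first-order upwind advection; differentiation as local loss
#' `k_f(a) * n`.
#'
#' The step size must satisfy the advection CFL condition
#' `dt <= da / max(s_i(a) + d_o(a))`; the solver refuses to run otherwise
#' and names the maximum stable step.  Cells advected through `a = 0`
#' (possible only when `d_o(0) > 0`) or through `a = a_max` are removed
#' from the population; the cumulative loss is returned so that it never
#' disappears silently.
#'
#' @param model A [model_spec()].
#' @param initial An [alp_distribution()] on a uniform grid; its `time` is
#'   overridden by `t_start`.
#' @param t_start,t_end Integration window (days); `t_start > 0` is
#'   required when the division time factor diverges at 0 (it is checked
#'   by evaluation).
#' @param n_steps Number of fixed time steps, `>= 1`.
#' @param scheme `"euler"` (first order, default) or `"heun"`
#'   (second-order predictor-corrector).
#' @param n_snapshots How many distribution snapshots to keep (evenly
#'   spaced in step index, always including start and end).
#' @return A list with elements `snapshots` (list of
#'   [alp_distribution()]), `moments` (a [moment_series()] recorded at
#'   every step), and `boundary_loss` (named vector: cells lost through
#'   `a = 0` and `a = a_max` over the run).
#' @export
solve_population_balance <- function(model, initial, t_start, t_end, n_steps,
                                     scheme = c("euler", "heun"),
                                     n_snapshots = 5) {
  scheme <- match.arg(scheme)
  if (!inherits(model, "model_spec")) stop("`model` must be a `model_spec`", call. = FALSE)
  if (!inherits(initial, "alp_distribution")) {
    stop("`initial` must be an `alp_distribution`", call. = FALSE)
  }
  if (n_steps < 1) stop("`n_steps` must be >= 1", call. = FALSE)
  if (t_end <= t_start) stop("`t_end` must exceed `t_start`", call. = FALSE)
  g0 <- model$division_time_factor(t_start)
  if (!is.finite(g0)) {
    stop("division time factor is singular at t_start = ", t_start,
         "; start at a strictly positive time", call. = FALSE)
  }

  grid <- initial$grid
  da <- diff(grid)
  if (diff(range(da)) > 1e-9 * mean(da)) {
    stop("solver requires a uniform activity grid", call. = FALSE)
  }
  da <- mean(da)
  G <- length(grid)
  dt <- (t_end - t_start) / n_steps

  aux <- list(G = G, da = da,
              kf = model$differentiation_rate(grid),
              si = model$synthesis_flux(grid),
              do_ = model$degradation_flux(grid))
  aux$has_si <- any(aux$si > 0)
  aux$has_do <- any(aux$do_ > 0)
  if (any(aux$kf < 0) || any(aux$si < 0) || any(aux$do_ < 0)) {
    stop("negative rates on the activity grid", call. = FALSE)
  }

  # CFL guard for the upwind advection terms (the half-width bottom cell
  # doubles the effective speed of any outflow through a = 0)
  vmax <- max(aux$si + aux$do_, 2 * aux$do_[1])
  if (vmax > 0 && dt > da / vmax) {
    stop(sprintf(
      "CFL violation: dt = %.4g exceeds the maximum stable step da/vmax = %.4g; increase n_steps to >= %d",
      dt, da / vmax, ceiling((t_end - t_start) * vmax / da)), call. = FALSE)
  }

  if (model$division_mode == "conserved") {
    K <- outer(grid, grid, model$division_kernel)
    if (any(!is.finite(K)) || any(K < 0)) {
      stop("division kernel must be finite and non-negative on the grid", call. = FALSE)
    }
    aux$K <- K
    # antidiagonal sums S_m = sum_{i+j=m+1} K[i,j]: discrete counterpart of
    # the parent-division rate integral; pairs with the gain sum so that the
    # division terms conserve Phi exactly on the uniform grid
    aux$Kdiag_sum <- vapply(seq_len(G), function(m) {
      i <- seq_len(m); sum(K[cbind(i, m - i + 1L)])
    }, numeric(1))
    aux$hankel_idx <- outer(seq_len(G), seq_len(G), `+`) - 1L
  }

  n <- initial$density
  times <- t_start + dt * (0:n_steps)
  Ns <- Phis <- numeric(n_steps + 1L)
  m0 <- compute_moments(alp_distribution(grid, n, t_start))
  Ns[1] <- m0[["N"]]; Phis[1] <- m0[["Phi"]]

  snap_at <- unique(round(seq(1, n_steps + 1L, length.out = max(2, n_snapshots))))
  snapshots <- vector("list", length(snap_at))
  names(snapshots) <- paste0("t", signif(times[snap_at], 6))
  snapshots[[1]] <- alp_distribution(grid, n, t_start)
  loss0 <- lossmax <- 0

  for (s in seq_len(n_steps)) {
    t <- times[s]
    r1 <- balance_rhs(n, t, model, aux)
    if (scheme == "euler") {
      n_new <- n + dt * r1$dn
      loss0 <- loss0 + dt * r1$outflow_a0
      lossmax <- lossmax + dt * r1$outflow_amax
    } else {
      pred <- pmax(n + dt * r1$dn, 0)
      r2 <- balance_rhs(pred, t + dt, model, aux)
      n_new <- n + dt / 2 * (r1$dn + r2$dn)
      loss0 <- loss0 + dt / 2 * (r1$outflow_a0 + r2$outflow_a0)
      lossmax <- lossmax + dt / 2 * (r1$outflow_amax + r2$outflow_amax)
    }
    if (any(is.na(n_new))) stop("NaN produced at t = ", t + dt, call. = FALSE)
    n_new[n_new < 0] <- 0
    n <- n_new
    m <- c(trapz(grid, n), trapz(grid, grid * n))
    Ns[s + 1L] <- m[1]; Phis[s + 1L] <- m[2]
    k <- match(s + 1L, snap_at)
    if (!is.na(k)) snapshots[[k]] <- alp_distribution(grid, n, times[s + 1L])
  }

  list(snapshots = snapshots,
       moments = moment_series(times, Ns, Phis),
       boundary_loss = c(a0 = loss0, a_max = lossmax))
}

#' Instantaneous moment rates implied by the balance equation
#'
#' Evaluates the right-hand sides of the moment balance relations for `N`
#' and `Phi` on a single distribution snapshot.  For conserved division
#' the division contribution to `dN/dt` is the double quadrature
#' `1/2 * int int k_d(a, a') n(a + a') da da'` (and zero for `dPhi/dt`,
#' since those divisions conserve total ALP activity); for symmetric
#' non-conserved division the reduced forms `dN/dt = g k N - int k_f n da`
#' and `dPhi/dt = g k Phi + int (s_i - d_o) n da - int a k_f n da` are
#' used.  Single integrals use the trapezoid rule, matching
#' [compute_moments()].
#'
#' @param model A [model_spec()].
#' @param dist An [alp_distribution()] (uniform grid required in conserved
#'   mode).
#' @return Named numeric vector `c(dN_dt = ..., dPhi_dt = ...)`.
#' @export
moment_rates <- function(model, dist) {
  if (!inherits(model, "model_spec")) stop("`model` must be a `model_spec`", call. = FALSE)
  if (!inherits(dist, "alp_distribution")) {
    stop("`dist` must be an `alp_distribution`", call. = FALSE)
  }
  grid <- dist$grid; n <- dist$density; t <- dist$time
  if (any(is.na(n))) stop("NaN in density", call. = FALSE)
  g <- model$division_time_factor(t)
  kf <- model$differentiation_rate(grid)
  si <- model$synthesis_flux(grid)
  do_ <- model$degradation_flux(grid)
  m <- compute_moments(dist)

  kf_loss_N <- trapz(grid, kf * n)
  kf_loss_Phi <- trapz(grid, grid * kf * n)
  flux_Phi <- trapz(grid, (si - do_) * n)

  if (model$division_mode == "non_conserved_symmetric") {
    dN <- g * model$division_rate * m[["N"]] - kf_loss_N
    dPhi <- g * model$division_rate * m[["Phi"]] + flux_Phi - kf_loss_Phi
  } else {
    da <- diff(grid)
    if (diff(range(da)) > 1e-9 * mean(da)) {
      stop("conserved-mode moment rates require a uniform grid", call. = FALSE)
    }
    da <- mean(da); G <- length(grid)
    K <- outer(grid, grid, model$division_kernel)
    npad <- c(n, numeric(G - 1L))
    H <- matrix(npad[outer(seq_len(G), seq_len(G), `+`) - 1L], G, G)
    dN_div <- 0.5 * da^2 * sum(K * H)
    dN <- g * dN_div - kf_loss_N
    dPhi <- flux_Phi - kf_loss_Phi          # conserved divisions leave Phi unchanged
  }
  out <- c(dN_dt = unname(dN), dPhi_dt = unname(dPhi))
  if (any(is.na(out))) stop("NaN in moment rates", call. = FALSE)
  out
}

#' Write distribution snapshots to CSV
#'
#' Long format with columns `time`, `a`, `n`.
#'
#' @param snapshots List of [alp_distribution()] (as returned by
#'   [solve_population_balance()]).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_snapshots_csv <- function(snapshots, path) {
  df <- do.call(rbind, lapply(snapshots, function(d) {
    data.frame(time = d$time, a = d$grid, n = d$density)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a moment series to CSV
#'
#' Columns `time`, `N`, `Phi`.
#'
#' @param ms A [moment_series()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_moment_series_csv <- function(ms, path) {
  utils::write.csv(as.data.frame(ms), path, row.names = FALSE)
  invisible(path)
}
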