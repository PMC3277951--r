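#' Convert concentrations to molecule counts
#'
#' @param state Nonnegative concentration vector.
#' @param omega System-size factor (molecules per concentration unit).
#' @return Integer vector `round(omega * state)`.
#' @export
concentration_to_counts <- function(state, omega) {
  stopifnot(omega > 0, all(state >= 0))
  as.integer(round(omega * state))
}

# marshal network description into the C++ SSA core arguments.
# Stochastic rate constant convention: a deterministic mass-action rate
# k * prod(conc_i^m_i) maps to propensity
#   k * omega^(1 - order) * prod(falling(n_i, m_i) / m_i!) ,
# with order = sum(m_i); the inverse-linear feedback factor is evaluated at
# the concentration n/omega.
ssa_args <- function(net, params, u_tot, omega) {
  nr <- length(net$reactions)
  cvec <- numeric(nr)
  fidx <- fmul <- ffac <- vector("list", nr)
  fb_on <- integer(nr); fb_kappa <- numeric(nr)
  for (j in seq_len(nr)) {
    fc <- net$factors[[j]]
    ord <- sum(fc$mult)
    cvec[j] <- params[[net$reactions[[j]]$rate]] * omega ^ (1 - ord)
    fidx[[j]] <- as.integer(fc$idx)        # 0 = free conserved species
    fmul[[j]] <- as.integer(fc$mult)
    ffac[[j]] <- 1 / prod(factorial(fc$mult))
    f <- net$fb[[j]]
    if (!is.null(f)) {
      fb_on[j] <- f$on
      fb_kappa[j] <- params[[f$constant]]
    }
  }
  list(stoich = matrix(as.integer(net$stoich), nrow(net$stoich)),
       cvec = cvec, fidx = fidx, fmul = fmul, ffac = ffac,
       fb_on = fb_on, fb_kappa = fb_kappa,
       utot_count = round(omega * u_tot),
       bound_idx = if (is.na(net$bound_idx)) 0L else net$bound_idx)
}

#' Gillespie stochastic simulation of the network
#'
#' Direct-method SSA in molecule counts.  Bimolecular rate constants are
#' rescaled by the system size `omega`; the inverse-linear feedback factor
#' is evaluated at the output concentration `count / omega`.  The free
#' conserved species is `round(omega * u_tot) - bound`, so the total enzyme
#' count is conserved exactly.
#'
#' @inheritParams evaluate_rhs
#' @param x0_counts Integer initial molecule counts (state order).
#' @param t_end Final time.
#' @param omega System size (molecules per concentration unit).
#' @param seed Integer seed for the self-contained RNG stream.
#' @param max_events Safety cap on the number of reaction events.
#' @return A `trajectory` (class also `ssa_trajectory`) with the jump times
#'   and the piecewise-constant states (in counts) at each event.
#' @export
ssa_simulate <- function(net, params, u_tot, x0_counts, t_end, omega, seed,
                         max_events = 5e7) {
  stopifnot(all(x0_counts >= 0), all(x0_counts == round(x0_counts)))
  a <- ssa_args(net, params, u_tot, omega)
  res <- .ssa_run_cpp(as.integer(x0_counts), a$stoich, a$cvec, a$fidx,
                      a$fmul, a$ffac, a$fb_on, a$fb_kappa, omega,
                      a$utot_count, a$bound_idx, t_end, numeric(0),
                      TRUE, seed, max_events)
  states <- res$event_states
  colnames(states) <- net$species
  structure(list(times = res$event_times, states = states,
                 input_level = u_tot, omega = omega, seed = seed),
            class = c("ssa_trajectory", "trajectory"))
}

# single SSA run sampled on a regular grid (counts); used by ensembles
ssa_grid_run <- function(net, params, u_tot, x0_counts, grid, omega, seed,
                         max_events = 5e7) {
  a <- ssa_args(net, params, u_tot, omega)
  res <- .ssa_run_cpp(as.integer(x0_counts), a$stoich, a$cvec, a$fidx,
                      a$fmul, a$ffac, a$fb_on, a$fb_kappa, omega,
                      a$utot_count, a$bound_idx, max(grid), grid,
                      FALSE, seed, max_events)
  colnames(res$grid_states) <- net$species
  res$grid_states
}

#' Run an SSA ensemble and collect output statistics
#'
#' Generates `n_runs` stochastic trajectories (per-run seeds spawned
#' deterministically from the single global seed), samples the output
#' species on a regular time grid by last-value interpolation, and returns
#' per-grid-point mean and sample standard deviation in concentration units.
#'
#' @inheritParams ssa_simulate
#' @param x0 Initial state in concentration units (converted with
#'   [concentration_to_counts()]).
#' @param n_runs Number of trajectories.
#' @param n_grid Number of regular grid time points.
#' @return A `stochastic_ensemble`: list with `grid_times`, `mean`, `sd`
#'   (concentration units), `n_runs`, `omega`, `seed`.
#' @export
ssa_ensemble <- function(net, params, u_tot, x0, t_end, omega, seed,
                         n_runs = 100, n_grid = 100) {
  grid <- seq(t_end / n_grid, t_end, length.out = n_grid)
  x0c <- concentration_to_counts(x0, omega)
  y <- matrix(0, n_runs, n_grid)
  for (r in seq_len(n_runs)) {
    st <- ssa_grid_run(net, params, u_tot, x0c, grid, omega,
                       seed = seed * 1e4 + r)
    y[r, ] <- st[, net$output_idx]
  }
  structure(list(grid_times = grid, mean = colMeans(y) / omega,
                 sd = apply(y, 2, sd) / omega,
                 n_runs = n_runs, omega = omega, seed = seed),
            class = "stochastic_ensemble")
}

#' Ensemble statistics from a list of jump trajectories
#'
#' Interpolates each count trajectory onto a regular grid
#' (last-value-carried-forward) and computes the per-grid-point mean and
#' sample standard deviation of the output species in concentration units.
#'
#' @param runs List of `ssa_trajectory` objects (from [ssa_simulate()]).
#' @param omega System size used for the runs.
#' @param grid_times Regular grid of evaluation times.
#' @param output_idx Column index of the output species.
#' @return A `stochastic_ensemble` (see [ssa_ensemble()]).
#' @export
ensemble_statistics <- function(runs, omega, grid_times, output_idx = NULL) {
  if (length(runs) < 2) stop("need at least 2 runs for ensemble statistics")
  y <- t(vapply(runs, function(tr) {
    oi <- output_idx %||% ncol(tr$states)
    idx <- findInterval(grid_times, tr$times)
    if (any(idx == 0)) stop("run does not cover the grid span")
    tr$states[idx, oi]
  }, numeric(length(grid_times))))
  structure(list(grid_times = grid_times, mean = colMeans(y) / omega,
                 sd = apply(y, 2, sd) / omega,
                 n_runs = length(runs), omega = omega,
                 seed = runs[[1]]$seed),
            class = "stochastic_ensemble")
}

#' Build a performance envelope from ensemble statistics
#'
#' The healthy performance band is centered on the steady-state output with
#' half-width `f * s_mean`, where `s_mean` is the time-averaged standard
#' deviation of the stochastic ensemble:
#' `y_lb = y_ss - f * s_mean`, `y_ub = y_ss + f * s_mean`.
#'
#' @param y_ss Steady-state output concentration the envelope is centered on.
#' @param ensemble A `stochastic_ensemble`.
#' @param f Envelope width factor (dimensionless, default 1.6).
#' @return A `performance_envelope`: list with `y_ss`, `s_mean`, `f`,
#'   `y_lb`, `y_ub`, `omega`, `n_runs`, `seed`.
#' @export
build_performance_envelope <- function(y_ss, ensemble, f = 1.6) {
  stopifnot(f > 0)
  y_ss <- unname(y_ss)
  s_mean <- mean(ensemble$sd)
  if (s_mean == 0)
    warning("degenerate envelope: s_mean = 0 (nominal screen collapses to equality)")
  structure(list(y_ss = y_ss, s_mean = s_mean, f = f,
                 y_lb = y_ss - f * s_mean, y_ub = y_ss + f * s_mean,
                 omega = ensemble$omega, n_runs = ensemble$n_runs,
                 seed = ensemble$seed),
            class = "performance_envelope")
}

#' @export
print.performance_envelope <- function(x, ...) {
  cat(sprintf("Performance envelope: y_ss = %.6g, s_mean = %.4g, f = %.3g\n",
              x$y_ss, x$s_mean, x$f))
  cat(sprintf("  bounds [%.6g, %.6g]  (omega = %g, %d runs, seed %g)\n",
              x$y_lb, x$y_ub, x$omega, x$n_runs, x$seed))
  invisible(x)
}

#' Export ensemble statistics to CSV (`time,mean,sd`)
#' @param ensemble A `stochastic_ensemble`.
#' @param path Output file.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  write.csv(data.frame(time = ensemble$grid_times, mean = ensemble$mean,
                       sd = ensemble$sd),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a performance envelope to JSON
#' @param envelope A `performance_envelope`.
#' @param path Output file.
#' @export
write_envelope_json <- function(envelope, path) {
  jsonlite::write_json(unclass(envelope), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
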