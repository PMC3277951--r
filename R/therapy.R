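#' Enumerate candidate therapy target sets
#'
#' All subsets of the non-excluded parameters of size `1..max_size`, ordered
#' deterministically by size and then lexicographically by parameter
#' position.  For the bundled case study the zeroth-order production
#' constant is excluded (it does not appear in the linearized model used by
#' the robustness screen), leaving six targetable parameters and 56 subsets
#' of size up to four.
#'
#' @param param_names Character vector of parameter names.
#' @param max_size Largest subset size.
#' @param excluded Parameters removed from the candidate pool.
#' @return List of character vectors (the target sets).
#' @export
enumerate_therapy_targets <- function(param_names, max_size = 4,
                                      excluded = character()) {
  pool <- setdiff(param_names, excluded)
  if (length(pool) == 0) stop("empty candidate pool after exclusions")
  if (max_size > length(pool))
    stop("max_size exceeds the number of candidate parameters")
  out <- list()
  for (s in seq_len(max_size))
    out <- c(out, combn(pool, s, simplify = FALSE))
  out
}

#' Least-squares therapy fitting cost
#'
#' Sum of squared deviations between the therapy output and the healthy
#' reference output at matched sample times:
#' `C = sum_i (y_dt(t_i) - y_h(t_i))^2`.
#'
#' @param y_dt Therapy output samples.
#' @param y_h Healthy output samples (same times).
#' @return The cost `C`.
#' @export
therapy_cost <- function(y_dt, y_h) {
  if (length(y_dt) != length(y_h)) stop("sample length mismatch")
  sum((y_dt - y_h)^2)
}

# regular cost-evaluation times: n points over (0, horizon]
cost_time_points <- function(horizon, n_points = 20) {
  seq(horizon / n_points, horizon, length.out = n_points)
}

# simulate the output at the cost time points; large penalty on failure
therapy_output <- function(net, params, u_tot, x0, t_points) {
  tr <- tryCatch(simulate_ode(net, params, u_tot, x0, c(0, t_points)),
                 error = function(e) NULL)
  if (is.null(tr)) return(NULL)
  tr$states[-1, net$output_idx]
}

#' Fit a therapy to the healthy output
#'
#' A therapy re-parameterizes the diseased-input model on a chosen subset of
#' rate parameters.  The targeted parameters are fitted by bounded
#' least squares (each within 0..2 times its nominal value, i.e. changes of
#' up to +/-100%) so that the model output under the diseased input,
#' started from the diseased steady state, tracks the healthy reference
#' output at `n_points` regularly spaced times.  A local quasi-Newton
#' optimizer is run from the nominal point plus seeded random restarts.
#'
#' @param net A [reaction_network()].
#' @param target_set Character vector of targeted parameter names.
#' @param nominal Named vector of nominal parameter values.
#' @param u_tot_d Diseased input level.
#' @param y_h_ref Healthy reference output: scalar (constant steady state)
#'   or vector of length `n_points`.
#' @param x0 Initial condition for the fitting simulations (the diseased
#'   steady state; computed from the nominal model when `NULL`).
#' @param horizon Simulated time span.
#' @param n_points Number of cost evaluation times.
#' @param n_restarts Seeded random restarts in addition to the nominal start.
#' @param seed Integer seed for the restart draws.
#' @param extra_starts Optional list of additional start vectors (multipliers
#'   of the nominal values, one per target).  The pipeline warm-starts each
#'   target set from the fitted optima of its proper subsets, which makes
#'   fit costs nest monotonically by target set.
#' @return A `therapy` object: list with `target_set`, `fitted_params`
#'   (full parameter vector, non-targets at nominal), `fit_cost`,
#'   `nominal_cost` and `converged`.
#' @export
fit_therapy <- function(net, target_set, nominal = net$parameters,
                        u_tot_d = net$input$diseased, y_h_ref,
                        x0 = NULL, horizon = 50, n_points = 20,
                        n_restarts = 4, seed = 1, extra_starts = NULL) {
  stopifnot(length(target_set) >= 1, all(target_set %in% names(nominal)))
  if (is.null(x0))
    x0 <- find_steady_state(net, nominal, u_tot_d)
  t_points <- cost_time_points(horizon, n_points)
  y_h <- if (length(y_h_ref) == 1) rep(y_h_ref, n_points) else y_h_ref
  stopifnot(length(y_h) == n_points)

  obj <- function(theta) {  # theta = multipliers of the nominal values
    p <- nominal
    p[target_set] <- theta * nominal[target_set]
    y <- therapy_output(net, p, u_tot_d, x0, t_points)
    if (is.null(y)) return(1e10)
    therapy_cost(y, y_h)
  }
  nominal_cost <- obj(rep(1, length(target_set)))

  set.seed(seed)
  starts <- c(list(rep(1, length(target_set))),
              lapply(seq_len(n_restarts),
                     function(i) runif(length(target_set), 0, 2)),
              extra_starts)
  best <- list(value = Inf, par = rep(1, length(target_set)),
               converged = FALSE)
  for (st in starts) {
    v0 <- obj(st)   # the start itself is a feasible point
    if (v0 < best$value) best <- list(value = v0, par = st, converged = TRUE)
    fit <- tryCatch(
      optim(st, obj, method = "L-BFGS-B",
            lower = rep(1e-8, length(target_set)),
            upper = rep(2, length(target_set)),
            control = list(maxit = 100, factr = 1e7)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$value < best$value)
      best <- list(value = fit$value, par = fit$par, converged = TRUE)
  }
  fitted <- nominal
  if (best$converged) {
    fitted[target_set] <- best$par * nominal[target_set]
    fit_cost <- min(best$value, nominal_cost)
    if (nominal_cost < best$value) fitted <- nominal  # nominal point is feasible
  } else {
    fit_cost <- Inf
  }
  structure(list(target_set = target_set, fitted_params = fitted,
                 fit_cost = fit_cost, nominal_cost = nominal_cost,
                 converged = best$converged),
            class = "therapy")
}

#' @export
print.therapy <- function(x, ...) {
  cat("Therapy targeting {", paste(x$target_set, collapse = ", "), "}: ",
      "C = ", format(x$fit_cost, digits = 4), "\n", sep = "")
  chg <- x$fitted_params[x$target_set]
  cat("  fitted values:", paste(x$target_set, signif(chg, 4), sep = "=",
                                collapse = ", "), "\n")
  invisible(x)
}

#' Nominal performance test against the healthy envelope
#'
#' Simulates the fitted therapy under the diseased input from the healthy
#' steady state (note: the fitting itself starts from the diseased steady
#' state) and requires the absolute deviation from the healthy output to
#' stay within the envelope half-width at every test time:
#' `|y_dt(t_i) - y_h(t_i)| <= (y_ub - y_lb) / 2`.
#'
#' @param net A [reaction_network()].
#' @param therapy A fitted `therapy`.
#' @param envelope A `performance_envelope`.
#' @param u_tot_d Diseased input level.
#' @param x0_healthy Healthy steady state (initial condition).
#' @param y_h Healthy reference output: scalar or length-`n_points` vector.
#' @param horizon,n_points Test time span and number of test points.
#' @return Logical pass/fail, with attributes `margin` (half-width minus the
#'   worst deviation) and `max_deviation`.
#' @export
nominal_performance_test <- function(net, therapy, envelope,
                                     u_tot_d = net$input$diseased,
                                     x0_healthy, y_h = envelope$y_ss,
                                     horizon = 50, n_points = 20) {
  t_points <- cost_time_points(horizon, n_points)
  y_ref <- if (length(y_h) == 1) rep(y_h, n_points) else y_h
  y <- therapy_output(net, therapy$fitted_params, u_tot_d, x0_healthy,
                      t_points)
  half <- (envelope$y_ub - envelope$y_lb) / 2
  if (is.null(y)) {
    res <- FALSE
    attr(res, "max_deviation") <- Inf
    attr(res, "margin") <- -Inf
    return(res)
  }
  dev <- max(abs(y - y_ref))
  res <- dev <= half
  attr(res, "max_deviation") <- dev
  attr(res, "margin") <- half - dev
  res
}

#' Export a therapy table to CSV
#'
#' Columns: `id,targets,fitted_values,fit_cost,nominal_pass,mu_rp,robust_pass`.
#'
#' @param therapies Data frame as produced by [run_pipeline()] (component
#'   `therapies`).
#' @param path Output file.
#' @export
write_therapy_csv <- function(therapies, path) {
  write.csv(therapies, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
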