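#' Construct a reaction network
#'
#' A `reaction_network` describes a mass-action ODE model of a small
#' biochemical network with a single constant input (a total enzyme
#' concentration partitioned between a free and a bound form) and a single
#' output species.  One multiplicative feedback factor per reaction is
#' supported (inverse-linear autoinhibition, `1 / (1 + kappa * conc)`).
#'
#' @param species Character vector of tracked species names, in state order.
#' @param parameters Named numeric vector of nominal (positive) rate
#'   parameters.
#' @param reactions List of reactions.  Each reaction is a list with elements
#'   `reactants` and `products` (named integer vectors of stoichiometric
#'   multiplicities; may reference the free conserved species), `rate` (the
#'   name of its rate constant) and optionally
#'   `feedback = list(type = "inverse_linear", on = <species>, constant = <parameter>)`.
#' @param input List with elements `name`, `healthy` and `diseased`: the name
#'   of the constant total-concentration input and its two operating levels.
#' @param output Name of the output species.
#' @param conservation List with elements `free` and `bound`: the free form
#'   is not a state variable but is computed as `input - bound` wherever it
#'   appears in a rate law.
#' @return An object of class `reaction_network`.
#' @export
reaction_network <- function(species, parameters, reactions, input,
                             output = species[length(species)],
                             conservation = NULL) {
  stopifnot(is.character(species), length(species) >= 1,
            !is.null(names(parameters)), all(parameters >= 0),
            is.list(reactions), length(reactions) >= 1,
            is.list(input), !is.null(input$name),
            output %in% species)
  ns <- length(species)
  nr <- length(reactions)
  free_name <- if (!is.null(conservation)) conservation$free else NA_character_
  bound_idx <- if (!is.null(conservation)) match(conservation$bound, species) else NA_integer_
  if (!is.null(conservation) && is.na(bound_idx))
    stop("conservation bound species '", conservation$bound, "' is not a tracked species")

  stoich <- matrix(0, ns, nr, dimnames = list(species, NULL))
  factors <- vector("list", nr)
  fb <- vector("list", nr)
  for (j in seq_len(nr)) {
    rx <- reactions[[j]]
    if (!rx$rate %in% names(parameters))
      stop("unknown rate constant '", rx$rate, "'")
    reac <- rx$reactants
    prod <- rx$products
    for (nm in names(reac)) {
      if (nm %in% species) stoich[nm, j] <- stoich[nm, j] - reac[[nm]]
      else if (!identical(nm, free_name)) stop("unknown reactant '", nm, "'")
    }
    for (nm in names(prod)) {
      if (nm %in% species) stoich[nm, j] <- stoich[nm, j] + prod[[nm]]
      else if (!identical(nm, free_name)) stop("unknown product '", nm, "'")
    }
    # rate-law factors: idx = state index, or 0 for the free conserved species
    if (length(reac)) {
      idx <- ifelse(names(reac) == free_name, 0L, match(names(reac), species))
      factors[[j]] <- list(idx = as.integer(idx), mult = as.numeric(unlist(reac)))
    } else {
      factors[[j]] <- list(idx = integer(0), mult = numeric(0))
    }
    if (!is.null(rx$feedback)) {
      fbk <- rx$feedback
      if (!identical(fbk$type, "inverse_linear"))
        stop("unsupported feedback type '", fbk$type, "'")
      fb[[j]] <- list(on = match(fbk$on, species), constant = fbk$constant)
      if (is.na(fb[[j]]$on)) stop("feedback species '", fbk$on, "' not tracked")
      if (!fbk$constant %in% names(parameters))
        stop("feedback constant '", fbk$constant, "' is not a parameter")
    }
  }
  structure(list(species = species, parameters = parameters,
                 reactions = reactions, input = input, output = output,
                 output_idx = match(output, species),
                 conservation = conservation, bound_idx = bound_idx,
                 stoich = stoich, factors = factors, fb = fb),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Reaction network:", length(x$species), "species,",
      length(x$reactions), "reactions\n")
  cat("  species:   ", paste(x$species, collapse = ", "), "\n")
  cat("  parameters:", paste(names(x$parameters), signif(x$parameters, 4),
                             sep = "=", collapse = ", "), "\n")
  cat("  input:     ", x$input$name, " (healthy ", x$input$healthy,
      ", diseased ", x$input$diseased, ")\n", sep = "")
  cat("  output:    ", x$output, "\n")
  invisible(x)
}

#' Read a reaction-network model file
#'
#' Reads a declarative model definition (JSON, or YAML when the `yaml`
#' package is available) with keys `species`, `parameters`, `reactions`,
#' `input`, and optionally `output` and `conservation`.  The bundled case
#' study (`system.file("extdata", "case_study.model", package = "mudrug")`)
#' describes a negative-feedback enzymatic motif: substrate X is converted to
#' product Y by an enzyme U through a complex UX, Y autoinhibits its own
#' production, and the constant total enzyme concentration u_tot is the
#' input.
#'
#' @param path Path to the model file.
#' @return A [reaction_network()].
#' @export
read_model_file <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  doc <- if (grepl("\\.(ya?ml)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML model files requires the 'yaml' package")
    yaml::yaml.load(txt)
  } else jsonlite::fromJSON(txt, simplifyVector = FALSE)
  pars <- unlist(doc$parameters)
  reactions <- lapply(doc$reactions, function(rx) {
    list(reactants = unlist(rx$reactants) %||% setNames(numeric(0), character(0)),
         products  = unlist(rx$products)  %||% setNames(numeric(0), character(0)),
         rate = rx$rate, feedback = rx$feedback)
  })
  reaction_network(species = unlist(doc$species), parameters = pars,
                   reactions = reactions, input = doc$input,
                   output = doc$output %||% unlist(doc$species)[length(unlist(doc$species))],
                   conservation = doc$conservation)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bundled case-study network
#'
#' Convenience loader for the packaged negative-feedback motif model.
#' @return A [reaction_network()].
#' @export
case_study_network <- function() {
  read_model_file(system.file("extdata", "case_study.model",
                              package = "mudrug", mustWork = TRUE))
}

# per-reaction rates; state in concentration units
reaction_rates <- function(net, state, params, u_tot) {
  u_free <- NA_real_
  if (!is.na(net$bound_idx)) {
    u_free <- u_tot - state[net$bound_idx]
    if (u_free < -1e-9 * max(1, abs(u_tot)))
      stop("bound species exceeds total input (free concentration would be negative)")
    u_free <- max(u_free, 0)
  }
  vapply(seq_along(net$reactions), function(j) {
    r <- params[[net$reactions[[j]]$rate]]
    fc <- net$factors[[j]]
    if (length(fc$idx)) {
      conc <- ifelse(fc$idx == 0L, u_free, state[pmax(fc$idx, 1L)])
      r <- r * prod(conc ^ fc$mult)
    }
    f <- net$fb[[j]]
    if (!is.null(f)) r <- r / (1 + params[[f$constant]] * state[f$on])
    r
  }, numeric(1))
}

#' Evaluate the right-hand side of the network ODE
#'
#' Mass-action time derivatives of the tracked species, with the free
#' conserved species computed as `u = u_tot - bound` and any inverse-linear
#' feedback factor applied to its reaction.
#'
#' @param net A [reaction_network()].
#' @param state Numeric vector of species concentrations (state order).
#' @param params Named numeric vector of parameter values.
#' @param u_tot Input level (total concentration, constant in time).
#' @return Numeric vector `d(state)/dt`.
#' @export
evaluate_rhs <- function(net, state, params, u_tot) {
  state <- as.numeric(state)
  drop(net$stoich %*% reaction_rates(net, state, params, u_tot))
}

# analytic Jacobian d(RHS)/d(state)
jac_state <- function(net, state, params, u_tot) {
  ns <- length(net$species)
  u_free <- if (!is.na(net$bound_idx)) max(u_tot - state[net$bound_idx], 0) else NA_real_
  drates <- matrix(0, length(net$reactions), ns)
  for (j in seq_along(net$reactions)) {
    k <- params[[net$reactions[[j]]$rate]]
    fc <- net$factors[[j]]
    f <- net$fb[[j]]
    conc <- if (length(fc$idx)) ifelse(fc$idx == 0L, u_free, state[pmax(fc$idx, 1L)]) else numeric(0)
    phi <- if (!is.null(f)) 1 / (1 + params[[f$constant]] * state[f$on]) else 1
    prodall <- if (length(conc)) prod(conc ^ fc$mult) else 1
    # product-rule terms for each rate-law factor
    for (m in seq_along(fc$idx)) {
      others <- if (length(conc) > 1) prod(conc[-m] ^ fc$mult[-m]) else 1
      dterm <- k * phi * others * fc$mult[m] * conc[m] ^ (fc$mult[m] - 1)
      tgt <- fc$idx[m]
      if (tgt == 0L) drates[j, net$bound_idx] <- drates[j, net$bound_idx] - dterm
      else drates[j, tgt] <- drates[j, tgt] + dterm
    }
    # feedback-factor term
    if (!is.null(f)) {
      kap <- params[[f$constant]]
      drates[j, f$on] <- drates[j, f$on] - k * prodall * kap * phi^2
    }
  }
  A <- net$stoich %*% drates
  dimnames(A) <- list(net$species, net$species)
  A
}

# analytic d(RHS)/d(u_tot)
jac_input <- function(net, state, params, u_tot) {
  u_free <- if (!is.na(net$bound_idx)) max(u_tot - state[net$bound_idx], 0) else NA_real_
  drates <- numeric(length(net$reactions))
  for (j in seq_along(net$reactions)) {
    fc <- net$factors[[j]]
    m <- which(fc$idx == 0L)
    if (!length(m)) next
    k <- params[[net$reactions[[j]]$rate]]
    f <- net$fb[[j]]
    phi <- if (!is.null(f)) 1 / (1 + params[[f$constant]] * state[f$on]) else 1
    conc <- ifelse(fc$idx == 0L, u_free, state[pmax(fc$idx, 1L)])
    others <- if (length(conc) > 1) prod(conc[-m] ^ fc$mult[-m]) else 1
    drates[j] <- k * phi * others * fc$mult[m] * conc[m] ^ (fc$mult[m] - 1)
  }
  drop(net$stoich %*% drates)
}

# analytic d(RHS)/d(parameter)
drhs_dparam <- function(net, state, params, u_tot, pname) {
  u_free <- if (!is.na(net$bound_idx)) max(u_tot - state[net$bound_idx], 0) else NA_real_
  drates <- numeric(length(net$reactions))
  for (j in seq_along(net$reactions)) {
    fc <- net$factors[[j]]
    f <- net$fb[[j]]
    conc <- if (length(fc$idx)) ifelse(fc$idx == 0L, u_free, state[pmax(fc$idx, 1L)]) else numeric(0)
    prodall <- if (length(conc)) prod(conc ^ fc$mult) else 1
    phi <- if (!is.null(f)) 1 / (1 + params[[f$constant]] * state[f$on]) else 1
    if (identical(net$reactions[[j]]$rate, pname))
      drates[j] <- drates[j] + prodall * phi
    if (!is.null(f) && identical(f$constant, pname)) {
      k <- params[[net$reactions[[j]]$rate]]
      drates[j] <- drates[j] - k * prodall * state[f$on] * phi^2
    }
  }
  drop(net$stoich %*% drates)
}

#' Solve for a steady state of the network
#'
#' Damped Newton iteration on the mass-action right-hand side using the
#' analytic Jacobian, with fall-back re-starts (including a long ODE
#' integration) when the iteration leaves the nonnegative orthant or stalls.
#'
#' @inheritParams evaluate_rhs
#' @param guess Nonnegative starting state.
#' @param tol Convergence tolerance on the infinity norm of the residual.
#' @return Steady-state concentration vector (named).
#' @export
find_steady_state <- function(net, params, u_tot, guess = NULL, tol = 1e-10) {
  ns <- length(net$species)
  if (is.null(guess)) guess <- rep(0.1, ns)
  stopifnot(all(guess >= 0))
  newton <- function(x0) {
    x <- x0
    for (it in 1:200) {
      r <- evaluate_rhs(net, x, params, u_tot)
      if (max(abs(r)) <= tol) return(x)
      J <- jac_state(net, x, params, u_tot)
      step <- tryCatch(solve(J, -r), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      lam <- 1
      repeat {
        xn <- x + lam * step
        ok <- all(is.finite(xn)) && all(xn >= -1e-12) &&
          (is.na(net$bound_idx) || xn[net$bound_idx] <= u_tot + 1e-12)
        if (ok) {
          rn <- tryCatch(evaluate_rhs(net, pmax(xn, 0), params, u_tot),
                         error = function(e) NULL)
          if (!is.null(rn) && max(abs(rn)) < max(abs(r)) * (1 - 0.25 * lam) + tol)
            break
        }
        lam <- lam / 2
        if (lam < 1e-6) return(NULL)
      }
      x <- pmax(xn, 0)
    }
    NULL
  }
  starts <- list(guess)
  # alternative deterministic starts
  base <- pmax(guess, 0.05)
  starts <- c(starts, list(base * 2, base * 0.5, rep(1, ns), rep(0.01, ns)))
  for (s in starts) {
    x <- newton(s)
    if (!is.null(x) && all(x >= 0)) return(setNames(x, net$species))
  }
  # last resort: relax toward the attractor by integration, then polish
  tr <- tryCatch(simulate_ode(net, params, u_tot, pmax(guess, 0.01),
                              times = c(0, 10^(0:4))),
                 error = function(e) NULL)
  if (!is.null(tr)) {
    x <- newton(pmax(tr$states[nrow(tr$states), ], 0))
    if (!is.null(x) && all(x >= 0)) return(setNames(x, net$species))
  }
  r <- evaluate_rhs(net, guess, params, u_tot)
  stop("steady-state solve failed to converge (best residual ",
       format(max(abs(r)), digits = 3), ")")
}

#' Simulate the deterministic ODE model
#'
#' Integrates the network ODE with a stiff solver (`deSolve::lsoda`) using
#' the analytic Jacobian.
#'
#' @inheritParams evaluate_rhs
#' @param x0 Initial state (nonnegative).
#' @param times Nondecreasing output times.
#' @param rtol,atol Relative / absolute solver tolerances.
#' @param compiled Use the compiled right-hand side (default); the pure-R
#'   rate-law evaluation with analytic Jacobian is kept as a cross-check
#'   path.
#' @return A `trajectory` object: list with `times`, `states` (matrix, one
#'   row per time, columns in species order) and `input_level`.
#' @export
simulate_ode <- function(net, params, u_tot, x0, times,
                         rtol = 1e-8, atol = 1e-10, compiled = TRUE) {
  stopifnot(all(diff(times) >= 0), all(x0 >= 0))
  t_uniq <- unique(c(times[1], times))
  out <- if (compiled) {
    rates <- vapply(net$reactions, function(rx) params[[rx$rate]], numeric(1))
    fb_on <- vapply(net$fb, function(f) if (is.null(f)) 0L else f$on,
                    integer(1))
    fb_kappa <- vapply(net$fb, function(f)
      if (is.null(f)) 0 else params[[f$constant]], numeric(1))
    .set_ode_network(length(net$species),
                     matrix(as.numeric(net$stoich), nrow(net$stoich)),
                     lapply(net$factors, function(f) as.integer(f$idx)),
                     lapply(net$factors, function(f) as.numeric(f$mult)),
                     rates, fb_on, fb_kappa,
                     if (is.na(net$bound_idx)) 0L else net$bound_idx, u_tot)
    deSolve::lsoda(y = as.numeric(x0), times = t_uniq,
                   func = "mudrug_derivs", parms = NULL,
                   dllname = "mudrug", initfunc = NULL,
                   rtol = rtol, atol = atol)
  } else {
    fn <- function(t, y, p) list(evaluate_rhs(net, y, params, u_tot))
    jac <- function(t, y, p) jac_state(net, y, params, u_tot)
    deSolve::lsoda(y = as.numeric(x0), times = t_uniq, func = fn,
                   parms = NULL, jacfunc = jac, jactype = "fullusr",
                   rtol = rtol, atol = atol)
  }
  if (attr(out, "istate")[1] < 0)
    stop("ODE integration failed (lsoda istate ",
         attr(out, "istate")[1], ")")
  states <- out[match(times, out[, 1]), -1, drop = FALSE]
  dimnames(states) <- list(NULL, net$species)
  structure(list(times = times, states = states, input_level = u_tot),
            class = "trajectory")
}

#' Write a trajectory to CSV
#'
#' @param traj A `trajectory` from [simulate_ode()] or [ssa_simulate()].
#' @param path Output file; header is `time,<species...>`.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(time = traj$times, traj$states, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Jacobian linearization to state-space form
#'
#' Linearizes the network around an operating point into deviation-variable
#' state-space form `dz/dt = A z + B v`, `w = C z + D v`, where `z` are
#' species deviations, `v` the deviation of the total-concentration input,
#' and `w` the deviation of the output species.  `A` and `B` are analytic
#' Jacobians of the declared rate laws; `D = 0` because the output is a
#' state.
#'
#' @inheritParams evaluate_rhs
#' @param operating_point State around which to linearize.  By default this
#'   must be a steady state of `(net, params, u_tot)`; set
#'   `check_equilibrium = FALSE` to linearize a (therapy) vector field around
#'   a reference point that is not its own equilibrium.
#' @param check_equilibrium Require the operating point to be an equilibrium
#'   (residual below `tol`)?
#' @param tol Equilibrium residual tolerance.
#' @return An [ss_model()] with the operating point attached.
#' @export
linearize <- function(net, params, u_tot, operating_point,
                      check_equilibrium = TRUE, tol = 1e-8) {
  operating_point <- as.numeric(operating_point)
  if (check_equilibrium) {
    r <- evaluate_rhs(net, operating_point, params, u_tot)
    if (max(abs(r)) > tol)
      stop("operating point is not a steady state (residual ",
           format(max(abs(r)), digits = 3), " > ", tol, ")")
  }
  A <- jac_state(net, operating_point, params, u_tot)
  B <- matrix(jac_input(net, operating_point, params, u_tot), ncol = 1)
  C <- matrix(0, 1, length(net$species))
  C[1, net$output_idx] <- 1
  D <- matrix(0, 1, 1)
  ss_model(A, B, C, D, operating_point = setNames(operating_point, net$species))
}
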