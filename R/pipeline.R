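#' Pipeline configuration
#'
#' Collects every tunable of the screening workflow with defaults matching
#' the bundled case study: envelope factor `f = 1.6`, parameter uncertainty
#' radius `r_k = 0.45`, 100 stochastic runs on a 100-point grid, cost and
#' screening evaluation at 20 regularly spaced time points, target sets of
#' up to 4 of the linearly appearing parameters, and a simulation horizon
#' of 50 time units.  The system size `omega` (molecules per concentration
#' unit) fixes the absolute envelope width and defaults to 1000.
#'
#' @param model Path to the model file (default: bundled case study).
#' @param omega System size for the stochastic simulations.
#' @param f Envelope width factor.
#' @param seed Single global integer seed; all random draws derive from it.
#' @param n_ssa_runs,n_grid SSA ensemble size and time-grid resolution.
#' @param n_cost_points Number of cost/screening time points.
#' @param horizon Simulated time span.
#' @param r_k Relative uncertainty radius applied to each parameter.
#' @param max_target_set Largest therapy target-set size.
#' @param excluded Parameters excluded from targeting/uncertainty (the
#'   default excludes the zeroth-order production constant, absent from the
#'   linearized model).
#' @param n_restarts Random restarts per therapy fit.
#' @param mu_method `"mixed"` or `"complex"` upper-bound method.
#' @param refine_threshold Mixed-bound refinement threshold (see
#'   [robust_performance_mu()]).
#' @param freq_grid Frequency grid for the mu sweep.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(model = NULL, omega = 1000, f = 1.6, seed = 1,
                            n_ssa_runs = 100, n_grid = 100,
                            n_cost_points = 20, horizon = 50, r_k = 0.45,
                            max_target_set = 4, excluded = "k3",
                            n_restarts = 4,
                            mu_method = c("mixed", "complex"),
                            refine_threshold = 0.7,
                            freq_grid = default_frequency_grid()) {
  stopifnot(omega > 0, f > 0, n_ssa_runs >= 2, n_grid >= 2,
            n_cost_points >= 1, horizon > 0, r_k >= 0, r_k < 1,
            max_target_set >= 1, n_restarts >= 0)
  structure(list(model = model, omega = omega, f = f, seed = as.integer(seed),
                 n_ssa_runs = n_ssa_runs, n_grid = n_grid,
                 n_cost_points = n_cost_points, horizon = horizon,
                 r_k = r_k, max_target_set = max_target_set,
                 excluded = excluded, n_restarts = n_restarts,
                 mu_method = match.arg(mu_method),
                 refine_threshold = refine_threshold,
                 freq_grid = freq_grid),
            class = "pipeline_config")
}

target_label <- function(ts) paste(ts, collapse = "+")

#' Run the full screening pipeline
#'
#' Executes the five stages end to end on a reaction network: (1) healthy
#' performance envelope from an SSA ensemble; (2) therapy enumeration and
#' bounded least-squares fitting; (3) nominal performance screen against
#' the envelope; (4) linearization, nominal stability check and robust
#' performance screen by mu-analysis of the M-Delta form under `r_k`
#' real parametric uncertainty; (5) local sensitivity analysis.  All
#' randomness derives from `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param net Optionally, an already-constructed [reaction_network()]
#'   (otherwise read from `config$model`, defaulting to the bundled case
#'   study).
#' @param out_dir If non-`NULL`, stage artifacts are written there via
#'   [write_report()].
#' @param quiet Suppress progress messages?
#' @return A `screening_report`: list with `config`, `envelope`,
#'   `therapies` (data frame), `mu_results` (list), `sensitivity`, and
#'   `summary` (gate counts and robust target sets).
#' @export
run_pipeline <- function(config = pipeline_config(), net = NULL,
                         out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  if (is.null(net))
    net <- if (is.null(config$model)) case_study_network()
           else read_model_file(config$model)
  u_h <- net$input$healthy; u_d <- net$input$diseased
  params <- net$parameters

  say("stage 1/5: steady states and healthy performance envelope")
  ss_h <- find_steady_state(net, params, u_h)
  ss_d <- find_steady_state(net, params, u_d)
  y_ss_h <- ss_h[net$output_idx]
  ens <- ssa_ensemble(net, params, u_h, ss_h, t_end = config$horizon,
                      omega = config$omega, seed = config$seed,
                      n_runs = config$n_ssa_runs, n_grid = config$n_grid)
  env <- build_performance_envelope(y_ss_h, ens, f = config$f)

  say("stage 2/5: enumerate and fit therapies")
  targets <- enumerate_therapy_targets(names(params),
                                       max_size = config$max_target_set,
                                       excluded = config$excluded)
  therapies <- vector("list", length(targets))
  mult_by_label <- list()   # fitted multipliers, for warm-starting supersets
  for (i in seq_along(targets)) {
    ts <- targets[[i]]
    extra <- list()
    if (length(ts) > 1) {
      subs <- combn(ts, length(ts) - 1, simplify = FALSE)
      for (s in subs) {
        m <- mult_by_label[[target_label(s)]]
        if (!is.null(m)) {
          st <- setNames(rep(1, length(ts)), ts)
          st[s] <- m
          extra <- c(extra, list(unname(st)))
        }
      }
    }
    therapies[[i]] <- fit_therapy(net, ts, nominal = params,
                                  u_tot_d = u_d, y_h_ref = y_ss_h,
                                  x0 = ss_d, horizon = config$horizon,
                                  n_points = config$n_cost_points,
                                  n_restarts = config$n_restarts,
                                  seed = config$seed * 131 + i,
                                  extra_starts = extra)
    mult_by_label[[target_label(ts)]] <-
      therapies[[i]]$fitted_params[ts] / params[ts]
  }

  say("stage 3/5: nominal performance screen")
  nominal_pass <- vapply(therapies, function(th)
    as.logical(nominal_performance_test(net, th, env, u_tot_d = u_d,
                                        x0_healthy = ss_h,
                                        horizon = config$horizon,
                                        n_points = config$n_cost_points)),
    logical(1))

  say("stage 4/5: robust performance screen (mu-analysis)")
  w_p <- performance_weight(env, u_d, u_h)
  uncertain_names <- setdiff(names(params), config$excluded)
  mu_results <- vector("list", length(therapies))
  mu_rp <- rep(NA_real_, length(therapies))
  robust_pass <- rep(NA, length(therapies))
  stable <- rep(NA, length(therapies))
  for (i in seq_along(therapies)) {
    if (!nominal_pass[i]) next
    th <- therapies[[i]]
    msys <- therapy_m_delta(net, th$fitted_params, w_p,
                            operating_point = ss_h, u_tot = u_h,
                            r_k = config$r_k,
                            uncertain_names = uncertain_names)
    sysn <- ss_model(msys$A, msys$B, msys$C, msys$D)
    stable[i] <- nominal_stability_check(sysn)
    if (!stable[i]) { robust_pass[i] <- FALSE; next }
    res <- robust_performance_mu(msys, omega = config$freq_grid,
                                 refine_threshold = config$refine_threshold)
    mu_results[[i]] <- res
    mu_rp[i] <- res$mu_rp
    robust_pass[i] <- res$verdict
  }

  say("stage 5/5: local sensitivity analysis")
  sens <- local_sensitivity_all(net, params, u_d, excluded = config$excluded)

  tab <- data.frame(
    id = seq_along(therapies),
    targets = vapply(targets, target_label, character(1)),
    fitted_values = vapply(therapies, function(th)
      paste(signif(th$fitted_params[th$target_set], 6), collapse = "|"),
      character(1)),
    fit_cost = vapply(therapies, function(th) th$fit_cost, numeric(1)),
    nominal_pass = nominal_pass,
    mu_rp = mu_rp,
    robust_pass = robust_pass,
    stringsAsFactors = FALSE)

  robust_ids <- tab$id[!is.na(tab$robust_pass) & tab$robust_pass]
  direction <- lapply(robust_ids, function(i) {
    th <- therapies[[i]]
    ch <- th$fitted_params[th$target_set] / params[th$target_set]
    setNames(ifelse(ch > 1, "increase", "decrease"), th$target_set)
  })
  names(direction) <- tab$targets[robust_ids]

  report <- structure(list(
    config = config, net = net,
    steady_states = list(healthy = ss_h, diseased = ss_d),
    envelope = env, ensemble = ens, therapies = tab,
    therapy_objects = therapies, w_p = w_p,
    mu_results = mu_results, sensitivity = sens,
    summary = list(n_enumerated = length(targets),
                   n_nominal_pass = sum(nominal_pass),
                   n_robust_pass = length(robust_ids),
                   robust_therapies = direction,
                   omega = config$omega, f = config$f,
                   r_k = config$r_k, seed = config$seed,
                   w_p = w_p, s_mean = env$s_mean,
                   y_ss_healthy = as.numeric(y_ss_h))),
    class = "screening_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Build the M-Delta system for one therapy
#'
#' Linearizes the therapy vector field around the healthy operating point
#' (the therapy's residual there is a constant bias handled by the nominal
#' screen, so the equilibrium check is waived), applies the uncertainty
#' description to the therapy's own parameter values, and assembles the
#' weighted M-Delta form.
#'
#' @param net A [reaction_network()].
#' @param therapy_params Full named parameter vector of the therapy.
#' @param w_p Performance weight.
#' @param operating_point Healthy steady state.
#' @param u_tot Input level at the operating point.
#' @param r_k Relative uncertainty radius.
#' @param uncertain_names Parameters carrying uncertainty.
#' @return An `m_delta_system`.
#' @export
therapy_m_delta <- function(net, therapy_params, w_p, operating_point,
                            u_tot = net$input$healthy, r_k = 0.45,
                            uncertain_names) {
  ssm <- linearize(net, therapy_params, u_tot, operating_point,
                   check_equilibrium = FALSE)
  uncertain <- lapply(uncertain_names, function(nm) {
    k <- therapy_params[[nm]]
    up <- make_uncertain_parameter(max(k * (1 - r_k), 1e-12),
                                   k * (1 + r_k), name = nm)
    up
  })
  pert <- param_perturbations(net, therapy_params, u_tot, operating_point,
                              uncertain)
  assemble_m_delta(ssm, pert, w_p)
}

#' @export
print.screening_report <- function(x, ...) {
  s <- x$summary
  cat("Therapy screening report\n")
  cat(sprintf("  enumerated therapies: %d\n", s$n_enumerated))
  cat(sprintf("  nominal-pass:         %d\n", s$n_nominal_pass))
  cat(sprintf("  robust-pass (mu<1):   %d\n", s$n_robust_pass))
  cat(sprintf("  envelope: y_ss = %.4g, s_mean = %.4g (omega = %g, f = %g, seed %d)\n",
              s$y_ss_healthy, s$s_mean, s$omega, s$f, s$seed))
  if (length(s$robust_therapies)) {
    cat("  robust therapies:\n")
    for (nm in names(s$robust_therapies)) {
      d <- s$robust_therapies[[nm]]
      cat("   -", nm, ":",
          paste(names(d), ifelse(d == "increase", "up", "down"),
                collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' Write all pipeline artifacts to a directory
#'
#' Writes the summary JSON, the therapy table, ensemble/envelope exports,
#' per-therapy mu sweeps, the sensitivity table, and a run log carrying the
#' configuration and seed.
#'
#' @param report A `screening_report` from [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  s <- report$summary
  jsonlite::write_json(s, p("summary.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  write_therapy_csv(report$therapies, p("therapies.csv"))
  write_ensemble_csv(report$ensemble, p("ensemble.csv"))
  write_envelope_json(report$envelope, p("envelope.json"))
  write_sensitivity_csv(report$sensitivity, p("sensitivity.csv"))
  mu_tab <- report$therapies[!is.na(report$therapies$mu_rp), ]
  if (nrow(mu_tab)) {
    mu_exp <- data.frame(therapy_id = mu_tab$id, targets = mu_tab$targets,
                         mu_rp = mu_tab$mu_rp,
                         peak_frequency = vapply(mu_tab$id, function(i)
                           report$mu_results[[i]]$peak_omega, numeric(1)),
                         upper_gap = vapply(mu_tab$id, function(i)
                           report$mu_results[[i]]$bound_gap %||% NA_real_,
                           numeric(1)),
                         verdict = mu_tab$robust_pass)
    write.csv(mu_exp, p("mu_results.csv"), row.names = FALSE, quote = FALSE)
  }
  cfg <- unclass(report$config)
  cfg$freq_grid <- NULL
  log <- list(config = cfg,
              freq_grid_range = range(report$config$freq_grid),
              n_freq = length(report$config$freq_grid),
              seed = report$config$seed)
  jsonlite::write_json(log, p("run_log.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}
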