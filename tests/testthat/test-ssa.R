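test_that("concentration/count conversion rounds and bounds correctly", {
  expect_equal(concentration_to_counts(c(y = 0.2), 1000), 200L)
  expect_equal(concentration_to_counts(c(0, 0, 0), 500), c(0L, 0L, 0L))
  st <- c(9.7779644, 0.1356677, 0.4440712)
  for (om in c(250, 1000)) {
    cts <- concentration_to_counts(st, om)
    expect_true(all(abs(cts / om - st) <= 0.5 / om + 1e-12))
  }
  expect_error(concentration_to_counts(c(-1, 0), 100))
})

test_that("jump trajectories conserve the enzyme pool and are seed-deterministic", {
  net <- cs_net()
  x0 <- concentration_to_counts(cs_ss("healthy"), 200)
  tr1 <- ssa_simulate(net, net$parameters, 0.2, x0, t_end = 5, omega = 200,
                      seed = 11)
  tr2 <- ssa_simulate(net, net$parameters, 0.2, x0, t_end = 5, omega = 200,
                      seed = 11)
  expect_identical(tr1$times, tr2$times)
  expect_identical(tr1$states, tr2$states)

  tr3 <- ssa_simulate(net, net$parameters, 0.2, x0, t_end = 5, omega = 200,
                      seed = 12)
  expect_false(identical(tr1$times, tr3$times))

  # total enzyme count (free + bound) is invariant at every event:
  # the bound form never exceeds the pool and counts stay nonnegative
  utot_count <- round(200 * 0.2)
  expect_true(all(tr1$states >= 0))
  expect_true(all(tr1$states[, "ux"] <= utot_count))
  # states only change by the stoichiometry of one reaction per event
  jumps <- diff(tr1$states)
  cols <- apply(abs(jumps), 1, sum)
  expect_true(all(cols >= 1 & cols <= 2))
})

test_that("ensemble statistics reduce to closed forms on constant runs", {
  mk <- function(y) structure(list(times = c(0, 10),
                                   states = cbind(x = c(0, 0), ux = c(0, 0),
                                                  y = c(y, y)),
                                   seed = 1),
                              class = "trajectory")
  grid <- seq(1, 9, by = 1)
  ens <- ensemble_statistics(list(mk(4), mk(4), mk(4)), omega = 2, grid)
  expect_equal(ens$mean, rep(2, 9))
  expect_equal(ens$sd, rep(0, 9))

  ens2 <- ensemble_statistics(list(mk(2), mk(6)), omega = 1, grid)
  expect_equal(ens2$mean, rep(4, 9))
  expect_equal(ens2$sd, rep(abs(2 - 6) / sqrt(2), 9))

  expect_error(ensemble_statistics(list(mk(1)), 1, grid), "at least 2")
})

test_that("performance envelope follows its defining identity", {
  ens <- cs_small_ensemble()
  y_ss <- unname(cs_ss("healthy")[3])
  env <- build_performance_envelope(y_ss, ens)
  expect_equal(env$f, 1.6)    # default width factor
  expect_equal(env$s_mean, mean(ens$sd))
  expect_equal(env$y_lb, y_ss - env$f * env$s_mean)
  expect_equal(env$y_ub, y_ss + env$f * env$s_mean)
  expect_equal(env$y_ub - env$y_lb, 2 * env$f * env$s_mean)

  # degenerate ensemble: warns, bounds collapse onto the steady state
  dg <- ens; dg$sd <- rep(0, length(dg$sd))
  expect_warning(env0 <- build_performance_envelope(y_ss, dg), "degenerate")
  expect_equal(env0$y_lb, env0$y_ub)
  expect_equal(env0$y_lb, y_ss)
})

test_that("the envelope contains the stochastic band at the default ensemble size", {
  net <- cs_net()
  ssh <- cs_ss("healthy")
  ens <- ssa_ensemble(net, net$parameters, 0.2, ssh, t_end = 50,
                      omega = 1000, seed = 1, n_runs = 100)
  env <- build_performance_envelope(unname(ssh[3]), ens)
  expect_true(all(ens$mean + ens$sd <= env$y_ub + 1e-12))
  expect_true(all(ens$mean - ens$sd >= env$y_lb - 1e-12))
})

test_that("pinned-seed ensembles are bit-reproducible", {
  net <- cs_net()
  ssh <- cs_ss("healthy")
  a <- ssa_ensemble(net, net$parameters, 0.2, ssh, t_end = 10, omega = 500,
                    seed = 3, n_runs = 10, n_grid = 20)
  b <- ssa_ensemble(net, net$parameters, 0.2, ssh, t_end = 10, omega = 500,
                    seed = 3, n_runs = 10, n_grid = 20)
  expect_identical(a$mean, b$mean)
  expect_identical(a$sd, b$sd)
})

test_that("intrinsic noise scales like one over the square root of system size", {
  net <- cs_net()
  ssh <- cs_ss("healthy")
  s <- vapply(c(250, 1000, 4000), function(om) {
    mean(ssa_ensemble(net, net$parameters, 0.2, ssh, t_end = 30, omega = om,
                      seed = 5, n_runs = 40, n_grid = 50)$sd)
  }, numeric(1))
  expect_lt(s[2] / s[1] / sqrt(250 / 1000), 1.3)
  expect_gt(s[2] / s[1] / sqrt(250 / 1000), 1 / 1.3)
  expect_lt(s[3] / s[2] / sqrt(1000 / 4000), 1.3)
  expect_gt(s[3] / s[2] / sqrt(1000 / 4000), 1 / 1.3)
})
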