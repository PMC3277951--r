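mk_msys <- function(k_changes = c(k2 = 0.4, k4 = 1), w_p = 0.1, r_k = 0.45) {
  net <- cs_net()
  p <- net$parameters
  p[names(k_changes)] <- k_changes
  therapy_m_delta(net, p, w_p, operating_point = cs_ss("healthy"),
                  u_tot = net$input$healthy, r_k = r_k,
                  uncertain_names = setdiff(names(p), "k3"))
}

test_that("performance weight follows the envelope half-width over the input step", {
  ens <- cs_small_ensemble()
  env <- build_performance_envelope(cs_ss("healthy")[3], ens)
  w <- performance_weight(env, 2, 0.2)
  expect_equal(w, env$f * env$s_mean / 1.8)
  # an envelope of width 2w maps to weight w / input step
  env2 <- env; env2$y_lb <- env$y_ss - 0.5; env2$y_ub <- env$y_ss + 0.5
  expect_equal(performance_weight(env2, 2, 0.2), 0.5 / 1.8)
  expect_error(performance_weight(env, 2, 2), "differ")
  # pinned-seed weight is reproducible
  ens2 <- cs_small_ensemble()
  expect_identical(w, performance_weight(
    build_performance_envelope(cs_ss("healthy")[3], ens2), 2, 0.2))
})

test_that("the M-Delta realization closes back onto the affine model exactly", {
  msys <- mk_msys()
  rblk <- which(msys$blocks$kind == "real")
  p <- length(rblk)
  # block bookkeeping: Delta dimension = sum of repetitions + performance
  expect_equal(sum(msys$blocks$dim),
               sum(msys$blocks$dim[rblk]) + 1)
  expect_equal(msys$blocks$kind[nrow(msys$blocks)], "complex")

  # with delta = 0 the closed loop is the weighted nominal model
  nom <- close_parametric_loop(msys, rep(0, p))
  expect_equal(nom$A, msys$nominal$A)
  expect_equal(nom$C, msys$nominal$C / msys$w_p)

  # sampled perturbations: the closed LFT must match the directly
  # affinized state-space model in frequency response
  w <- c(0, 10^seq(-3, 2, length.out = 20))
  set.seed(3)
  deltas <- rbind(diag(p), -diag(p) / 2,
                  matrix(runif(3 * p, -1, 1), ncol = p))
  for (r in seq_len(nrow(deltas))) {
    d <- deltas[r, ]
    closed <- close_parametric_loop(msys, d)
    A <- msys$nominal$A; B <- msys$nominal$B
    for (j in seq_len(p)) {
      A <- A + d[j] * msys$perturbations[[j]]$dA
      B <- B + d[j] * msys$perturbations[[j]]$dB
    }
    direct <- ss_model(A, B, msys$nominal$C / msys$w_p,
                       msys$nominal$D / msys$w_p)
    expect_lt(max(Mod(ss_freqresp(closed, w) - ss_freqresp(direct, w))),
              1e-8)
  }

  # matrix-level check: upper LFT of M(jw) with diag(delta) equals the
  # perturbed system's frequency response
  d <- deltas[nrow(deltas), ]
  Mw <- mudrug:::m_delta_freqresp(msys, w)
  q <- msys$q
  drep <- rep(d, times = msys$blocks$dim[rblk])
  closed <- close_parametric_loop(msys, d)
  Gd <- ss_freqresp(closed, w)
  for (i in seq_along(w)) {
    Mi <- Mw[, , i]
    Fu <- Mi[q + 1, q + 1] +
      Mi[q + 1, 1:q, drop = FALSE] %*% diag(drep, q) %*%
      solve(diag(q) - Mi[1:q, 1:q] %*% diag(drep, q),
            Mi[1:q, q + 1, drop = FALSE])
    expect_lt(Mod(Fu[1, 1] - Gd[i]), 1e-8)
  }
})

test_that("vanishing uncertainty collapses Delta to the performance block", {
  wmsg <- capture_warnings(msys <- mk_msys(r_k = 0))
  expect_true(any(grepl("dropped", wmsg)))
  expect_equal(msys$q, 0)
  expect_equal(nrow(msys$blocks), 1)
  # mu of the remaining 1x1 complex block = weighted nominal gain
  w <- default_frequency_grid(60)
  res <- robust_performance_mu(msys, omega = w)
  gain <- hinf_norm(ss_model(msys$nominal$A, msys$nominal$B,
                             msys$nominal$C / msys$w_p,
                             msys$nominal$D / msys$w_p), w)
  expect_equal(res$mu_rp, gain, tolerance = 1e-4)
})

test_that("mu sweep returns sandwiched bounds and is monotone in the weight", {
  msys <- mk_msys(w_p = 0.1)
  w <- default_frequency_grid(40)
  res <- robust_performance_mu(msys, omega = w, lower_every = 5)
  f <- res$freq
  have <- !is.na(f$mu_lower)
  expect_true(any(have))
  expect_true(all(f$mu_lower[have] <= f$mu_upper[have] + 1e-6))
  expect_gte(res$mu_rp, max(f$mu_upper) - 1e-12)

  # doubling w_p relaxes the performance channel: mu_rp non-increasing
  msys2 <- mk_msys(w_p = 0.2)
  res2 <- robust_performance_mu(msys2, omega = w)
  expect_lte(res2$mu_rp, res$mu_rp + 1e-6)

  # a therapy identical to the healthy plant gives a zero deviation system
  net <- cs_net()
  sys_h <- linearize(net, net$parameters, 0.2, cs_ss("healthy"))
  dz <- build_deviation_system(sys_h, sys_h)
  pert <- list(list(name = "k1", dA = matrix(0, 6, 6), dB = matrix(0, 6, 1)))
  wmsg <- capture_warnings(mz <- assemble_m_delta(dz, pert, w_p = 0.1))
  expect_true(any(grepl("dropped", wmsg)))
  rz <- robust_performance_mu(mz, omega = w)
  expect_lt(rz$mu_rp, 1e-8)
  expect_true(rz$verdict)
})

test_that("sampling oracle is consistent with the mu verdict", {
  msys <- mk_msys(w_p = 0.05)
  w <- default_frequency_grid(40)
  res <- robust_performance_mu(msys, omega = w)
  wc <- worst_case_gain_oracle(msys, n_samples = 30, seed = 5, omega = w)
  # nominal-only sampling reduces to the nominal weighted gain
  nomgain <- hinf_norm(close_parametric_loop(
    msys, rep(0, sum(msys$blocks$kind == "real"))), w)
  expect_gte(wc$gain + 1e-9, nomgain)
  # soundness: an oracle violation forbids a robust verdict
  if (wc$gain >= 1) expect_gte(res$mu_rp, 1)
  # the oracle gain never exceeds what mu certifies as the worst case
  if (res$mu_rp < 1) expect_lt(wc$gain, 1)
})

test_that("unstable nominal systems are rejected", {
  sys <- ss_model(matrix(1), matrix(1), matrix(1))
  pert <- list(list(name = "p", dA = matrix(0.1), dB = matrix(0)))
  msys <- assemble_m_delta(sys, pert, w_p = 1)
  expect_error(robust_performance_mu(msys), "unstable")
})
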