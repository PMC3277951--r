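test_that("rate laws evaluate to the expected mass-action derivatives", {
  net <- cs_net()
  zero <- setNames(rep(0, 7), names(net$parameters))
  expect_equal(unname(evaluate_rhs(net, c(1, 0.1, 2), zero, 2)), rep(0, 3))

  # at the origin only the zeroth-order production of X is active
  d0 <- evaluate_rhs(net, c(0, 0, 0), net$parameters, 2)
  expect_equal(unname(d0), c(net$parameters[["k3"]], 0, 0))

  # steady state annihilates the right-hand side
  ssh <- cs_ss("healthy")
  expect_lt(max(abs(evaluate_rhs(net, ssh, net$parameters, 0.2))), 1e-8)

  # bound species above the total input is a domain error
  expect_error(evaluate_rhs(net, c(1, 0.5, 1), net$parameters, 0.2),
               "exceeds")
})

test_that("steady states solve the network and order as expected", {
  net <- cs_net()
  ssh <- cs_ss("healthy")
  ssd <- cs_ss("diseased")
  expect_lt(max(abs(evaluate_rhs(net, ssh, net$parameters, 0.2))), 1e-10)
  expect_lt(max(abs(evaluate_rhs(net, ssd, net$parameters, 2))), 1e-10)
  expect_true(all(ssh >= 0) && all(ssd >= 0))
  # output is up-regulated in the diseased condition
  expect_gt(ssd[net$output_idx], ssh[net$output_idx])

  # independent long-time integration lands on the same point
  tr <- simulate_ode(net, net$parameters, 0.2, c(5, 0.01, 0.1),
                     times = c(0, 200))
  expect_lt(max(abs(tr$states[2, ] - ssh)), 1e-6)

  # flux balance: production equals total degradation at equilibrium
  k <- net$parameters
  expect_lt(abs(k[["k3"]] - k[["k_m3"]] * ssh[1] - k[["k4"]] * ssh[3]), 1e-8)
  expect_lt(abs(k[["k3"]] - k[["k_m3"]] * ssd[1] - k[["k4"]] * ssd[3]), 1e-8)
})

test_that("ODE simulation respects equilibria and converges between them", {
  net <- cs_net()
  k <- net$parameters
  ssh <- cs_ss("healthy")
  ssd <- cs_ss("diseased")
  tt <- seq(0, 50, length.out = 51)

  tr <- simulate_ode(net, k, 0.2, ssh, tt)
  expect_lt(max(abs(sweep(tr$states, 2, ssh))), 1e-6)

  # switching the input drives the healthy state to the diseased attractor
  tr2 <- simulate_ode(net, k, 2, ssh, tt)
  expect_lt(max(abs(tr2$states[51, ] - ssd)), 1e-5)

  # no active reactions: constant trajectory
  zero <- setNames(rep(0, 7), names(k))
  tr3 <- simulate_ode(net, zero, 2, c(1, 0.1, 2), tt)
  expect_equal(tr3$states[51, ], tr3$states[1, ], tolerance = 1e-10)

  # compiled and pure-R rate evaluations agree to solver tolerance
  tr4 <- simulate_ode(net, k, 2, ssh, tt, compiled = FALSE)
  expect_lt(max(abs(tr2$states - tr4$states)), 1e-6)
})

test_that("linearization matches finite differences and drops k3", {
  net <- cs_net()
  k <- net$parameters
  ssh <- cs_ss("healthy")
  L <- linearize(net, k, 0.2, ssh)
  expect_equal(dim(L$A), c(3, 3))
  expect_equal(L$D, matrix(0, 1, 1))

  # central finite-difference Jacobian oracle
  Afd <- matrix(0, 3, 3)
  for (j in 1:3) {
    h <- 1e-6 * max(abs(ssh[j]), 1)
    sp <- sm <- ssh
    sp[j] <- sp[j] + h; sm[j] <- sm[j] - h
    Afd[, j] <- (evaluate_rhs(net, sp, k, 0.2) -
                   evaluate_rhs(net, sm, k, 0.2)) / (2 * h)
  }
  expect_lt(max(abs(L$A - Afd)), 1e-5)
  hB <- 1e-6
  Bfd <- (evaluate_rhs(net, ssh, k, 0.2 + hB) -
            evaluate_rhs(net, ssh, k, 0.2 - hB)) / (2 * hB)
  expect_lt(max(abs(L$B - Bfd)), 1e-5)

  # the zeroth-order production constant is absent from A and B
  for (fac in c(0.5, 1.5)) {
    k2 <- k; k2[["k3"]] <- k[["k3"]] * fac
    L2 <- linearize(net, k2, 0.2, ssh, check_equilibrium = FALSE)
    expect_equal(L2$A, L$A)
    expect_equal(L2$B, L$B)
  }

  # both nominal operating points are stable
  expect_true(all(Re(eigen(L$A)$values) < 0))
  Ld <- linearize(net, k, 2, cs_ss("diseased"))
  expect_true(all(Re(eigen(Ld$A)$values) < 0))

  # a non-equilibrium operating point is rejected unless waived
  expect_error(linearize(net, k, 2, ssh), "not a steady state")
})

test_that("linear model reproduces small nonlinear input steps locally", {
  net <- cs_net()
  k <- net$parameters
  ssh <- cs_ss("healthy")
  L <- linearize(net, k, 0.2, ssh)
  du <- 0.01 * 0.2   # 1% input step
  tt <- seq(0, 30, length.out = 40)
  ylin <- ss_step(L, tt, u = du)[, 1]
  tr <- simulate_ode(net, k, 0.2 + du, ssh, tt)
  ynl <- tr$states[, net$output_idx] - ssh[net$output_idx]
  i <- which(abs(ynl) > 0.2 * max(abs(ynl)))
  expect_lt(max(abs(ylin[i] - ynl[i]) / abs(ynl[i])), 0.05)
})

test_that("model files round-trip through the declarative reader", {
  net <- cs_net()
  expect_equal(net$species, c("x", "ux", "y"))
  expect_equal(length(net$reactions), 6)
  expect_equal(net$parameters[["k1"]], 1)
  expect_equal(net$input$healthy, 0.2)
  expect_equal(net$input$diseased, 2)
  expect_equal(net$output, "y")
  # validation errors
  expect_error(reaction_network(c("a"), c(k = 1),
                                list(list(reactants = c(b = 1),
                                          products = c(a = 1), rate = "k")),
                                input = list(name = "u", healthy = 1,
                                             diseased = 2)),
               "unknown reactant")
  expect_error(reaction_network(c("a"), c(k = 1),
                                list(list(reactants = c(a = 1),
                                          products = NULL, rate = "nope")),
                                input = list(name = "u", healthy = 1,
                                             diseased = 2)),
               "unknown rate constant")
})
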