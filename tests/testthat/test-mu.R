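test_that("uncertain parameters realize their interval endpoints", {
  up <- make_uncertain_parameter(0.55, 1.45)
  expect_equal(up$k_mean, 1)
  expect_equal(up$r_k, 0.45)
  expect_equal(realize_parameter(up, 1), 1.45)
  expect_equal(realize_parameter(up, -1), 0.55)

  up0 <- make_uncertain_parameter(3, 3)
  expect_equal(up0$r_k, 0)
  expect_equal(realize_parameter(up0, 0.7), 3)

  up2 <- list(k_mean = 2, r_k = 0.45)
  class(up2) <- "uncertain_parameter"
  expect_equal(realize_parameter(up2, 1), 2.9)
  expect_error(make_uncertain_parameter(0, 1), "positive")
})

test_that("mu bounds hit exact values on canonical structures", {
  # zero matrix: mu = 0 for any structure
  bl <- block_structure(c("real", "complex"), c(2, 1))
  expect_equal(as.numeric(mu_upper_bound(matrix(0, 3, 3), bl)), 0)
  expect_equal(mu_lower_bound(matrix(0, 3, 3), bl)$lower, 0)

  # one full complex block: mu equals the largest singular value
  bc <- block_structure("complex", 2)
  M <- diag(c(3, 1))
  expect_equal(as.numeric(mu_upper_bound(M, bc)), 3, tolerance = 1e-8)
  expect_equal(mu_lower_bound(M, bc)$lower, 3, tolerance = 1e-8)
  set.seed(1)
  for (i in 1:5) {
    R <- rcmat(3)
    expect_equal(as.numeric(mu_upper_bound(R, block_structure("complex", 3))),
                 max(svd(R)$d), tolerance = 1e-8)
  }

  # purely real block against an imaginary gain: no real perturbation
  # can create singularity, mu is (numerically) zero
  br <- block_structure("real", 1)
  expect_lt(as.numeric(mu_upper_bound(matrix(1i, 1, 1), br)), 0.05)
})

test_that("mu bounds obey scaling, sandwich and conservatism ordering", {
  set.seed(42)
  bl <- block_structure(c("real", "real", "complex"), c(1, 1, 1))
  for (i in 1:6) {
    M <- rcmat(3)
    ub <- mu_upper_bound(M, bl)
    lb <- mu_lower_bound(M, bl, upper = as.numeric(ub))$lower
    cub <- attr(ub, "complex_upper")
    # sandwich and conservatism ordering
    expect_lte(lb, as.numeric(ub) + 1e-6)
    expect_lte(as.numeric(ub), cub + 1e-9)
    # scaling law mu(aM) = |a| mu(M)
    for (a in c(2.5, -0.3)) {
      ub2 <- as.numeric(mu_upper_bound(a * M, bl))
      expect_equal(ub2, abs(a) * as.numeric(ub), tolerance = 1e-6)
      lb2 <- mu_lower_bound(a * M, bl, upper = ub2)$lower
      expect_equal(lb2, abs(a) * lb, tolerance = 5e-2)
    }
  }
})

test_that("lower-bound witnesses certify singularity", {
  set.seed(7)
  bl <- block_structure(c("real", "real", "complex"), c(1, 1, 1))
  for (i in 1:4) {
    M <- rcmat(3)
    res <- mu_lower_bound(M, bl)
    if (res$lower <= 0) next
    # normalized witness: ||Delta|| <= 1 and det(I - (1/mu) M Delta) ~ 0
    expect_lte(max(svd(res$witness)$d), 1 + 1e-6)
    s_min <- min(svd(diag(3) - (1 / res$lower) * M %*% res$witness)$d)
    expect_lt(s_min, 1e-6 * max(1, max(abs(M))))
  }
})

test_that("mu lower bound tracks an independent brute-force search", {
  set.seed(11)
  bl <- block_structure(c("real", "real", "complex"), c(1, 1, 1))
  for (i in 1:3) {
    M <- rcmat(3)
    ub <- as.numeric(mu_upper_bound(M, bl))
    lb <- mu_lower_bound(M, bl, upper = ub)$lower
    brute <- brute_mu_lower(M, 2, delta_grid = seq(-1, 1, by = 0.1))
    expect_gte(ub + 1e-6, brute)          # upper bound dominates any witness
    expect_gt(lb, 0.9 * brute)            # search is competitive with brute force
  }
})

test_that("upper bound dominates brute-force estimates across mixed structures", {
  set.seed(99)
  n_checked <- 0
  for (trial in 1:50) {
    nreal <- sample(1:3, 1)
    bl <- block_structure(c(rep("real", nreal), "complex"),
                          rep(1, nreal + 1))
    M <- rcmat(nreal + 1)
    ub <- as.numeric(mu_upper_bound(M, bl))
    brute <- brute_mu_lower(M, nreal)
    expect_gte(ub + 1e-6 * max(1, ub), brute)
    lb <- mu_lower_bound(M, bl, upper = ub)$lower
    expect_lte(lb, ub + 1e-6 * max(1, ub))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 50)
})
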