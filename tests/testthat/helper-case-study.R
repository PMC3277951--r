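# shared fixtures: the bundled case-study network, its steady states, and a
# lazily computed full default screen (reused by the acceptance tests)

.cs <- new.env()

cs_net <- function() {
  if (is.null(.cs$net)) .cs$net <- case_study_network()
  .cs$net
}

cs_ss <- function(condition = c("healthy", "diseased")) {
  condition <- match.arg(condition)
  key <- paste0("ss_", condition)
  if (is.null(.cs[[key]])) {
    net <- cs_net()
    u <- if (condition == "healthy") net$input$healthy else net$input$diseased
    .cs[[key]] <- find_steady_state(net, net$parameters, u)
  }
  .cs[[key]]
}

# full screening chain at the default study conditions (seed 1); computed at
# most once per test session
cs_screen <- function() {
  if (is.null(.cs$screen))
    .cs$screen <- run_pipeline(pipeline_config(seed = 1), quiet = TRUE)
  .cs$screen
}

# small pinned-seed healthy ensemble for envelope tests
cs_small_ensemble <- function() {
  if (is.null(.cs$ens)) {
    net <- cs_net()
    .cs$ens <- ssa_ensemble(net, net$parameters, net$input$healthy,
                            cs_ss("healthy"), t_end = 50, omega = 1000,
                            seed = 7, n_runs = 40)
  }
  .cs$ens
}

# independent brute-force lower estimate of mu for structures of real scalar
# blocks plus one trailing 1x1 complex block: for each candidate real
# direction, bisect on beta in the singularity condition
# sigma(N_beta(delta)) >= beta, closing the real loop by direct solve.
brute_mu_lower <- function(M, n_real, delta_grid = c(-1, -0.5, 0.5, 1)) {
  nr <- n_real
  ridx <- seq_len(nr)
  cidx <- nr + 1
  gain <- function(delta, beta) {
    A <- diag(nr) - sweep(M[ridx, ridx, drop = FALSE], 2, delta / beta, `*`)
    X <- tryCatch(solve(A, M[ridx, cidx, drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(X)) return(Inf)
    N <- M[cidx, cidx] +
      sweep(M[cidx, ridx, drop = FALSE], 2, delta / beta, `*`) %*% X
    abs(N[1, 1])
  }
  cands <- as.matrix(expand.grid(rep(list(delta_grid), nr)))
  best <- 0
  smax <- max(svd(M)$d)
  for (r in seq_len(nrow(cands))) {
    d <- cands[r, ]
    f <- function(beta) gain(d, beta) >= beta
    hi <- smax * 1.001
    if (f(hi)) { best <- max(best, hi); next }
    lo <- 1e-6 * smax
    if (!f(lo)) {
      bs <- exp(seq(log(lo), log(hi), length.out = 25))
      ok <- vapply(bs, f, logical(1))
      if (!any(ok)) next
      lo <- max(bs[ok])
    }
    for (i in 1:30) { mid <- sqrt(lo * hi); if (f(mid)) lo <- mid else hi <- mid }
    best <- max(best, lo)
  }
  best
}

# random complex matrix helper
rcmat <- function(n, m = n) matrix(rnorm(n * m), n) + 1i * matrix(rnorm(n * m), n)
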