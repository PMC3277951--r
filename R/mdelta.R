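#' Performance weight from the envelope and input step
#'
#' The weighted robust-performance criterion requires the gain from the
#' input deviation to the normalized output deviation to stay below one;
#' the weight relating the two is
#' `w_p = ((y_ub - y_lb)/2) / (u_tot_d - u_tot_h) = f s_mean / (u_tot_d - u_tot_h)`.
#'
#' @param envelope A `performance_envelope`.
#' @param u_tot_d,u_tot_h Diseased and healthy input levels.
#' @return Positive scalar weight.
#' @export
performance_weight <- function(envelope, u_tot_d, u_tot_h) {
  if (u_tot_d == u_tot_h) stop("input levels must differ")
  half <- unname(envelope$y_ub - envelope$y_lb) / 2
  if (half <= 0) stop("degenerate envelope: performance criterion unsatisfiable")
  half / (u_tot_d - u_tot_h)
}

# first-order coefficient matrices of the linearization with respect to each
# uncertain parameter, with the operating point held fixed at nominal:
#   A(delta) ~ A0 + sum_j delta_j dA_j,  dA_j = r_j k_mean_j dA/dk_j .
# Derivatives of the analytic Jacobians are taken by central differences in
# the parameter (exact for rate constants, first-order for the feedback
# constant, matching the affine uncertainty embedding).
param_perturbations <- function(net, params, u_tot, operating_point,
                                uncertain) {
  lapply(uncertain, function(up) {
    k <- up$k_mean
    h <- 1e-6 * max(abs(k), 1e-6)
    pp <- pm <- params
    pp[up$name] <- k + h
    pm[up$name] <- k - h
    dA <- (jac_state(net, operating_point, pp, u_tot) -
             jac_state(net, operating_point, pm, u_tot)) / (2 * h)
    dB <- (jac_input(net, operating_point, pp, u_tot) -
             jac_input(net, operating_point, pm, u_tot)) / (2 * h)
    list(name = up$name, dA = up$r_k * k * dA,
         dB = up$r_k * k * matrix(dB, ncol = 1))
  })
}

#' Assemble the M-Delta system from a nominal model and perturbations
#'
#' Pulls affine real parameter perturbations of the state-space matrices
#' out of the nominal deviation model by a linear fractional transformation.
#' Each parameter's coefficient matrix `[dA_j dB_j; dC_j dD_j]` is
#' rank-factorized; its rank sets the repetition count of the corresponding
#' real scalar block of Delta.  A complex performance block is appended:
#' the performance output is the model output divided by `w_p` and the
#' performance input is the (unit-normalized) model input, so that robust
#' performance is equivalent to `mu < 1` for the mixed structure.
#'
#' @param ss_dev Nominal deviation model ([ss_model()]).
#' @param perturbations Named list, one element per uncertain parameter,
#'   each with coefficient matrices `dA` and `dB` (and optionally `dC`,
#'   `dD`) already scaled by `r_k k_mean` (see Details in the vignette);
#'   built by the pipeline from a [reaction_network()] and
#'   [make_uncertain_parameter()] descriptions.
#' @param w_p Performance weight ([performance_weight()]).
#' @param drop_tol Relative singular-value threshold below which a
#'   parameter is dropped from Delta (with a warning).
#' @return An `m_delta_system`: list with the M realization (`A`, `B`, `C`,
#'   `D`), the `block_structure`, `w_p`, the retained perturbations, and the
#'   nominal model.
#' @export
assemble_m_delta <- function(ss_dev, perturbations, w_p, drop_tol = 1e-12) {
  A0 <- ss_dev$A; B0 <- ss_dev$B; C0 <- ss_dev$C; D0 <- ss_dev$D
  n <- nrow(A0); m <- ncol(B0); pdim <- nrow(C0)
  Lx <- NULL; Ly <- NULL; Rz <- NULL; Rv <- NULL
  kinds <- integer(0); dims <- integer(0); labels <- character(0)
  kept <- list()
  scale_ref <- max(abs(A0), abs(B0), 1e-300)
  for (pb in perturbations) {
    dC <- pb$dC %||% matrix(0, pdim, n)
    dD <- pb$dD %||% matrix(0, pdim, m)
    P <- rbind(cbind(pb$dA, pb$dB), cbind(dC, dD))
    sv <- svd(P)
    r <- sum(sv$d > drop_tol * max(scale_ref, sv$d[1]))
    if (r == 0) {
      warning("parameter '", pb$name, "' has numerically zero effect; ",
              "dropped from Delta")
      next
    }
    L <- sv$u[, seq_len(r), drop = FALSE] %*% diag(sqrt(sv$d[seq_len(r)]), r)
    R <- diag(sqrt(sv$d[seq_len(r)]), r) %*% t(sv$v[, seq_len(r), drop = FALSE])
    Lx <- cbind(Lx, L[seq_len(n), , drop = FALSE])
    Ly <- cbind(Ly, L[n + seq_len(pdim), , drop = FALSE])
    Rz <- rbind(Rz, R[, seq_len(n), drop = FALSE])
    Rv <- rbind(Rv, R[, n + seq_len(m), drop = FALSE])
    dims <- c(dims, r); labels <- c(labels, pb$name)
    kept <- c(kept, list(pb))
  }
  q <- sum(dims)
  blocks <- block_structure(c(rep("real", length(dims)), "complex"),
                            c(dims, max(pdim, m)),
                            c(labels, "performance"))
  if (pdim != m) stop("non-square performance channel not supported")
  B_M <- cbind(Lx %||% matrix(0, n, 0), B0)
  C_M <- rbind(Rz %||% matrix(0, 0, n), C0 / w_p)
  D_M <- rbind(cbind(matrix(0, q, q), Rv %||% matrix(0, 0, m)),
               cbind((Ly %||% matrix(0, pdim, 0)) / w_p, D0 / w_p))
  structure(list(A = A0, B = B_M, C = C_M, D = D_M,
                 blocks = blocks, w_p = w_p, q = q,
                 perturbations = kept, nominal = ss_dev),
            class = "m_delta_system")
}

#' @export
print.m_delta_system <- function(x, ...) {
  cat("M-Delta system:", nrow(x$A), "states; Delta =",
      paste(sprintf("%s(%s,%d)", x$blocks$label, x$blocks$kind,
                    x$blocks$dim), collapse = " + "),
      "\n  w_p =", format(x$w_p, digits = 6), "\n")
  invisible(x)
}

# M(jw) on a frequency grid: (q+p) x (q+m) complex slices
m_delta_freqresp <- function(msys, omega) {
  sys <- ss_model(msys$A, msys$B, msys$C, msys$D)
  G <- ss_freqresp(sys, omega)
  if (!is.array(G) || length(dim(G)) != 3)
    G <- array(G, c(1, 1, length(omega)))
  G
}

#' Close the parametric loop of an M-Delta system at a real perturbation
#'
#' Substitutes fixed normalized values for the real parameter blocks and
#' returns the resulting weighted performance channel as a state-space
#' model.  With all `delta = 0` this recovers the weighted nominal model
#' exactly.
#'
#' @param msys An `m_delta_system`.
#' @param delta Numeric vector, one value per real (parameter) block, each
#'   in `[-1, 1]`.
#' @return An [ss_model()].
#' @export
close_parametric_loop <- function(msys, delta) {
  rblk <- which(msys$blocks$kind == "real")
  stopifnot(length(delta) == length(rblk))
  q <- msys$q
  n <- nrow(msys$A)
  m <- ncol(msys$B) - q
  pdim <- nrow(msys$C) - q
  drep <- rep(delta, times = msys$blocks$dim[rblk])
  Bw <- msys$B[, seq_len(q), drop = FALSE]
  Bu <- msys$B[, q + seq_len(m), drop = FALSE]
  Cz <- msys$C[seq_len(q), , drop = FALSE]
  Cy <- msys$C[q + seq_len(pdim), , drop = FALSE]
  Dvu <- msys$D[seq_len(q), q + seq_len(m), drop = FALSE]
  Dyw <- msys$D[q + seq_len(pdim), seq_len(q), drop = FALSE]
  Dyu <- msys$D[q + seq_len(pdim), q + seq_len(m), drop = FALSE]
  BwD <- sweep(Bw, 2, drep, `*`)
  DywD <- sweep(Dyw, 2, drep, `*`)
  ss_model(msys$A + BwD %*% Cz, Bu + BwD %*% Dvu,
           Cy + DywD %*% Cz, Dyu + DywD %*% Dvu)
}

#' Robust-performance mu analysis over a frequency sweep
#'
#' Evaluates `M(jw)` on a frequency grid, computes a certified upper bound
#' on the structured singular value at each frequency (complex D-scaling
#' everywhere; mixed D,G-scaling refinement where the conservative bound
#' exceeds `refine_threshold`), locally refines the grid around the peak,
#' and computes structured lower bounds on a subsample of frequencies and
#' at the peak.  The verdict uses the peak upper bound (`mu_rp < 1`), so a
#' therapy is declared robust only if certified.
#'
#' @param msys An `m_delta_system`.
#' @param omega Frequency grid (default [default_frequency_grid()]).
#' @param refine_threshold Conservative-bound level above which the mixed
#'   D,G bound is computed.
#' @param lower_every Compute the lower bound at every `lower_every`-th
#'   grid frequency (plus the peak); `Inf` disables all but the peak.
#' @param peak_refine Rounds of local grid refinement around the peak.
#' @return A `mu_result`: list with `freq` (data frame: `omega`,
#'   `mu_upper`, `mu_lower`), `mu_rp`, `verdict`, `peak_omega`,
#'   `bound_gap`.
#' @export
robust_performance_mu <- function(msys, omega = default_frequency_grid(),
                                  refine_threshold = 0.7, lower_every = 10,
                                  peak_refine = 2) {
  if (!all(Re(eigen(msys$A, only.values = TRUE)$values) < 0))
    stop("nominal system is unstable; robust performance undefined")
  blocks <- msys$blocks
  eval_mu <- function(w) {
    Mw <- m_delta_freqresp(msys, w)[, , 1]
    cub <- mu_upper_complex(Mw, blocks)
    val <- as.numeric(cub)
    if (any(blocks$kind == "real") && val >= refine_threshold)
      val <- as.numeric(mu_upper_bound(Mw, blocks))
    val
  }
  mu_up <- vapply(omega, eval_mu, numeric(1))
  # local peak refinement
  om <- omega
  for (round in seq_len(peak_refine)) {
    i <- which.max(mu_up)
    lo <- if (i > 1) om[i - 1] else om[i] / 2
    hi <- if (i < length(om)) om[i + 1] else om[i] * 2
    if (lo <= 0) lo <- hi / 100
    new_w <- setdiff(exp(seq(log(max(lo, 1e-12)), log(hi), length.out = 6))[2:5], om)
    if (!length(new_w)) break
    new_mu <- vapply(new_w, eval_mu, numeric(1))
    om <- c(om, new_w); mu_up <- c(mu_up, new_mu)
    ord <- order(om); om <- om[ord]; mu_up <- mu_up[ord]
  }
  ipk <- which.max(mu_up)
  mu_lo <- rep(NA_real_, length(om))
  lidx <- unique(c(ipk, seq(1, length(om),
                            by = max(1, min(lower_every, length(om))))))
  for (i in lidx) {
    Mw <- m_delta_freqresp(msys, om[i])[, , 1]
    mu_lo[i] <- mu_lower_bound(Mw, blocks, upper = max(mu_up[i], 1e-12),
                               n_sweeps = 0)$lower
  }
  mu_rp <- mu_up[ipk]
  structure(list(freq = data.frame(omega = om, mu_upper = mu_up,
                                   mu_lower = mu_lo),
                 mu_rp = mu_rp, verdict = mu_rp < 1,
                 peak_omega = om[ipk],
                 bound_gap = if (is.na(mu_lo[ipk])) NA_real_
                             else mu_rp - mu_lo[ipk]),
            class = "mu_result")
}

#' @export
print.mu_result <- function(x, ...) {
  cat(sprintf("mu_RP = %.4f (%s) at omega = %.4g; bound gap %.3g\n",
              x$mu_rp, if (x$verdict) "robust" else "not robust",
              x$peak_omega, x$bound_gap))
  invisible(x)
}

#' Sampling-based worst-case gain oracle
#'
#' Lower estimate of the worst-case weighted performance gain: samples
#' normalized real parameter perturbations (all hypercube vertices plus a
#' Latin hypercube), closes the parametric loop, and takes the largest
#' weighted H-infinity gain.  An unstable sample is reported as infinite
#' gain (a robust-performance failure).
#'
#' @param msys An `m_delta_system`.
#' @param n_samples Number of Latin-hypercube samples (in addition to the
#'   vertices and the nominal point).
#' @param seed Integer seed for the Latin hypercube.
#' @param omega Frequency grid for the gain evaluation.
#' @return List with `gain` (max weighted gain), `delta` (arg max) and
#'   `gains` (all sampled gains).
#' @export
worst_case_gain_oracle <- function(msys, n_samples = 200, seed = 1,
                                   omega = default_frequency_grid()) {
  stopifnot(n_samples >= 1)
  p <- sum(msys$blocks$kind == "real")
  samples <- matrix(0, 1, p)
  if (p >= 1 && p <= 10)
    samples <- rbind(samples, as.matrix(expand.grid(rep(list(c(-1, 1)), p))))
  if (n_samples > 0 && p >= 1) {
    set.seed(seed)
    samples <- rbind(samples, 2 * lhs::randomLHS(n_samples, p) - 1)
  }
  gains <- apply(samples, 1, function(d) {
    sys <- close_parametric_loop(msys, d)
    if (!nominal_stability_check(sys)) return(Inf)
    hinf_norm(sys, omega)
  })
  i <- which.max(gains)
  list(gain = gains[i], delta = samples[i, ], gains = gains)
}

#' Export a mu frequency sweep to CSV (`omega,mu_lower,mu_upper`)
#' @param result A `mu_result`.
#' @param path Output file.
#' @export
write_mu_csv <- function(result, path) {
  write.csv(result$freq[, c("omega", "mu_lower", "mu_upper")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}
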