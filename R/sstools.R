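#' Construct a linear time-invariant state-space model
#'
#' Minimal LTI container `dz/dt = A z + B v; w = C z + D v` used for the
#' linearized deviation models.
#'
#' @param A,B,C,D Real matrices with consistent dimensions.
#' @param operating_point Optional state vector the model was linearized at.
#' @return Object of class `ss_model`.
#' @export
ss_model <- function(A, B, C, D = NULL, operating_point = NULL) {
  A <- as.matrix(A); B <- as.matrix(B); C <- as.matrix(C)
  n <- nrow(A)
  if (is.null(D)) D <- matrix(0, nrow(C), ncol(B))
  D <- as.matrix(D)
  stopifnot(ncol(A) == n, nrow(B) == n, ncol(C) == n,
            nrow(D) == nrow(C), ncol(D) == ncol(B))
  structure(list(A = A, B = B, C = C, D = D,
                 operating_point = operating_point),
            class = "ss_model")
}

#' @export
print.ss_model <- function(x, ...) {
  cat("State-space model:", nrow(x$A), "states,", ncol(x$B), "input(s),",
      nrow(x$C), "output(s)\n")
  invisible(x)
}

#' Frequency response of a state-space model
#'
#' Evaluates `G(j w) = C (j w I - A)^-1 B + D` on a grid of angular
#' frequencies.
#'
#' @param sys An [ss_model()].
#' @param omega Numeric vector of angular frequencies (rad/time).
#' @return For single-input single-output systems, a complex vector; in
#'   general a `p x m x length(omega)` complex array.
#' @export
ss_freqresp <- function(sys, omega) {
  n <- nrow(sys$A)
  p <- nrow(sys$C); m <- ncol(sys$B)
  out <- array(0i, c(p, m, length(omega)))
  for (i in seq_along(omega)) {
    X <- solve(1i * omega[i] * diag(n) - sys$A, sys$B)
    out[, , i] <- sys$C %*% X + sys$D
  }
  if (p == 1 && m == 1) drop(out) else out
}

#' Steady-state (DC) gain
#' @param sys An [ss_model()].
#' @return `D - C A^-1 B`.
#' @export
ss_dcgain <- function(sys) sys$D - sys$C %*% solve(sys$A, sys$B)

#' H-infinity norm over a frequency grid
#'
#' Peak largest singular value of the frequency response over a grid (plus
#' the feedthrough at infinite frequency).  A grid estimate is a lower
#' approximation of the true norm; the default grid is dense enough for the
#' smooth low-order systems analyzed here.
#'
#' @param sys An [ss_model()].
#' @param omega Frequency grid; defaults to [default_frequency_grid()].
#' @return Peak gain (numeric).
#' @export
hinf_norm <- function(sys, omega = default_frequency_grid()) {
  p <- nrow(sys$C); m <- ncol(sys$B)
  if (p == 1 && m == 1) {
    # modal evaluation: one eigendecomposition, then O(n) per frequency
    ev <- tryCatch(eigen(sys$A), error = function(e) NULL)
    if (!is.null(ev) && rcond(ev$vectors) > 1e-12) {
      res <- drop(sys$C %*% ev$vectors) * drop(solve(ev$vectors, sys$B))
      g <- vapply(omega, function(w)
        Mod(sum(res / (1i * w - ev$values)) + sys$D[1, 1]), numeric(1))
      return(max(g, abs(sys$D[1, 1])))
    }
  }
  G <- ss_freqresp(sys, omega)
  g <- if (is.array(G) && length(dim(G)) == 3)
    vapply(seq_len(dim(G)[3]), function(i) max(svd(G[, , i])$d), numeric(1))
  else Mod(G)
  max(g, max(svd(sys$D)$d))
}

#' Default frequency grid for robustness analysis
#'
#' Zero frequency plus `n` logarithmically spaced points in
#' `[w_min, w_max]` rad/time.
#'
#' @param n Number of log-spaced points.
#' @param w_min,w_max Grid limits.
#' @return Numeric vector of angular frequencies.
#' @export
default_frequency_grid <- function(n = 120, w_min = 1e-4, w_max = 1e3) {
  c(0, 10 ^ seq(log10(w_min), log10(w_max), length.out = n))
}

#' Time response of a state-space model
#'
#' Response to a constant (step) input from an initial deviation state,
#' computed with the stiff ODE integrator.
#'
#' @param sys An [ss_model()].
#' @param times Output times.
#' @param u Constant input vector (length = number of inputs).
#' @param z0 Initial state (defaults to zero).
#' @return Matrix of outputs, one row per time.
#' @export
ss_step <- function(sys, times, u = rep(1, ncol(sys$B)), z0 = NULL) {
  n <- nrow(sys$A)
  if (is.null(z0)) z0 <- rep(0, n)
  u <- matrix(u, ncol = 1)
  fn <- function(t, z, p) list(drop(sys$A %*% z + sys$B %*% u))
  t_uniq <- unique(c(times[1], times))
  out <- deSolve::lsoda(as.numeric(z0), t_uniq, fn, NULL,
                        rtol = 1e-12, atol = 1e-14)
  z <- out[match(times, out[, 1]), -1, drop = FALSE]
  Y <- z %*% t(sys$C)
  sweep(Y, 2, drop(sys$D %*% u), `+`)
}

#' Difference (deviation) interconnection of two systems
#'
#' Parallel interconnection whose output is `y1 - y2` under a shared input:
#' the general form of a deviation model between a therapy branch and the
#' healthy branch.
#'
#' @param sys1,sys2 [ss_model()] objects with identical I/O dimensions.
#' @return An [ss_model()] with the stacked state.
#' @export
build_deviation_system <- function(sys1, sys2) {
  if (ncol(sys1$B) != ncol(sys2$B) || nrow(sys1$C) != nrow(sys2$C))
    stop("incompatible input/output dimensions")
  n1 <- nrow(sys1$A); n2 <- nrow(sys2$A)
  A <- rbind(cbind(sys1$A, matrix(0, n1, n2)),
             cbind(matrix(0, n2, n1), sys2$A))
  B <- rbind(sys1$B, sys2$B)
  C <- cbind(sys1$C, -sys2$C)
  D <- sys1$D - sys2$D
  ss_model(A, B, C, D)
}

#' Nominal stability check
#'
#' @param sys An [ss_model()].
#' @return `TRUE` iff every eigenvalue of `A` has negative real part.
#' @export
nominal_stability_check <- function(sys) {
  all(Re(eigen(sys$A, only.values = TRUE)$values) < 0)
}
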