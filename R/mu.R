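#' Describe a bounded uncertain parameter
#'
#' A parameter fluctuating in `[k_min, k_max]` is written
#' `k = k_mean (1 + r_k delta)` with `k_mean = (k_min + k_max)/2`,
#' `r_k = (k_max - k_min)/(k_max + k_min)` and a real normalized
#' perturbation `|delta| <= 1`.
#'
#' @param k_min,k_max Interval bounds, `0 < k_min <= k_max`.
#' @param name Optional parameter name.
#' @return An `uncertain_parameter`: list with `name`, `k_mean`, `r_k`.
#' @export
make_uncertain_parameter <- function(k_min, k_max, name = NULL) {
  if (k_min <= 0) stop("k_min must be positive")
  if (k_max < k_min) stop("k_max must be >= k_min")
  structure(list(name = name, k_mean = (k_min + k_max) / 2,
                 r_k = (k_max - k_min) / (k_max + k_min)),
            class = "uncertain_parameter")
}

#' Realize an uncertain parameter at a normalized perturbation
#' @param up An `uncertain_parameter`.
#' @param delta Real perturbation with `|delta| <= 1`.
#' @return `k_mean * (1 + r_k * delta)`.
#' @export
realize_parameter <- function(up, delta) {
  stopifnot(abs(delta) <= 1 + 1e-12)
  up$k_mean * (1 + up$r_k * delta)
}

#' Define the block structure of a Delta perturbation
#'
#' @param kinds Character vector: `"real"` (repeated real scalar block
#'   `delta I`) or `"complex"` (full square complex block).
#' @param dims Integer vector of block dimensions.
#' @param labels Optional block labels (parameter names, "performance").
#' @return A `block_structure` (data frame with one row per block).
#' @export
block_structure <- function(kinds, dims, labels = NULL) {
  stopifnot(length(kinds) == length(dims), all(kinds %in% c("real", "complex")),
            all(dims >= 1))
  if (is.null(labels)) labels <- paste0("block", seq_along(kinds))
  structure(data.frame(kind = kinds, dim = as.integer(dims),
                       label = labels, stringsAsFactors = FALSE),
            class = c("block_structure", "data.frame"))
}

# row/column index ranges of each block within Delta
block_indices <- function(blocks) {
  ends <- cumsum(blocks$dim)
  starts <- c(1L, head(ends, -1) + 1L)
  Map(seq.int, starts, ends)
}

# expand per-block values to the full Delta dimension
block_expand <- function(blocks, per_block) {
  rep(per_block, times = blocks$dim)
}

# ---------------------------------------------------------------------------
# upper bounds on mu

# complex-mu D-scaling bound: inf over block-diagonal D > 0 of
# sigma_max(D M D^-1); Perron-vector initialization, BFGS polish on log d.
mu_upper_complex <- function(M, blocks, maxit = 60) {
  nrm <- max(svd(M)$d)
  if (nrm == 0) return(0)
  nb <- nrow(blocks)
  if (nb == 1) return(nrm)
  idx <- block_indices(blocks)
  dims <- blocks$dim
  # Perron initialization on the matrix of inter-block gains
  P <- matrix(0, nb, nb)
  for (i in seq_len(nb)) for (j in seq_len(nb))
    P[i, j] <- max(svd(M[idx[[i]], idx[[j]], drop = FALSE])$d)
  P <- P + 1e-12 * nrm
  v <- abs(eigen(P)$vectors[, 1])
  w <- abs(eigen(t(P))$vectors[, 1])
  l0 <- 0.5 * (log(w) - log(v))
  l0 <- l0 - l0[nb]

  obj_env <- new.env()
  fobj <- function(l) {
    drep <- rep(exp(c(l, 0)), times = dims)
    X <- M * outer(drep, 1 / drep)
    sv <- svd(X, nu = 1, nv = 1)
    assign("last", list(X = X, sv = sv, drep = drep), envir = obj_env)
    sv$d[1]
  }
  gobj <- function(l) {
    e <- get("last", envir = obj_env)
    u <- e$sv$u[, 1]; v1 <- e$sv$v[, 1]
    Xv <- e$X %*% v1
    uX <- Conj(t(e$X) %*% Conj(u))      # (u^H X) as a column
    a <- Re(Conj(u) * Xv)               # u^H E_i X v contributions
    b <- Re(uX * v1)                    # u^H X E_i v contributions
    g <- vapply(seq_len(nb), function(i) sum(a[idx[[i]]]) -
                  sum(b[idx[[i]]]), numeric(1))
    g[-length(g)]
  }
  fit <- tryCatch(optim(l0[-nb], fobj, gobj, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-10)),
                  error = function(e) NULL)
  val <- min(nrm, if (is.null(fit)) fobj(l0[-nb]) else fit$value)
  attr(val, "logd") <- if (is.null(fit)) l0 else c(fit$par, 0)
  val
}

# mixed-mu D,G-scaling feasibility: beta is a certified upper bound iff
# there exist block-diagonal D > 0 (commuting with Delta) and Hermitian
# block-diagonal G (supported on the real blocks) with
#   M^H D M + i (G M - M^H G) - beta^2 D <= 0.
# The test minimizes the (scale-normalized) top eigenvalue over (log d, g)
# by BFGS with the analytic eigenvalue gradient, and certifies feasibility
# by an exact eigenvalue check at the minimizer.
mixed_feasible <- function(M, blocks, beta, init = NULL, maxit = 70) {
  nb <- nrow(blocks)
  idx <- block_indices(blocks)
  dims <- blocks$dim
  real_blocks <- which(blocks$kind == "real")
  npar <- nb + length(real_blocks)
  if (is.null(init)) init <- rep(0, npar)
  MH <- Conj(t(M))

  build_H <- function(par) {
    drep <- rep(exp(par[seq_len(nb)]), times = dims)
    g <- numeric(nb)
    g[real_blocks] <- par[nb + seq_along(real_blocks)]
    grep <- rep(g, times = dims)
    H <- MH %*% (drep * M) + 1i * (grep * M - t(t(MH) * grep)) -
      beta^2 * diag(drep)
    list(H = H, drep = drep, grep = grep)
  }
  env <- new.env()
  env$best <- list(val = Inf, par = init)
  clamp <- -0.05 * max(1, beta^2)   # plateau once clearly feasible
  fobj <- function(par) {
    if (any(!is.finite(par)) || max(abs(par)) > 500) return(1e6)
    b <- build_H(par)
    if (any(!is.finite(b$H))) return(1e6)
    ei <- eigen(b$H, symmetric = TRUE)
    assign("last", list(b = b, lam = ei$values[1], v = ei$vectors[, 1]),
           envir = env)
    val <- ei$values[1] / mean(b$drep)
    if (val < env$best$val) env$best <- list(val = val, par = par)
    max(val, clamp)
  }
  gobj <- function(par) {
    e <- get("last", envir = env)
    v <- e$v; lam <- e$lam
    s <- mean(e$b$drep)
    Mv <- M %*% v
    dl <- numeric(nb); dg <- numeric(length(real_blocks))
    N <- length(e$b$drep)
    d_per <- exp(par[seq_len(nb)])
    for (i in seq_len(nb)) {
      ii <- idx[[i]]
      dlam <- d_per[i] * (sum(Mod(Mv[ii])^2) - beta^2 * sum(Mod(v[ii])^2))
      ds <- d_per[i] * dims[i] / N
      dl[i] <- (dlam * s - lam * ds) / s^2
    }
    for (k in seq_along(real_blocks)) {
      ii <- idx[[real_blocks[k]]]
      a <- sum(Conj(v[ii]) * Mv[ii])
      dg[k] <- (-2 * Im(a)) / s
    }
    c(dl, dg)
  }
  tryCatch(optim(init, fobj, gobj, method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-12)),
           error = function(e) NULL)
  par <- env$best$par
  b <- build_H(par)
  lam <- eigen(b$H, symmetric = TRUE, only.values = TRUE)$values[1]
  list(feasible = lam <= 1e-9 * max(1, beta^2) * max(b$drep),
       par = par, lam = lam)
}

#' Upper bound on the structured singular value
#'
#' Computes a certified upper bound on `mu` of a complex matrix with
#' respect to a block structure of repeated real scalar and full complex
#' blocks.  The default is the mixed-mu D,G-scaling bound (bisection on
#' `beta`, with each candidate certified by an exact eigenvalue test);
#' `method = "complex"` gives the pure D-scaling bound, which treats the
#' real blocks as complex and is therefore more conservative but always an
#' upper bound.
#'
#' @param M Complex matrix (dimensions matching the structure).
#' @param blocks A [block_structure()].
#' @param method `"mixed"` (default) or `"complex"`.
#' @param tol_rel Relative bisection tolerance.
#' @return The bound, with attribute `complex_upper` (the D-only bound).
#' @export
mu_upper_bound <- function(M, blocks, method = c("mixed", "complex"),
                           tol_rel = 2e-3) {
  method <- match.arg(method)
  M <- as.matrix(M)
  n <- sum(blocks$dim)
  stopifnot(nrow(M) == n, ncol(M) == n)
  # normalize so the bound is exactly homogeneous: mu(aM) = |a| mu(M)
  scl <- max(svd(M)$d)
  if (scl == 0) {
    out <- 0
    attr(out, "complex_upper") <- 0
    return(out)
  }
  M <- M / scl
  cub <- mu_upper_complex(M, blocks)
  cval <- as.numeric(cub)
  if (method == "complex" || cval == 0 || !any(blocks$kind == "real")) {
    out <- cval * scl
    attr(out, "complex_upper") <- cval * scl
    return(out)
  }
  lo <- 0; hi <- cval
  init <- NULL
  for (it in 1:40) {
    if ((hi - lo) <= tol_rel * hi) break
    mid <- (hi + lo) / 2
    fs <- mixed_feasible(M, blocks, mid, init = init)
    if (fs$feasible) {
      hi <- mid
      init <- fs$par
    } else lo <- mid
  }
  out <- hi * scl
  attr(out, "complex_upper") <- cval * scl
  out
}

# ---------------------------------------------------------------------------
# lower bound on mu

# close the real blocks of an M-Delta matrix at Delta_r = diag(delta)/beta
# and return the remaining complex-channel matrix, or Inf-signal if the
# real loop itself is (nearly) singular.
close_real_blocks <- function(M, ridx, cidx, delta_rep, beta) {
  Dr <- delta_rep / beta
  M11 <- M[ridx, ridx, drop = FALSE]
  A <- diag(length(ridx)) - sweep(M11, 2, Dr, `*`)
  X <- tryCatch(solve(A, M[ridx, cidx, drop = FALSE]),
                error = function(e) NULL)
  if (is.null(X)) return(NULL)
  M[cidx, cidx, drop = FALSE] +
    sweep(M[cidx, ridx, drop = FALSE], 2, Dr, `*`) %*% X
}

#' Lower bound on the structured singular value, with witness
#'
#' A valid lower bound obtained by searching over the real perturbations
#' (vertex enumeration plus coordinate ascent) with the complex block closed
#' analytically: `beta` is a lower bound when some admissible `delta`
#' achieves `sigma_max(N_beta(delta)) >= beta`, where `N_beta` closes the
#' real blocks at `diag(delta)/beta`.  The returned witness `Delta` is
#' normalized (`||Delta|| <= 1`) and satisfies
#' `det(I - (1/mu_lower) M Delta) ~ 0`.
#'
#' Supports any number of repeated real scalar blocks and at most one full
#' complex block.
#'
#' @inheritParams mu_upper_bound
#' @param upper Optional known upper bound (search start).
#' @param n_sweeps Coordinate-ascent sweeps over the real direction after
#'   vertex enumeration (0 = vertices only, the cheap setting used inside
#'   frequency sweeps).
#' @return List with `lower` (numeric, >= 0) and `witness` (complex matrix).
#' @export
mu_lower_bound <- function(M, blocks, upper = NULL, n_sweeps = 2) {
  M <- as.matrix(M)
  # normalize for exact scaling homogeneity
  scl <- max(svd(M)$d)
  if (scl > 0 && abs(scl - 1) > 1e-12) {
    res <- mu_lower_bound(M / scl, blocks,
                          upper = if (is.null(upper)) NULL else upper / scl,
                          n_sweeps = n_sweeps)
    return(list(lower = res$lower * scl, witness = res$witness))
  }
  idx <- block_indices(blocks)
  rblk <- which(blocks$kind == "real")
  cblk <- which(blocks$kind == "complex")
  if (length(cblk) > 1)
    stop("lower bound supports at most one complex block")
  ridx <- unlist(idx[rblk])
  cidx <- unlist(idx[cblk])
  n <- sum(blocks$dim)
  zero_w <- matrix(0i, n, n)

  if (length(rblk) == 0) {
    sv <- svd(M)
    lb <- sv$d[1]
    W <- zero_w
    if (lb > 0) W[cidx, cidx] <- sv$v[, 1] %*% Conj(t(sv$u[, 1]))
    return(list(lower = lb, witness = W))
  }
  p <- length(rblk)

  if (length(cblk) == 0) {
    # purely real structure: vertex real-eigenvalue bound
    best <- 0; bestd <- rep(1, p)
    verts <- as.matrix(expand.grid(rep(list(c(-1, 1)), p)))
    for (r in seq_len(nrow(verts))) {
      drep <- block_expand(blocks, verts[r, ])
      ev <- eigen(sweep(M, 2, drep, `*`), only.values = TRUE)$values
      re <- Re(ev[abs(Im(ev)) <= 1e-9 * (abs(ev) + 1e-300)])
      re <- re[re > 0]
      if (length(re) && max(re) > best) { best <- max(re); bestd <- verts[r, ] }
    }
    W <- zero_w
    diag(W)[ridx] <- block_expand(blocks[rblk, , drop = FALSE], bestd)
    return(list(lower = best, witness = W))
  }

  # the achieved level of a fixed real direction delta: the largest beta
  # with sigma_max(N_beta(delta)) >= beta, where N_beta closes the real
  # blocks at diag(delta)/beta (a scalar fixed-point problem per direction)
  gfun <- function(delta, beta) {
    drep <- block_expand(blocks[rblk, , drop = FALSE], delta)
    N <- close_real_blocks(M, ridx, cidx, drep, beta)
    if (is.null(N)) return(Inf)
    max(svd(N)$d)
  }
  hi0 <- upper %||% max(svd(M)$d)
  if (hi0 <= 0) return(list(lower = 0, witness = zero_w))
  direction_mu <- function(delta) {
    cond <- function(beta) gfun(delta, beta) >= beta
    hi <- hi0 * (1 + 1e-9)
    if (cond(hi)) return(hi)
    bs <- exp(seq(log(1e-7 * hi0), log(hi), length.out = 25))
    ok <- vapply(bs, cond, logical(1))
    if (!any(ok)) return(0)
    lo <- max(bs[ok])
    above <- bs[!ok & bs > lo]
    if (length(above)) hi <- min(above)
    for (i in 1:30) {
      mid <- sqrt(lo * hi)
      if (cond(mid)) lo <- mid else hi <- mid
    }
    lo
  }
  # candidate directions: hypercube vertices (plus a coarse interior
  # lattice for small structures when ascent sweeps are enabled), then
  # coordinate ascent on the direction
  verts <- if (p <= 4 && n_sweeps > 0) {
    as.matrix(expand.grid(rep(list(c(-1, -0.5, 0, 0.5, 1)), p)))
  } else if (p <= 10) {
    as.matrix(expand.grid(rep(list(c(-1, 1)), p)))
  } else {  # large structures: axis patterns and the diagonal corners
    rbind(matrix(rep(c(-1, 1), each = p), 2, p, byrow = TRUE),
          diag(2, p) - 1, 1 - diag(2, p))
  }
  vals <- apply(verts, 1, direction_mu)
  beta_f <- max(vals)
  dbest <- verts[which.max(vals), ]
  gridv <- seq(-1, 1, length.out = 11)
  for (sweep_i in seq_len(n_sweeps)) for (j in seq_len(p)) {
    cand <- vapply(gridv, function(gv) {
      d <- dbest; d[j] <- gv; direction_mu(d)
    }, numeric(1))
    if (max(cand) > beta_f) {
      beta_f <- max(cand); dbest[j] <- gridv[which.max(cand)]
    }
  }
  if (beta_f <= 0) return(list(lower = 0, witness = zero_w))
  beta_f <- min(beta_f, hi0)
  # build the normalized witness at beta_f
  drep <- block_expand(blocks[rblk, , drop = FALSE], dbest)
  N <- close_real_blocks(M, ridx, cidx, drep, beta_f)
  W <- zero_w
  diag(W)[ridx] <- drep
  if (!is.null(N)) {
    sv <- svd(N)
    cval <- sv$d[1]
    if (cval > 0)
      W[cidx, cidx] <- (beta_f / cval) * sv$v[, 1] %*% Conj(t(sv$u[, 1]))
  }
  list(lower = beta_f, witness = W)
}
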