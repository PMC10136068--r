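#' Solver parameters for the one-step proximal-descent reconstruction
#'
#' Defaults follow the simulation-study settings: balance parameter
#' `t = 0.02`, step-size scaling `theta = 0.2`, per-material total-variation
#' weights `lam = c(1e-6, 1e-6, 1e-5)` (tissue, bone, iodine), 90 ordered
#' subsets and 100 outer iterations. `alpha` and `beta` are the proximal
#' penalties of the splitting; they must satisfy `alpha > beta > 0` and the
#' step-size constraint `c = 1 - t*beta*||lam K||^2 / (2*alpha) >= 0`.
#'
#' @param alpha,beta Proximal penalty parameters, `alpha > beta > 0`.
#' @param t Balance between current and proximal points in the midpoint
#'   update.
#' @param theta Adaptive step-size scaling in (0, 2).
#' @param lam Per-material regularization weights (length K, >= 0).
#' @param n_iter Maximum outer iterations.
#' @param n_subsets Ordered-subsets count for the inner sweeps.
#' @param relax Inner relaxation in (0, 1].
#' @param eps Relative-change stopping tolerance (0 disables early stop).
#' @param inner_passes Full ordered-subsets sweeps per proximal solve.
#' @return An `ipad_params` list (validated).
#' @export
ipad_params <- function(alpha = 0.1, beta = 0.05, t = 0.02, theta = 0.2,
                        lam = c(1e-6, 1e-6, 1e-5), n_iter = 100L,
                        n_subsets = 90L, relax = 1.0, eps = 0,
                        inner_passes = 1L) {
  if (!(alpha > beta && beta > 0)) stop("require alpha > beta > 0",
                                        call. = FALSE)
  if (!(theta > 0 && theta < 2)) stop("theta must lie in (0, 2)",
                                      call. = FALSE)
  if (any(lam < 0)) stop("lam must be non-negative", call. = FALSE)
  if (!(relax > 0 && relax <= 1)) stop("relax must lie in (0, 1]",
                                       call. = FALSE)
  p <- structure(list(alpha = alpha, beta = beta, t = t, theta = theta,
                      lam = lam, n_iter = as.integer(n_iter),
                      n_subsets = as.integer(n_subsets), relax = relax,
                      eps = eps, inner_passes = as.integer(inner_passes)),
                 class = "ipad_params")
  cc <- check_constant_c(p)
  if (!cc$valid) {
    stop(sprintf("parameter constraint violated: c = %.4g < 0", cc$c),
         call. = FALSE)
  }
  p
}

#' Step-size constraint constant
#'
#' `c = 1 - t * beta * ||lam K||^2 / (2 * alpha)`, evaluated with the
#' classical upper bound `||lam K||^2 <= 8 * max(lam)^2` for the 2-D forward
#' difference operator. Convergence of the solver requires `c >= 0`.
#'
#' @param params An [ipad_params()] (validation is skipped so invalid
#'   configurations can be inspected).
#' @return List with the value `c` and logical `valid`.
#' @export
check_constant_c <- function(params) {
  cval <- 1 - params$t * params$beta * op_norm_sq(params$lam) /
    (2 * params$alpha)
  list(c = cval, valid = cval >= 0)
}

#' Squared operator norm of the weighted gradient operator
#'
#' @param lam Per-material regularization weights.
#' @param grid_n Grid side for the power-iteration estimate.
#' @param method `"bound"` returns the classical bound `8 * max(lam)^2`;
#'   `"power"` runs power iteration on [grad_K()]/[grad_K_adjoint()], which is
#'   never larger than the bound.
#' @export
op_norm_sq <- function(lam, grid_n = 16L, method = c("bound", "power")) {
  method <- match.arg(method)
  if (method == "bound") return(8 * max(lam)^2)
  k <- length(lam)
  set.seed(7L)
  x <- array(stats::rnorm(grid_n * grid_n * k), dim = c(grid_n, grid_n, k))
  est <- 0
  for (it in 1:200) {
    g <- grad_K(x, lam)
    x2 <- grad_K_adjoint(g, lam)
    nrm <- sqrt(sum(x2^2))
    if (nrm == 0) return(0)
    est_new <- nrm / sqrt(sum(x^2))
    x <- x2 / nrm
    if (abs(est_new - est) < 1e-12 * max(est, 1)) { est <- est_new; break }
    est <- est_new
  }
  est
}

# forward difference with replicate (Neumann) boundary: last difference 0
fwd_diff_rows <- function(m) {
  d <- m * 0
  n <- nrow(m)
  d[seq_len(n - 1), ] <- m[2:n, ] - m[seq_len(n - 1), ]
  d
}
fwd_diff_cols <- function(m) {
  d <- m * 0
  n <- ncol(m)
  d[, seq_len(n - 1)] <- m[, 2:n] - m[, seq_len(n - 1)]
  d
}
# adjoints (negative divergence with matching boundary)
fwd_diff_rows_adj <- function(v) {
  n <- nrow(v)
  d <- v * 0
  d[1, ] <- -v[1, ]
  if (n > 2) d[2:(n - 1), ] <- v[seq_len(n - 2), ] - v[2:(n - 1), ]
  d[n, ] <- v[n - 1, ]
  d
}
fwd_diff_cols_adj <- function(v) {
  n <- ncol(v)
  d <- v * 0
  d[, 1] <- -v[, 1]
  if (n > 2) d[, 2:(n - 1)] <- v[, seq_len(n - 2)] - v[, 2:(n - 1)]
  d[, n] <- v[, n - 1]
  d
}

#' Weighted finite-difference (gradient) operator and its adjoint
#'
#' Forward differences per material and direction with replicate boundary;
#' each material channel is scaled by its regularization weight, folding the
#' per-material `lam` into the operator.
#'
#' @param b `n x n x K` material array (or `I x K` matrix).
#' @param lam Per-material weights (length K).
#' @return `grad_K()`: an `n x n x 2 x K` gradient field (directions: rows,
#'   columns). `grad_K_adjoint()`: an `n x n x K` array.
#' @export
grad_K <- function(b, lam) {
  if (is.matrix(b)) b <- material_images(b)
  d <- dim(b)
  stopifnot(length(lam) == d[3])
  g <- array(0, dim = c(d[1], d[2], 2, d[3]))
  for (k in seq_len(d[3])) {
    g[, , 1, k] <- lam[k] * fwd_diff_rows(b[, , k])
    g[, , 2, k] <- lam[k] * fwd_diff_cols(b[, , k])
  }
  g
}

#' @rdname grad_K
#' @param g `n x n x 2 x K` gradient field.
#' @export
grad_K_adjoint <- function(g, lam) {
  d <- dim(g)
  stopifnot(length(d) == 4, d[3] == 2, length(lam) == d[4])
  out <- array(0, dim = c(d[1], d[2], d[4]))
  for (k in seq_len(d[4])) {
    out[, , k] <- lam[k] * (fwd_diff_rows_adj(g[, , 1, k]) +
                            fwd_diff_cols_adj(g[, , 2, k]))
  }
  out
}

#' Soft-shrinkage (proximal operator of the l1 norm)
#'
#' Elementwise `sign(v) * max(|v| - r, 0)`.
#' @param v Numeric array.
#' @param r Non-negative threshold.
#' @export
shrink <- function(v, r) {
  if (r < 0) stop("threshold must be non-negative", call. = FALSE)
  sign(v) * pmax(abs(v) - r, 0)
}

# ---------------------------------------------------------------------------
# ordered-subsets context: per-subset operators and normalizations cached
# once per reconstruction
# ---------------------------------------------------------------------------
make_os_context <- function(A, n_subsets) {
  geom <- A$geometry
  idx <- os_subsets(geom, n_subsets)
  subs <- lapply(idx, function(j) {
    At_s <- A$At[, j, drop = FALSE]
    cs <- Matrix::rowSums(At_s)
    list(rays = j, At = At_s, row_sums = A$row_sums[j],
         inv_col_sums = ifelse(cs > 0, 1 / cs, 0))
  })
  list(subsets = subs, n_subsets = length(subs))
}

# Vectorized per-ray solve of the K x K linearized spectral system
# W_j dt_j = r_j (rows = bins) for S = K = 3, via cofactor expansion.
# Rays with a near-singular system get a zero correction.
solve3_per_ray <- function(W, R) {
  a <- W[[1]][, 1]; b <- W[[1]][, 2]; c <- W[[1]][, 3]
  d <- W[[2]][, 1]; e <- W[[2]][, 2]; f <- W[[2]][, 3]
  g <- W[[3]][, 1]; h <- W[[3]][, 2]; i <- W[[3]][, 3]
  A11 <- e * i - f * h; A12 <- c * h - b * i; A13 <- b * f - c * e
  A21 <- f * g - d * i; A22 <- a * i - c * g; A23 <- c * d - a * f
  A31 <- d * h - e * g; A32 <- b * g - a * h; A33 <- a * e - b * d
  det <- a * A11 + b * A21 + c * A31
  scale <- (abs(a) + abs(e) + abs(i))^3 + 1e-300
  inv <- ifelse(abs(det) > 1e-10 * scale, 1 / det, 0)
  r1 <- R[, 1]; r2 <- R[, 2]; r3 <- R[, 3]
  cbind((A11 * r1 + A12 * r2 + A13 * r3) * inv,
        (A21 * r1 + A22 * r2 + A23 * r3) * inv,
        (A31 * r1 + A32 * r2 + A33 * r3) * inv)
}

# material path-length corrections for one subset: exact per-ray inversion
# of the linearized spectral system when S = K = 3, damped normal equations
# otherwise
material_corrections <- function(bp, pm_sub, spectra, n_mat) {
  ns_bins <- nrow(spectra$S)
  R <- t(pm_sub) - bp$p                       # J x S residuals
  if (ns_bins == 3L && n_mat == 3L) {
    return(solve3_per_ray(bp$W, R))
  }
  # general case: ridge-stabilized least squares per ray, averaged over bins
  corr <- matrix(0, nrow(R), n_mat)
  den <- matrix(0, nrow(R), n_mat)
  for (s in seq_len(ns_bins)) {
    W <- bp$W[[s]]
    corr <- corr + W * R[, s]
    den <- den + W * W
  }
  corr / pmax(den, 1e-300)
}

# one ordered-subsets ESART sweep over all subsets (data updates only);
# mutates and returns u (I x K). pm is the measured S x J matrix.
os_sweep <- function(u, pm, ctx, spectra, mu, relax, prox = NULL,
                     clamp = TRUE) {
  for (sub in ctx$subsets) {
    tvals <- as.matrix(Matrix::crossprod(sub$At, u))
    bp <- bin_projections(tvals, spectra, mu, want_weights = TRUE)
    dt <- material_corrections(bp, pm[, sub$rays, drop = FALSE], spectra,
                               ncol(u))
    corr <- dt * ifelse(sub$row_sums > 0, 1 / sub$row_sums, 0)
    u <- u + relax * as.matrix(sub$At %*% corr) * sub$inv_col_sums
    if (!is.null(prox)) {
      u <- (u + prox$w * prox$center) / (1 + prox$w)
    }
    if (clamp) u[u < 0] <- 0
  }
  u
}

#' Approximate resolvent of the data fidelity (ordered-subsets ESART)
#'
#' Solves `argmin_u G(u) + (alpha/2) ||u - center||^2` approximately:
#' starting from `center`, each ordered-subsets pass linearizes the
#' polychromatic model around the current iterate, solves each ray's
#' linearized spectral system for material path-length corrections
#' (exactly when bins = materials = 3, by damped least squares otherwise),
#' distributes them over pixels with SART normalization, pulls the iterate
#' toward the proximal center with weight `relax/n_subsets * alpha`, and
#' clamps to non-negative coefficients. A divergence guard halves the relaxation and
#' restarts if the iterate norm grows more than tenfold within one pass.
#'
#' @param center Proximal center, `I x K` matrix.
#' @param data Measured [sinogram()].
#' @param A System matrix.
#' @param spectra,table Spectral model shared with the simulation.
#' @param params An [ipad_params()].
#' @param ctx Optional precomputed subset context (internal reuse).
#' @param u0 Inner-iterate initializer; defaults to `center`. The outer
#'   solver warm-starts this with the previous iteration's proximal point,
#'   which is what makes a one-pass sweep an accurate resolvent: the exact
#'   minimizer does not depend on the initializer, and warm starting lets
#'   inner progress accumulate across outer iterations.
#' @return `I x K` matrix.
#' @export
esart_prox <- function(center, data, A, spectra, table, params, ctx = NULL,
                       u0 = NULL) {
  if (is.null(ctx)) ctx <- make_os_context(A, params$n_subsets)
  relax <- params$relax
  for (attempt in 1:4) {
    u <- if (is.null(u0)) center else u0
    prox <- list(w = relax / ctx$n_subsets * params$alpha, center = center)
    ok <- TRUE
    for (pass in seq_len(params$inner_passes)) {
      n0 <- sqrt(sum(u^2))
      u <- os_sweep(u, data$p, ctx, spectra, table$mu, relax, prox = prox)
      n1 <- sqrt(sum(u^2))
      # growth guard; the first pass from an all-zero start sets the scale
      if (!is.finite(n1) || (n0 > 0 && n1 > 10 * max(n0, 1))) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(u)
    relax <- relax / 2
  }
  stop("inner ESART sweeps diverged; reduce the relaxation parameter",
       call. = FALSE)
}

#' One proximal step of the splitting
#'
#' Computes the proximal point `u` via [esart_prox()] with center
#' `b - (1/alpha) K^T lam y`, the midpoint `y_hat = (1 - t) b + t u`, and the
#' shrunk dual surrogate `v = shrink(lam K y_hat + y / beta, 1 / beta)`.
#'
#' @param b Current `I x K` iterate.
#' @param y Current dual gradient field (`n x n x 2 x K`).
#' @inheritParams esart_prox
#' @param u0 Optional warm start for the inner solve (see [esart_prox()]).
#' @return List `u`, `y_hat` (both `I x K`) and `v` (gradient field).
#' @export
proximal_step <- function(b, y, data, A, spectra, table, params, ctx = NULL,
                          u0 = NULL) {
  n <- A$geometry$grid_n
  k <- ncol(b)
  kty <- matrix(grad_K_adjoint(y, params$lam), n * n, k)
  center <- b - kty / params$alpha
  u <- esart_prox(center, data, A, spectra, table, params, ctx, u0 = u0)
  y_hat <- (1 - params$t) * b + params$t * u
  K_yhat <- grad_K(material_images(y_hat, grid_n = n), params$lam)
  v <- shrink(K_yhat + y / params$beta, 1 / params$beta)
  list(u = u, y_hat = y_hat, v = v)
}

#' Adaptive descent step
#'
#' Builds the primal/dual descent directions
#' `d1 = alpha (b - u) + beta K^T lam (lam K y_hat - v)`,
#' `d2 = v - lam K u`, the adaptive step size
#' `gamma = theta * (alpha ||b - u||^2 + beta <lam K b - v, lam K y_hat - v>)
#'  / (||d1||^2 + ||d2||^2)`, and the updated iterates `b - gamma d1`,
#' `y - gamma d2`. A zero denominator signals a fixed point (`converged`);
#' a negative step is clamped to zero and flagged.
#'
#' @param b,y Current iterates.
#' @param u,y_hat,v Results of [proximal_step()] at the same iteration.
#' @param params An [ipad_params()].
#' @return List `b`, `y`, `gamma`, `converged`, `clamped`, and the direction
#'   norms `d1_norm`, `d2_norm`.
#' @export
descent_step <- function(b, y, u, y_hat, v, params) {
  n <- as.integer(round(sqrt(nrow(b))))
  lam <- params$lam
  K_yhat <- grad_K(material_images(y_hat, grid_n = n), lam)
  K_b <- grad_K(material_images(b, grid_n = n), lam)
  K_u <- grad_K(material_images(u, grid_n = n), lam)
  d1 <- params$alpha * (b - u) +
    params$beta * matrix(grad_K_adjoint(K_yhat - v, lam), nrow(b), ncol(b))
  d2 <- v - K_u
  d1n <- sqrt(sum(d1^2)); d2n <- sqrt(sum(d2^2))
  den <- d1n^2 + d2n^2
  if (den == 0) {
    return(list(b = b, y = y, gamma = 0, converged = TRUE, clamped = FALSE,
                d1_norm = 0, d2_norm = 0))
  }
  num <- params$alpha * sum((b - u)^2) +
    params$beta * sum((K_b - v) * (K_yhat - v))
  gamma <- params$theta * num / den
  clamped <- FALSE
  if (gamma < 0) { gamma <- 0; clamped <- TRUE }
  list(b = b - gamma * d1, y = y - gamma * d2, gamma = gamma,
       converged = FALSE, clamped = clamped, d1_norm = d1n, d2_norm = d2n)
}

per_material_rmse <- function(bmat, truth_mat) {
  vapply(seq_len(ncol(bmat)),
         function(k) sqrt(mean((bmat[, k] - truth_mat[, k])^2)), numeric(1))
}

#' One-step multi-material reconstruction (iterative proximal adaptive
#' descent)
#'
#' Alternates the proximal step ([proximal_step()]) and the adaptive descent
#' step ([descent_step()]) from zero initial images and zero dual variable,
#' recording per-iteration objective, fidelity, total-variation value, step
#' size, relative change and (when ground truth is supplied) per-material
#' RMSE. Deterministic given its inputs.
#'
#' @param data Measured multi-bin [sinogram()].
#' @param A System matrix matching the data geometry.
#' @param spectra,table Spectral model.
#' @param params An [ipad_params()]; the constraint `c >= 0` is enforced.
#' @param truth Optional [material_images()] ground truth for error
#'   tracking.
#' @param verbose Print a one-line progress summary every 10 iterations.
#' @return An `ipad_fit`: `b` (reconstructed [material_images()]), `history`
#'   (data frame of iteration records), `params`, `converged`.
#' @export
ipad_run <- function(data, A, spectra, table, params = ipad_params(),
                     truth = NULL, verbose = FALSE) {
  cc <- check_constant_c(params)
  if (!cc$valid) stop("parameter constraint c >= 0 violated", call. = FALSE)
  geom <- A$geometry
  n <- geom$grid_n
  k <- ncol(table$mu)
  ctx <- make_os_context(A, params$n_subsets)
  b <- matrix(0, n * n, k)
  y <- array(0, dim = c(n, n, 2, k))
  truth_mat <- if (!is.null(truth)) coef_matrix(truth) else NULL
  hist <- vector("list", params$n_iter)
  converged <- FALSE
  u_warm <- NULL
  for (it in seq_len(params$n_iter)) {
    ps <- proximal_step(b, y, data, A, spectra, table, params, ctx,
                        u0 = u_warm)
    u_warm <- ps$u
    ds <- descent_step(b, y, ps$u, ps$y_hat, ps$v, params)
    b_prev <- b
    b <- ds$b; y <- ds$y
    nprev <- sqrt(sum(b_prev^2))
    rel <- if (nprev > 0) sqrt(sum((b - b_prev)^2)) / nprev else NA_real_
    fid <- fidelity(material_images(b, grid_n = n), A, spectra, table, data)
    tv <- sum(abs(grad_K(material_images(b, grid_n = n), params$lam)))
    rec <- data.frame(iter = it, objective = fid + tv, fidelity = fid,
                      tv = tv, gamma = ds$gamma, d1_norm = ds$d1_norm,
                      d2_norm = ds$d2_norm, rel_change = rel)
    if (!is.null(truth_mat)) {
      rm <- per_material_rmse(b, truth_mat)
      rec$rmse_total <- sqrt(mean((b - truth_mat)^2))
      for (j in seq_len(k)) rec[[paste0("rmse_", j)]] <- rm[j]
    }
    hist[[it]] <- rec
    if (verbose && it %% 10 == 0) {
      message(sprintf("iter %3d  obj %.6g  gamma %.3g  rel %.3g",
                      it, rec$objective, ds$gamma, rel))
    }
    if (ds$converged || (params$eps > 0 && is.finite(rel) &&
                         rel <= params$eps)) {
      converged <- TRUE
      hist <- hist[seq_len(it)]
      break
    }
  }
  structure(list(b = material_images(b, grid_n = n,
                                     materials = colnames(table$mu)),
                 history = do.call(rbind, hist), params = params,
                 converged = converged),
            class = "ipad_fit")
}

#' @export
print.ipad_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<ipad_fit> %d iterations, final objective %.6g%s\n",
              nrow(h), h$objective[nrow(h)],
              if ("rmse_total" %in% names(h))
                sprintf(", total RMSE %.3g", h$rmse_total[nrow(h)]) else ""))
  invisible(x)
}
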