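#' Image-domain decomposition baseline (FBP + direct matrix inversion)
#'
#' Reconstructs each energy bin's log sinogram by filtered backprojection
#' into an effective attenuation image, then inverts the bin-mean
#' attenuation matrix ([bin_mean_mu()] at zero material images) pixel by
#' pixel. No regularization and no clamping are applied, so the
#' characteristic noise amplification and beam-hardening residual of
#' image-domain decomposition are fully visible.
#'
#' @param sinos Measured multi-bin [sinogram()] (S bins; requires S = K).
#' @param geom The acquisition [scan_geometry()].
#' @param spectra,table Spectral model (defines the decomposition matrix).
#' @param filter FBP filter, see [fbp()].
#' @return A [material_images()] stack with the decomposition matrix and its
#'   condition number attached as attributes.
#' @export
direct_decompose <- function(sinos, geom, spectra, table,
                             filter = c("hann", "ram-lak")) {
  filter <- match.arg(filter)
  s_bins <- nrow(sinos$p)
  k <- ncol(table$mu)
  if (s_bins != k) {
    stop("direct decomposition needs as many bins as materials", call. = FALSE)
  }
  M <- bin_mean_mu(spectra, table)
  cn <- kappa(M, exact = TRUE)
  if (!is.finite(cn) || cn > 1e12) {
    stop(sprintf("decomposition matrix is singular (condition number %.3g)",
                 cn), call. = FALSE)
  }
  n <- geom$grid_n
  f <- vapply(seq_len(s_bins),
              function(s) as.numeric(fbp(geom, sino_bin(sinos, s), filter)),
              numeric(n * n))
  b <- t(solve(M, t(f)))
  out <- material_images(b, materials = table$names, grid_n = n)
  attr(out, "decomposition_matrix") <- M
  attr(out, "condition_number") <- cn
  out
}

#' Ordered-subsets ESART baseline (unregularized one-step reconstruction)
#'
#' Iterates the linearized SART data-update sweeps of [esart_prox()] only --
#' no proximal pull, no total-variation term, no descent step -- from zero
#' initial images, with the same subset ordering and relaxation as the
#' regularized solver. On noisy data this baseline exhibits the classical
#' semi-convergence of unregularized algebraic methods.
#'
#' @inheritParams ipad_run
#' @return An `ipad_fit`-like object with `b` and an RMSE `history`.
#' @export
osesart_run <- function(data, A, spectra, table, params = ipad_params(),
                        truth = NULL, verbose = FALSE) {
  geom <- A$geometry
  n <- geom$grid_n
  k <- ncol(table$mu)
  ctx <- make_os_context(A, params$n_subsets)
  b <- matrix(0, n * n, k)
  truth_mat <- if (!is.null(truth)) coef_matrix(truth) else NULL
  hist <- vector("list", params$n_iter)
  relax <- params$relax
  for (it in seq_len(params$n_iter)) {
    n0 <- sqrt(sum(b^2))
    b_new <- os_sweep(b, data$p, ctx, spectra, table$mu, relax, prox = NULL)
    if (n0 > 0 && sqrt(sum(b_new^2)) > 10 * max(n0, 1) && relax > 2^-4) {
      relax <- relax / 2
      next
    }
    rel <- sqrt(sum((b_new - b)^2)) / max(n0, 1e-300)
    b <- b_new
    rec <- data.frame(iter = it, rel_change = rel)
    if (!is.null(truth_mat)) {
      rm <- per_material_rmse(b, truth_mat)
      rec$rmse_total <- sqrt(mean((b - truth_mat)^2))
      for (j in seq_len(k)) rec[[paste0("rmse_", j)]] <- rm[j]
    }
    hist[[it]] <- rec
    if (verbose && it %% 10 == 0) {
      message(sprintf("osesart iter %3d  rel %.3g", it, rel))
    }
  }
  structure(list(b = material_images(b, grid_n = n,
                                     materials = colnames(table$mu)),
                 history = do.call(rbind, hist), params = params,
                 converged = FALSE),
            class = "ipad_fit")
}

#' Virtual monochromatic image synthesis
#'
#' Combines reconstructed material images with their attenuation curves at a
#' single requested energy: `f_E = sum_k mu_k(E) * b_k` (1/mm).
#'
#' @param b A [material_images()] stack.
#' @param table Matching [builtin_attenuation_table()].
#' @param energy Energy in keV within the table's grid range.
#' @return `n x n` attenuation image (1/mm).
#' @export
monochromatic_image <- function(b, table, energy) {
  e <- table$grid$energies
  if (energy < min(e) || energy > max(e)) {
    stop("energy outside the attenuation table range", call. = FALSE)
  }
  mu_e <- vapply(seq_len(ncol(table$mu)),
                 function(k) stats::approx(e, table$mu[, k], xout = energy)$y,
                 numeric(1))
  n <- dim(b)[1]
  matrix(coef_matrix(b) %*% mu_e, n, n)
}
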