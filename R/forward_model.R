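#' Stack of basis-material images
#'
#' Material images are stored as an `n x n x K` array of dimensionless basis
#' coefficients (1.0 = the material's reference density/concentration).
#'
#' @param b `n x n x K` array, or `I x K` matrix plus `grid_n`.
#' @param materials Optional material labels.
#' @param grid_n Grid side, required when `b` is an `I x K` matrix.
#' @return A `material_images` array.
#' @export
material_images <- function(b, materials = NULL, grid_n = NULL) {
  if (is.matrix(b)) {
    if (is.null(grid_n)) grid_n <- as.integer(round(sqrt(nrow(b))))
    stopifnot(grid_n * grid_n == nrow(b))
    b <- array(b, dim = c(grid_n, grid_n, ncol(b)))
  }
  stopifnot(is.array(b), length(dim(b)) == 3L, dim(b)[1] == dim(b)[2])
  if (!is.null(materials)) dimnames(b) <- list(NULL, NULL, materials)
  structure(b, class = c("material_images", "array"))
}

#' @export
print.material_images <- function(x, ...) {
  d <- dim(x)
  nm <- dimnames(x)[[3]]
  cat(sprintf("<material_images> %d x %d x %d%s; range [%.4g, %.4g]\n",
              d[1], d[2], d[3],
              if (is.null(nm)) "" else paste0(" (", paste(nm, collapse = ", "), ")"),
              min(x), max(x)))
  invisible(x)
}

# canonical I x K coefficient matrix view
coef_matrix <- function(b) {
  d <- dim(b)
  matrix(b, d[1] * d[2], d[3])
}

n_materials <- function(b) dim(b)[3]

#' Multi-bin log-domain sinogram container
#'
#' @param p `S bins x J rays` matrix of negative-log projections (view-major
#'   ray ordering).
#' @param geom The [scan_geometry()] the rays belong to.
#' @param meta Optional provenance list (spectra fingerprint, noise model).
#' @export
sinogram <- function(p, geom, meta = list()) {
  stopifnot(is.matrix(p), inherits(geom, "scan_geometry"),
            ncol(p) == geom$n_views * geom$n_det)
  structure(list(p = p, geom = geom, meta = meta), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d bins x %d rays (%d views x %d det)\n",
              nrow(x$p), ncol(x$p), x$geom$n_views, x$geom$n_det))
  invisible(x)
}

#' Extract one bin of a sinogram as a views x detectors matrix
#' @param sino A [sinogram()].
#' @param s Bin index.
#' @export
sino_bin <- function(sino, s) {
  g <- sino$geom
  t(matrix(sino$p[s, ], g$n_det, g$n_views))
}

# Stable weighted log-sum-exp over energies.
# tvals: J x K material path lengths; mu: M x K; returns list with
#   xmat  J x M exponents (sum_k mu_mk * t_jk)
#   E     J x M exp(-(x - rowmin)) and rowmin for reuse
ray_exponents <- function(tvals, mu) {
  X <- tvals %*% t(mu)
  xmin <- X[, 1]
  m <- ncol(X)
  if (m > 1) for (j in 2:m) xmin <- pmin(xmin, X[, j])
  E <- exp(-(X - xmin))
  list(E = E, xmin = xmin)
}

# per-bin log projections and linearization weights from ray path lengths
bin_projections <- function(tvals, spectra, mu, want_weights = FALSE) {
  ex <- ray_exponents(tvals, mu)
  ns <- nrow(spectra$S)
  p <- matrix(0, nrow(tvals), ns)
  W <- if (want_weights) vector("list", ns) else NULL
  for (s in seq_len(ns)) {
    den <- as.numeric(ex$E %*% spectra$S[s, ])
    if (any(den <= 0)) stop("spectral denominator underflow", call. = FALSE)
    p[, s] <- ex$xmin - log(den)
    if (want_weights) {
      W[[s]] <- (ex$E %*% (spectra$S[s, ] * mu)) / den
    }
  }
  list(p = p, W = W)
}

#' Polychromatic forward projection
#'
#' Evaluates the nonlinear multi-energy measurement model: for bin `s` and
#' ray `j`,
#' `p[s, j] = -log( sum_m S[s, m] * exp(-sum_k mu[m, k] * (A b_k)_j) )`.
#' The material path lengths `A b_k` are computed once per material and
#' reused across bins and energies.
#'
#' @param b [material_images()] with K matching the attenuation table.
#' @param A A [build_system_matrix()].
#' @param spectra A [make_spectrum()] result.
#' @param table A [builtin_attenuation_table()] on the same grid.
#' @return A [sinogram()] of modeled log projections.
#' @export
poly_project <- function(b, A, spectra, table) {
  if (!all(is.finite(b))) stop("non-finite material images", call. = FALSE)
  if (n_materials(b) != ncol(table$mu)) {
    stop("material count of b does not match the attenuation table",
         call. = FALSE)
  }
  tvals <- forward(A, coef_matrix(b))
  bp <- bin_projections(tvals, spectra, table$mu)
  sinogram(t(bp$p), A$geometry,
           meta = list(thresholds = spectra$thresholds))
}

#' Linearization weights of the polychromatic model
#'
#' The partial derivative of the log projection with respect to the material
#' path length: a spectrum-weighted effective attenuation that depends on the
#' current images through beam hardening,
#' `w[s, j, k] = sum_m S[s,m] e^{-x_jm} mu[m,k] / sum_m S[s,m] e^{-x_jm}`.
#' At `b = 0` this reduces to [bin_mean_mu()]; for a single-energy bin it is
#' the attenuation at that energy, independent of `b`. Exponentials are
#' evaluated with per-ray max subtraction.
#'
#' @inheritParams poly_project
#' @return `S x J x K` array.
#' @export
linearization_weights <- function(b, A, spectra, table) {
  tvals <- forward(A, coef_matrix(b))
  bp <- bin_projections(tvals, spectra, table$mu, want_weights = TRUE)
  ns <- nrow(spectra$S)
  k <- ncol(table$mu)
  out <- array(0, dim = c(ns, nrow(tvals), k))
  for (s in seq_len(ns)) out[s, , ] <- bp$W[[s]]
  out
}

#' Data-fidelity value of the one-step model
#'
#' `G(b) = 0.5 * || P(b) - PM ||_2^2` over all bins and rays.
#'
#' @inheritParams poly_project
#' @param pm Measured [sinogram()].
#' @export
fidelity <- function(b, A, spectra, table, pm) {
  stopifnot(inherits(pm, "sinogram"))
  pb <- poly_project(b, A, spectra, table)
  if (!all(dim(pb$p) == dim(pm$p))) stop("sinogram shape mismatch",
                                         call. = FALSE)
  0.5 * sum((pb$p - pm$p)^2)
}

#' Gradient of the data fidelity
#'
#' Backprojects the linearization-weighted residual:
#' `dG/db_k = A^T sum_s w[s, , k] * (p_s(b) - pm_s)`.
#'
#' @inheritParams fidelity
#' @return `I x K` gradient matrix.
#' @export
fidelity_grad <- function(b, A, spectra, table, pm) {
  tvals <- forward(A, coef_matrix(b))
  bp <- bin_projections(tvals, spectra, table$mu, want_weights = TRUE)
  acc <- matrix(0, nrow(tvals), ncol(table$mu))
  for (s in seq_len(nrow(spectra$S))) {
    res <- bp$p[, s] - pm$p[s, ]
    acc <- acc + bp$W[[s]] * res
  }
  backproject(A, acc)
}

#' Poisson noise model for photon-counting measurements
#'
#' @param I0 Incident photon count per ray per bin.
#' @param seed RNG seed making the injection reproducible.
#' @export
noise_model <- function(I0, seed = 1L) {
  if (!is.numeric(I0) || I0 <= 0) stop("I0 must be positive", call. = FALSE)
  structure(list(I0 = I0, seed = as.integer(seed)), class = "noise_model")
}

# Poisson sampler that stays exact for moderate intensities and switches to
# the Gaussian limit where counts would overflow integer storage
rpois_large <- function(lambda) {
  out <- numeric(length(lambda))
  big <- lambda > 1e8
  if (any(!big)) out[!big] <- stats::rpois(sum(!big), lambda[!big])
  if (any(big)) out[big] <- round(stats::rnorm(sum(big), lambda[big],
                                               sqrt(lambda[big])))
  out
}

#' Inject Poisson counting noise into a clean sinogram
#'
#' Transmission counts are drawn per ray and per bin as
#' `c ~ Poisson(I0 * exp(-p))`, independently across bins, and returned to
#' the log domain as `-log(max(c, 1) / I0)` (zero counts are clamped to one
#' photon so the projection stays finite).
#'
#' @param clean A [sinogram()] of noise-free log projections.
#' @param noise A [noise_model()].
#' @return A [sinogram()] with the noise model echoed into `meta`.
#' @export
add_poisson_noise <- function(clean, noise) {
  stopifnot(inherits(clean, "sinogram"), inherits(noise, "noise_model"))
  if (!all(is.finite(clean$p))) stop("non-finite clean sinogram", call. = FALSE)
  lambda <- noise$I0 * exp(-clean$p)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(noise$seed)
  counts <- matrix(rpois_large(as.numeric(lambda)), nrow(clean$p))
  noisy <- -log(pmax(counts, 1) / noise$I0)
  sinogram(noisy, clean$geom,
           meta = c(clean$meta, list(I0 = noise$I0, seed = noise$seed)))
}
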