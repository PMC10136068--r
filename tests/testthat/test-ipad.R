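test_that("weighted gradient operator and adjoint are exact partners", {
  lam <- c(1e-6, 1e-6, 1e-5)
  # constant image has zero gradient under the replicate boundary
  const <- material_images(array(3.7, c(16, 16, 3)))
  expect_equal(max(abs(grad_K(const, lam))), 0)
  # adjoint identity <Kx, g> = <x, K^T g>
  set.seed(31)
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  g <- array(rnorm(16 * 16 * 2 * 3), c(16, 16, 2, 3))
  lhs <- sum(grad_K(x, lam) * g)
  rhs <- sum(x * grad_K_adjoint(g, lam))
  expect_lt(abs(lhs - rhs) / max(abs(lhs), 1e-300), 1e-10)
  # a zero weight silences that material's channel
  g0 <- grad_K(x, c(0, 1, 1))
  expect_equal(max(abs(g0[, , , 1])), 0)
})

test_that("operator-norm bound dominates the power-iteration estimate and
           the dense spectral norm", {
  expect_equal(op_norm_sq(c(1, 1, 1)), 8)
  expect_equal(op_norm_sq(c(1e-6, 1e-6, 1e-5)), 8e-10)
  est <- op_norm_sq(1, grid_n = 16, method = "power")
  expect_lte(est, 8)
  # dense oracle: assemble the 512 x 256 forward-difference operator
  # column by column and take its largest singular value
  D <- vapply(seq_len(256), function(i) {
    e <- matrix(0, 16, 16); e[i] <- 1
    as.numeric(grad_K(material_images(array(e, c(16, 16, 1))), 1))
  }, numeric(512))
  s1 <- max(svd(D)$d)^2
  expect_lt(abs(est - s1) / s1, 0.05)
  expect_lte(s1, 8 + 1e-12)
})

test_that("soft shrinkage matches its closed form", {
  expect_equal(shrink(0, 0.3), 0)
  expect_equal(shrink(0.5, 0.2), 0.3, tolerance = 1e-15)
  expect_equal(shrink(-0.1, 0.2), 0)
  expect_equal(shrink(-0.9, 0.2), -0.7, tolerance = 1e-15)
  set.seed(32)
  v <- array(rnorm(40), c(2, 5, 2, 2))
  expect_equal(shrink(v, 0), v)
  expect_equal(shrink(v, 0.4), sign(v) * pmax(abs(v) - 0.4, 0))
  expect_error(shrink(v, -1), "non-negative")
})

test_that("the step-size constraint constant follows its formula", {
  p0 <- ipad_params(t = 0)
  expect_equal(check_constant_c(p0)$c, 1)
  # study parameters: c = 1 - 0.02 * 0.5 * 8e-10 / 2, indistinguishable from 1
  p <- ipad_params(alpha = 1, beta = 0.5, t = 0.02,
                   lam = c(1e-6, 1e-6, 1e-5))
  cc <- check_constant_c(p)
  expect_equal(cc$c, 1 - 0.02 * 0.5 * 8e-10 / 2, tolerance = 1e-15)
  expect_true(cc$valid)
  # constructed violation: t*beta*||K||^2/(2 alpha) = 2 -> c = -1
  bad <- structure(list(alpha = 1, beta = 0.5, t = 2 / (0.5 * 8 / 2),
                        theta = 0.2, lam = c(1, 1, 1)),
                   class = "ipad_params")
  ccb <- check_constant_c(bad)
  expect_equal(ccb$c, -1, tolerance = 1e-12)
  expect_false(ccb$valid)
  expect_error(ipad_params(t = 1e12, lam = c(1, 1, 1)), "constraint")
  expect_error(ipad_params(alpha = 0.4, beta = 0.5), "alpha > beta")
  expect_error(ipad_params(theta = 2.5), "theta")
})

test_that("the inner resolvent respects its fixed points", {
  m <- tiny_model()
  A <- disc_A64()
  ph <- disc_phantom64()
  truth <- spectralct:::coef_matrix(ph)
  sino <- poly_project(ph, A, m$spectra, m$table)
  pars <- ipad_params(n_subsets = 30, n_iter = 5)
  # consistent data with center at the truth: residuals vanish, iterate stays
  u <- esart_prox(truth, sino, A, m$spectra, m$table, pars)
  expect_lt(max(abs(u - truth)), 1e-10)
  # zero relaxation: no data update, no pull away from the center
  pars0 <- pars; pars0$relax <- 0
  set.seed(33)
  center <- truth + matrix(abs(rnorm(length(truth), sd = 0.05)), nrow(truth))
  u0 <- esart_prox(center, sino, A, m$spectra, m$table, pars0)
  expect_equal(u0, center)
})

test_that("single-bin single-material sweeps converge like a linear SART", {
  m <- tiny_model()
  A <- disc_A64()
  geom <- A$geometry
  n <- geom$grid_n
  cc <- (seq_len(n) - 0.5 - n / 2) * geom$pixel_size
  d2 <- outer(cc^2, cc^2, `+`)
  disc <- matrix(0, n, n); disc[d2 <= 12^2] <- 1
  grid <- m$grid
  sp1 <- one_hot_spectra(grid, match(60, grid$energies))
  tab1 <- builtin_attenuation_table("tissue", grid)
  b <- material_images(array(disc, c(n, n, 1)))
  sino <- poly_project(b, A, sp1, tab1)
  ctx <- spectralct:::make_os_context(A, 30)
  u <- matrix(0, n * n, 1)
  r0 <- sqrt(sum(sino$p^2))   # residual of the zero start
  for (pass in 1:10) {
    u <- spectralct:::os_sweep(u, sino$p, ctx, sp1, tab1$mu, relax = 1)
  }
  r10 <- sqrt(sum((poly_project(material_images(u, grid_n = n), A, sp1,
                                tab1)$p - sino$p)^2))
  expect_lt(r10, r0 / 100)
})

test_that("proximal step blends current and proximal points as prescribed", {
  m <- tiny_model()
  geom <- scan_geometry(300, 600, 30, 360, 128, 0.496, 32, 0.992)
  A <- cached_system_matrix("disc32", geom)
  ph <- material_images(array(0.3, c(32, 32, 3)))
  sino <- poly_project(ph, A, m$spectra, m$table)
  set.seed(34)
  b <- matrix(runif(32 * 32 * 3), 32 * 32, 3)
  y <- array(rnorm(32 * 32 * 2 * 3, sd = 0.01), c(32, 32, 2, 3))
  p1 <- ipad_params(t = 1, n_subsets = 10)
  s1 <- proximal_step(b, y, sino, A, m$spectra, m$table, p1)
  expect_equal(s1$y_hat, s1$u)
  p0 <- ipad_params(t = 1e-12, n_subsets = 10)   # t -> 0 keeps the iterate
  s0 <- proximal_step(b, y, sino, A, m$spectra, m$table, p0)
  expect_equal(s0$y_hat, b, tolerance = 1e-9)
  # dual surrogate: with y = 0 and beta = 1 it is the unit-threshold shrink
  pb <- ipad_params(beta = 1, alpha = 2, n_subsets = 10)
  sb <- proximal_step(b, array(0, dim(y)), sino, A, m$spectra, m$table, pb)
  Kyh <- grad_K(material_images(sb$y_hat, grid_n = 32), pb$lam)
  expect_equal(sb$v, shrink(Kyh, 1))
})

test_that("descent step honors its closed form, scales with theta, and
           detects fixed points", {
  lam <- c(0.3, 0.2)
  pars <- structure(list(alpha = 1, beta = 0.5, t = 0.5, theta = 0.2,
                         lam = lam), class = "ipad_params")
  set.seed(35)
  n <- 4
  b <- matrix(runif(n * n * 2), n * n, 2)
  u <- matrix(runif(n * n * 2), n * n, 2)
  y <- array(rnorm(n * n * 2 * 2), c(n, n, 2, 2))
  y_hat <- 0.5 * b + 0.5 * u
  v <- shrink(grad_K(material_images(y_hat, grid_n = n), lam) + y / 0.5, 2)
  ds <- descent_step(b, y, u, y_hat, v, pars)
  # independent oracle: assemble the dense weighted-gradient operator and
  # evaluate the update formulas by matrix algebra
  Kmat <- vapply(seq_len(n * n * 2), function(i) {
    e <- matrix(0, n * n, 2); e[i] <- 1
    as.numeric(grad_K(material_images(e, grid_n = n), lam))
  }, numeric(n * n * 2 * 2))
  bv <- as.numeric(b); uv <- as.numeric(u); yv <- as.numeric(y)
  yh <- as.numeric(y_hat); vv <- as.numeric(v)
  d1 <- 1 * (bv - uv) + 0.5 * as.numeric(t(Kmat) %*% (Kmat %*% yh - vv))
  d2 <- vv - as.numeric(Kmat %*% uv)
  gamma <- 0.2 * (1 * sum((bv - uv)^2) +
                    0.5 * sum((Kmat %*% bv - vv) * (Kmat %*% yh - vv))) /
    (sum(d1^2) + sum(d2^2))
  expect_equal(ds$gamma, gamma, tolerance = 1e-12)
  expect_equal(as.numeric(ds$b), bv - gamma * d1, tolerance = 1e-12)
  expect_equal(as.numeric(ds$y), yv - gamma * d2, tolerance = 1e-12)
  # doubling theta doubles the step
  pars2 <- pars; pars2$theta <- 0.4
  expect_equal(descent_step(b, y, u, y_hat, v, pars2)$gamma, 2 * ds$gamma,
               tolerance = 1e-12)
  # exact fixed point of the optimality system
  vfix <- grad_K(material_images(b, grid_n = n), lam)
  dsf <- descent_step(b, y, b, b, vfix, pars)
  expect_true(dsf$converged)
  expect_equal(dsf$b, b)
})

test_that("the full solver converges on noise-free data and respects the
           parameter guard", {
  m <- tiny_model()
  A <- disc_A64()
  ph <- disc_phantom64()
  sino <- poly_project(ph, A, m$spectra, m$table)
  # zero iterations returns the zero initialization
  f0 <- ipad_run(sino, A, m$spectra, m$table,
                 ipad_params(n_iter = 0, n_subsets = 30))
  expect_equal(max(abs(f0$b)), 0)
  expect_null(f0$history)
  pars <- ipad_params(n_iter = 30, n_subsets = 30)
  fit <- ipad_run(sino, A, m$spectra, m$table, pars, truth = ph)
  h <- fit$history
  # error decreases monotonically past the transient and ends far below its
  # starting level
  expect_true(all(diff(h$rmse_total[-(1:3)]) < 0))
  expect_lt(h$rmse_total[30], 0.1 * h$rmse_total[1])
  expect_true(all(h$gamma >= 0))
  expect_equal(h$objective, h$fidelity + h$tv)
  bad <- structure(list(alpha = 1, beta = 0.5, t = 1e9, theta = 0.2,
                        lam = c(1, 1, 1), n_iter = 1L, n_subsets = 30L,
                        relax = 1, eps = 0, inner_passes = 1L),
                   class = "ipad_params")
  expect_error(ipad_run(sino, A, m$spectra, m$table, bad), "c >= 0")
})

test_that("at convergence the descent directions collapse relative to the
           first iteration", {
  m <- tiny_model()
  A <- disc_A64()
  ph <- disc_phantom64()
  sino <- poly_project(ph, A, m$spectra, m$table)
  fit <- ipad_run(sino, A, m$spectra, m$table,
                  ipad_params(n_iter = 60, n_subsets = 30), truth = ph)
  h <- fit$history
  # the primal direction alpha(b - u) vanishes at the fixed point
  expect_lt(h$d1_norm[nrow(h)], 1e-3 * h$d1_norm[1])
  # the dual direction is bounded by the regularization scale: v - lam K u
  # with lam <= 1e-5 stays tiny throughout (its own fixed point is only
  # approached on the much slower dual timescale ~ 1/(gamma * lam))
  expect_lt(max(h$d2_norm), 1e-2)
})

test_that("stronger illumination gives no worse reconstructions", {
  m <- tiny_model()
  A <- disc_A64()
  ph <- disc_phantom64()
  clean <- poly_project(ph, A, m$spectra, m$table)
  pars <- ipad_params(n_iter = 40, n_subsets = 30)
  f_low <- ipad_run(add_poisson_noise(clean, noise_model(5e5, 11)),
                    A, m$spectra, m$table, pars, truth = ph)
  f_high <- ipad_run(add_poisson_noise(clean, noise_model(5e6, 11)),
                     A, m$spectra, m$table, pars, truth = ph)
  expect_lte(tail(f_high$history$rmse_total, 1),
             tail(f_low$history$rmse_total, 1))
})
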