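test_that("polychromatic projection reduces to known limits", {
  m <- tiny_model()
  A <- disc_A64()
  # zero images: normalized spectra integrate to one, so -log(1) = 0
  p0 <- poly_project(zero_materials(64), A, m$spectra, m$table)
  expect_lt(max(abs(p0$p)), 1e-12)
  # single-energy bins: exact Beer's-law reduction
  ph <- disc_phantom64()
  grid <- m$grid
  idx <- match(c(40, 60, 80), grid$energies)
  sp1 <- one_hot_spectra(grid, idx)
  p_mono <- poly_project(ph, A, sp1, m$table)
  tvals <- forward(A, spectralct:::coef_matrix(ph))
  expected <- tvals %*% t(m$table$mu[idx, , drop = FALSE])
  expect_lt(max(abs(t(p_mono$p) - expected)), 1e-12)
  expect_error(poly_project(material_images(array(NaN, c(64, 64, 3))),
                            A, m$spectra, m$table), "non-finite")
})

test_that("polychromatic projection matches a naive per-ray oracle", {
  # brute-force oracle: direct evaluation of -log(sum_m S e^{-x}) per ray,
  # without the stable code path
  m <- tiny_model()
  A <- disc_A64()
  ph <- disc_phantom64()
  p <- poly_project(ph, A, m$spectra, m$table)
  tvals <- forward(A, spectralct:::coef_matrix(ph))
  X <- tvals %*% t(m$table$mu)
  set.seed(5)
  rays <- sample(nrow(X), 50)
  for (j in rays) {
    for (s in 1:3) {
      oracle <- -log(sum(m$spectra$S[s, ] * exp(-X[j, ])))
      expect_equal(p$p[s, j], oracle, tolerance = 1e-12)
    }
  }
})

test_that("linearization weights are the spectral derivative of the
           projection", {
  m <- tiny_model()
  geom <- scan_geometry(300, 600, 24, 360, 32, 0.7, 16, 0.62)
  A <- cached_system_matrix("tiny16", geom)
  # at b = 0 the weights collapse to the bin-mean attenuation
  W0 <- linearization_weights(zero_materials(16), A, m$spectra, m$table)
  M <- bin_mean_mu(m$spectra, m$table)
  for (s in 1:3) {
    expect_lt(max(abs(sweep(W0[s, , ], 2, M[s, ]))), 1e-12)
  }
  # single-energy bin: weights equal that energy's attenuation for any b
  idx <- match(55, m$grid$energies)
  sp1 <- one_hot_spectra(m$grid, idx)
  set.seed(8)
  b <- material_images(array(runif(16 * 16 * 3) * 0.3, c(16, 16, 3)))
  W1 <- linearization_weights(b, A, sp1, m$table)
  for (k in 1:3) {
    expect_lt(max(abs(W1[1, , k] - m$table$mu[idx, k])), 1e-14)
  }
  # bounds: weights stay inside the bin's attenuation range
  W <- linearization_weights(b, A, m$spectra, m$table)
  for (s in 1:3) {
    sup <- m$spectra$S[s, ] > 0
    for (k in 1:3) {
      expect_gte(min(W[s, , k]), min(m$table$mu[sup, k]) - 1e-12)
      expect_lte(max(W[s, , k]), max(m$table$mu[sup, k]) + 1e-12)
    }
  }
  # directional finite difference of the projection matches W * A(delta)
  set.seed(9)
  d <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  eps <- 1e-6
  p0 <- poly_project(b, A, m$spectra, m$table)$p
  p1 <- poly_project(material_images(unclass(b) + eps * d), A,
                     m$spectra, m$table)$p
  fd <- (p1 - p0) / eps
  ad <- forward(A, spectralct:::coef_matrix(material_images(d)))
  pred <- sapply(1:3, function(s) rowSums(W[s, , ] * ad))
  expect_lt(max(abs(fd - t(pred))) / max(abs(fd)), 1e-4)
})

test_that("fidelity and its gradient are consistent", {
  m <- tiny_model()
  geom <- scan_geometry(300, 600, 24, 360, 32, 0.7, 16, 0.62)
  A <- cached_system_matrix("tiny16", geom)
  set.seed(3)
  b <- material_images(array(runif(16 * 16 * 3) * 0.5, c(16, 16, 3)))
  bt <- material_images(array(runif(16 * 16 * 3) * 0.4, c(16, 16, 3)))
  pm <- poly_project(bt, A, m$spectra, m$table)
  expect_equal(fidelity(b, A, m$spectra, m$table,
                        poly_project(b, A, m$spectra, m$table)), 0)
  # constant offset: G = S*J/2
  pm1 <- pm; pm1$p <- poly_project(b, A, m$spectra, m$table)$p + 1
  expect_equal(fidelity(b, A, m$spectra, m$table, pm1),
               length(pm1$p) / 2, tolerance = 1e-12)
  # brute-force small case
  pb <- poly_project(b, A, m$spectra, m$table)
  acc <- 0
  for (s in 1:3) for (j in seq_len(ncol(pm$p))) {
    acc <- acc + (pb$p[s, j] - pm$p[s, j])^2
  }
  expect_equal(fidelity(b, A, m$spectra, m$table, pm), acc / 2,
               tolerance = 1e-10)
  # gradient against central finite differences along random directions
  gr <- fidelity_grad(b, A, m$spectra, m$table, pm)
  set.seed(4)
  for (trial in 1:3) {
    d <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
    eps <- 1e-6
    fp <- fidelity(material_images(unclass(b) + eps * d), A, m$spectra,
                   m$table, pm)
    fm <- fidelity(material_images(unclass(b) - eps * d), A, m$spectra,
                   m$table, pm)
    fd <- (fp - fm) / (2 * eps)
    an <- sum(gr * matrix(d, 256, 3))
    expect_lt(abs(fd - an) / abs(an), 1e-4)
  }
})

test_that("a homogeneous object beam-hardens: polychromatic projections fall
           below the bin-mean monochromatic ones on long paths", {
  m <- tiny_model()
  A <- disc_A64()
  geom <- A$geometry
  n <- geom$grid_n
  cc <- (seq_len(n) - 0.5 - n / 2) * geom$pixel_size
  d2 <- outer(cc^2, cc^2, `+`)
  tissue <- matrix(0, n, n); tissue[d2 <= 13^2] <- 1
  b <- material_images(array(c(tissue, tissue * 0, tissue * 0),
                             c(n, n, 3)))
  p_poly <- poly_project(b, A, m$spectra, m$table)
  lens <- forward(A, tissue)
  M <- bin_mean_mu(m$spectra, m$table)
  central <- seq_len(geom$n_det)   # first view
  long <- central[lens[central] > 20]
  for (s in 1:3) {
    p_mono <- M[s, 1] * lens[long]
    expect_true(all(p_poly$p[s, long] < p_mono))
  }
})

test_that("Poisson injection is seeded, unbiased at high flux, and clamps
           zero counts", {
  m <- tiny_model()
  A <- disc_A64()
  ph <- disc_phantom64()
  clean <- poly_project(ph, A, m$spectra, m$table)
  nm <- noise_model(1e12, seed = 99)
  n1 <- add_poisson_noise(clean, nm)
  n2 <- add_poisson_noise(clean, nm)
  expect_identical(n1$p, n2$p)
  expect_false(identical(add_poisson_noise(clean, noise_model(1e12, 100))$p,
                         n1$p))
  # delta method: mean log perturbation is 0 within 3 standard errors
  lambda <- 1e12 * exp(-clean$p)
  z <- mean(n1$p - clean$p)
  se <- sqrt(sum(1 / lambda)) / length(lambda)
  expect_lt(abs(z), 3 * se)
  # the study's photon levels are accepted
  for (I0 in c(5e5, 1e6, 5e6)) {
    expect_s3_class(add_poisson_noise(clean, noise_model(I0, 1)), "sinogram")
  }
  # zero-count clamp keeps projections finite and bounded by log(I0)
  hot <- clean; hot$p <- hot$p + 30    # transmission ~ e^-30
  ny <- add_poisson_noise(hot, noise_model(10, seed = 1))
  expect_true(all(is.finite(ny$p)))
  expect_lte(max(ny$p), log(10) + 1e-12)
  expect_error(noise_model(0), "positive")
})
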