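# shared small fixtures; system matrices are cached per session because the
# Siddon build is the slow part of the small tests
.fixture_env <- new.env(parent = emptyenv())

cached_system_matrix <- function(key, geom) {
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- build_system_matrix(geom)
  }
  .fixture_env[[key]]
}

tiny_model <- function() {
  if (is.null(.fixture_env$model)) {
    .fixture_env$model <- default_spectral_model()
  }
  .fixture_env$model
}

disc_A64 <- function(n_views = 90) {
  cached_system_matrix(paste0("disc64_", n_views),
                       geometry_disc(64, n_views))
}

disc_phantom64 <- function() {
  if (is.null(.fixture_env$ph64)) {
    .fixture_env$ph64 <- suppressWarnings(disc_phantom(64))
  }
  .fixture_env$ph64
}

# one-hot spectra on selected grid energies (bins x energies), for
# monochromatic reductions
one_hot_spectra <- function(grid, energy_idx) {
  S <- matrix(0, length(energy_idx), length(grid$energies))
  for (s in seq_along(energy_idx)) S[s, energy_idx[s]] <- 1
  structure(list(grid = grid, S = S,
                 thresholds = c(grid$energies[energy_idx],
                                max(grid$energies))),
            class = "binned_spectra")
}

zero_materials <- function(n, k = 3) {
  material_images(array(0, dim = c(n, n, k)))
}
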