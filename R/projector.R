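#' Fan-beam scan geometry
#'
#' Describes a 2-D flat-detector fan-beam acquisition and the reconstruction
#' grid. The image is centered at the isocenter with pixel centers at
#' `(i + 0.5 - n/2) * pixel_size`; views rotate counter-clockwise starting
#' with the source on the +x axis; detector index 0 sits at the most negative
#' tangential offset.
#'
#' @param sod Source-to-object (isocenter) distance, mm.
#' @param sdd Source-to-detector distance, mm (`sod < sdd`).
#' @param n_views Number of projection views over `angular_range`.
#' @param angular_range Scanned arc in degrees (360 for a full scan).
#' @param n_det Number of detector elements.
#' @param det_pitch Detector element size, mm.
#' @param grid_n Reconstruction grid side, pixels.
#' @param pixel_size Pixel size, mm.
#' @return A `scan_geometry` object.
#' @export
scan_geometry <- function(sod, sdd, n_views, angular_range = 360,
                          n_det, det_pitch, grid_n, pixel_size) {
  if (!(sod > 0 && sdd > sod)) stop("require 0 < sod < sdd", call. = FALSE)
  if (n_views < 1 || n_det < 1 || grid_n < 1) {
    stop("n_views, n_det and grid_n must be >= 1", call. = FALSE)
  }
  if (det_pitch <= 0 || pixel_size <= 0) {
    stop("det_pitch and pixel_size must be positive", call. = FALSE)
  }
  g <- structure(list(sod = sod, sdd = sdd, n_views = as.integer(n_views),
                      angular_range = angular_range, n_det = as.integer(n_det),
                      det_pitch = det_pitch, grid_n = as.integer(grid_n),
                      pixel_size = pixel_size),
                 class = "scan_geometry")
  fov <- n_det * det_pitch * sod / sdd         # field of view at isocenter
  circle <- grid_n * pixel_size                # reconstruction circle diameter
  if (fov < circle * (1 - 1e-9)) {
    warning(sprintf(paste0("detector field of view (%.1f mm) does not cover ",
                           "the reconstruction circle (%.1f mm)"), fov, circle))
  }
  g
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(paste0("<scan_geometry> sod %.4g / sdd %.4g mm, %d views over ",
                     "%g deg,\n  %d detectors x %.4g mm, grid %d^2 x %.4g mm\n"),
              x$sod, x$sdd, x$n_views, x$angular_range, x$n_det, x$det_pitch,
              x$grid_n, x$pixel_size))
  invisible(x)
}

#' Sparse fan-beam system matrix (Siddon tracing)
#'
#' Builds the discrete X-ray transform as a sparse matrix of exact ray/pixel
#' intersection lengths (mm). The matrix is stored transposed
#' (pixels x rays) so that columns align with detector readings; `forward()`
#' and `backproject()` are exact adjoints of one another by construction.
#'
#' @param geom A [scan_geometry()].
#' @return A `system_matrix` with the sparse operator and cached
#'   `row_sums` (per-ray total intersection length, mm) and `col_sums`
#'   (per-pixel total weight).
#' @export
build_system_matrix <- function(geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  raw <- siddon_fan_system(geom$sod, geom$sdd, geom$n_views,
                           geom$angular_range, geom$n_det, geom$det_pitch,
                           geom$grid_n, geom$pixel_size)
  J <- as.integer(raw$ncol)
  At <- methods::new("dgCMatrix", i = raw$i, p = raw$p, x = raw$x,
                     Dim = c(raw$nrow, J))
  row_sums <- Matrix::colSums(At)    # per ray
  if (all(row_sums == 0)) {
    stop("geometry error: no ray intersects the reconstruction grid",
         call. = FALSE)
  }
  structure(list(geometry = geom, At = At,
                 row_sums = row_sums,
                 col_sums = Matrix::rowSums(At)),
            class = "system_matrix")
}

#' @export
print.system_matrix <- function(x, ...) {
  cat(sprintf("<system_matrix> %d rays x %d pixels, %.3g nonzeros\n",
              ncol(x$At), nrow(x$At), Matrix::nnzero(x$At)))
  invisible(x)
}

as_image_vec <- function(A, img) {
  n <- A$geometry$grid_n
  if (is.matrix(img) && all(dim(img) == c(n, n))) return(as.numeric(img))
  if (is.numeric(img) && length(img) == n * n) return(as.numeric(img))
  stop("image shape does not match the geometry grid", call. = FALSE)
}

#' Apply the X-ray transform
#'
#' @param A A [build_system_matrix()] object.
#' @param img `grid_n x grid_n` image (or `I`-vector, or `I x K` matrix of
#'   stacked images).
#' @return Ray-sum vector of length `n_views * n_det` (view-major), or a
#'   `J x K` matrix for multi-column input.
#' @export
forward <- function(A, img) {
  stopifnot(inherits(A, "system_matrix"))
  n <- A$geometry$grid_n
  if (is.matrix(img) && nrow(img) == n * n) {
    return(as.matrix(Matrix::crossprod(A$At, img)))
  }
  as.numeric(Matrix::crossprod(A$At, as_image_vec(A, img)))
}

#' Apply the adjoint (unfiltered backprojection)
#'
#' @param A A `system_matrix`.
#' @param rays Ray vector of length `n_views * n_det`, or a `J x K` matrix.
#' @return `grid_n x grid_n` image, or `I x K` matrix for matrix input.
#' @export
backproject <- function(A, rays) {
  stopifnot(inherits(A, "system_matrix"))
  J <- ncol(A$At)
  if (is.matrix(rays)) {
    if (nrow(rays) != J) stop("ray matrix has wrong length", call. = FALSE)
    return(as.matrix(A$At %*% rays))
  }
  if (length(rays) != J) stop("ray vector has wrong length", call. = FALSE)
  n <- A$geometry$grid_n
  matrix(as.numeric(A$At %*% rays), n, n)
}

# view subsets for ordered-subsets sweeps: view v belongs to subset
# (v mod n_subsets); returns ray index lists (view-major ray ordering)
os_subsets <- function(geom, n_subsets) {
  n_subsets <- min(n_subsets, geom$n_views)
  lapply(seq_len(n_subsets) - 1L, function(s) {
    views <- seq.int(s, geom$n_views - 1L, by = n_subsets)
    idx <- outer(seq_len(geom$n_det), views * geom$n_det, `+`)
    as.integer(idx)
  })
}

# band-limited ramp filter frequency response of length npad, detector
# sampling tau (mm); apodization "ram-lak" (none) or "hann"
ramp_response <- function(npad, tau, filter = c("hann", "ram-lak")) {
  filter <- match.arg(filter)
  n <- c(0:(npad / 2), (-npad / 2 + 1):(-1))
  h <- numeric(npad)
  h[n == 0] <- 1 / (4 * tau^2)
  odd <- n %% 2 != 0
  h[odd] <- -1 / (pi * n[odd] * tau)^2
  H <- Re(stats::fft(h))
  if (filter == "hann") {
    j <- seq_len(npad) - 1
    H <- H * 0.5 * (1 + cos(2 * pi * pmin(j, npad - j) / npad))
  }
  H
}

#' Filtered backprojection for flat-detector fan-beam data
#'
#' Standard reconstruction: cosine weighting of the detector rows, ramp
#' filtering (band-limited Ram-Lak, optionally Hann-apodized) along the
#' detector, and distance-weighted backprojection. Linear in the sinogram.
#'
#' @param geom A [scan_geometry()]; the sinogram must cover its full
#'   `angular_range`.
#' @param sino `n_views x n_det` log-domain sinogram.
#' @param filter `"hann"` (Hann-apodized ramp, default) or `"ram-lak"`.
#' @return `grid_n x grid_n` image in the sinogram's attenuation units
#'   (1/mm for line integrals of 1/mm images).
#' @export
fbp <- function(geom, sino, filter = c("hann", "ram-lak")) {
  stopifnot(inherits(geom, "scan_geometry"))
  filter <- match.arg(filter)
  if (geom$n_views < 2) stop("FBP needs at least 2 views", call. = FALSE)
  if (!is.matrix(sino) || nrow(sino) != geom$n_views ||
      ncol(sino) != geom$n_det) {
    stop("sinogram must be n_views x n_det", call. = FALSE)
  }
  nd <- geom$n_det
  tau <- geom$det_pitch * geom$sod / geom$sdd     # pitch at isocenter
  u <- (seq_len(nd) - 0.5 - nd / 2) * tau
  w1 <- geom$sod / sqrt(geom$sod^2 + u^2)

  npad <- 2^ceiling(log2(2 * nd))
  H <- ramp_response(npad, tau, filter)
  pw <- sweep(sino, 2, w1, `*`)
  padded <- matrix(0, geom$n_views, npad)
  padded[, seq_len(nd)] <- pw
  ft <- t(stats::mvfft(t(padded)))
  ft <- sweep(ft, 2, H, `*`)
  q <- Re(t(stats::mvfft(t(ft), inverse = TRUE))) / npad
  q <- q[, seq_len(nd), drop = FALSE] * tau

  n <- geom$grid_n
  cc <- (seq_len(n) - 0.5 - n / 2) * geom$pixel_size
  xc <- rep(cc, times = n)
  yc <- rep(cc, each = n)
  dbeta <- geom$angular_range * pi / 180 / geom$n_views
  acc <- numeric(n * n)
  redundancy <- geom$angular_range / 180      # full scan covers each ray twice
  for (v in seq_len(geom$n_views)) {
    beta <- (v - 1) * dbeta
    cb <- cos(beta); sb <- sin(beta)
    U <- geom$sod - (xc * cb + yc * sb)
    tt <- -xc * sb + yc * cb
    uu <- geom$sod * tt / U
    fidx <- uu / tau + nd / 2 + 0.5
    j0 <- floor(fidx)
    fr <- fidx - j0
    ok <- j0 >= 1 & j0 < nd
    val <- numeric(n * n)
    qv <- q[v, ]
    val[ok] <- (1 - fr[ok]) * qv[j0[ok]] + fr[ok] * qv[j0[ok] + 1]
    acc <- acc + val * (geom$sod^2 / U^2)
  }
  matrix(acc * dbeta / redundancy, n, n)
}
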