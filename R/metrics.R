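#' Root-mean-square error between two images
#' @param x,ref Numeric arrays of identical shape.
#' @export
rmse <- function(x, ref) {
  if (!all(dim(x) == dim(ref)) || length(x) != length(ref)) {
    stop("shape mismatch", call. = FALSE)
  }
  sqrt(mean((x - ref)^2))
}

#' Peak signal-to-noise ratio (dB)
#'
#' `10 log10(peak^2 / mse)` with the peak taken as the reference image's
#' dynamic range (`max(ref) - min(ref)`), the per-material convention used
#' throughout this package's reports. A zero-error comparison is capped at
#' 300 dB.
#'
#' @param x,ref Images of identical shape; `ref` must be non-constant.
#' @export
psnr <- function(x, ref) {
  if (!all(dim(x) == dim(ref)) || length(x) != length(ref)) {
    stop("shape mismatch", call. = FALSE)
  }
  peak <- max(ref) - min(ref)
  if (peak == 0) stop("reference image is constant: peak undefined",
                      call. = FALSE)
  mse <- mean((x - ref)^2)
  if (mse == 0) return(300)
  min(10 * log10(peak^2 / mse), 300)
}

gaussian_kernel_1d <- function(sigma = 1.5, radius = 5L) {
  w <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  w / sum(w)
}

# separable valid-region filtering: returns (n-2r) x (m-2r) filtered image
filter_valid <- function(x, w) {
  r <- (length(w) - 1L) / 2L
  n <- nrow(x); m <- ncol(x)
  Wr <- matrix(0, n - 2 * r, n)
  for (i in seq_len(n - 2 * r)) Wr[i, i:(i + 2 * r)] <- w
  Wc <- matrix(0, m - 2 * r, m)
  for (i in seq_len(m - 2 * r)) Wc[i, i:(i + 2 * r)] <- w
  Wr %*% x %*% t(Wc)
}

#' Structural similarity index
#'
#' Mean SSIM with an 11 x 11 Gaussian window (sigma = 1.5), stability
#' constants K1 = 0.01, K2 = 0.03, population (weighted) variances, and the
#' border cropped to the window's valid region -- the standard
#' reference-implementation conventions.
#'
#' @param x,ref Images of identical shape (at least 11 x 11).
#' @param data_range Dynamic range; defaults to `max(ref) - min(ref)`.
#' @export
ssim <- function(x, ref, data_range = max(ref) - min(ref)) {
  if (!all(dim(x) == dim(ref))) stop("shape mismatch", call. = FALSE)
  if (min(dim(x)) < 11) stop("images must be at least 11 x 11", call. = FALSE)
  w <- gaussian_kernel_1d(1.5, 5L)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  mx <- filter_valid(x, w)
  my <- filter_valid(ref, w)
  sxx <- filter_valid(x * x, w) - mx^2
  syy <- filter_valid(ref * ref, w) - my^2
  sxy <- filter_valid(x * ref, w) - mx * my
  num <- (2 * mx * my + c1) * (2 * sxy + c2)
  den <- (mx^2 + my^2 + c1) * (sxx + syy + c2)
  mean(num / den)
}

#' Per-material and averaged image-quality report
#'
#' Computes RMSE, PSNR and SSIM per basis material against ground truth, the
#' arithmetic mean over materials ("averaged" row), and the total RMSE over
#' the concatenated stack. PSNR/SSIM use each material's ground-truth dynamic
#' range as peak.
#'
#' @param b Reconstructed [material_images()].
#' @param truth Ground-truth [material_images()] of identical shape.
#' @return An `eval_report` data frame (one row per material plus
#'   `averaged`), with the total RMSE as attribute `total_rmse`.
#' @export
eval_report <- function(b, truth) {
  stopifnot(all(dim(b) == dim(truth)))
  k <- n_materials(b)
  nm <- dimnames(truth)[[3]]
  if (is.null(nm)) nm <- paste0("material_", seq_len(k))
  rows <- lapply(seq_len(k), function(j) {
    data.frame(material = nm[j],
               rmse = rmse(b[, , j], truth[, , j]),
               psnr = psnr(b[, , j], truth[, , j]),
               ssim = ssim(b[, , j], truth[, , j]))
  })
  rep_df <- do.call(rbind, rows)
  avg <- data.frame(material = "averaged",
                    rmse = mean(rep_df$rmse), psnr = mean(rep_df$psnr),
                    ssim = mean(rep_df$ssim))
  out <- rbind(rep_df, avg)
  attr(out, "total_rmse") <- sqrt(mean((unclass(b) - unclass(truth))^2))
  class(out) <- c("eval_report", "data.frame")
  out
}

#' @export
print.eval_report <- function(x, ...) {
  df <- as.data.frame(x)
  df$rmse <- signif(df$rmse, 4)
  df$psnr <- round(df$psnr, 3)
  df$ssim <- round(df$ssim, 4)
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("total RMSE: %.4g\n", attr(x, "total_rmse")))
  invisible(x)
}
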