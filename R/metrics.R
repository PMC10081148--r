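#' 3 x 3 median filter
#'
#' The denoising step applied to every magnitude image before RMSE/SSIM are
#' measured. Borders are handled by mirroring across the array edge;
#' constant images are fixed points.
#'
#' @param image Real matrix.
#' @param size Odd window side, default 3.
#' @return Filtered matrix, same size.
#' @export
median_filter_image <- function(image, size = 3L) {
  stopifnot(is.matrix(image), size %% 2L == 1L, size >= 1L)
  .cpp_median_filter(image, as.integer(size))
}

median_filter_series <- function(series, size = 3L) {
  out <- series
  for (t in seq_len(dim(series)[3]))
    out[, , t] <- median_filter_image(series[, , t], size)
  out
}

#' Root-mean-square error between two image series
#'
#' `sqrt(mean((a - b)^2))`, pooled over all pixels and frames.
#'
#' @param a,b Real arrays of identical shape.
#' @return Single nonnegative number; 0 iff `a == b`.
#' @export
rmse <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("`a` and `b` must have identical shape")
  sqrt(mean((a - b)^2))
}

gaussian_window <- function(size = 11L, sigma = 1.5) {
  x <- freq_index(size) + if (size %% 2L == 0L) 0.5 else 0
  g <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

ssim_frame <- function(a, b, L, K1 = 0.01, K2 = 0.03,
                       window = gaussian_window()) {
  C1 <- (K1 * L)^2
  C2 <- (K2 * L)^2
  mu1 <- .cpp_conv2_valid(a, window)
  mu2 <- .cpp_conv2_valid(b, window)
  s11 <- .cpp_conv2_valid(a * a, window) - mu1 * mu1
  s22 <- .cpp_conv2_valid(b * b, window) - mu2 * mu2
  s12 <- .cpp_conv2_valid(a * b, window) - mu1 * mu2
  mean(((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
         ((mu1 * mu1 + mu2 * mu2 + C1) * (s11 + s22 + C2)))
}

#' Structural similarity index between two image series
#'
#' Mean local SSIM with the standard 11 x 11 Gaussian window (sigma 1.5) and
#' stabilisation constants `K1 = 0.01`, `K2 = 0.03`; local statistics are
#' taken over the valid (fully overlapped) window positions and, for a 3D
#' series, the per-frame values are averaged. The dynamic range is the
#' max - min of the reference `b` over the whole series (1 is substituted for
#' a constant reference).
#'
#' @param a Test series (real matrix or 3D array).
#' @param b Reference series, same shape; sets the dynamic range.
#' @param K1,K2 Stabilisation constants.
#' @return A value <= 1, with `ssim(x, x) == 1` exactly.
#' @export
ssim <- function(a, b, K1 = 0.01, K2 = 0.03) {
  if (!all(dim(a) == dim(b))) stop("`a` and `b` must have identical shape")
  L <- max(b) - min(b)
  if (L == 0) L <- 1
  w <- gaussian_window()
  if (length(dim(a)) == 2L) return(ssim_frame(a, b, L, K1, K2, w))
  mean(vapply(seq_len(dim(a)[3]), function(t)
    ssim_frame(a[, , t], b[, , t], L, K1, K2, w), numeric(1)))
}
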