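#' Grid radial k-space samples onto a Cartesian matrix
#'
#' Scatters every radial sample onto its 4 surrounding Cartesian k-space cells
#' with bilinear weights. A cell's value is the weight-normalised sum of the
#' contributions it received; the binary mask `W` marks cells whose total
#' weight exceeds a small threshold ("measured" cells), and `d` is zeroed
#' wherever `W` is 0. `d` and `W` are the inputs of the iterative
#' reconstruction ([reconstruct()]).
#'
#' No density compensation is applied: the iterative method's fidelity term
#' compares masked Fourier coefficients directly.
#'
#' @param frame A `radial_kspace`.
#' @param N Output grid side; defaults to `n_samples`.
#' @param weight_threshold Minimum accumulated weight for a cell to count as
#'   measured.
#' @return A `cartesian_kspace`: list with complex `N x N` matrix `d`, binary
#'   matrix `W` and `N` (DC at 0-based index `N %/% 2` on both axes).
#' @export
grid_radial <- function(frame, N = NULL, weight_threshold = 1e-8) {
  stopifnot(inherits(frame, "radial_kspace"))
  if (length(frame$lines) == 0L || frame$sampling$n_views < 1L)
    stop("cannot grid an empty radial frame")
  if (is.null(N)) N <- frame$sampling$n_samples
  N <- as.integer(N)
  cN <- N %/% 2L
  f <- freq_index(frame$sampling$n_samples)
  th <- frame$sampling$angles_deg * pi / 180
  # 0-based fractional cell coordinates of every sample, views stacked
  px <- as.vector(outer(cos(th), f)) + cN
  py <- as.vector(outer(sin(th), f)) + cN
  val <- as.vector(frame$lines)
  ix <- floor(px); iy <- floor(py)
  fx <- px - ix;  fy <- py - iy
  wsum <- numeric(N * N)
  vre <- numeric(N * N)
  vim <- numeric(N * N)
  for (corner in 1:4) {
    cx <- ix + (corner == 2L | corner == 4L)
    cy <- iy + (corner >= 3L)
    w <- ifelse(cx == ix, 1 - fx, fx) * ifelse(cy == iy, 1 - fy, fy)
    ok <- cx >= 0 & cx < N & cy >= 0 & cy < N & w > 0
    if (!any(ok)) next
    idx <- cy[ok] * N + cx[ok] + 1  # rows index x (first array dim), cols y
    acc <- rowsum(cbind(w[ok], w[ok] * Re(val[ok]), w[ok] * Im(val[ok])),
                  group = idx)
    at <- as.integer(rownames(acc))
    wsum[at] <- wsum[at] + acc[, 1]
    vre[at] <- vre[at] + acc[, 2]
    vim[at] <- vim[at] + acc[, 3]
  }
  W <- matrix(as.numeric(wsum > weight_threshold), N, N)
  d <- matrix(complex(real = vre, imaginary = vim), N, N)
  d[W == 0] <- 0 + 0i
  d[W == 1] <- d[W == 1] / wsum[as.vector(W == 1)]
  structure(list(d = d, W = W, N = N), class = "cartesian_kspace")
}

#' @export
print.cartesian_kspace <- function(x, ...) {
  cat(sprintf("<cartesian_kspace> %d x %d, coverage %.3f\n",
              x$N, x$N, mask_coverage(x)))
  invisible(x)
}

#' Fraction of measured Cartesian k-space cells
#'
#' @param W A binary mask matrix or a `cartesian_kspace`.
#' @return `mean(W)`, in \[0, 1\].
#' @export
mask_coverage <- function(W) {
  if (inherits(W, "cartesian_kspace")) W <- W$W
  stopifnot(all(W %in% c(0, 1)))
  mean(W)
}
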