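#' Radial sampling pattern
#'
#' Uniformly spaced view angles over \[0, 180) degrees: view `j` (0-based)
#' sits at `angle_offset + j * 180 / n_views`. Each view is a full diameter
#' through the k-space centre with `n_samples` uniformly spaced radial
#' frequencies, DC at 0-based index `n_samples %/% 2`.
#'
#' @param n_views Number of views (>= 1).
#' @param n_samples Samples per line (>= 2); conventionally the image grid
#'   size, so the radial frequency step equals the Cartesian k-space cell.
#' @param angle_offset Angle of the first view in degrees (default 0); an
#'   interleaved dynamic acquisition rotates this from frame to frame.
#' @return A `radial_sampling` with fields `n_views`, `angles_deg`,
#'   `n_samples`, `sample_spacing` (1/FOV units).
#' @export
radial_sampling <- function(n_views, n_samples, angle_offset = 0) {
  if (!is.numeric(n_views) || length(n_views) != 1L || n_views < 1)
    stop("`n_views` must be a positive count")
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 2)
    stop("`n_samples` must be a count >= 2")
  structure(list(n_views = as.integer(n_views),
                 angles_deg = angle_offset + (seq_len(n_views) - 1) * 180 / n_views,
                 n_samples = as.integer(n_samples),
                 sample_spacing = 1 / n_samples),
            class = "radial_sampling")
}

#' @export
print.radial_sampling <- function(x, ...) {
  cat(sprintf("<radial_sampling> %d views over [0, 180) deg (step %.4g), %d samples/line\n",
              x$n_views, 180 / x$n_views, x$n_samples))
  invisible(x)
}

new_radial_kspace <- function(sampling, lines, frame_index = 0L) {
  stopifnot(inherits(sampling, "radial_sampling"),
            nrow(lines) == sampling$n_views,
            ncol(lines) == sampling$n_samples)
  structure(list(sampling = sampling, lines = lines,
                 frame_index = as.integer(frame_index)),
            class = "radial_kspace")
}

#' @export
print.radial_kspace <- function(x, ...) {
  cat(sprintf("<radial_kspace> frame %d: %d views x %d samples\n",
              x$frame_index, x$sampling$n_views, x$sampling$n_samples))
  invisible(x)
}

#' Simulate radial k-space acquisition of one image
#'
#' Evaluates the discrete-space Fourier transform of a square complex image
#' along each view's diameter (central-slice theorem): sample `k` of the line
#' at angle `theta` is
#' \deqn{S(f_k, \theta) = \sum_{x,y} m[x,y]\,
#'   e^{-2\pi i (f_k/N)(\tilde x \cos\theta + \tilde y \sin\theta)}}
#' with signed frequency index \eqn{f_k = k - n/2} and centred pixel
#' coordinates. Independent complex Gaussian noise of standard deviation
#' `noise_sigma` is then added to every sample.
#'
#' Two algebraically identical evaluation paths are provided: `"separable"`
#' factors the exponential into a row and a column phase matrix and uses two
#' matrix products per view; `"nudft"` is the literal nonuniform-DFT sum over
#' all pixels (slow; intended for verification on small images).
#'
#' @param image Square complex (or real) matrix.
#' @param sampling A [radial_sampling()].
#' @param noise_sigma Complex-noise standard deviation per sample (on each of
#'   the real and imaginary parts).
#' @param seed Optional integer seed for the noise (global RNG state is left
#'   untouched).
#' @param frame_index Time index stored on the result.
#' @param method `"separable"` (default) or `"nudft"`.
#' @return A `radial_kspace` frame.
#' @export
simulate_acquisition <- function(image, sampling, noise_sigma = 0, seed = NULL,
                                 frame_index = 0L,
                                 method = c("separable", "nudft")) {
  method <- match.arg(method)
  if (!is.matrix(image) || nrow(image) != ncol(image))
    stop("`image` must be a square matrix")
  stopifnot(inherits(sampling, "radial_sampling"))
  N <- nrow(image)
  n <- sampling$n_samples
  f <- freq_index(n)
  xt <- freq_index(N)
  th <- sampling$angles_deg * pi / 180
  lines <- matrix(0 + 0i, sampling$n_views, n)
  if (method == "separable") {
    for (v in seq_len(sampling$n_views)) {
      Ex <- exp(-2i * pi / N * outer(f * cos(th[v]), xt))   # n x N
      Ey <- exp(-2i * pi / N * outer(f * sin(th[v]), xt))
      C <- image %*% t(Ey)                                  # N x n
      lines[v, ] <- colSums(t(Ex) * C)
    }
  } else {
    XY <- expand.grid(x = xt, y = xt)
    img <- as.vector(image)
    for (v in seq_len(sampling$n_views)) {
      for (k in seq_len(n)) {
        ph <- exp(-2i * pi / N * f[k] *
                    (cos(th[v]) * XY$x + sin(th[v]) * XY$y))
        lines[v, k] <- sum(img * ph)
      }
    }
  }
  if (noise_sigma > 0) {
    nz <- length(lines)
    noise <- with_local_seed(seed,
      complex(real = rnorm(nz, sd = noise_sigma),
              imaginary = rnorm(nz, sd = noise_sigma)))
    lines <- lines + matrix(noise, nrow(lines), ncol(lines))
  }
  new_radial_kspace(sampling, lines, frame_index)
}

#' Acquire a whole dynamic series
#'
#' Applies [simulate_acquisition()] to every frame, with a per-frame seed
#' derived from `seed` so the noise is reproducible yet independent across
#' frames.
#'
#' @param series A `dynamic_series`.
#' @param sampling A [radial_sampling()].
#' @param noise_sigma Complex-noise standard deviation per k-space sample.
#' @param seed Base integer seed (frame `t` uses `seed + t - 1`), or `NULL`.
#' @return List of `radial_kspace` frames.
#' @export
acquire_series <- function(series, sampling, noise_sigma = 0, seed = NULL) {
  lapply(seq_len(n_frames(series)), function(t) {
    simulate_acquisition(series[, , t], sampling, noise_sigma,
                         seed = if (is.null(seed)) NULL else seed + t - 1L,
                         frame_index = t - 1L)
  })
}

#' Uniformly undersample the views of a radial frame
#'
#' Keeps views whose 0-based index is congruent to `offset` modulo
#' `keep_every`; sample values are untouched. 72 views with `keep_every = 3`
#' yields the 24-view sparse data (7.5 degree spacing). In a dynamic series
#' an *interleaved* scheme rotates `offset` with the frame index, so that
#' `keep_every` consecutive frames jointly cover all view angles — the
#' pattern under which a temporal constraint can fill in a frame's unmeasured
#' views from its neighbours.
#'
#' @param frame A `radial_kspace`.
#' @param keep_every Decimation factor; must divide `n_views`.
#' @param offset 0-based index of the first retained view (default 0),
#'   `0 <= offset < keep_every`.
#' @return A `radial_kspace` with `n_views / keep_every` views.
#' @export
undersample <- function(frame, keep_every, offset = 0L) {
  stopifnot(inherits(frame, "radial_kspace"))
  nv <- frame$sampling$n_views
  if (keep_every < 1 || nv %% keep_every != 0)
    stop("`keep_every` must divide the number of views (", nv, ")")
  if (offset < 0 || offset >= keep_every)
    stop("`offset` must lie in [0, keep_every)")
  keep <- seq(1L + offset, nv, by = keep_every)
  new_radial_kspace(
    radial_sampling(nv %/% keep_every, frame$sampling$n_samples,
                    angle_offset = frame$sampling$angles_deg[1L + offset]),
    frame$lines[keep, , drop = FALSE],
    frame$frame_index)
}
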