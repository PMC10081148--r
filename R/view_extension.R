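#' Estimate the deformation field between two adjacent radial lines
#'
#' Finds, for every sample on the first line, a corresponding sample on the
#' second line, under the model that adjacent view angles see nearly the same
#' radial profile up to a smooth radial deformation. The correspondence
#' `j(i)` is the monotone non-decreasing map minimising
#' \deqn{\sum_i \left(|L_1[i]| - |L_4[j(i)]|\right)^2}
#' plus a proximity regulariser `lambda * sum (j(i) - i)^2`, subject to pinned
#' endpoints `j(1) = 1`, `j(n) = n` and the DC pin `j(c) = c` (the k-space
#' centre must map to itself). The optimum is found exactly by dynamic
#' programming on the magnitude profiles; among equal-cost maps the one
#' closest to the identity (minimal `sum |j(i) - i|`) is preferred, so
#' radially consistent lines yield the identity map.
#'
#' The regulariser expresses that adjacent views see almost the same radial
#' profile, so the correspondence should be a *small* deformation: without it
#' a monotone magnitude match is free to ride the oscillations of the k-space
#' profile and wander far from the diagonal. By default `lambda` is scaled to
#' one tenth of the mean squared magnitude mismatch of the identity map, which
#' makes the matcher scale invariant, leaves genuine shifts detectable, and
#' vanishes (exact tie-break to identity) for identical lines.
#'
#' @param line1,line4 Complex vectors of equal length (>= 4).
#' @param lambda Proximity penalty per squared sample of displacement;
#'   `NULL` (default) for the data-scaled choice above.
#' @return A `deformation_field`: list with integer map `j` (1-based), the
#'   matching cost, the `lambda` used, and the line length `n`.
#' @export
estimate_deformation <- function(line1, line4, lambda = NULL) {
  if (length(line1) != length(line4))
    stop("`line1` and `line4` must have equal length")
  n <- length(line1)
  if (n < 4) stop("lines must have length >= 4")
  a <- abs(line1)
  b <- abs(line4)
  if (is.null(lambda)) lambda <- 0.1 * mean((a - b)^2)
  res <- .cpp_deformation_dp(a, b, lambda)
  structure(list(j = as.integer(res$j), cost = res$cost, lambda = lambda,
                 n = n),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  cat(sprintf("<deformation_field> n = %d, cost = %.4g, max |j - i| = %d\n",
              x$n, x$cost, max(abs(x$j - seq_len(x$n)))))
  invisible(x)
}

#' Synthesise an intermediate radial line from a measured pair
#'
#' Every correspondence `(i, j(i))` of the deformation field defines a segment
#' in polar k-space coordinates from `(r_i, theta1)` to `(r_j, theta4)`, where
#' `r` is the signed radius (frequency index minus centre). The segment
#' crosses the target angle at parameter `s = (theta_target - theta1) /
#' (theta4 - theta1)`; the crossing radius and the assigned complex value are
#' the corresponding linear interpolations
#' `rho_i = (1-s) r_i + s r_{j(i)}` and
#' `v_i = (1-s) L1[i] + s L4[j(i)]`
#' (real and imaginary parts interpolated directly). The scattered
#' `(rho_i, v_i)` pairs — strictly increasing in `rho` because both `r_i` and
#' `r_{j(i)}` are monotone — are then resampled onto the uniform radial grid
#' by linear interpolation, zero outside the scattered support.
#'
#' @param line1,line4 The measured complex lines.
#' @param field [estimate_deformation()] result for this pair.
#' @param theta1,theta4,theta_target View angles in degrees with
#'   `theta1 < theta_target < theta4` (angles need not be reduced mod 180).
#' @return Complex vector: the synthesised line at `theta_target`.
#' @export
synthesize_intermediate <- function(line1, line4, field,
                                    theta1, theta4, theta_target) {
  stopifnot(inherits(field, "deformation_field"),
            length(line1) == field$n, length(line4) == field$n)
  if (!(theta1 < theta_target && theta_target < theta4))
    stop("`theta_target` must lie strictly between `theta1` and `theta4`")
  n <- field$n
  r <- freq_index(n)
  s <- (theta_target - theta1) / (theta4 - theta1)
  rho <- (1 - s) * r + s * r[field$j]
  v <- (1 - s) * line1 + s * line4[field$j]
  re <- approx(rho, Re(v), xout = r, rule = 1)$y
  im <- approx(rho, Im(v), xout = r, rule = 1)$y
  re[is.na(re)] <- 0
  im[is.na(im)] <- 0
  complex(real = re, imaginary = im)
}

# Half-turn partner of a radial line: S(r, theta + 180) = S(-r, theta), i.e.
# the samples in reversed radial order. With an even sample count the
# most-negative frequency has no positive partner and keeps its own value.
reverse_line <- function(v) {
  n <- length(v)
  cc <- n %/% 2L
  out <- v
  k0 <- seq_len(n - 1L)             # 0-based indices 1 .. n-1
  out[k0 + 1L] <- v[2L * cc - k0 + 1L]
  if (n %% 2L == 0L) out[1L] <- v[1L]
  out
}

#' Extend a sparse radial frame to three times the views
#'
#' Between every pair of angularly adjacent measured lines, two new lines are
#' synthesised at 1/3 and 2/3 of the angular gap via the deformation method
#' ([estimate_deformation()] + [synthesize_intermediate()]), turning e.g. a
#' 24-view frame into a 72-view frame. Measured lines are carried over
#' bit-exactly at their original angles. The wraparound gap between the last
#' view and the first view + 180 degrees is bridged by pairing the last line
#' with the radially reversed first line (the half-turn identity of k-space).
#'
#' @param frame24 A `radial_kspace` with uniformly spaced views (>= 2).
#' @return A `radial_kspace` with `3 * n_views` uniformly spaced views.
#' @export
extend_views <- function(frame24) {
  stopifnot(inherits(frame24, "radial_kspace"))
  nv <- frame24$sampling$n_views
  if (nv < 2) stop("view extension needs at least 2 views")
  n <- frame24$sampling$n_samples
  ang <- frame24$sampling$angles_deg
  gap <- 180 / nv
  out <- matrix(0 + 0i, 3L * nv, n)
  for (v in seq_len(nv)) {
    L1 <- frame24$lines[v, ]
    th1 <- ang[v]
    if (v < nv) {
      L4 <- frame24$lines[v + 1L, ]
    } else {
      L4 <- reverse_line(frame24$lines[1L, ])
    }
    th4 <- th1 + gap
    fld <- estimate_deformation(L1, L4)
    out[3L * (v - 1L) + 1L, ] <- L1
    out[3L * (v - 1L) + 2L, ] <-
      synthesize_intermediate(L1, L4, fld, th1, th4, th1 + gap / 3)
    out[3L * (v - 1L) + 3L, ] <-
      synthesize_intermediate(L1, L4, fld, th1, th4, th1 + 2 * gap / 3)
  }
  new_radial_kspace(radial_sampling(3L * nv, n), out, frame24$frame_index)
}
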