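# Independent oracles and small fixtures, built in code at test time.

# Radially symmetric soft-edged disk: band-limited enough that its radial
# k-space lines are angle-independent to high accuracy.
soft_disk <- function(N, r = 0.55, w = 0.06, amplitude = 1) {
  co <- (seq_len(N) - 1 - N %/% 2) / (N / 2)
  X <- matrix(co, N, N)
  Y <- matrix(co, N, N, byrow = TRUE)
  rho <- sqrt(X^2 + Y^2)
  amplitude / (1 + exp((rho - r) / w))
}

hard_disk <- function(N, r = 0.6) {
  co <- (seq_len(N) - 1 - N %/% 2) / (N / 2)
  X <- matrix(co, N, N)
  Y <- matrix(co, N, N, byrow = TRUE)
  (X^2 + Y^2 <= r^2) * 1.0
}

# Brute-force nonuniform DFT of an image along one view angle.
nudft_line_oracle <- function(image, angle_deg, n_samples) {
  N <- nrow(image)
  xt <- seq_len(N) - 1 - N %/% 2
  f <- seq_len(n_samples) - 1 - n_samples %/% 2
  th <- angle_deg * pi / 180
  out <- complex(n_samples)
  for (k in seq_len(n_samples)) {
    acc <- 0 + 0i
    for (x in seq_len(N))
      for (y in seq_len(N))
        acc <- acc + image[x, y] *
          exp(-2i * pi / N * f[k] * (cos(th) * xt[x] + sin(th) * xt[y]))
    out[k] <- acc
  }
  out
}

# Exhaustive minimum over monotone maps with pinned endpoints and DC pin,
# using the same augmented cost as the DP (magnitude mismatch + lambda
# proximity; lexicographic tie on sum |j - i|).
exhaustive_deformation <- function(a, b, lambda) {
  n <- length(a)
  cc <- n %/% 2 + 1  # 1-based DC pin
  best <- list(cost = Inf, tie = Inf)
  recurse <- function(i, jprev, cost, tie) {
    if (cost > best$cost ||
        (cost == best$cost && tie >= best$tie)) return()
    if (i > n) {
      best <<- list(cost = cost, tie = tie)
      return()
    }
    jset <- if (i == 1) 1 else if (i == cc) cc else if (i == n) n
      else seq(jprev, if (i < cc) cc else n)
    for (j in jset) {
      if (j < jprev) next
      recurse(i + 1, j,
              cost + (a[i] - b[j])^2 + lambda * (j - i)^2,
              tie + abs(j - i))
    }
  }
  recurse(1, 1, 0, 0)
  best
}

# Straight-from-definition SSIM (valid windows, Gaussian 11x11 sigma 1.5).
ssim_reference <- function(a, b, L, K1 = 0.01, K2 = 0.03) {
  win <- 11L
  h <- win %/% 2
  x <- -h:h
  g <- exp(-x^2 / (2 * 1.5^2))
  Wg <- outer(g, g)
  Wg <- Wg / sum(Wg)
  C1 <- (K1 * L)^2
  C2 <- (K2 * L)^2
  n1 <- nrow(a); n2 <- ncol(a)
  vals <- c()
  for (i in (h + 1):(n1 - h))
    for (j in (h + 1):(n2 - h)) {
      pa <- a[(i - h):(i + h), (j - h):(j + h)]
      pb <- b[(i - h):(i + h), (j - h):(j + h)]
      mu1 <- sum(Wg * pa); mu2 <- sum(Wg * pb)
      s11 <- sum(Wg * pa * pa) - mu1^2
      s22 <- sum(Wg * pb * pb) - mu2^2
      s12 <- sum(Wg * pa * pb) - mu1 * mu2
      vals <- c(vals, ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
                  ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)))
    }
  mean(vals)
}

# Brute-force sliding-window median with mirrored borders.
median_filter_oracle <- function(x, k = 3L) {
  h <- k %/% 2
  n1 <- nrow(x); n2 <- ncol(x)
  ref <- function(p, n) { p <- ifelse(p < 1, 1 - p, p); ifelse(p > n, 2 * n + 1 - p, p) }
  out <- x
  for (i in seq_len(n1))
    for (j in seq_len(n2)) {
      ii <- ref(i + (-h:h), n1)
      jj <- ref(j + (-h:h), n2)
      out[i, j] <- median(x[ii, jj])
    }
  out
}

# Direct loop-summation of the spatio-temporally constrained objective
# (orthonormal fidelity convention).
objective_oracle <- function(m, data, cfg) {
  Tn <- dim(m)[3]; N <- dim(m)[1]
  fid <- 0; tem <- 0; tv <- 0
  for (t in seq_len(Tn)) {
    Fm <- radialrecon:::kspace_forward(m[, , t])
    fid <- fid + sum(abs(data[[t]]$W * Fm - data[[t]]$d)^2) / N^2
    for (i in seq_len(N))
      for (j in seq_len(N)) {
        dx <- if (i < N) m[i + 1, j, t] - m[i, j, t] else 0
        dy <- if (j < N) m[i, j + 1, t] - m[i, j, t] else 0
        tv <- tv + sqrt(abs(dx)^2 + abs(dy)^2 + cfg$epsilon)
        if (t < Tn) tem <- tem + abs(m[i, j, t + 1] - m[i, j, t])^2
      }
  }
  fid + cfg$alpha1 * tem + cfg$alpha2 * tv
}

random_complex_array <- function(dims) {
  array(complex(real = rnorm(prod(dims)), imaginary = rnorm(prod(dims))), dims)
}

# Random sparse Cartesian k-space frames with matched d/W.
random_kspace_frames <- function(N, Tn, density = 0.4) {
  lapply(seq_len(Tn), function(t) {
    W <- matrix(rbinom(N * N, 1, density) * 1.0, N, N)
    d <- matrix(complex(real = rnorm(N * N), imaginary = rnorm(N * N)), N, N) * W
    structure(list(d = d, W = W, N = as.integer(N)), class = "cartesian_kspace")
  })
}

# Bilinear image rotation about the grid centre (zero outside), for the
# FBP rotation-equivariance check.
rotate_image <- function(img, angle_deg) {
  N <- nrow(img)
  ct <- N %/% 2 + 1
  th <- angle_deg * pi / 180
  out <- matrix(0, N, N)
  for (j in seq_len(N))
    for (i in seq_len(N)) {
      x <- i - ct; y <- j - ct
      xs <- cos(th) * x + sin(th) * y + ct
      ys <- -sin(th) * x + cos(th) * y + ct
      i0 <- floor(xs); j0 <- floor(ys)
      if (i0 >= 1 && i0 + 1 <= N && j0 >= 1 && j0 + 1 <= N) {
        fx <- xs - i0; fy <- ys - j0
        out[i, j] <- (1 - fx) * (1 - fy) * img[i0, j0] +
          fx * (1 - fy) * img[i0 + 1, j0] +
          (1 - fx) * fy * img[i0, j0 + 1] +
          fx * fy * img[i0 + 1, j0 + 1]
      }
    }
  out
}

# Noiseless step-change series (value jumps in a central region at
# `step_frame`), for the temporal-bias direction test.
step_series <- function(N = 64, Tn = 6, step_frame = 4, step = 2) {
  co <- (seq_len(N) - 1 - N %/% 2) / (N / 2)
  X <- matrix(co, N, N); Y <- matrix(co, N, N, byrow = TRUE)
  reg <- (X^2 + Y^2 <= 0.35^2)
  body <- (X^2 + Y^2 <= 0.8^2)
  arr <- array(0 + 0i, c(N, N, Tn))
  for (t in seq_len(Tn))
    arr[, , t] <- 0.3 * body + (if (t >= step_frame) step else 0) * reg
  list(series = dynamic_series(arr), region = reg, step = step,
       step_frame = step_frame, base = 0.3)
}
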