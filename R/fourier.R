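# Centred-FFT bookkeeping, shared by every module that touches k-space.
#
# Convention: for an axis of length n the DC sample sits at 0-based index
# n %/% 2 (1-based n %/% 2 + 1), and spatial coordinates are integers
# x - n %/% 2.  `kspace_forward()` is the unnormalised 2D DFT conjugated by
# the matching shift permutations; `kspace_inverse()` is its exact inverse.

fftshift_vec <- function(v) {
  n <- length(v)
  v[((seq_len(n) - 1L - n %/% 2L) %% n) + 1L]
}

ifftshift_vec <- function(v) {
  n <- length(v)
  v[((seq_len(n) - 1L + n %/% 2L) %% n) + 1L]
}

fftshift_mat <- function(m) {
  r <- ((seq_len(nrow(m)) - 1L - nrow(m) %/% 2L) %% nrow(m)) + 1L
  s <- ((seq_len(ncol(m)) - 1L - ncol(m) %/% 2L) %% ncol(m)) + 1L
  m[r, s, drop = FALSE]
}

ifftshift_mat <- function(m) {
  r <- ((seq_len(nrow(m)) - 1L + nrow(m) %/% 2L) %% nrow(m)) + 1L
  s <- ((seq_len(ncol(m)) - 1L + ncol(m) %/% 2L) %% ncol(m)) + 1L
  m[r, s, drop = FALSE]
}

kspace_forward <- function(m) fftshift_mat(fft(ifftshift_mat(m)))

kspace_inverse <- function(d) fftshift_mat(fft(ifftshift_mat(d), inverse = TRUE)) / length(d)

# Signed frequency / coordinate index for an axis of length n: -(n%/%2) ... .
freq_index <- function(n) seq_len(n) - 1L - n %/% 2L

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}
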