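# Discrete Fourier helpers shared by all modules.
#
# Convention (fixed package-wide): the spectrum is stored in "display" order,
# i.e. frequency increases with array index and the carrier (0 Hz offset) sits
# at index floor(n/2)+1.  The FID is obtained from the spectrum by
#   fid = ifft(ifftshift(spectrum))          (unitary up to the usual 1/n)
# and the spectrum is recovered by
#   spectrum = fftshift(fft(fid)).
# The pair is an exact inverse to numerical precision.

fftshift <- function(x) {
  n <- length(x)
  if (n < 2L) return(x)
  s <- n %/% 2L
  c(x[(s + 1L):n], x[1:s])
}

ifftshift <- function(x) {
  n <- length(x)
  if (n < 2L) return(x)
  s <- ceiling(n / 2)
  c(x[(s + 1L):n], x[1:s])
}

ifft <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# FFT along one margin of a multi-dimensional array. `dim_idx` selects the
# dimension; all other margins are carried along. Used for the spatial
# transforms of CSI grids (grids are small, clarity over speed).
fft_along <- function(x, dim_idx, inverse = FALSE) {
  d <- dim(x)
  nd <- length(d)
  perm <- c(dim_idx, seq_len(nd)[-dim_idx])
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = d[dim_idx])
  m <- stats::mvfft(m, inverse = inverse)
  if (inverse) m <- m / d[dim_idx]
  xp <- array(m, dim = d[perm])
  aperm(xp, order(perm))
}

# Centered symmetric k-space mask retaining ceiling(frac * n) samples.
# Ties (even retained count on an odd removal split) keep one extra
# low-frequency sample on the DC side.
kspace_mask <- function(n, frac) {
  stopifnot(frac > 0, frac <= 1)
  keep <- min(n, as.integer(ceiling(frac * n)))
  centre <- n %/% 2L + 1L
  half_lo <- ceiling((keep - 1L) / 2)
  half_hi <- floor((keep - 1L) / 2)
  idx <- (centre - half_lo):(centre + half_hi)
  mask <- numeric(n)
  mask[idx] <- 1
  mask
}

# Hamming taper over the retained central support, zero elsewhere.
hamming_mask <- function(n, frac) {
  mask <- kspace_mask(n, frac)
  idx <- which(mask > 0)
  if (length(idx) > 1L) mask[idx] <- as.numeric(signal::hamming(length(idx)))
  mask
}

complex_noise <- function(n, sd) {
  complex(real = stats::rnorm(n, 0, sd), imaginary = stats::rnorm(n, 0, sd))
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

wrap_phase <- function(x) x %% (2 * pi)
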