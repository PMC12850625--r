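# SNR evaluation from electromagnetic field exports.
#
# The receive array's thermal noise covariance follows from the electric
# fields each loop induces in the conducting sample,
#   R_ik = sum_voxels sigma(x) * (E_i(x) . conj(E_k(x))) * dV,
# and per-voxel SNR of a combined acquisition follows the matched-filter
# form  SNR = const * |p^H R^-1 b| / sqrt(b^H R^-1 b),
# with p the (proxy) signal vector and b the sensitivity vector used for
# weighting. All physical constants default to 1: the package reports
# relative SNR, and every comparison of interest is a ratio in which they
# cancel.

#' Per-channel field set
#'
#' Container for exported per-channel complex fields on one spatial grid:
#' electric fields (for the noise covariance), receive fields `B1-` (signal
#' proxy / sensitivity), and the sample's conductivity map.
#'
#' @param e_fields complex array `(Nch, Nx, Ny, Nz, 3)`, V/m per unit loop
#'   current.
#' @param b1_minus complex array `(Nch, Nx, Ny, Nz)`.
#' @param conductivity real array `(Nx, Ny, Nz)`, S/m, >= 0.
#' @param voxel_volume voxel volume in m^3.
#' @param frequency Larmor frequency in Hz.
#' @return object of class `field_set`.
#' @export
field_set <- function(e_fields, b1_minus, conductivity, voxel_volume,
                      frequency) {
  de <- dim(e_fields); db <- dim(b1_minus); dc <- dim(conductivity)
  if (length(de) != 5L || de[5] != 3L)
    stop("e_fields must be (Nch, Nx, Ny, Nz, 3)")
  if (length(db) != 4L) stop("b1_minus must be (Nch, Nx, Ny, Nz)")
  if (length(dc) != 3L) stop("conductivity must be (Nx, Ny, Nz)")
  if (!all(de[2:4] == dc) || !all(db[2:4] == dc) || de[1] != db[1])
    stop("field grids are not congruent across channels")
  if (any(conductivity < 0)) stop("conductivity must be >= 0")
  if (voxel_volume <= 0 || frequency <= 0)
    stop("voxel_volume and frequency must be > 0")
  structure(list(e_fields = e_fields, b1_minus = b1_minus,
                 conductivity = conductivity, voxel_volume = voxel_volume,
                 frequency = frequency),
            class = "field_set")
}

#' Synthetic loop-array field set
#'
#' A synthetic stand-in for exported EM simulation fields, for testing and
#' demonstration only: `n_channels` loops are placed around a cylinder
#' enclosing the grid; each channel's fields decay exponentially with
#' distance from its loop with a propagation phase, and the conductivity map
#' is a uniform tissue-like value inside an ellipsoid. Not a solution of
#' Maxwell's equations.
#'
#' @param n_channels number of channels.
#' @param grid length-3 integer grid size.
#' @param frequency Hz (default 120.6e6, 31P at 7 T).
#' @param voxel_m voxel edge length in meters.
#' @param conductivity_sm tissue conductivity inside the ellipsoid.
#' @param seed integer seed for the random polarization draws.
#' @return a [field_set()].
#' @export
synth_field_set <- function(n_channels = 4L, grid = c(8L, 8L, 4L),
                            frequency = 120.6e6, voxel_m = 0.02,
                            conductivity_sm = 0.6, seed = 1L) {
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  xs <- (seq_len(nx) - (nx + 1) / 2) * voxel_m
  ys <- (seq_len(ny) - (ny + 1) / 2) * voxel_m
  zs <- (seq_len(nz) - (nz + 1) / 2) * voxel_m
  radius <- max(abs(c(xs, ys))) * 1.3 + voxel_m
  wavelength <- 3e8 / frequency / 9      # crude in-tissue wavelength
  k_wave <- 2 * pi / wavelength
  e <- array(0i, dim = c(n_channels, nx, ny, nz, 3))
  b <- array(0i, dim = c(n_channels, nx, ny, nz))
  withr::with_seed(seed, {
    pol <- matrix(complex(real = stats::rnorm(3 * n_channels),
                          imaginary = stats::rnorm(3 * n_channels)),
                  n_channels, 3)
    for (ch in seq_len(n_channels)) {
      th <- 2 * pi * ch / n_channels
      cx <- radius * cos(th); cy <- radius * sin(th)
      for (i in seq_len(nx)) for (j in seq_len(ny)) for (k in seq_len(nz)) {
        d <- sqrt((xs[i] - cx)^2 + (ys[j] - cy)^2 + zs[k]^2)
        amp <- exp(-d / (radius)) * exp(-1i * k_wave * d)
        e[ch, i, j, k, ] <- amp * pol[ch, ]
        b[ch, i, j, k] <- amp * exp(1i * th)
      }
    }
  })
  cond <- array(0, dim = grid)
  for (i in seq_len(nx)) for (j in seq_len(ny)) for (k in seq_len(nz)) {
    r2 <- (xs[i] / max(abs(xs)))^2 + (ys[j] / max(abs(ys)))^2 +
      (zs[k] / max(abs(zs), voxel_m))^2
    if (r2 <= 1.05) cond[i, j, k] <- conductivity_sm
  }
  field_set(e, b, cond, voxel_volume = voxel_m^3, frequency = frequency)
}

#' Noise covariance from electric fields
#'
#' `R_ik = sum_v sigma_v * (E_i(v) . conj(E_k(v))) * dV` over the grid. The
#' conjugated product makes `R` Hermitian positive semi-definite, the form
#' required of a thermal noise covariance.
#'
#' @param fs a [field_set()].
#' @return a [noise_covariance()].
#' @export
noise_cov_from_fields <- function(fs) {
  stopifnot(inherits(fs, "field_set"))
  if (all(fs$conductivity == 0))
    stop("conductivity is zero everywhere; noise covariance is singular")
  nch <- dim(fs$e_fields)[1]
  nvox <- prod(dim(fs$conductivity))
  # (Nch) x (Nvox*3) matrix of field components
  E <- matrix(fs$e_fields, nrow = nch)
  sig <- rep(as.vector(fs$conductivity), times = 3)
  Ew <- sweep(E, 2, sig, `*`)
  R <- (Ew %*% Conj(t(E))) * fs$voxel_volume
  R <- (R + Conj(t(R))) / 2
  noise_covariance(R)
}

#' Physical constants of the SNR expression
#'
#' All default to 1, i.e. relative-SNR mode; the constant multiplying the
#' matched-filter quotient is `omega * M * V_vox / sqrt(4 * k_B * T *
#' delta_f)`.
#'
#' @param omega,M,V_vox,k_B,T,delta_f positive scalars.
#' @return object of class `snr_constants`.
#' @export
snr_constants <- function(omega = 1, M = 1, V_vox = 1, k_B = 1, T = 1,
                          delta_f = 1) {
  vals <- c(omega = omega, M = M, V_vox = V_vox, k_B = k_B, T = T,
            delta_f = delta_f)
  if (any(vals <= 0)) stop("all SNR constants must be > 0")
  structure(as.list(vals), class = "snr_constants")
}

snr_prefactor <- function(consts) {
  if (is.null(consts)) return(1)
  with(consts, omega * M * V_vox / sqrt(4 * k_B * T * delta_f))
}

#' Voxel-wise combined SNR map
#'
#' `SNR(v) = const * |p(v)^H R^-1 b(v)| / sqrt(b(v)^H R^-1 b(v))` with
#' `p` the signal proxy (`B1-` of the target nucleus) and `b` the weighting
#' sensitivity. With `fs_sens = fs_signal` this is the matched-filter bound
#' (`const * sqrt(p^H R^-1 p)`), the optimal-SNR reference.
#'
#' @param fs_signal [field_set()] supplying `p` via its `b1_minus`.
#' @param fs_sens [field_set()] supplying `b`; defaults to `fs_signal`.
#' @param R a [noise_covariance()] (or matrix); default computed from
#'   `fs_signal`'s electric fields.
#' @param consts a [snr_constants()] or `NULL` (all 1).
#' @param tol voxels with `b^H R^-1 b` below `tol` times its volume maximum
#'   are returned as `NA`.
#' @return real array `(Nx, Ny, Nz)`.
#' @export
snr_map <- function(fs_signal, fs_sens = fs_signal, R = NULL, consts = NULL,
                    tol = 1e-12) {
  stopifnot(inherits(fs_signal, "field_set"), inherits(fs_sens, "field_set"))
  gd <- dim(fs_signal$conductivity)
  if (!all(dim(fs_sens$conductivity) == gd) ||
      dim(fs_sens$b1_minus)[1] != dim(fs_signal$b1_minus)[1])
    stop("signal and sensitivity field sets are not congruent")
  if (is.null(R)) R <- noise_cov_from_fields(fs_signal)
  nch <- dim(fs_signal$b1_minus)[1]
  Rm <- resolve_R(R, nch)
  P <- matrix(fs_signal$b1_minus, nrow = nch)
  B <- matrix(fs_sens$b1_minus, nrow = nch)
  Y <- solve(Rm, B)
  num <- Mod(colSums(Conj(P) * Y))
  quad <- Re(colSums(Conj(B) * Y))
  ok <- quad > tol * max(quad, .Machine$double.xmin)
  snr <- rep(NA_real_, length(quad))
  snr[ok] <- snr_prefactor(consts) * num[ok] / sqrt(quad[ok])
  array(snr, dim = gd)
}

#' Voxel-wise SNR ratio map
#'
#' `snr_map` with the alternative sensitivity divided by `snr_map` with the
#' reference sensitivity; physical constants cancel. When the reference is
#' the matched filter (`fs_sens_ref = fs_signal`), the Cauchy-Schwarz
#' inequality bounds the ratio by 1 at every voxel. Voxels where the
#' reference is flagged/zero are returned as `NA`.
#'
#' @param fs_signal,fs_sens_alt,fs_sens_ref [field_set()] objects.
#' @inheritParams snr_map
#' @return real array `(Nx, Ny, Nz)` of ratios.
#' @export
snr_ratio_map <- function(fs_signal, fs_sens_alt, fs_sens_ref = fs_signal,
                          R = NULL, consts = NULL, tol = 1e-12) {
  if (is.null(R)) R <- noise_cov_from_fields(fs_signal)
  alt <- snr_map(fs_signal, fs_sens_alt, R, consts, tol)
  ref <- snr_map(fs_signal, fs_sens_ref, R, consts, tol)
  out <- alt / ref
  out[!is.finite(ref) | ref == 0] <- NA_real_
  out
}
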