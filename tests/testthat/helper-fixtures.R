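# Shared fixtures: small models and independent oracles, built in code.

# compact two-peak model: PCr at band center, an alpha-ATP-like line off-center
small_model <- function(n_points = 128L) {
  spectral_model(
    data.frame(shift = c(0, -7.52), amplitude = c(1, 0.55),
               linewidth = c(12, 20), phase = 0),
    n_points = n_points, bandwidth = 5000, carrier_ppm = 0, f0_mhz = 120.6)
}

# independent closed-form Lorentzian sum (oracle for make_spectrum)
lorentz_sum_oracle <- function(model) {
  ax <- model_axes(model)
  out <- rep(0 + 0i, model$n_points)
  for (r in seq_len(nrow(model$resonances))) {
    A <- model$resonances$amplitude[r]
    ph <- model$resonances$phase[r]
    hwhm <- model$resonances$linewidth[r] / 2
    fc <- (model$resonances$shift[r] - model$carrier_ppm) * model$f0_mhz
    out <- out + A * exp(1i * ph) * hwhm / (hwhm + 1i * (ax$freq_hz - fc))
  }
  out
}

# analytic combined-SNR of weight vector w against truth b, covariance R
analytic_snr <- function(w, b, R) {
  Mod(sum(Conj(w) * b)) / sqrt(Re(Conj(w) %*% R %*% w)[1, 1])
}

# brute-force noise covariance from fields (triple spatial loop, oracle)
brute_force_field_cov <- function(fs) {
  d <- dim(fs$conductivity)
  nch <- dim(fs$e_fields)[1]
  R <- matrix(0 + 0i, nch, nch)
  for (i in seq_len(nch)) for (k in seq_len(nch)) {
    acc <- 0 + 0i
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      acc <- acc + fs$conductivity[x, y, z] *
        sum(fs$e_fields[i, x, y, z, ] * Conj(fs$e_fields[k, x, y, z, ]))
    }
    R[i, k] <- acc * fs$voxel_volume
  }
  R
}

# component-form SNR (explicit double sum over channel pairs, oracle for the
# vector matched-filter expression): weights w = R^-1 b
component_form_snr <- function(p, b, R) {
  w <- solve(R, b)
  n <- length(p)
  num <- 0
  den <- 0
  for (i in seq_len(n)) for (k in seq_len(n)) {
    ai <- Mod(w[i]) * Mod(p[i]); ak <- Mod(w[k]) * Mod(p[k])
    thi <- Arg(Conj(w[i]) * p[i]); thk <- Arg(Conj(w[k]) * p[k])
    num <- num + ai * ak * cos(thi - thk)
    den <- den + Mod(w[i]) * Mod(w[k]) * Mod(R[i, k]) *
      cos(Arg(R[i, k]) + Arg(w[k]) - Arg(w[i]))
  }
  sqrt(num / den)
}

random_unit_weights <- function(nch, n) {
  w <- matrix(complex(real = rnorm(nch * n), imaginary = rnorm(nch * n)),
              nch, n)
  sweep(w, 2, sqrt(colSums(Mod(w)^2)), `/`)
}

random_spd_cov <- function(nch) {
  A <- matrix(complex(real = rnorm(nch^2), imaginary = rnorm(nch^2)), nch, nch)
  A %*% Conj(t(A)) + diag(nch) * 0.5
}
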