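test_that("sensitivity estimation averages the requested FID points", {
  m <- small_model(64L)
  fid <- spectrum_to_fid(make_spectrum(m))
  b <- true_sensitivity(5)
  p <- synth_voxel(fid, b, sigma = 0)

  # noise-free: estimate proportional to b with factor mean(s over range)
  est <- estimate_sensitivity(p, c(2L, 5L))
  expect_equal(est$values, b$values * mean(fid$samples[2:5]), tolerance = 1e-12)
  expect_identical(est$provenance, "self")

  # default in vivo range uses exactly 4 points; Monte Carlo range 5 points
  expect_length(seq.int(2L, 5L), 4L)
  est15 <- estimate_sensitivity(p, c(1L, 5L))
  expect_equal(est15$values, b$values * mean(fid$samples[1:5]), tolerance = 1e-12)

  expect_error(estimate_sensitivity(p, c(5L, 2L)), "first <= last")
  expect_error(estimate_sensitivity(p, c(1L, 1000L)), "outside")
})

test_that("noise covariance estimation is consistent and guards degeneracy", {
  set.seed(21)
  nch <- 4L
  X <- matrix(complex(real = rnorm(1e5 * nch), imaginary = rnorm(1e5 * nch)),
              ncol = nch)
  R <- estimate_noise_covariance(X)
  frob <- function(M) sqrt(sum(Mod(M)^2))
  expect_lt(frob(R$matrix - diag(2, nch)) / frob(diag(2, nch)), 0.05)

  # duplicated channel: off-diagonal equals the diagonal
  X2 <- cbind(X[, 1], X[, 1], X[, 2])
  expect_warning(R2 <- estimate_noise_covariance(X2), "jitter")
  expect_equal(Re(R2$matrix[1, 2]), Re(R2$matrix[1, 1]), tolerance = 1e-6)

  expect_error(estimate_noise_covariance(matrix(0i, 100, 3)), "zero")
  expect_error(estimate_noise_covariance(matrix(1i, 2, 3)), "more noise samples")
})

test_that("uniform-noise Roemer combination has the declared gain and noise", {
  m <- small_model()
  sp <- make_spectrum(m)
  fid <- spectrum_to_fid(sp)

  # single channel identity case: P = C * p
  p1 <- synth_voxel(fid, sensitivity_vector(1 + 0i), sigma = 0)
  cs1 <- roemer_combine(p1, 1 + 0i, R = matrix(1), scale = 2)
  expect_equal(cs1$fid, 2 * fid$samples, tolerance = 1e-12)

  # 16 unit-magnitude channels, noise-free: peak height 4x the true signal
  b16 <- true_sensitivity(16)
  p16 <- synth_voxel(fid, b16, sigma = 0)
  cs16 <- roemer_combine(p16, b16)
  expect_equal(max(Re(cs16$spectrum)) / max(Re(sp$values)), 4,
               tolerance = 1e-8)

  # uniform-noise contract: combined pure-noise std equals sigma * C
  set.seed(31)
  nch <- 6L; sigma <- 0.8; nsamp <- 10000L
  noise <- matrix(complex(real = rnorm(nch * nsamp, 0, sigma),
                          imaginary = rnorm(nch * nsamp, 0, sigma)), nch)
  pn <- multichannel_fid(noise, dwell = 1 / 5000)
  b <- sensitivity_vector(complex(real = rnorm(nch), imaginary = rnorm(nch)))
  csn <- roemer_combine(pn, b, scale = 1.5)
  expect_equal(stats::sd(Re(csn$fid)), 1.5 * sigma, tolerance = 0.05)
})

test_that("combination is whitening-equivalent and scale-invariant", {
  set.seed(41)
  m <- small_model(64L)
  fid <- spectrum_to_fid(make_spectrum(m))
  for (rep in 1:20) {
    nch <- sample(2:6, 1)
    b <- sensitivity_vector(complex(real = rnorm(nch), imaginary = rnorm(nch)))
    p <- synth_voxel(fid, b, sigma = 0.3)
    R <- random_spd_cov(nch)

    # whitening: combine(p, b, R) == combine(Wp, Wb, I), W = R^{-1/2}
    e <- eigen(R)
    W <- e$vectors %*% diag(1 / sqrt(Re(e$values))) %*% Conj(t(e$vectors))
    pw <- multichannel_fid(W %*% p$data, p$dwell)
    direct <- roemer_combine(p, b, R)$fid
    white <- roemer_combine(pw, sensitivity_vector(as.vector(W %*% b$values)))$fid
    expect_lt(max(Mod(direct - white)) / max(Mod(direct)), 1e-8)

    # scale invariance: |P| unchanged under b -> c*b
    cc <- complex(real = rnorm(1), imaginary = rnorm(1))
    scaled <- roemer_combine(p, sensitivity_vector(cc * b$values), R)$fid
    expect_equal(Mod(scaled), Mod(direct), tolerance = 1e-8)
  }
})

test_that("matched-filter weighting beats random weights in analytic SNR", {
  set.seed(51)
  for (rep in 1:25) {
    nch <- 3L
    b <- complex(real = rnorm(nch), imaginary = rnorm(nch))
    R <- random_spd_cov(nch)
    w_opt <- solve(R, b)
    snr_opt <- analytic_snr(w_opt, b, R)
    w_rand <- random_unit_weights(nch, 2000L)
    snr_rand <- apply(w_rand, 2, analytic_snr, b = b, R = R)
    expect_true(all(snr_opt >= snr_rand - 1e-12))
  }
})

test_that("uniform-sensitivity form flattens gain and flags degenerate voxels", {
  m <- small_model(64L)
  fid <- spectrum_to_fid(make_spectrum(m))
  b <- sensitivity_vector(c(2 + 1i, -1 + 0.5i, 0.3 - 2i))
  p <- synth_voxel(fid, b, sigma = 0)
  cs <- roemer_combine_uniform_sensitivity(p, b)
  expect_equal(cs$fid, fid$samples, tolerance = 1e-10)

  # Nch = 1, b = 2, p = 2s -> P = s
  p1 <- multichannel_fid(matrix(2 * fid$samples, 1), fid$dwell)
  expect_equal(roemer_combine_uniform_sensitivity(p1, 2 + 0i)$fid,
               fid$samples, tolerance = 1e-12)

  # relation to the uniform-noise variant: factor sqrt(b^H R^-1 b)
  cs_un <- roemer_combine(p, b)
  expect_equal(cs_un$fid, cs$fid * sqrt(sum(Mod(b$values)^2)),
               tolerance = 1e-10)

  # degenerate b -> flagged missing, not an exception
  csf <- roemer_combine_uniform_sensitivity(p, sensitivity_vector(rep(0i, 3)))
  expect_true(csf$flagged)
  expect_true(all(is.na(csf$fid)))
})

test_that("sum-of-squares keeps magnitudes and a positive noise floor", {
  m <- small_model(64L)
  fid <- spectrum_to_fid(make_spectrum(m))
  p1 <- multichannel_fid(matrix(fid$samples, 1), fid$dwell)
  expect_equal(sum_of_squares(p1), Mod(fid$samples), tolerance = 1e-12)

  b16 <- true_sensitivity(16)
  p16 <- synth_voxel(fid, b16, sigma = 0)
  expect_equal(sum_of_squares(p16), 4 * Mod(fid$samples), tolerance = 1e-10)

  # pure-noise floor matches the chi-distribution mean within MC error
  set.seed(61)
  nch <- 8L; sigma <- 1
  noise <- matrix(complex(real = rnorm(nch * 1e4, 0, sigma),
                          imaginary = rnorm(nch * 1e4, 0, sigma)), nch)
  sos <- sum_of_squares(multichannel_fid(noise, 1 / 5000))
  expect_true(all(sos > 0))
  chi_mean <- sigma * sqrt(2) * exp(lgamma((2 * nch + 1) / 2) - lgamma(nch))
  expect_equal(mean(sos), chi_mean, tolerance = 0.02)
})

test_that("phase correction recovers the reference-peak phase", {
  m <- small_model()
  sp <- make_spectrum(m)
  fid <- spectrum_to_fid(sp)
  p <- synth_voxel(fid, true_sensitivity(4), sigma = 0)
  cs <- roemer_combine(p, true_sensitivity(4))

  # already phased: recovered phases ~ 0 (mod 2pi)
  pc0 <- phase_correct(cs)
  expect_lt(min(pc0$phi0, 2 * pi - pc0$phi0), 0.05)
  expect_lt(abs(pc0$phi1) * cs$bandwidth / 2, 0.05)

  # inject exp(i(0.7 + 0.002 (f - f_PCr))): zero-order recovered as -0.7 and
  # the real PCr height restored (phi1 is only weakly identified by a
  # narrow window; the restored height is the contract)
  ref_height <- max(Re(cs$spectrum[abs(cs$ppm) <= 1]))
  inj <- cs
  inj$spectrum <- cs$spectrum * exp(1i * (0.7 + 0.002 * (cs$freq_hz -
    mean(cs$freq_hz[abs(cs$ppm) <= 1]))))
  pc <- phase_correct(inj)
  expect_lt(abs(Arg(exp(1i * (pc$phi0 + 0.7)))), 0.05)
  got <- max(Re(pc$spectrum[abs(pc$ppm) <= 1]))
  expect_equal(got, ref_height, tolerance = 5e-3)

  # pure noise: finite phases, flagged low-confidence
  set.seed(71)
  nz <- cs
  nz$spectrum <- complex(real = rnorm(length(cs$spectrum)),
                         imaginary = rnorm(length(cs$spectrum)))
  pcn <- phase_correct(nz)
  expect_true(is.finite(pcn$phi0) && is.finite(pcn$phi1))
  expect_true(pcn$low_confidence)
})

test_that("SNR metrics use the 10-20 ppm noise convention", {
  m <- spectral_model(data.frame(shift = 0, amplitude = 3, linewidth = 10,
                                 phase = 0), n_points = 4096L)
  sp <- make_spectrum(m)
  set.seed(81)
  sigma <- 0.05
  noisy <- sp
  noisy$values <- sp$values + complex(real = rnorm(4096, 0, sigma),
                                      imaginary = rnorm(4096, 0, sigma))
  sm <- snr_metrics(noisy, peak_windows = list(PCr = c(-1, 1)))
  expect_equal(unname(sm$snr["PCr"]), 3 / sigma, tolerance = 0.1)

  expect_error(snr_metrics(noisy, noise_window = c(10, 20),
                           peak_windows = list(x = c(15, 18))), "overlaps")

  z <- sp; z$values[] <- 0i
  smz <- snr_metrics(z)
  expect_identical(smz$noise_sd, 0)
  expect_true(smz$flagged && all(is.na(smz$snr)))
})

test_that("dataset-level combination matches the voxel-level operator", {
  m <- small_model(32L)
  cmap <- array(1L, c(3L, 2L, 1L))
  ph <- synth_csi_phantom(cmap, list(m), n_channels = 3L,
                          k_weighting = "none", truncation_fraction = 1,
                          sigma = 0.005, seed = 13)
  res_self <- combine_csi(ph$target)
  expect_equal(dim(res_self$combined$data), c(3L, 2L, 1L, 1L, 32L))
  # voxel check against a direct call
  p <- multichannel_fid(ph$target$data[2, 1, 1, , ], ph$target$dwell)
  direct <- roemer_combine(p, estimate_sensitivity(p, c(2L, 5L)))
  expect_equal(res_self$combined$data[2, 1, 1, 1, ], direct$fid,
               tolerance = 1e-12)

  res_cross <- combine_csi(ph$target, b_map = ph$b_true)
  expect_identical(res_cross$provenance, "cross")
  expect_equal(nrow(res_cross$snr), 6L)
})
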