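test_that("Lorentzian spectra follow the peak-normalization convention", {
  # single line: real-part peak height equals the amplitude at its shift
  m <- spectral_model(data.frame(shift = 3, amplitude = 2.5, linewidth = 10,
                                 phase = 0), n_points = 512L)
  sp <- make_spectrum(m)
  at <- which.max(Re(sp$values))
  expect_equal(sp$ppm[at], 3, tolerance = 0.1)
  expect_equal(max(Re(sp$values)), 2.5, tolerance = 1e-2)

  # empty resonance list -> all-zero spectrum
  m0 <- spectral_model(data.frame(shift = numeric(), amplitude = numeric(),
                                  linewidth = numeric(), phase = numeric()))
  expect_true(all(make_spectrum(m0)$values == 0))

  # two equal lines at +-5 ppm: real part symmetric about 0 ppm, and the
  # whole spectrum matches an independently evaluated Lorentzian sum
  m2 <- spectral_model(data.frame(shift = c(-5, 5), amplitude = 1,
                                  linewidth = 15, phase = 0), n_points = 256L)
  sp2 <- make_spectrum(m2)
  expect_equal(sp2$values, lorentz_sum_oracle(m2), tolerance = 1e-12)
  re <- Re(sp2$values)
  n <- length(re)
  centre <- n %/% 2 + 1L
  k <- seq_len(centre - 2L)
  expect_equal(re[centre + k], re[centre - k], tolerance = 1e-10)
})

test_that("model validation names the offending resonance", {
  expect_error(spectral_model(data.frame(shift = 50, amplitude = 1,
                                         linewidth = 10, phase = 0)),
               "50.00 ppm")
  expect_error(spectral_model(data.frame(shift = 0, amplitude = 1,
                                         linewidth = -1, phase = 0)),
               "linewidth")
  expect_error(spectral_model(data.frame(shift = 0, amplitude = 1,
                                         linewidth = 1, phase = 0),
                              n_points = 4L), "n_points")
})

test_that("spectrum/FID transforms are exact inverses", {
  m <- small_model()
  sp <- make_spectrum(m)
  fid <- spectrum_to_fid(sp)
  back <- fid_to_spectrum(fid)
  expect_lt(max(Mod(back$values - sp$values)) / max(Mod(sp$values)), 1e-10)

  # all-zero spectrum -> all-zero FID
  z <- sp; z$values[] <- 0i
  expect_true(all(spectrum_to_fid(z)$samples == 0))

  # delta at band center -> constant-magnitude FID
  d <- sp; d$values[] <- 0i; d$values[length(d$values) %/% 2 + 1L] <- 1 + 0i
  mag <- Mod(spectrum_to_fid(d)$samples)
  expect_equal(max(mag) - min(mag), 0, tolerance = 1e-14)

  # random complex spectra roundtrip (property, fixed seed)
  set.seed(42)
  for (n in c(33L, 64L, 101L)) {
    mr <- spectral_model(data.frame(shift = 0, amplitude = 1, linewidth = 10,
                                    phase = 0), n_points = n)
    spr <- make_spectrum(mr)
    spr$values <- complex(real = rnorm(n), imaginary = rnorm(n))
    rt <- fid_to_spectrum(spectrum_to_fid(spr))
    expect_lt(max(Mod(rt$values - spr$values)) / max(Mod(spr$values)), 1e-10)
  }
})

test_that("true sensitivities are unit-magnitude quadrature phases", {
  b16 <- true_sensitivity(16)
  expect_equal(Mod(b16$values), rep(1, 16))
  expect_equal(sort(Arg(exp(1i * (Arg(b16$values))))),
               sort(Arg(exp(1i * (1:16) * 2 * pi / 16))), tolerance = 1e-12)
  expect_identical(b16$provenance, "true")

  expect_equal(true_sensitivity(1)$values, exp(2i * pi), tolerance = 1e-12)
  expect_lt(Mod(sum(true_sensitivity(4)$values)), 1e-12)
  expect_lt(Mod(sum(true_sensitivity(16)$values)), 1e-12)
  expect_error(true_sensitivity(0), "n_channels")
})

test_that("voxel synthesis obeys the additive complex Gaussian noise model", {
  m <- small_model(64L)
  fid <- spectrum_to_fid(make_spectrum(m))
  b <- true_sensitivity(4)

  p0 <- synth_voxel(fid, b, sigma = 0)
  expect_equal(p0$data[3, ], b$values[3] * fid$samples, tolerance = 1e-14)

  # s = 0: per-channel real-part variance ~ sigma^2 (law of large numbers)
  zfid <- fid; zfid$samples[] <- 0i
  set.seed(7)
  xs <- replicate(200, synth_voxel(zfid, true_sensitivity(2), sigma = 1)$data[1, ])
  expect_equal(stats::var(Re(as.vector(xs))), 1, tolerance = 0.03)

  # determinism: identical seeds give bit-identical data
  expect_identical(synth_voxel(fid, b, 0.5, seed = 11)$data,
                   synth_voxel(fid, b, 0.5, seed = 11)$data)

  # empirical inter-channel covariance of pure noise ~ 2*sigma^2*I
  nch <- 4L
  nsamp <- 100000L
  set.seed(5)
  X <- matrix(complex(real = rnorm(nsamp * nch, 0, 0.7),
                      imaginary = rnorm(nsamp * nch, 0, 0.7)), nsamp, nch)
  R <- (t(X) %*% Conj(X)) / (nsamp - 1)
  target <- diag(2 * 0.7^2, nch)
  frob <- function(M) sqrt(sum(Mod(M)^2))
  expect_lt(frob(R - target) / frob(target), 0.05)
})

test_that("cross-nucleus sensitivity perturbation and noise behave as declared", {
  b <- true_sensitivity(8)
  expect_equal(synth_cross_sensitivity(b, 0, 0, seed = 1)$values, b$values,
               tolerance = 1e-14)

  # sigma_cross = sigma/10 keeps the combined-SNR loss small; oracle is the
  # analytic SNR ratio |bhat^H b|^2 / (bhat^H bhat * b^H b)
  set.seed(8)
  losses <- replicate(50, {
    bh <- synth_cross_sensitivity(b, sigma_cross = 0.1)$values
    Mod(sum(Conj(bh) * b$values))^2 /
      (Re(sum(Conj(bh) * bh)) * Re(sum(Conj(b$values) * b$values)))
  })
  expect_gt(mean(losses), 0.95)

  # calibrated systematic perturbation alone: <= 5% SNR loss
  set.seed(9)
  losses2 <- replicate(50, {
    bh <- synth_cross_sensitivity(b, 0, perturbation = 0.2)$values
    Mod(sum(Conj(bh) * b$values))^2 /
      (Re(sum(Conj(bh) * bh)) * Re(sum(Conj(b$values) * b$values)))
  })
  expect_gt(min(losses2), 0.95)
})

test_that("CSI phantom reproduces signals exactly without truncation and
           leaks monotonically with it", {
  m <- small_model(32L)
  cmap <- array(0L, c(12L, 1L, 1L))
  cmap[2:4, 1, 1] <- 1L      # high compartment
  cmap[5:9, 1, 1] <- 2L      # low compartment; 10:12 stays zero
  m_low <- m; m_low$resonances$amplitude <- m$resonances$amplitude * 0.25

  exact <- synth_csi_phantom(cmap, list(m, m_low), n_channels = 2L,
                             k_weighting = "none", truncation_fraction = 1,
                             sigma = 0, seed = 1)
  fid1 <- spectrum_to_fid(make_spectrum(m))$samples
  bt <- true_sensitivity(2)$values
  expect_equal(exact$target$data[3, 1, 1, 1, ], bt[1] * fid1,
               tolerance = 1e-10)
  expect_equal(max(Mod(exact$target$data[11, 1, 1, , ])), 0, tolerance = 1e-12)

  # leakage trend on a longer profile with an interior zero compartment
  # (sidelobe oscillation makes the decrease a trend, not strictly
  # pointwise; it vanishes exactly at full k-space)
  cmap2 <- array(0L, c(192L, 1L, 1L))
  cmap2[10:40, 1, 1] <- 1L
  cmap2[41:170, 1, 1] <- 2L
  cmap2[100:130, 1, 1] <- 0L             # zero-signal compartment inside
  leak_at <- function(fr) {
    ph <- synth_csi_phantom(cmap2, list(m, m_low), n_channels = 2L,
                            k_weighting = "none", truncation_fraction = fr,
                            sigma = 0, seed = 1)
    mean(Mod(ph$target$data[103:127, 1, 1, , ]))
  }
  leak <- vapply(c(0.5, 0.7, 0.95, 1), leak_at, numeric(1))
  expect_gt(leak[3], 0)
  expect_gt(leak[1], leak[3])
  expect_gt(leak[2], leak[3])
  expect_lt(leak[4], 1e-12)

  # determinism of the full generator
  a <- synth_csi_phantom(cmap, list(m, m_low), n_channels = 2L, sigma = 0.01,
                         sigma_cross = 0.001, seed = 3)
  b2 <- synth_csi_phantom(cmap, list(m, m_low), n_channels = 2L, sigma = 0.01,
                          sigma_cross = 0.001, seed = 3)
  expect_identical(a$target$data, b2$target$data)
  expect_identical(a$cross$data, b2$cross$data)
})
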