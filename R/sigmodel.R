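#' Spectral model for synthetic MRS signals
#'
#' A `spectral_model` describes a noiseless single-voxel spectrum as a sum of
#' Lorentzian resonances on a ppm axis, together with the acquisition axis
#' (number of complex points and readout bandwidth). The amplitude convention
#' is *peak normalization*: a resonance of amplitude `A` and phase 0
#' contributes a real-part peak height of `A` at its chemical shift.
#'
#' @param resonances data frame with columns `shift` (ppm), `amplitude`
#'   (a.u., >= 0), `linewidth` (full width at half maximum, Hz, > 0) and
#'   `phase` (radians).
#' @param n_points number of complex spectral/FID points (>= 8).
#' @param bandwidth readout bandwidth in Hz.
#' @param carrier_ppm ppm value assigned to the center of the readout band.
#'   With the default 0 the PCr resonance of the default 31P model sits at
#'   band center.
#' @param f0_mhz Larmor frequency in MHz used to convert ppm to Hz
#'   (default 120.6, 31P at 7 T).
#' @return an object of class `spectral_model`.
#' @seealso [default_p31_model()], [make_spectrum()]
#' @export
spectral_model <- function(resonances, n_points = 256L, bandwidth = 5000,
                           carrier_ppm = 0, f0_mhz = 120.6) {
  resonances <- as.data.frame(resonances)
  needed <- c("shift", "amplitude", "linewidth", "phase")
  missing_cols <- setdiff(needed, names(resonances))
  if (length(missing_cols) > 0)
    stop("resonances lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (n_points < 8L) stop("n_points must be >= 8")
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  if (f0_mhz <= 0) stop("f0_mhz must be > 0")
  if (nrow(resonances) > 0) {
    if (any(resonances$linewidth <= 0)) stop("every linewidth must be > 0")
    if (any(resonances$amplitude < 0)) stop("amplitudes must be >= 0")
  }
  model <- structure(
    list(resonances = resonances, n_points = as.integer(n_points),
         bandwidth = bandwidth, carrier_ppm = carrier_ppm, f0_mhz = f0_mhz),
    class = "spectral_model")
  span <- model_ppm_span(model)
  if (nrow(resonances) > 0) {
    out <- resonances$shift < span[1] | resonances$shift > span[2]
    if (any(out))
      stop(sprintf("resonance at %.2f ppm lies outside the readout band [%.2f, %.2f] ppm",
                   resonances$shift[which(out)[1]], span[1], span[2]))
  }
  model
}

model_ppm_span <- function(model) {
  half <- model$bandwidth / 2 / model$f0_mhz
  model$carrier_ppm + c(-half, half)
}

#' Default synthetic 31P spectral model
#'
#' A multi-peak 31P brain-like spectrum: PCr at 0 ppm (band center) plus
#' phosphomonoester, inorganic phosphate, phosphodiester and the three ATP
#' resonances at literature chemical shifts. Relative amplitudes and
#' linewidths are package defaults chosen to give a realistic-looking
#' spectrum; they are illustrative, not a reproduction of any measured
#' dataset. No resonance lies in the 10-20 ppm region, which is reserved as
#' the noise window of [snr_metrics()].
#'
#' @inheritParams spectral_model
#' @return a [spectral_model()].
#' @export
default_p31_model <- function(n_points = 256L, bandwidth = 5000,
                              f0_mhz = 120.6) {
  res <- data.frame(
    label = c("PCr", "PME", "Pi", "PDE", "gATP", "aATP", "bATP"),
    shift = c(0, 6.7, 4.82, 2.9, -2.48, -7.52, -16.26),
    amplitude = c(1.0, 0.25, 0.4, 0.3, 0.55, 0.55, 0.45),
    linewidth = c(12, 18, 15, 18, 20, 20, 24),
    phase = 0)
  spectral_model(res, n_points = n_points, bandwidth = bandwidth,
                 carrier_ppm = 0, f0_mhz = f0_mhz)
}

#' Frequency and ppm axes of a spectral model
#'
#' Frequency offsets (Hz, relative to the carrier) and the corresponding ppm
#' coordinates, in display order: frequency increases with index and the
#' carrier sits at index `floor(n/2)+1`. ppm increases with frequency offset;
#' the axis is stored explicitly with every spectrum so no left-right display
#' convention is assumed.
#'
#' @param model a [spectral_model()].
#' @return list with `freq_hz` and `ppm` numeric vectors.
#' @export
model_axes <- function(model) {
  n <- model$n_points
  freq <- (seq_len(n) - (n %/% 2 + 1L)) * model$bandwidth / n
  list(freq_hz = freq, ppm = model$carrier_ppm + freq / model$f0_mhz)
}

#' Evaluate the complex spectrum of a spectral model
#'
#' Each resonance contributes a complex Lorentzian
#' `A * exp(i*phase) * g / (g + i*(f - f0))` with `g` the half width at half
#' maximum in Hz, so that a zero-phase line has real-part peak height `A` at
#' its shift.
#'
#' @param model a [spectral_model()].
#' @return an object of class `mrs_spectrum`: list with complex `values`,
#'   `ppm`, `freq_hz`, `bandwidth`, `carrier_ppm`, `f0_mhz`.
#' @export
make_spectrum <- function(model) {
  stopifnot(inherits(model, "spectral_model"))
  ax <- model_axes(model)
  values <- complex(length.out = model$n_points)
  if (nrow(model$resonances) > 0) {
    for (r in seq_len(nrow(model$resonances))) {
      res <- model$resonances[r, ]
      f0 <- (res$shift - model$carrier_ppm) * model$f0_mhz
      g <- res$linewidth / 2
      values <- values + res$amplitude * exp(1i * res$phase) *
        g / (g + 1i * (ax$freq_hz - f0))
    }
  }
  structure(list(values = values, ppm = ax$ppm, freq_hz = ax$freq_hz,
                 bandwidth = model$bandwidth, carrier_ppm = model$carrier_ppm,
                 f0_mhz = model$f0_mhz),
            class = "mrs_spectrum")
}

as_mrs_spectrum <- function(values, template) {
  structure(list(values = values, ppm = template$ppm,
                 freq_hz = template$freq_hz, bandwidth = template$bandwidth,
                 carrier_ppm = template$carrier_ppm, f0_mhz = template$f0_mhz),
            class = "mrs_spectrum")
}

#' Convert a spectrum to its FID
#'
#' Inverse Fourier transform under the package's fixed ordering convention
#' (see `fourier.R`): `fid_to_spectrum(spectrum_to_fid(x))` reproduces `x`
#' to numerical precision.
#'
#' @param spectrum an `mrs_spectrum`.
#' @return object of class `fid_signal`: complex `samples`, `dwell` (s), and
#'   the axis metadata of its spectrum.
#' @export
spectrum_to_fid <- function(spectrum) {
  stopifnot(inherits(spectrum, "mrs_spectrum"))
  if (any(!is.finite(Re(spectrum$values)) | !is.finite(Im(spectrum$values))))
    stop("spectrum contains non-finite values")
  samples <- ifft(ifftshift(spectrum$values))
  structure(list(samples = samples, dwell = 1 / spectrum$bandwidth,
                 bandwidth = spectrum$bandwidth, ppm = spectrum$ppm,
                 freq_hz = spectrum$freq_hz, carrier_ppm = spectrum$carrier_ppm,
                 f0_mhz = spectrum$f0_mhz),
            class = "fid_signal")
}

#' @rdname spectrum_to_fid
#' @param fid a `fid_signal` (or a `multichannel_fid` combined down to one
#'   channel).
#' @export
fid_to_spectrum <- function(fid) {
  stopifnot(inherits(fid, "fid_signal"))
  structure(list(values = fftshift(stats::fft(fid$samples)), ppm = fid$ppm,
                 freq_hz = fid$freq_hz, bandwidth = fid$bandwidth,
                 carrier_ppm = fid$carrier_ppm, f0_mhz = fid$f0_mhz),
            class = "mrs_spectrum")
}

#' Sensitivity vectors
#'
#' A per-channel complex receive sensitivity for one voxel, tagged by
#' provenance: `"true"` (noise-free ground truth), `"self"` (estimated from
#' the data being combined), `"other"` (from an independent equal-noise
#' acquisition) or `"cross"` (from another nucleus, e.g. 23Na).
#'
#' @param values complex vector, one entry per channel.
#' @param provenance one of `"true"`, `"self"`, `"other"`, `"cross"`.
#' @param source_snr SNR of the signal the sensitivity was derived from
#'   (dimensionless), or `NA` if unknown.
#' @return object of class `sensitivity_vector`.
#' @export
sensitivity_vector <- function(values, provenance = c("true", "self", "other", "cross"),
                               source_snr = NA_real_) {
  provenance <- match.arg(provenance)
  structure(list(values = as.complex(values), provenance = provenance,
                 source_snr = source_snr),
            class = "sensitivity_vector")
}

#' Quadrature-phase unit-magnitude true sensitivity
#'
#' The idealized phased-array sensitivity used by the Monte Carlo study:
#' every channel has unit magnitude and the channels step through one full
#' phase cycle, `b_k = exp(i * k * 2*pi / n_channels)`, `k = 1..n_channels`.
#'
#' @param n_channels number of receive channels (>= 1).
#' @return a [sensitivity_vector()] with provenance `"true"`.
#' @export
true_sensitivity <- function(n_channels) {
  if (length(n_channels) != 1L || n_channels < 1)
    stop("n_channels must be a single integer >= 1")
  k <- seq_len(n_channels)
  sensitivity_vector(exp(1i * k * 2 * pi / n_channels), provenance = "true")
}

#' Multi-channel FID container
#'
#' @param data complex matrix, channels in rows, FID samples in columns.
#' @param dwell dwell time in seconds.
#' @param f0_mhz,carrier_ppm axis metadata (see [spectral_model()]).
#' @return object of class `multichannel_fid`.
#' @export
multichannel_fid <- function(data, dwell, f0_mhz = 120.6, carrier_ppm = 0) {
  data <- as.matrix(data)
  if (nrow(data) < 1L) stop("need at least one channel")
  if (any(!is.finite(Re(data)) | !is.finite(Im(data))))
    stop("multichannel FID must be finite-valued")
  structure(list(data = data, dwell = dwell, f0_mhz = f0_mhz,
                 carrier_ppm = carrier_ppm),
            class = "multichannel_fid")
}

n_channels <- function(p) nrow(p$data)

mcfid_axes <- function(p) {
  n <- ncol(p$data)
  bw <- 1 / p$dwell
  freq <- (seq_len(n) - (n %/% 2 + 1L)) * bw / n
  list(freq_hz = freq, ppm = p$carrier_ppm + freq / p$f0_mhz, bandwidth = bw)
}

#' Synthesize one noisy multi-channel voxel
#'
#' Implements the signal model `p_k = b_k * s + n_k` with independent complex
#' Gaussian noise per channel and per sample: real and imaginary components
#' each have standard deviation `sigma`, and there is no inter-channel noise
#' correlation.
#'
#' @param fid a [spectrum_to_fid()] result, the true single-voxel FID `s`.
#' @param b a [sensitivity_vector()].
#' @param sigma per-component noise standard deviation (>= 0).
#' @param seed optional integer; when given, the draw is reproducible.
#' @return a [multichannel_fid()].
#' @export
synth_voxel <- function(fid, b, sigma, seed = NULL) {
  stopifnot(inherits(fid, "fid_signal"), inherits(b, "sensitivity_vector"))
  if (sigma < 0) stop("sigma must be >= 0")
  nch <- length(b$values)
  nf <- length(fid$samples)
  with_seed_if(seed, {
    noise <- if (sigma > 0) matrix(complex_noise(nch * nf, sigma), nch, nf)
             else matrix(0i, nch, nf)
    data <- outer(b$values, fid$samples) + noise
    multichannel_fid(data, dwell = fid$dwell, f0_mhz = fid$f0_mhz,
                     carrier_ppm = fid$carrier_ppm)
  })
}

#' Emulate a cross-nucleus (23Na-like) sensitivity estimate
#'
#' Returns the true sensitivity perturbed by (a) an optional small systematic
#' complex deviation, standing in for the receive-field difference between
#' the two Larmor frequencies, and (b) independent complex Gaussian noise of
#' per-component standard deviation `sigma_cross`, standing in for the (high
#' but finite) SNR of the cross-nucleus acquisition. The noise is drawn
#' independently of any data noise.
#'
#' @param b_true a [sensitivity_vector()].
#' @param sigma_cross per-component noise std of the sensitivity estimate.
#' @param perturbation relative magnitude of the systematic complex deviation
#'   (0 = none). Each channel is multiplied by `1 + perturbation * u_k` with
#'   `u_k` a fixed unit-modulus complex number drawn once per call.
#' @param seed optional integer seed.
#' @return a [sensitivity_vector()] with provenance `"cross"`.
#' @export
synth_cross_sensitivity <- function(b_true, sigma_cross, perturbation = 0,
                                    seed = NULL) {
  stopifnot(inherits(b_true, "sensitivity_vector"))
  if (sigma_cross < 0 || perturbation < 0)
    stop("sigma_cross and perturbation must be >= 0")
  nch <- length(b_true$values)
  with_seed_if(seed, {
    u <- exp(1i * stats::runif(nch, 0, 2 * pi))
    v <- b_true$values * (1 + perturbation * u)
    if (sigma_cross > 0) v <- v + complex_noise(nch, sigma_cross)
    snr <- if (sigma_cross > 0) mean(Mod(b_true$values)) / sigma_cross else Inf
    sensitivity_vector(v, provenance = "cross", source_snr = snr)
  })
}

#' Hermitian noise covariance container
#'
#' @param matrix complex square matrix; must be Hermitian to numerical
#'   tolerance with strictly positive eigenvalues.
#' @return object of class `noise_covariance`.
#' @export
noise_covariance <- function(matrix) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix)) stop("covariance must be square")
  herm_err <- max(Mod(matrix - Conj(t(matrix))))
  if (herm_err > 1e-8 * max(Mod(matrix), 1e-300))
    stop("covariance is not Hermitian")
  ev <- eigen((matrix + Conj(t(matrix))) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) <= 0) stop("covariance is not positive-definite")
  structure(list(matrix = matrix), class = "noise_covariance")
}

registered_nuclei <- function() c("31P", "23Na", "1H", "13C", "19F", "2H", "17O")

#' CSI dataset container
#'
#' A spatial grid of multi-channel FIDs plus acquisition metadata, the unit
#' the I/O layer and the CLI read and write.
#'
#' @param data complex array of dimension `(Nx, Ny, Nz, Nch, Nfid)`.
#' @param voxel_mm voxel size, mm, length-3.
#' @param fov_mm field of view, mm, length-3; must equal grid size times
#'   voxel size (to 1e-6 relative).
#' @param nucleus one of `registered` nuclei labels (e.g. `"31P"`, `"23Na"`).
#' @param dwell dwell time, s.
#' @param noise_scan optional complex matrix `(N_samples, Nch)` from a
#'   noise-only acquisition.
#' @param f0_mhz,carrier_ppm spectral axis metadata.
#' @return object of class `csi_dataset`.
#' @export
csi_dataset <- function(data, voxel_mm, fov_mm, nucleus, dwell,
                        noise_scan = NULL, f0_mhz = 120.6, carrier_ppm = 0) {
  if (length(dim(data)) != 5L)
    stop("data must be a 5-D array (Nx, Ny, Nz, Nch, Nfid)")
  if (!nucleus %in% registered_nuclei())
    stop("unknown nucleus label '", nucleus, "'; registered: ",
         paste(registered_nuclei(), collapse = ", "))
  if (length(voxel_mm) != 3L || length(fov_mm) != 3L)
    stop("voxel_mm and fov_mm must have length 3")
  expected_fov <- dim(data)[1:3] * voxel_mm
  if (any(abs(fov_mm - expected_fov) > 1e-6 * pmax(expected_fov, 1)))
    stop("fov_mm must equal grid size * voxel_mm per component")
  if (!is.null(noise_scan)) noise_scan <- as.matrix(noise_scan)
  structure(list(data = data, voxel_mm = as.numeric(voxel_mm),
                 fov_mm = as.numeric(fov_mm), nucleus = nucleus, dwell = dwell,
                 noise_scan = noise_scan, f0_mhz = f0_mhz,
                 carrier_ppm = carrier_ppm),
            class = "csi_dataset")
}

csi_grid_dim <- function(ds) dim(ds$data)[1:3]

# Extract one voxel as a multichannel_fid.
csi_voxel <- function(ds, i, j, k) {
  multichannel_fid(ds$data[i, j, k, , , drop = TRUE], dwell = ds$dwell,
                   f0_mhz = ds$f0_mhz, carrier_ppm = ds$carrier_ppm)
}

#' Synthesize a paired low-SNR / high-SNR CSI phantom
#'
#' Builds two CSI datasets on one spatial grid: a low-SNR target-nucleus
#' (31P-like) dataset and a high-SNR cross-nucleus (23Na-like) dataset that
#' shares the receive sensitivities up to an optional systematic perturbation
#' and per-channel global phase offsets. Per nucleus, the voxel-wise
#' noise-free signal is compartment spectrum x per-channel sensitivity; each
#' spatial dimension is Fourier transformed to k-space, multiplied by the
#' chosen window, truncated to the central fraction of samples, and
#' transformed back, emulating the point-spread function of low-resolution
#' CSI with Hamming-weighted, truncated k-space sampling. Independent complex
#' Gaussian noise is then added per channel.
#'
#' @param compartment_map integer array `(Nx, Ny, Nz)`; 0 = empty, values
#'   `1..K` select a model from `models`.
#' @param models list of K [spectral_model()] objects (target nucleus), all
#'   sharing `n_points` and `bandwidth`.
#' @param b_map complex array `(Nch, Nx, Ny, Nz)` of per-channel
#'   sensitivities, or `NULL` for a spatially uniform [true_sensitivity()].
#' @param n_channels used when `b_map` is `NULL`.
#' @param k_weighting `"hamming"` or `"none"`.
#' @param truncation_fraction fraction of central k-space retained, per
#'   dimension, in (0, 1].
#' @param sigma per-component noise std of the target dataset.
#' @param sigma_cross per-component noise std of the cross dataset.
#' @param cross_model [spectral_model()] for the cross nucleus; default one
#'   resonance at the carrier with amplitude `cross_amplitude`.
#' @param cross_amplitude amplitude of the default cross-nucleus line. The
#'   default 10 encodes the order-of-magnitude concentration advantage of
#'   23Na over 31P.
#' @param cross_perturbation systematic sensitivity deviation between the
#'   nuclei (see [synth_cross_sensitivity()]).
#' @param channel_phase_offsets optional per-channel phases (radians) applied
#'   to the cross-nucleus sensitivities/data, emulating the hardware phase
#'   offset between the two receive chains that [calibrate_phase()] removes.
#' @param voxel_mm voxel size, mm.
#' @param seed optional integer seed.
#' @return list with `target` and `cross` ([csi_dataset()]s), `b_true`
#'   (complex `(Nch, Nx, Ny, Nz)` array), `b_cross` (idem, perturbed and
#'   phase-offset), and `channel_phase_offsets`.
#' @export
synth_csi_phantom <- function(compartment_map, models, b_map = NULL,
                              n_channels = 8L,
                              k_weighting = c("hamming", "none"),
                              truncation_fraction = 0.95,
                              sigma = 0, sigma_cross = 0,
                              cross_model = NULL, cross_amplitude = 10,
                              cross_perturbation = 0,
                              channel_phase_offsets = NULL,
                              voxel_mm = c(20, 20, 20), seed = NULL) {
  k_weighting <- match.arg(k_weighting)
  compartment_map <- as.array(compartment_map)
  if (length(dim(compartment_map)) != 3L)
    stop("compartment_map must be a 3-D array")
  gd <- dim(compartment_map)
  K <- max(compartment_map)
  if (K < 1 || length(models) < K)
    stop("need one spectral model per compartment label")
  ref <- models[[1]]
  nf <- ref$n_points
  if (is.null(b_map)) {
    bt <- true_sensitivity(n_channels)$values
    b_map <- array(rep(bt, times = prod(gd)), dim = c(n_channels, gd))
  } else {
    b_map <- as.array(b_map)
    if (!all(dim(b_map)[-1] == gd))
      stop("b_map grid does not match compartment_map grid")
    n_channels <- dim(b_map)[1]
  }
  if (is.null(cross_model)) {
    cross_model <- spectral_model(
      data.frame(shift = 0, amplitude = cross_amplitude, linewidth = 25,
                 phase = 0),
      n_points = nf, bandwidth = ref$bandwidth,
      carrier_ppm = ref$carrier_ppm, f0_mhz = ref$f0_mhz * 78.9 / 120.6)
  }
  if (is.null(channel_phase_offsets)) channel_phase_offsets <- numeric(n_channels)
  if (length(channel_phase_offsets) != n_channels)
    stop("channel_phase_offsets must have one entry per channel")

  fids <- lapply(models, function(m) spectrum_to_fid(make_spectrum(m))$samples)
  cross_fid <- spectrum_to_fid(make_spectrum(cross_model))$samples

  build <- function(fid_list, bmap, noise_sd) {
    # noise-free voxel signal: compartment FID x channel sensitivity
    data <- array(0i, dim = c(gd, n_channels, nf))
    for (cmp in seq_len(K)) {
      idx <- which(compartment_map == cmp, arr.ind = TRUE)
      if (nrow(idx) == 0) next
      for (r in seq_len(nrow(idx))) {
        i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
        data[i, j, k, , ] <- outer(bmap[, i, j, k], fid_list[[cmp]])
      }
    }
    # spatial k-space windowing + truncation, per dimension
    masks <- lapply(gd, function(n) {
      if (n == 1L) return(1)
      if (k_weighting == "hamming") hamming_mask(n, truncation_fraction)
      else kspace_mask(n, truncation_fraction)
    })
    if (any(gd > 1L)) {
      for (d in 1:3) {
        if (gd[d] == 1L) next
        data <- fft_along(data, d)
        m <- ifftshift(masks[[d]])
        data <- sweep(data, d, m, `*`)
        data <- fft_along(data, d, inverse = TRUE)
      }
    }
    if (noise_sd > 0)
      data <- data + array(complex_noise(length(data), noise_sd), dim = dim(data))
    data
  }

  with_seed_if(seed, {
    target_data <- build(fids, b_map, sigma)
    u <- exp(1i * stats::runif(n_channels, 0, 2 * pi))
    pert <- 1 + cross_perturbation * u
    b_cross <- b_map * as.vector(pert * exp(1i * channel_phase_offsets))
    if (sigma_cross > 0)
      b_cross <- b_cross + array(complex_noise(length(b_cross), sigma_cross),
                                 dim = dim(b_cross))
    cross_data <- build(list(cross_fid)[rep(1, K)], b_cross, sigma_cross)
    fov <- gd * voxel_mm
    list(
      target = csi_dataset(target_data, voxel_mm, fov, "31P",
                           dwell = 1 / ref$bandwidth, f0_mhz = ref$f0_mhz,
                           carrier_ppm = ref$carrier_ppm),
      cross = csi_dataset(cross_data, voxel_mm, fov, "23Na",
                          dwell = 1 / cross_model$bandwidth,
                          f0_mhz = cross_model$f0_mhz,
                          carrier_ppm = cross_model$carrier_ppm),
      b_true = b_map, b_cross = b_cross,
      channel_phase_offsets = channel_phase_offsets)
  })
}
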