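#' Ripple artifact specification
#'
#' Model of the low-spatial-frequency "fuzzy ripple" artifact arising from
#' gradient trajectory imperfections at EPI ramp-sampling corners: a
#' multiplicative sinusoidal modulation along the readout axis whose sign
#' flips with read polarity (odd parity). This synthetic functional form is
#' the simplest model consistent with the artifact being cancelled by
#' dual-read-polarity combination; it is not a physical trajectory model.
#'
#' @param amplitude Modulation amplitude as a fraction of the local signal
#'   (>= 0).
#' @param freq Spatial frequency in cycles per field of view along the
#'   readout axis.
#' @param parity Logical; if `TRUE` (default) the modulation sign flips
#'   with read polarity.
#' @param phase Phase offset of the sinusoid (radians).
#' @return A `ripple_spec` list.
#' @export
ripple_spec <- function(amplitude = 0.1, freq = 3, parity = TRUE,
                        phase = 0.7) {
  if (amplitude < 0) stop("ripple amplitude must be non-negative")
  structure(list(amplitude = as.numeric(amplitude), freq = as.numeric(freq),
                 parity = isTRUE(parity), phase = as.numeric(phase)),
            class = "ripple_spec")
}

#' Generate a synthetic digital brain-like phantom
#'
#' Deterministic (seeded) concentric "cortex" geometry: a WM core, a GM
#' ribbon of configurable thickness and a CSF rim, built as nested spheres
#' whose radius may be perturbed by a low-order angular modulation to
#' emulate folding. Per-tissue T1/M0 are drawn from the simulation defaults
#' with optional within-tissue variation; a band-limited random B0 field
#' (Hz) and a smooth low-order polynomial B1+ field complete the phantom.
#'
#' @param seed Integer seed; the phantom is bit-reproducible given the seed.
#' @param shape Integer dimensions, each >= 32.
#' @param voxel_mm Isotropic voxel size in mm.
#' @param gm_thickness GM ribbon thickness in voxels.
#' @param csf_thickness CSF rim thickness in voxels.
#' @param wm_radius WM core radius as a fraction of the half field of view.
#' @param fold_amp Amplitude of the angular folding perturbation (fraction
#'   of the local radius; 0 = exact spheres).
#' @param fold_freq Angular frequency of the folding perturbation.
#' @param tissues Named list of [tissue_params()] (CSF, GM, WM).
#' @param t1_variation Within-tissue T1/M0 coefficient of variation.
#' @param b0_peak_hz Peak |B0| off-resonance inside the support (Hz).
#' @param b0_smooth_vox Gaussian smoothing scale of the B0 field (voxels).
#' @param b1_inhom Peak deviation of the B1+ field from 1.
#' @return An object of class `phantom`: list with arrays `labels`
#'   (0 background, 1 CSF, 2 GM, 3 WM), `t1` (ms), `m0`, `b0` (Hz), `b1`,
#'   plus `voxel_mm` and `affine`.
#' @examples
#' ph <- generate_phantom(1, shape = c(32, 32, 32))
#' table(ph$labels)
#' @export
generate_phantom <- function(seed, shape = c(48, 48, 48), voxel_mm = 0.8,
                             gm_thickness = 4, csf_thickness = 3,
                             wm_radius = 0.5, fold_amp = 0.06,
                             fold_freq = 5, tissues = default_tissues(),
                             t1_variation = 0.02,
                             b0_peak_hz = 30, b0_smooth_vox = 5,
                             b1_inhom = 0.15) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 32L))
    stop("phantom shape must be at least 32 voxels along every axis")
  set.seed(as.integer(seed))
  ctr <- (shape + 1) / 2
  half <- min(shape) / 2
  ax <- lapply(1:3, function(k) seq_len(shape[k]) - ctr[k])
  X <- array(rep(ax[[1]], times = shape[2] * shape[3]), shape)
  Y <- array(rep(rep(ax[[2]], each = shape[1]), times = shape[3]), shape)
  Z <- array(rep(ax[[3]], each = shape[1] * shape[2]), shape)
  r <- sqrt(X^2 + Y^2 + Z^2)
  theta <- atan2(Y, X)
  phi <- acos(ifelse(r > 0, Z / pmax(r, 1e-9), 1))
  rho <- 1 + fold_amp * sin(fold_freq * theta) * sin(2 * phi)
  r_wm <- wm_radius * half * rho
  r_gm <- r_wm + gm_thickness
  r_csf <- r_gm + csf_thickness
  labels <- array(0L, shape)
  labels[r <= r_csf] <- 1L
  labels[r <= r_gm] <- 2L
  labels[r <= r_wm] <- 3L
  t1 <- array(0, shape); m0 <- array(0, shape)
  lab_of <- c(CSF = 1L, GM = 2L, WM = 3L)
  for (nm in names(lab_of)) {
    sel <- labels == lab_of[[nm]]
    nv <- sum(sel)
    tp <- tissues[[nm]]
    jitter_t1 <- if (t1_variation > 0) stats::rnorm(nv, 1, t1_variation) else rep(1, nv)
    jitter_m0 <- if (t1_variation > 0) stats::rnorm(nv, 1, t1_variation) else rep(1, nv)
    t1[sel] <- tp$T1 * pmax(jitter_t1, 0.5)
    m0[sel] <- tp$M0 * pmax(jitter_m0, 0.5)
  }
  supp <- labels > 0L
  fm <- generate_field_maps(seed + 1L, shape, peak_hz = b0_peak_hz,
                            b1_inhom = b1_inhom,
                            smooth_vox = b0_smooth_vox, support = supp)
  aff <- diag(c(rep(voxel_mm, 3), 1))
  aff[1:3, 4] <- -(ctr - 1) * voxel_mm
  structure(list(labels = labels, t1 = t1, m0 = m0,
                 b0 = fm$b0$data, b1 = fm$b1$data,
                 voxel_mm = voxel_mm, affine = aff,
                 params = list(wm_radius = wm_radius,
                               gm_thickness = gm_thickness,
                               csf_thickness = csf_thickness,
                               fold_amp = fold_amp,
                               tissues = tissues)),
            class = "phantom")
}

#' Generate smooth synthetic B0 and B1 field maps
#'
#' Band-limited random fields, deterministic given the seed. The B0 field
#' is Gaussian-smoothed white noise rescaled so its maximum magnitude
#' equals `peak_hz` and its mean over the support is zero; off-resonance
#' does not stop at the object edge, so the field stays smooth across the
#' whole grid. The B1+ field is a smooth low-order polynomial
#' modulation around 1 with peak deviation `b1_inhom`, normalised to mean 1
#' over the support — a synthetic stand-in for a measured low-resolution
#' transmit-field template.
#'
#' @param seed Integer seed.
#' @param shape Integer dimensions (length 3).
#' @param peak_hz Peak |B0| (Hz, >= 0).
#' @param b1_inhom Peak |B1 - 1| (>= 0).
#' @param smooth_vox Gaussian smoothing sigma of the B0 noise (voxels).
#' @param support Logical array of the object support, or `NULL` for the
#'   whole grid.
#' @param affine Voxel-to-world affine for the returned volumes.
#' @return List with `b0` and `b1` [image_volume()]s.
#' @export
generate_field_maps <- function(seed, shape, peak_hz = 30, b1_inhom = 0.15,
                                smooth_vox = 5, support = NULL,
                                affine = diag(4)) {
  if (peak_hz < 0) stop("peak_hz must be non-negative")
  shape <- as.integer(shape)
  set.seed(as.integer(seed))
  if (is.null(support)) support <- array(TRUE, shape)
  b0 <- array(0, shape)
  if (peak_hz > 0) {
    # smooth everywhere (off-resonance does not stop at the object edge);
    # zero mean over the support, peak magnitude scaled to peak_hz
    b0 <- smooth3d(array(stats::rnorm(prod(shape)), shape), smooth_vox)
    b0 <- b0 - mean(b0[support])
    mx <- max(abs(b0))
    if (mx > 0) b0 <- b0 * (peak_hz / mx)
  }
  ctr <- (shape + 1) / 2
  nx <- lapply(1:3, function(k) (seq_len(shape[k]) - ctr[k]) / (shape[k] / 2))
  Xn <- array(rep(nx[[1]], times = shape[2] * shape[3]), shape)
  Yn <- array(rep(rep(nx[[2]], each = shape[1]), times = shape[3]), shape)
  Zn <- array(rep(nx[[3]], each = shape[1] * shape[2]), shape)
  co <- stats::runif(6, -1, 1)
  pol <- co[1] * Xn + co[2] * Yn + co[3] * Zn +
    co[4] * Xn * Yn + co[5] * (Xn^2 - Zn^2) + co[6] * (Yn^2 - 0.5)
  # centre and scale over the support: mean exactly 1 and peak deviation
  # exactly b1_inhom inside the object
  pol <- pol - mean(pol[support])
  mx <- max(abs(pol[support]))
  b1 <- 1 + if (mx > 0) pol * (b1_inhom / mx) else 0
  b1 <- pmax(b1, 0.1)
  list(b0 = image_volume(b0, affine),
       b1 = image_volume(array(b1, shape), affine))
}

#' Noise-free steady-state signal maps for a phantom
#'
#' Evaluates the Bloch steady-state signals voxelwise over the phantom
#' support using its T1, M0 and B1 maps.
#'
#' @param ph A [phantom()][generate_phantom()].
#' @param p A [protocol_config()].
#' @return List of real arrays `S1`, `S2` (zero outside the support).
#' @export
signal_maps <- function(ph, p) {
  stopifnot(inherits(ph, "phantom"))
  supp <- ph$labels > 0L
  S1 <- array(0, dim(ph$labels)); S2 <- S1
  s <- bloch_signals(p, ph$t1[supp], ph$b1[supp], ph$m0[supp])
  S1[supp] <- s$S1
  S2[supp] <- s$S2
  list(S1 = S1, S2 = S2)
}

#' Simulate the eight-image polarity acquisition of a phantom
#'
#' Forward image-space acquisition model: per voxel and inversion time the
#' steady-state Bloch signal (local T1, M0, B1); per (read, phase) polarity
#' combination the signal is modulated by the ripple artifact
#' `1 + r * amplitude * sin(...)` (sign flipping with read polarity `r`
#' when the parity flag is set), geometrically distorted along the PE axis
#' with polarity `d` using the phantom's B0 field and the protocol's
#' effective echo spacing, and finally corrupted by independent complex
#' Gaussian noise of standard deviation `noise_sigma` per channel. No
#' k-space effects (partial-Fourier blurring, T2* decay) are modelled.
#'
#' @param ph A phantom from [generate_phantom()].
#' @param p A [protocol_config()].
#' @param ripple A [ripple_spec()].
#' @param noise_sigma Complex noise SD per channel (signal units).
#' @param seed Integer seed; the output is bit-reproducible given the seed.
#' @return A [polarity_set()] of eight complex [polarity_image()]s. The
#'   noise-free signal maps are attached as attribute `"truth"`.
#' @export
simulate_acquisition <- function(ph, p, ripple = ripple_spec(),
                                 noise_sigma = 0, seed = 1) {
  stopifnot(inherits(ph, "phantom"), inherits(ripple, "ripple_spec"))
  validate_protocol(p)
  set.seed(as.integer(seed))
  sm <- signal_maps(ph, p)
  shape <- dim(ph$labels)
  xs <- seq_len(shape[1])
  mod1d <- ripple$amplitude *
    sin(2 * pi * ripple$freq * (xs - 1) / shape[1] + ripple$phase)
  modx <- array(rep(mod1d, times = shape[2] * shape[3]), shape)
  imgs <- list()
  for (ti in 1:2) {
    base <- if (ti == 1L) sm$S1 else sm$S2
    for (r in c(-1L, 1L)) for (d in c(-1L, 1L)) {
      rip_sign <- if (ripple$parity) r else 1L
      img <- base * (1 + rip_sign * modx)
      vol <- image_volume(img, ph$affine, pe_axis = 2L)
      if (max(abs(ph$b0)) > 0)
        vol <- apply_distortion(vol, ph$b0, p$esp_eff, d)
      cplx <- vol$data + 0i
      if (noise_sigma > 0)
        cplx <- cplx + complex(real = stats::rnorm(prod(shape), 0, noise_sigma),
                               imaginary = stats::rnorm(prod(shape), 0, noise_sigma))
      cv <- image_volume(array(cplx, shape), ph$affine, pe_axis = 2L)
      imgs[[length(imgs) + 1L]] <- polarity_image(cv, r, d, ti)
    }
  }
  out <- polarity_set(imgs)
  attr(out, "truth") <- sm
  out
}

#' Noise level for a target signal-to-noise ratio
#'
#' The per-channel complex noise SD giving the requested SNR, defined as
#' the mean TI2 signal magnitude over the phantom support divided by the
#' noise SD.
#'
#' @param ph A phantom.
#' @param p A [protocol_config()].
#' @param snr Target SNR (> 0).
#' @return Noise sigma in signal units.
#' @export
noise_sigma_for_snr <- function(ph, p, snr) {
  if (!(snr > 0)) stop("snr must be positive")
  sm <- signal_maps(ph, p)
  mean(abs(sm$S2[ph$labels > 0L])) / snr
}

#' Per-tissue masks of a phantom
#'
#' @param ph A phantom.
#' @return Named list of logical arrays (CSF, GM, WM).
#' @export
phantom_masks <- function(ph) {
  list(CSF = ph$labels == 1L, GM = ph$labels == 2L, WM = ph$labels == 3L)
}
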