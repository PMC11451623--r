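---
title: "Two-inversion 3D-EPI T1 mapping: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-inversion 3D-EPI T1 mapping: models, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t1epi)
```

## The acquisition being modelled

`t1epi` models a T1-weighted structural acquisition built from a segmented
3D-EPI readout inside an inversion-recovery (IR) loop. One IR cycle of
duration `TR_IR` contains an adiabatic inversion (efficiency `eps_inv`)
followed by two readout blocks at inversion times `TI1` and `TI2`, each a
train of non-selective excitations with block-specific flip angles `alpha1`
and `alpha2`. A volume needs `seg` such cycles (the segmentation factor),
and the whole volume acquisition is repeated `n_combo = 4` times with all
combinations of reversed read and phase-encode gradient polarity. Reversed
read polarity flips the low-spatial-frequency "fuzzy ripple" artifact that
EPI trajectory imperfections imprint on the image; reversed phase-encode
(PE) polarity mirrors the B0-driven geometric distortion. Complex averaging
over the four polarity combinations therefore cancels the ripple, and the
opposite-distortion pair supports field estimation or acquisition-level
distortion matching to a functional EPI protocol.

The package implements this chain end to end on synthetic data: a Bloch
steady-state engine, CNR-based flip-angle design, a lookup-table T1
quantifier with transmit-field (B1+) correction, the four-way polarity
combination with the MP2RAGE-style UNI statistic, a reversed-PE distortion
module, and a digital phantom simulator that generates every input the
pipeline consumes.

## Bloch steady state

Between pulses, longitudinal magnetisation relaxes mono-exponentially
toward `M0` with time constant `T1`; each pulse acts linearly on `Mz`
(excitation: gain `cos(alpha * b1)` where `b1` is the relative transmit
scale; inversion: gain `-eps_inv`). One IR cycle is therefore an affine map
`Mz_end = a * Mz_start + b`, and the periodic steady state is its exact
fixed point `Mz* = b / (1 - a)` — no iteration, no convergence tolerance.
The test suite keeps an independent brute-force oracle (500 consecutive
cycles stepped event by event from thermal equilibrium) and requires
agreement to 1e-10 relative.

Signals are read out where image contrast is set: at the k-space-centre
excitation of each block (the middle pulse under linear ordering),
`S_i = M0 * Mz_pre,i * sin(alpha_i * b1)`. Signals are signed
(phase-sensitive reconstruction): before the post-inversion zero crossing
they are negative. Signal modulation across the other pulses of a block is
visible in `simulate_mz_trajectory()` (the saw-tooth) but deliberately not
propagated into image contrast; k-space-level effects (partial-Fourier
blurring, T2* decay, MT saturation during the train) are not modelled.

The excitation spacing `TR_exc` defaults to the largest spacing (with a
1 ms guard) that packs both blocks into the cycle with the centre pulse at
the block centre; it is a config field because vendors pack differently.

**Timing accounting.** `compute_timing()` emits its formulas alongside the
numbers, because echo-train accounting conventions differ between
implementations: with the default whole-brain protocol (matrix
232×232×186, partial Fourier 6/8, segmentation 14, CAIPI `Rz` 3) it
reports `TA = n_combo * seg * TR_IR = 212.8 s`, `n_exc = ceil(186/3) = 62`
and `ETL = ceil(232 * 0.75 / 14) = 13`. A vendor may count one echo more
(e.g. a navigator or a different rounding convention); by printing the
formula the report makes any such off-by-one visible instead of hiding it.
The default `TR_IR` of 3.8 s and the TI defaults (800/2700 ms) are
assumptions exposed in the config, not measured constants.

**Look-Locker regime.** For a contiguous train of identical pulses the
classic apparent-rate correction `1/T1* = 1/T1 - ln(cos(alpha))/TR_exc` is
exact at any flip angle (the driven recovery is a geometric recurrence).
The correction fails for this sequence because the readout is *not* one
contiguous train: two blocks with block-specific flip angles, separated by
free-recovery gaps. The suite encodes this with two dense equal-flip
blocks separated by a 400 ms gap: a free mono-exponential fit across both
blocks matches the closed form to 0.3% at 2 degrees and deviates by ~24%
at 30 degrees — quantifying why a small-angle analysis is not justified at
the large flip angles this protocol uses.

## Flip-angle design by propagation of uncertainty

`cnr_surface()` evaluates, on a grid of flip-angle pairs, the GM–WM
contrast-to-noise ratio of the UNI statistic
`U = S1*S2 / (S1^2 + S2^2)` under independent additive Gaussian noise of
standard deviation `sigma` on each signal:

    CNR = |U_GM - U_WM| / sqrt(sd_UNI,GM^2 + sd_UNI,WM^2),

with `sd_UNI` from the first-order delta method (analytic derivatives,
cross-checked against central differences in the tests). The noise model —
equal, independent `sigma` on S1 and S2 — is the simplest reading of
Gaussian propagation of uncertainty; it is configurable, and a raw
signal-difference CNR is available behind `statistic = "difference"`.

Two caveats are worth stating plainly. First, the first-order expansion
degrades where either signal approaches `sigma` (near the S2 zero
crossing): there the delta method overestimates CNR, although a Monte
Carlo check shows the *location* of the optimum is still approximately
right. Second, with the placeholder inversion times shipped as defaults,
both the delta method and Monte Carlo place the optimum at a small second
flip angle (around 8/2 degrees at `sigma = 0.005`); `optimize_flip_angles()`
logs a warning whenever the optimum falls at or below 10 degrees, since
protocols of this family are expected to operate above the conventional
small-angle regime. The warning marks the optimum as timing-sensitive
rather than asserting it wrong.

The optimizer returns the global grid argmax (ties broken toward the
smaller `alpha1 + alpha2`, then smaller `alpha1`) refined by a quadratic
fit over the surrounding 3×3 neighbourhood when that fit is concave and
stays within one grid step.

## Lookup-table T1 quantification

`build_lookup_table()` tabulates a statistic of the steady-state signal
pair over a T1 grid (default 300–5000 ms, step 10 ms) for each of several
B1+ scales. The default statistic is the signed ratio `S1/S2`, restricted
per B1 curve to the longest strictly monotone run (the ratio has a pole at
the S2 zero crossing); the common monotone T1 range across B1 curves is
kept and any trimming is logged. The UNI statistic and a magnitude-only
mode (with its reduced valid range) are alternatives. Inversion uses
shape-preserving monotone cubic (Fritsch–Carlson) interpolation of the
statistic-to-T1 relation; B1 values between tabulated curves invert on the
two bracketing curves and interpolate the T1 linearly in B1 — so the B1
grid must be dense enough (0.05 steps here) that curvature across one B1
cell stays below a T1 step. Out-of-range statistics clamp to the
corresponding end of the T1 range with a flag; NaN inputs flag as
no-signal rather than erroring, because background voxels are a normal
occurrence, not an exception.

`estimate_t1_map()` computes the statistic voxelwise (for complex data the
phase-sensitive projection `Re(S1 * Conj(S2)) / |S2|^2`), resamples a
lower-resolution B1+ map to the image grid trilinearly if needed, and
inverts with the local B1. `histogram_peaks()` reports per-tissue modal T1
as the kernel-density mode (Silverman bandwidth, `bw.nrd0`); exact ties
break toward the lower T1, and near-constant inputs return the common
value directly since a density bandwidth is undefined there.

## Polarity combination

Complex averaging only helps if the global phases agree, so
`combine_polarity_set()` aligns each image's global phase to the first by
the phase of their inner product over the support before taking the
complex mean per inversion time. The default combines images as acquired
("acquisition space"), which is valid when distortions are matched or
negligible — the operating point of the distortion-free protocol; an
unwarp-first mode (each PE polarity unwarped with a supplied field map
before averaging) is explicit opt-in. The UNI image is computed from the
combined complex pair, consistent with complex-valued averaging upstream;
averaging per-combination UNIs is available for comparison
(`average_uni = TRUE`). UNI is bounded in [-0.5, 0.5] by construction and
cancels receive bias and proton density; voxels with zero combined power
are set to 0 and masked.

`tsnr_map()` is the voxelwise temporal mean over the sample standard
deviation (denominator n-1), with zero-SD voxels reported as 0 and masked.

## Geometric distortion

The distortion model is the standard 1-D PE-shift approximation: a voxel
at off-resonance `dB0` (Hz) displaces along PE by
`d * dB0 * esp_eff[s] * Npe` voxels, where `d` is the PE polarity and
`esp_eff` the effective echo spacing. `apply_distortion()` discretises the
warp conservatively: each output voxel integrates the input over its
pulled-back cell via the interpolated cumulative line integral, so the
line integral along PE is conserved to rounding (the Jacobian intensity
pile-up is implicit in the cell widths). Displacements beyond half the FOV
are refused — fold-over is not modelled.

Undoing a known distortion is *not* the opposite-polarity warp: where the
shift varies, that naive inverse errs by about `s * ds/dy` voxels.
`unwarp_distortion()` instead inverts the 1-D coordinate map exactly (a
fixed-point iteration per column, 8 iterations) and resamples with the
matching Jacobian, recovering smooth inputs to interpolation accuracy
(interior round-trip errors around 1e-4 relative in the suite).

`estimate_field_from_pair()` estimates the field from a reversed-PE pair
in two symmetric stages. A demons-style multiscale stage updates a
voxelwise displacement `s` so that the `+PE` image unwarped by `-s`
matches the `-PE` image unwarped by `+s`; both arms include the Jacobian
modulation, which matters more than it may seem: in flat regions the
polarity pair differs by intensity pile-up alone, and without the Jacobian
term that residual is mis-attributed to displacement. The update is
Gaussian-smoothed (fluid-like, sigma 1.5) and the accumulated field
re-smoothed each iteration (diffusion-like, sigma 1.0). The second stage
refits the same symmetric cost over a tensor-product cubic B-spline field
(knot spacing 4 voxels) by Gauss–Newton with Levenberg–Marquardt damping
and a weak quadratic anchor (0.01) to the demons result. The spline
parameterisation supplies smoothness without the amplitude attenuation
that repeated Gaussian smoothing causes in regions with little image
contrast, and its derivative term exploits the Jacobian signal that flat
regions do carry. The construction is exactly antisymmetric — swapping the
inputs negates the estimate — and deterministic. The dense spline design
matrix restricts the refinement to moderate grids (it is skipped with a
log note beyond ~2000 coefficients); the demons stage alone is returned
there.

`synthesize_warp_level()` scales the displacement by a warp fraction
`lambda` at a reference echo spacing, so a structural image can be warped
retrospectively to any distortion level. `match_echo_spacing()` performs
the same matching at the acquisition level: since the per-train line
spacing is fixed, the effective echo spacing scales inversely with the
segmentation factor, and the function picks the integer segmentation whose
displacement-per-Hz product best matches the functional acquisition,
reporting the residual or erroring with the nearest feasible settings.

## The synthetic phantom, and what passing tests do not show

`generate_phantom()` builds a concentric "cortex": a WM sphere, a GM
ribbon of configurable thickness (default 4 voxels), and a CSF rim, with
an optional low-order angular perturbation of the radii to emulate
folding. Simulation tissue values are 7T-plausible defaults — GM 1800 ms,
WM 1200 ms, CSF 4000 ms, with 2% within-tissue variation — not measured
reference values. The B0 field is Gaussian-smoothed white noise, smooth
across the whole grid (off-resonance does not stop at the object edge),
zero-mean over the support, with a configurable peak (default 30 Hz); the
B1+ field is a low-order polynomial, exactly mean 1 over the support with
peak deviation 0.15 — a synthetic stand-in for a measured low-resolution
transmit template, and labelled as such.

`simulate_acquisition()` applies, per polarity combination, (i) the ripple
artifact as a multiplicative low-frequency sinusoid along the readout axis
whose sign flips with read polarity — the simplest form consistent with
cancellation by dual-read-polarity combination, chosen because the
artifact's physical origin (trajectory imperfections at ramp-sampling
corners) has no published closed-form model; (ii) the PE distortion with
the phantom's B0 and the protocol's `esp_eff`; (iii) independent complex
Gaussian noise. The artifact operators are exactly the inverse-testable
ones used by the combination and distortion modules, so the cancellation
and unwarping tests are closed-loop: they demonstrate internal consistency
of the chain, and parameter recovery under the stated noise model. They do
not demonstrate robustness to effects the simulator omits — k-space
partial-Fourier blurring, T2* decay and MT saturation during the train,
coil sensitivities, motion, physiological noise, or ripple artifacts with
a different functional form than the model used to cancel them.

## Problem sizes and numerical choices

The suite and the acceptance script run on 32-voxel cube phantoms with 20
noise replicates at SNR 20 for parameter recovery, one 4-voxel-peak field
recovery, 100 replicates for the noise-averaging check, and 1e5 random
pairs for the UNI bound — sizes chosen so the full pipeline is exercised
end to end in a few minutes of CPU time. Key tolerances: steady state vs
brute force 1e-10 relative; lookup round trip within one T1 grid step;
field recovery below 0.5 voxel RMSE in the support; modal-T1 bias below 2%
and RMSE below 5% across replicates. Seeds control every stochastic step;
identical seeds reproduce every output bit for bit.

Known limitations, beyond the simulator's fidelity limits above: the
distortion model ignores in-plane readout-axis distortion and
through-plane dephasing; the field estimator assumes the two polarities
image the same object (no motion between them); the delta-method CNR is
first-order; and quantitative accuracy of the T1 map inherits any error in
the assumed B1+ template, which the ablation test quantifies rather than
removes.
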