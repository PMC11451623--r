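# Shared fixtures: small, fast protocol and phantom configurations used
# across the suite. Everything is generated in code; no binary fixtures.

# Default-timing protocol with a small matrix so that one readout block has
# 10 excitations instead of 62 (fast event loops, same structure).
small_protocol <- function(...) {
  protocol_config(N = c(32L, 32L, 30L), ...)
}

# Phantom sized for fast end-to-end runs.
small_phantom <- function(seed = 1, ...) {
  generate_phantom(seed, shape = c(32L, 32L, 32L), ...)
}

# erode a logical mask by roughly `vox` voxels (Gaussian threshold)
erode_mask <- function(mask, vox = 2) {
  sm <- t1epi:::smooth3d(array(as.numeric(mask), dim(mask)), vox)
  sm > 0.99
}

# two equal-flip readout blocks, dense pulses, separated by a recovery gap:
# the sampling layout of a segmented Look-Locker-style readout
ll_protocol <- function(alpha, gap = 400, trx = 10, ne = 40) {
  ic <- ne %/% 2L
  ti1 <- 50 + ic * trx
  ti2 <- ti1 + (ne - 1 - ic) * trx + gap + ic * trx + trx
  protocol_config(TI1 = ti1, TI2 = ti2, TR_IR = ti2 + (ne - ic) * trx + 2500,
                  alpha1 = alpha, alpha2 = alpha, seg = 1L, Rz = 1L,
                  N = c(32L, 32L, ne), TR_exc = trx)
}
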