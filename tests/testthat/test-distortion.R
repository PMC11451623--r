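# shared distortion fixture: noise-free phantom signal image with a mild
# point-spread smoothing (as any EPI readout has), plus a smooth field
dist_fixture <- function(seed = 7, psf = 1) {
  ph <- small_phantom(5, b0_peak_hz = 0)
  sm <- signal_maps(ph, small_protocol())
  img <- image_volume(t1epi:::smooth3d(sm$S2, psf), ph$affine)
  supp <- ph$labels > 0L
  fm <- generate_field_maps(seed, dim(supp), peak_hz = 50, smooth_vox = 8,
                            support = supp)
  esp <- 1
  # scale so the peak displacement anywhere is 4 voxels
  fld <- fm$b0$data * 4 / (max(abs(fm$b0$data)) *
                             t1epi:::shift_per_hz(esp, dim(supp)[2]))
  list(img = img, fld = fld, esp = esp, supp = supp, ph = ph,
       shift = fld * t1epi:::shift_per_hz(esp, dim(supp)[2]))
}

test_that("zero field is the identity; uniform field shifts by the closed form", {
  v <- image_volume(array(rnorm(8^3), c(8, 8, 8)))
  expect_equal(apply_distortion(v, array(0, c(8, 8, 8)), 0.5, 1)$data, v$data)
  # uniform 10 Hz, esp 0.5 ms, Npe 100 -> 0.5 voxel shift along PE
  n <- 24
  ramp <- array(rep(seq_len(n), each = n), c(n, n, n))  # linear in y
  vr <- image_volume(ramp)
  fld <- array(10, c(n, n, n))
  for (d in c(1, -1)) {
    out <- apply_distortion(vr, fld, 0.5, d, Npe = 100)
    interior <- out$data[, 5:20, ]
    expect_equal(interior, ramp[, 5:20, ] - d * 0.5, tolerance = 1e-6)
  }
})

test_that("a point source lands at the predicted coordinate with intensity conserved", {
  n <- 32
  img <- array(0, c(n, n, n))
  img[16, 16, 16] <- 1
  img <- t1epi:::smooth3d(img, 1.5)           # smooth blob, not a delta spike
  fx <- dist_fixture()
  out <- apply_distortion(image_volume(img), fx$fld, fx$esp, +1)
  expect_equal(sum(out$data), sum(img), tolerance = 1e-6)
  # centroid along PE moves by the local shift
  w <- out$data[16, , 16] / sum(out$data[16, , 16])
  centroid <- sum(w * seq_len(n))
  expect_lt(abs(centroid - (16 + fx$shift[16, 16, 16])), 0.1)
})

test_that("displacements beyond half the FOV are refused", {
  n <- 16
  v <- image_volume(array(1, c(n, n, n)))
  fld <- array(1000, c(n, n, n))
  expect_error(apply_distortion(v, fld, 1, 1), "half the field of view")
})

test_that("unwarping with the true field recovers the original within interpolation error", {
  fx <- dist_fixture()
  vp <- apply_distortion(fx$img, fx$fld, fx$esp, +1)
  rec <- unwarp_distortion(vp, fx$fld, fx$esp, +1)
  interior <- erode_mask(fx$supp, 2)
  rel <- sqrt(mean((rec$data[interior] - fx$img$data[interior])^2)) /
    sqrt(mean(fx$img$data[interior]^2))
  expect_lt(rel, 0.01)
})

test_that("identical inputs give a zero field; swapping inputs negates it exactly", {
  fx <- dist_fixture()
  z <- estimate_field_from_pair(fx$img, fx$img, fx$esp, refine = FALSE)
  expect_lt(max(abs(z$data)), 1e-8)
  vp <- apply_distortion(fx$img, fx$fld, fx$esp, +1)
  vm <- apply_distortion(fx$img, fx$fld, fx$esp, -1)
  a <- estimate_field_from_pair(vp, vm, fx$esp, n_iter = 10L,
                                levels = c(3, 1.5), refine = FALSE)
  b <- estimate_field_from_pair(vm, vp, fx$esp, n_iter = 10L,
                                levels = c(3, 1.5), refine = FALSE)
  expect_equal(a$data, -b$data, tolerance = 1e-12)
})

test_that("field recovery: RMSE < 0.5 voxel; doubling the field doubles the estimate", {
  fx <- dist_fixture()
  vp <- apply_distortion(fx$img, fx$fld, fx$esp, +1)
  vm <- apply_distortion(fx$img, fx$fld, fx$esp, -1)
  est <- estimate_field_from_pair(vp, vm, fx$esp)
  s_est <- attr(est, "displacement")
  expect_lt(sqrt(mean((s_est[fx$supp] - fx$shift[fx$supp])^2)), 0.5)
  # linearity: doubling the field doubles the estimated displacement
  # (regression slope over the well-determined voxels, moderate shifts)
  vp1 <- apply_distortion(fx$img, fx$fld * 0.375, fx$esp, +1)
  vm1 <- apply_distortion(fx$img, fx$fld * 0.375, fx$esp, -1)
  vp2 <- apply_distortion(fx$img, fx$fld * 0.75, fx$esp, +1)
  vm2 <- apply_distortion(fx$img, fx$fld * 0.75, fx$esp, -1)
  s1 <- attr(estimate_field_from_pair(vp1, vm1, fx$esp, refine = FALSE),
             "displacement")
  s2 <- attr(estimate_field_from_pair(vp2, vm2, fx$esp, refine = FALSE),
             "displacement")
  sel <- fx$supp & abs(fx$shift) > 1
  slope <- sum(s1[sel] * s2[sel]) / sum(s1[sel]^2)
  expect_equal(slope, 2, tolerance = 0.1)
})

test_that("unwarped polarity mean approaches the undistorted phantom", {
  fx <- dist_fixture()
  vp <- apply_distortion(fx$img, fx$fld, fx$esp, +1)
  vm <- apply_distortion(fx$img, fx$fld, fx$esp, -1)
  est <- estimate_field_from_pair(vp, vm, fx$esp)
  up <- unwarp_distortion(vp, est$data, fx$esp, +1)
  um <- unwarp_distortion(vm, est$data, fx$esp, -1)
  interior <- erode_mask(fx$supp, 2)
  rmse <- function(a) sqrt(mean((a[interior] - fx$img$data[interior])^2))
  r_avg <- rmse((up$data + um$data) / 2)
  expect_lt(r_avg, rmse(vp$data))      # closer than either distorted input
  expect_lt(r_avg, rmse(vm$data))
})

test_that("warp synthesis: identity at 0, composition at 1, approximate semigroup", {
  fx <- dist_fixture()
  v <- fx$img
  expect_identical(synthesize_warp_level(v, fx$fld, warp_spec(0, fx$esp)), v)
  full <- synthesize_warp_level(v, fx$fld, warp_spec(1, fx$esp, 1))
  expect_equal(full$data, apply_distortion(v, fx$fld, fx$esp, 1)$data)
  half2 <- synthesize_warp_level(
    synthesize_warp_level(v, fx$fld, warp_spec(0.5, fx$esp, 1)),
    fx$fld, warp_spec(0.5, fx$esp, 1))
  # equivalent displacement difference below 0.05 voxels: compare centroid
  # displacement of a smooth blob through both paths
  interior <- erode_mask(fx$supp, 2)
  num <- sum(abs(full$data[interior] - half2$data[interior]))
  den <- sum(abs(full$data[interior] -
                   synthesize_warp_level(v, fx$fld,
                                         warp_spec(0.95, fx$esp, 1))$data[interior]))
  # the two-step composition is closer to the full warp than a 5% level error
  expect_lt(num, den)
})

test_that("echo-spacing matching adjusts segmentation to the functional product", {
  p <- small_protocol()                       # esp_eff 0.07 ms, seg 14, Ny 32
  same <- match_echo_spacing(p, p$esp_eff, p$N[2])
  expect_equal(same$seg, p$seg)
  expect_equal(attr(same, "residual"), 0)
  # doubling the functional esp (same Npe) halves the segmentation
  dbl <- match_echo_spacing(p, 2 * p$esp_eff, p$N[2])
  expect_equal(dbl$seg, p$seg / 2)
  expect_equal(dbl$esp_eff * dbl$seg, p$esp_eff * p$seg, tolerance = 1e-12)
  # infeasible: tolerance too tight for an irrational ratio
  expect_error(match_echo_spacing(p, p$esp_eff * 1.03, p$N[2], tol = 1e-4),
               "nearest candidates")
})
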