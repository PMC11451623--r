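make_table <- function(p = small_protocol(), ...) {
  build_lookup_table(p, t1_range = c(400, 4500), t1_step = 25,
                     b1_grid = c(0.8, 0.9, 1, 1.1, 1.2), ...)
}

test_that("tabulated statistic equals the steady-state signals at grid nodes", {
  p <- small_protocol()
  tab <- make_table(p)
  k <- match(1, tab$b1)
  idx <- match(c(800, 1500, 3000), tab$T1)
  s <- bloch_signals(p, tab$T1[idx])
  expect_equal(tab$stat[idx, k], s$S1 / s$S2, tolerance = 1e-12)
})

test_that("two builds with identical configuration are identical", {
  expect_identical(make_table(), make_table())
})

test_that("halving the T1 step changes interpolated inverses below the step bound", {
  p <- small_protocol()
  coarse <- build_lookup_table(p, c(600, 3000), 100, b1_grid = c(0.9, 1, 1.1))
  fine <- build_lookup_table(p, c(600, 3000), 50, b1_grid = c(0.9, 1, 1.1))
  vals <- bloch_signals(p, seq(700, 2900, by = 37))
  r <- vals$S1 / vals$S2
  t_coarse <- invert_lookup(coarse, r, 1)$T1
  t_fine <- invert_lookup(fine, r, 1)$T1
  expect_lt(max(abs(t_coarse - t_fine)), 100)
})

test_that("inversion round-trips tabulation (ratio and UNI statistics)", {
  p <- small_protocol()
  for (statistic in c("ratio", "uni")) {
    tab <- make_table(p, statistic = statistic)
    s <- bloch_signals(p, 1500)
    v <- switch(statistic, ratio = s$S1 / s$S2,
                uni = s$S1 * s$S2 / (s$S1^2 + s$S2^2))
    inv <- invert_lookup(tab, v, 1)
    expect_lt(abs(inv$T1 - 1500), 1)
    expect_identical(inv$flag, 0L)
  }
})

test_that("200 random (T1, b1) pairs invert within one grid step", {
  p <- small_protocol()
  # B1 handled by linear interpolation between curves, so the B1 grid must
  # be dense enough that curvature across one B1 cell stays below a T1 step
  tab <- build_lookup_table(p, t1_range = c(400, 4500), t1_step = 25,
                            b1_grid = seq(0.8, 1.2, by = 0.05))
  set.seed(42)
  T1s <- runif(200, 450, 4400)
  b1s <- runif(200, 0.82, 1.18)
  vals <- numeric(200)
  for (k in 1:200) {
    o <- brute_force_signals(p, T1s[k], b1s[k], n_cycles = 60)
    vals[k] <- o$S1 / o$S2
  }
  inv <- invert_lookup(tab, vals, b1s)
  expect_true(all(inv$flag == 0L))
  expect_lt(max(abs(inv$T1 - T1s)), 25)
})

test_that("out-of-range statistics clamp with flags; NaN maps to no-signal", {
  tab <- make_table()
  k <- match(1, tab$b1)
  lo_end <- tab$stat[1, k]; hi_end <- tab$stat[nrow(tab$stat), k]
  beyond <- c(lo_end + sign(lo_end - hi_end), hi_end - sign(lo_end - hi_end))
  inv <- invert_lookup(tab, c(beyond, NaN), 1)
  expect_setequal(inv$flag[1:2], c(1L, 2L))
  expect_true(inv$T1[1] %in% range(tab$T1) && inv$T1[2] %in% range(tab$T1))
  expect_identical(inv$flag[3], 3L)
  expect_true(is.na(inv$T1[3]))
})

test_that("noiseless uniform-B1 phantom recovers ground-truth T1 voxelwise", {
  p <- small_protocol()
  ph <- small_phantom(2, t1_variation = 0, b0_peak_hz = 0, b1_inhom = 0)
  sm <- signal_maps(ph, p)
  v1 <- image_volume(sm$S1, ph$affine)
  v2 <- image_volume(sm$S2, ph$affine)
  tab <- make_table(p)
  tm <- estimate_t1_map(v1, v2, tab)
  supp <- ph$labels > 0L
  ok <- supp & tm$mask == 0L
  expect_gt(mean(ok[supp]), 0.99)
  expect_lt(max(abs(tm$t1$data[ok] - ph$t1[ok])), 25)
  # background voxels carry the no-signal flag and no T1
  expect_true(all(tm$mask[!supp] == 3L))
  expect_true(all(is.na(tm$t1$data[!supp])))
})

test_that("ignoring a non-nominal B1 biases T1; supplying the map removes the bias", {
  p <- small_protocol()
  ph <- small_phantom(2, t1_variation = 0, b0_peak_hz = 0, b1_inhom = 0)
  ph$b1[] <- 0.8
  sm <- signal_maps(ph, p)
  v1 <- image_volume(sm$S1, ph$affine); v2 <- image_volume(sm$S2, ph$affine)
  tab <- make_table(p)
  gm <- ph$labels == 2L
  biased <- estimate_t1_map(v1, v2, tab)            # assumes b1 = 1
  corrected <- estimate_t1_map(v1, v2, tab, image_volume(ph$b1, ph$affine))
  err_b <- median(biased$t1$data[gm] - ph$t1[gm], na.rm = TRUE)
  err_c <- median(corrected$t1$data[gm] - ph$t1[gm], na.rm = TRUE)
  expect_gt(abs(err_b), 50)          # the B1 correction is doing real work
  expect_lt(abs(err_c), 25)
})

test_that("t1 map estimation is equivariant under spatial permutation", {
  p <- small_protocol()
  ph <- small_phantom(4, b0_peak_hz = 0)
  sm <- signal_maps(ph, p)
  tab <- make_table(p)
  b1v <- image_volume(ph$b1, ph$affine)
  tm <- estimate_t1_map(image_volume(sm$S1, ph$affine),
                        image_volume(sm$S2, ph$affine), tab, b1v)
  perm <- function(a) aperm(a, c(2, 3, 1))
  tmp <- estimate_t1_map(image_volume(perm(sm$S1), ph$affine),
                         image_volume(perm(sm$S2), ph$affine), tab,
                         image_volume(perm(ph$b1), ph$affine))
  expect_equal(tmp$t1$data, perm(tm$t1$data))
  expect_equal(tmp$mask, perm(tm$mask))
})

test_that("histogram peaks: delta distribution, bimodal tie-break, minimum count", {
  d <- c(32L, 32L, 32L)
  t1 <- array(NA_real_, d); mask <- array(0L, d)
  gm <- array(FALSE, d); gm[1:16, , 1:4] <- TRUE
  t1[gm] <- 1800; mask[gm] <- 0L
  tm <- structure(list(t1 = image_volume(t1, diag(4)), mask = mask),
                  class = "t1_map")
  expect_equal(unname(histogram_peaks(tm, list(GM = gm))), 1800)
  # bimodal: taller mode wins
  set.seed(1)
  bi <- array(FALSE, d); bi[, , 5:12] <- TRUE
  t1[bi] <- c(rnorm(4000, 1000, 30), rnorm(2000, 2200, 30),
              rnorm(sum(bi) - 6000, 1000, 30))
  mask[bi] <- 0L
  tm2 <- structure(list(t1 = image_volume(t1, diag(4)), mask = mask),
                   class = "t1_map")
  expect_lt(abs(unname(histogram_peaks(tm2, list(X = bi))) - 1000), 60)
  few <- array(FALSE, d); few[1:3, 1, 1] <- TRUE
  expect_error(histogram_peaks(tm, list(X = few)), "in-range voxels")
})

test_that("trilinear resampling reproduces a linear field exactly", {
  src_dim <- c(16L, 16L, 16L)
  ijk <- expand.grid(i = 0:15, j = 0:15, k = 0:15)
  lin <- with(ijk, 2 + 0.5 * i - 0.25 * j + 0.1 * k)
  src <- image_volume(array(lin, src_dim), diag(c(2, 2, 2, 1)))
  tgt <- resample_trilinear(src, c(32L, 32L, 32L), diag(c(1, 1, 1, 1)))
  ijk2 <- expand.grid(i = 0:31, j = 0:31, k = 0:31) / 2  # world == src voxel
  want <- with(ijk2, 2 + 0.5 * i - 0.25 * j + 0.1 * k)
  inside <- ijk2$i <= 15 & ijk2$j <= 15 & ijk2$k <= 15
  expect_equal(as.vector(tgt$data)[inside], want[inside], tolerance = 1e-12)
})
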