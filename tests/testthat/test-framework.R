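test_that("NIfTI round trip preserves data, affine and PE-axis annotation", {
  dir <- withr::local_tempdir()
  aff <- diag(c(0.8, 0.8, 0.8, 1)); aff[1:3, 4] <- c(-12, -12, -12)
  v <- image_volume(array(0, c(8, 8, 8)), aff, pe_axis = 1L)
  f <- file.path(dir, "zeros.nii.gz")
  save_nifti(v, f)
  v2 <- load_nifti(f)
  expect_identical(v2$data, v$data)
  expect_equal(v2$affine, aff)
  expect_identical(v2$pe_axis, 1L)
  set.seed(3)
  vr <- image_volume(array(rnorm(512), c(8, 8, 8)), aff)
  save_nifti(vr, file.path(dir, "rand.nii.gz"))
  expect_equal(load_nifti(file.path(dir, "rand.nii.gz"))$data, vr$data,
               tolerance = 1e-12)
})

test_that("4D volumes keep the frame axis last", {
  dir <- withr::local_tempdir()
  v <- image_volume(array(seq_len(2 * 4^3), c(4, 4, 4, 2)))
  f <- file.path(dir, "series.nii.gz")
  save_nifti(v, f)
  v2 <- load_nifti(f)
  expect_identical(dim(v2$data), c(4L, 4L, 4L, 2L))
  expect_equal(v2$data, v$data)
})

test_that("complex volumes round trip through a real/imaginary pair", {
  dir <- withr::local_tempdir()
  set.seed(4)
  cx <- array(complex(real = rnorm(64), imaginary = rnorm(64)), c(4, 4, 4))
  v <- image_volume(cx, pe_axis = 2L)
  f <- file.path(dir, "cplx.nii.gz")
  save_nifti(v, f)
  expect_true(file.exists(file.path(dir, "cplx_real.nii.gz")))
  expect_true(file.exists(file.path(dir, "cplx_imag.nii.gz")))
  v2 <- load_nifti(f)
  expect_true(is.complex(v2$data))
  expect_equal(v2$data, cx, tolerance = 1e-12)
  expect_identical(v2$pe_axis, 2L)
})

test_that("I/O error paths: missing, truncated and non-finite inputs", {
  dir <- withr::local_tempdir()
  expect_error(load_nifti(file.path(dir, "nope.nii.gz")), "not found")
  # truncated payload must error, not return garbage
  good <- file.path(dir, "ok.nii")
  save_nifti(image_volume(array(1, c(8, 8, 8))), good)
  raw_ <- readBin(good, "raw", file.size(good))
  trunc <- file.path(dir, "trunc.nii")
  writeBin(raw_[1:100], trunc)
  suppressWarnings(expect_error(load_nifti(trunc)))
  bad <- image_volume(array(c(NaN, rep(1, 7)), c(2, 2, 2)))
  expect_error(save_nifti(bad, file.path(dir, "bad.nii.gz")), "non-finite")
})

test_that("the shipped default protocol file loads and validates", {
  cfg <- load_config(system.file("extdata", "default_protocol.cfg",
                                 package = "t1epi"))
  expect_s3_class(cfg$protocol, "protocol_config")
  expect_identical(cfg$protocol$N, c(232L, 232L, 186L))
  expect_identical(cfg$protocol$seg, 14L)
  expect_identical(cfg$protocol$Rz, 3L)
  expect_equal(cfg$protocol$pF, 0.75)
  expect_identical(cfg$pe_axis, 2L)
})

test_that("config error paths: inverted TIs, empty file, unknown key", {
  dir <- withr::local_tempdir()
  base <- readLines(system.file("extdata", "default_protocol.cfg",
                                package = "t1epi"))
  bad <- sub("^ti2.*", "ti2 = 500", base)
  f <- file.path(dir, "bad.cfg")
  writeLines(bad, f)
  expect_error(load_config(f), "TI1 < TI2")
  writeLines(character(0), f)
  expect_error(load_config(f), "required keys")
  writeLines(c(base, "warp_factor = 2"), f)
  expect_error(load_config(f), "unknown config key")
  writeLines(c(base, "ti1 = 700"), f)
  expect_error(load_config(f), "duplicated")
})

test_that("CLI timing and lookup subcommands run and write their outputs", {
  dir <- withr::local_tempdir()
  out_csv <- file.path(dir, "timing.csv")
  capture.output(rep_ <- suppressMessages(
    cli_main(c("timing", "--out", out_csv))))
  expect_s3_class(rep_, "timing_report")
  expect_true(file.exists(out_csv))
  df <- utils::read.csv(out_csv)
  expect_equal(df$value[df$quantity == "TA_s"], 212.8)
  lk <- file.path(dir, "lookup.csv")
  tab <- suppressMessages(cli_main(c("lookup", "--out", lk)))
  expect_s3_class(tab, "t1_lookup")
  first <- readLines(lk, n = 1)
  expect_match(first, "statistic=ratio")
})

test_that("CLI simulate/combine/t1map chain is reproducible end to end", {
  dir <- withr::local_tempdir()
  cfgf <- file.path(dir, "proto.cfg")
  base <- readLines(system.file("extdata", "default_protocol.cfg",
                                package = "t1epi"))
  writeLines(sub("^nx.*", "nx = 32",
                 sub("^ny.*", "ny = 32", sub("^nz.*", "nz = 30", base))), cfgf)
  simdir <- file.path(dir, "sim")
  suppressMessages(cli_main(c("simulate", "--config", cfgf, "--seed", "5",
                              "--out", simdir, "--shape", "32")))
  expect_true(file.exists(file.path(simdir, "manifest.csv")))
  man <- utils::read.csv(file.path(simdir, "manifest.csv"))
  expect_identical(nrow(man), 8L)
  simdir2 <- file.path(dir, "sim2")
  suppressMessages(cli_main(c("simulate", "--config", cfgf, "--seed", "5",
                              "--out", simdir2, "--shape", "32")))
  a <- load_nifti(file.path(simdir, man$path[1]))
  b <- load_nifti(file.path(simdir2, man$path[1]))
  expect_identical(a$data, b$data)     # same seed, byte-identical voxels
  combdir <- file.path(dir, "comb")
  suppressMessages(cli_main(c("combine", "--config", cfgf,
                              "--manifest", file.path(simdir, "manifest.csv"),
                              "--out", combdir)))
  t1dir <- file.path(dir, "t1")
  suppressMessages(cli_main(c("t1map", "--config", cfgf,
                              "--s1", file.path(combdir, "combined_ti1.nii.gz"),
                              "--s2", file.path(combdir, "combined_ti2.nii.gz"),
                              "--b1", file.path(simdir, "truth_b1.nii.gz"),
                              "--out", t1dir)))
  t1 <- load_nifti(file.path(t1dir, "t1_ms.nii.gz"))
  truth <- load_nifti(file.path(simdir, "truth_t1.nii.gz"))
  mask <- load_nifti(file.path(t1dir, "t1_mask.nii.gz"))
  ok <- mask$data == 0 & truth$data > 0
  expect_gt(sum(ok), 1000)
  relerr <- abs(t1$data[ok] - truth$data[ok]) / truth$data[ok]
  expect_lt(median(relerr), 0.05)
})
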