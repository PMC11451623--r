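#' Tag a complex volume with its acquisition polarities
#'
#' @param vol A complex [image_volume()].
#' @param read_pol Read gradient polarity, +1 or -1.
#' @param phase_pol Phase-encode polarity, +1 or -1.
#' @param ti Inversion-time index, 1 or 2.
#' @return An object of class `polarity_image`.
#' @export
polarity_image <- function(vol, read_pol, phase_pol, ti) {
  stopifnot(inherits(vol, "image_volume"))
  if (!is.complex(vol$data))
    stop("polarity images must hold complex data")
  if (!(read_pol %in% c(-1, 1)) || !(phase_pol %in% c(-1, 1)))
    stop("polarities must be +1 or -1")
  if (!(ti %in% c(1L, 2L))) stop("ti must be 1 or 2")
  structure(list(vol = vol, read_pol = as.integer(read_pol),
                 phase_pol = as.integer(phase_pol), ti = as.integer(ti)),
            class = "polarity_image")
}

#' Assemble the eight-image polarity set
#'
#' One complex volume per (read polarity, phase polarity, TI) triple: four
#' polarity combinations at each of the two inversion times, all on
#' congruent grids.
#'
#' @param images List of eight [polarity_image()]s.
#' @return An object of class `polarity_set` (the list, validated and
#'   ordered by TI, read, phase).
#' @export
polarity_set <- function(images) {
  if (length(images) != 8L ||
      !all(vapply(images, inherits, TRUE, "polarity_image")))
    stop("a polarity set needs exactly eight polarity images")
  key <- vapply(images, function(im)
    paste(im$ti, im$read_pol, im$phase_pol), "")
  want <- as.vector(outer(1:2, c("-1 -1", "-1 1", "1 -1", "1 1"), paste))
  if (!setequal(key, want) || anyDuplicated(key))
    stop("need exactly one image per (read, phase, TI) combination")
  d <- dim(images[[1L]]$vol$data)
  if (!all(vapply(images, function(im)
    identical(dim(im$vol$data), d), TRUE)))
    stop("polarity images are on incongruent grids")
  structure(images[order(match(key, want))], class = "polarity_set")
}

# fetch one member by (ti, r, d)
set_get <- function(set, ti, r, d) {
  for (im in set)
    if (im$ti == ti && im$read_pol == r && im$phase_pol == d) return(im)
  stop("polarity image not found")
}

#' Bias-cancelling UNI image from a TI1/TI2 pair
#'
#' Voxelwise `UNI = Re(Conj(S1) * S2) / (|S1|^2 + |S2|^2)`, the
#' MP2RAGE-style ratio of the two inversion-time images. The statistic is
#' bounded in \\[-0.5, 0.5\\] and cancels receive bias and proton density.
#' Voxels where both inputs are zero are set to 0 and excluded from the
#' returned validity mask.
#'
#' @param S1,S2 [image_volume()]s (complex or real) on congruent grids.
#' @return An [image_volume()] (real) with an extra element `mask`
#'   (logical array, `FALSE` where the statistic was undefined).
#' @examples
#' v <- function(x) image_volume(array(as.complex(x), c(2, 2, 2)))
#' uni_image(v(1), v(1))$data[1]
#' @export
uni_image <- function(S1, S2) {
  stopifnot(inherits(S1, "image_volume"), inherits(S2, "image_volume"))
  if (!identical(dim(S1$data), dim(S2$data)))
    stop("TI1 and TI2 volumes are on different grids")
  den <- Mod(S1$data)^2 + Mod(S2$data)^2
  u <- Re(Conj(S1$data) * S2$data) / den
  ok <- den > 0
  u[!ok] <- 0
  out <- image_volume(u, S1$affine, S1$pe_axis)
  out$mask <- ok
  out
}

# align the global phase of img to ref by the phase of their inner product
# over the support of ref (voxels with non-negligible magnitude)
align_phase <- function(img, ref) {
  supp <- Mod(ref) > 0.01 * max(Mod(ref))
  ip <- sum(Conj(ref[supp]) * img[supp])
  if (Mod(ip) == 0) return(img)
  img * exp(-1i * Arg(ip))
}

#' Combine the four polarity acquisitions per inversion time
#'
#' Complex averaging over the four (read, phase) polarity images of each
#' inversion time, after aligning each image's global phase to the first
#' (complex averaging of misaligned global phases destroys signal). In
#' `"acquisition"` mode (default) the images are averaged as acquired —
#' valid when geometric distortions are matched or negligible. In
#' `"unwarp-first"` mode each phase polarity is first unwarped with a
#' supplied off-resonance field via [apply_distortion()], then averaged.
#' The UNI image is computed from the combined TI pair (computing it per
#' combination and averaging is available via `average_uni = TRUE`).
#'
#' @param set A [polarity_set()].
#' @param mode `"acquisition"` or `"unwarp-first"`.
#' @param field [image_volume()] of off-resonance (Hz); required in
#'   unwarp-first mode.
#' @param p A [protocol_config()]; required in unwarp-first mode (supplies
#'   the effective echo spacing).
#' @param average_uni Logical; average per-combination UNI images instead
#'   of computing UNI from the combined complex pair.
#' @return List with `S1`, `S2` (combined complex [image_volume()]s) and
#'   `uni` (real [image_volume()] with `mask`).
#' @export
combine_polarity_set <- function(set, mode = c("acquisition", "unwarp-first"),
                                 field = NULL, p = NULL,
                                 average_uni = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(set, "polarity_set"))
  if (mode == "unwarp-first" && (is.null(field) || is.null(p)))
    stop("unwarp-first combination needs a field map and a protocol config")
  combos <- expand.grid(r = c(-1L, 1L), d = c(-1L, 1L))
  comb <- vector("list", 2L)
  for (ti in 1:2) {
    imgs <- lapply(seq_len(nrow(combos)), function(k) {
      im <- set_get(set, ti, combos$r[k], combos$d[k])
      v <- im$vol
      if (mode == "unwarp-first")
        v <- unwarp_distortion(v, field, p$esp_eff, im$phase_pol)
      v
    })
    ref <- imgs[[1L]]$data
    acc <- ref
    for (k in 2:length(imgs))
      acc <- acc + align_phase(imgs[[k]]$data, ref)
    comb[[ti]] <- image_volume(acc / length(imgs), imgs[[1L]]$affine,
                               imgs[[1L]]$pe_axis)
  }
  if (average_uni) {
    us <- lapply(seq_len(nrow(combos)), function(k) {
      uni_image(set_get(set, 1L, combos$r[k], combos$d[k])$vol,
                set_get(set, 2L, combos$r[k], combos$d[k])$vol)
    })
    acc <- us[[1L]]$data
    msk <- us[[1L]]$mask
    for (k in 2:length(us)) { acc <- acc + us[[k]]$data; msk <- msk & us[[k]]$mask }
    uni <- image_volume(acc / length(us), us[[1L]]$affine, us[[1L]]$pe_axis)
    uni$mask <- msk
  } else {
    uni <- uni_image(comb[[1L]], comb[[2L]])
  }
  list(S1 = comb[[1L]], S2 = comb[[2L]], uni = uni)
}

#' Temporal signal-to-noise ratio map
#'
#' Voxelwise temporal mean divided by temporal standard deviation (sample
#' SD, denominator n-1) over the frames of a 4D series. Voxels with zero
#' temporal SD are reported as 0 and excluded from the mask.
#'
#' @param series A 4D [image_volume()] (frame axis last) with at least 3
#'   frames.
#' @return A real 3D [image_volume()] with an extra logical element `mask`.
#' @export
tsnr_map <- function(series) {
  stopifnot(inherits(series, "image_volume"))
  d <- dim(series$data)
  if (length(d) != 4L) stop("tsnr_map needs a 4D series")
  if (d[4] < 3L) stop("tsnr_map needs at least 3 frames")
  x <- series$data
  if (is.complex(x)) x <- Mod(x)
  mu <- rowMeans(x, dims = 3L)
  sd_ <- sqrt(rowSums((x - as.vector(mu))^2, dims = 3L) / (d[4] - 1L))
  tsnr <- ifelse(sd_ > 0, mu / sd_, 0)
  out <- image_volume(array(tsnr, d[1:3]), series$affine, series$pe_axis)
  out$mask <- array(sd_ > 0, d[1:3])
  out
}
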