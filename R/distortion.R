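# displacement (voxels) along PE per Hz of off-resonance
shift_per_hz <- function(esp_eff_ms, Npe) esp_eff_ms * 1e-3 * Npe

# move the PE axis of a 3D array to dimension 1 and back
pe_first <- function(a, pe) aperm(a, c(pe, setdiff(1:3, pe)))
pe_back <- function(a, pe) aperm(a, order(c(pe, setdiff(1:3, pe))))

# 1-D conservative resampling of all PE columns. The continuum map is
# output(y) = input(y - d*s(y)) * (1 - d*s'(y)); it is discretised in
# conservative (area-weighted) form: each output voxel integrates the
# input over its pulled-back cell,
#   out[y] = C(u(y + 1/2)) - C(u(y - 1/2)),  u(t) = t - d*s(t),
# where C is the interpolated cumulative line integral of the column.
# The sum over a column telescopes, so the line integral along PE is
# conserved to rounding whenever the pulled-back cells stay inside the
# FOV; cells pulled from outside contribute zero. The Jacobian intensity
# modulation is implicit in the cell widths. C is interpolated with a
# shape-preserving cubic ("cubic", default) or linearly ("linear",
# equivalent to area-weighted linear resampling).
# a: array with PE first; s: displacement (voxels) with PE first; d: +1/-1.
warp_columns <- function(a, s, d, interp = c("cubic", "linear")) {
  interp <- match.arg(interp)
  n <- dim(a)[1L]
  ncol_ <- prod(dim(a)[-1L])
  dim(a) <- c(n, ncol_)
  dim(s) <- c(n, ncol_)
  y <- seq_len(n)
  yh <- c(y - 0.5, n + 0.5)            # cell edges
  out <- a * 0
  for (c_ in seq_len(ncol_)) {
    sc <- s[, c_]
    if (all(sc == 0)) { out[, c_] <- a[, c_]; next }
    s_h <- stats::approx(y, sc, yh, rule = 2)$y
    u <- pmin(pmax(yh - d * s_h, 0.5), n + 0.5)
    col <- a[, c_]
    if (is.complex(col)) {
      out[, c_] <- complex(real = diff(cum_interp(Re(col), u, interp)),
                           imaginary = diff(cum_interp(Im(col), u, interp)))
    } else {
      out[, c_] <- diff(cum_interp(col, u, interp))
    }
  }
  out
}

# interpolated cumulative line integral of a column, evaluated at
# positions u in [0.5, n + 0.5]
cum_interp <- function(col, u, interp) {
  n <- length(col)
  edges <- c(0.5, seq_len(n) + 0.5)
  C <- c(0, cumsum(col))
  if (interp == "linear") {
    stats::approx(edges, C, u, rule = 2)$y
  } else {
    stats::splinefun(edges, C, method = "monoH.FC")(u)
  }
}

# central-difference gradient along dim 1 (one-sided at the ends)
apply_grad1 <- function(s) {
  n <- nrow(s)
  g <- s
  if (n >= 3L) g[2:(n - 1L), ] <- (s[3:n, , drop = FALSE] -
                                     s[1:(n - 2L), , drop = FALSE]) / 2
  g[1L, ] <- s[2L, ] - s[1L, ]
  g[n, ] <- s[n, ] - s[n - 1L, ]
  g
}

#' Apply B0-driven EPI geometric distortion along the phase-encode axis
#'
#' Displaces each voxel along the PE axis by
#' `d * dB0(x) [Hz] * esp_eff [s] * Npe` voxels — the standard 1-D EPI
#' distortion model — using 1-D interpolation with Jacobian intensity
#' modulation so the line integral along PE is conserved. Reversing the PE
#' polarity `d` mirrors the distortion.
#'
#' @param vol An [image_volume()] (3D, real or complex).
#' @param field [image_volume()] (or bare array) of off-resonance in Hz on
#'   the same grid.
#' @param esp_eff Effective echo spacing in ms.
#' @param d PE polarity, +1 or -1.
#' @param Npe PE matrix size (defaults to the volume's PE dimension).
#' @param interp `"cubic"` (monotone, default) or `"linear"`.
#' @return The distorted [image_volume()].
#' @export
apply_distortion <- function(vol, field, esp_eff, d, Npe = NULL,
                             interp = c("cubic", "linear")) {
  interp <- match.arg(interp)
  stopifnot(inherits(vol, "image_volume"), d %in% c(-1, 1))
  f <- if (inherits(field, "image_volume")) field$data else field
  if (!identical(dim(f), dim(vol$data)))
    stop("field map grid does not match the image grid")
  pe <- vol$pe_axis
  if (is.null(Npe)) Npe <- dim(vol$data)[pe]
  s <- f * shift_per_hz(esp_eff, Npe)
  if (max(abs(s)) > dim(vol$data)[pe] / 2)
    stop("displacement exceeds half the field of view; ",
         "fold-over is not modelled")
  a <- pe_first(vol$data, pe)
  sv <- pe_first(s, pe)
  out <- pe_back(array(warp_columns(a, sv, d, interp), dim(a)), pe)
  image_volume(out, vol$affine, pe)
}

#' Remove a known B0-driven EPI distortion (exact inverse warp)
#'
#' Inverts the forward model of [apply_distortion()]: the forward warp maps
#' source coordinate `u = y - d*s(y)` to target `y`, so simply re-applying
#' the warp with opposite polarity is only a first-order inverse (it errs by
#' about `s * ds/dy` voxels where the shift varies). This function instead
#' solves the 1-D coordinate inversion `t(u) = s(u + d*t(u))` per voxel by
#' fixed-point iteration and resamples with the matching Jacobian, which
#' recovers the undistorted volume to interpolation accuracy.
#'
#' @inheritParams apply_distortion
#' @param d The PE polarity the distortion was *applied* with.
#' @param n_fp Fixed-point iterations for the coordinate inversion.
#' @return The unwarped [image_volume()].
#' @export
unwarp_distortion <- function(vol, field, esp_eff, d, Npe = NULL,
                              interp = c("cubic", "linear"), n_fp = 8L) {
  interp <- match.arg(interp)
  stopifnot(inherits(vol, "image_volume"), d %in% c(-1, 1))
  f <- if (inherits(field, "image_volume")) field$data else field
  if (!identical(dim(f), dim(vol$data)))
    stop("field map grid does not match the image grid")
  pe <- vol$pe_axis
  if (is.null(Npe)) Npe <- dim(vol$data)[pe]
  s <- pe_first(f * shift_per_hz(esp_eff, Npe), pe)
  n <- dim(s)[1L]
  dim_s <- dim(s)
  dim(s) <- c(n, prod(dim_s[-1L]))
  y <- seq_len(n)
  t_ <- s
  for (k in seq_len(n_fp)) {           # t(u) = s(u + d*t(u))
    u_eval <- pmin(pmax(y + d * t_, 1), n)
    u0 <- pmin(floor(u_eval), n - 1L)
    fu <- u_eval - u0
    idx <- rep((seq_len(ncol(s)) - 1L) * n, each = n)
    t_ <- array(s[as.vector(u0) + idx] * (1 - as.vector(fu)) +
                  s[as.vector(u0) + 1L + idx] * as.vector(fu), dim(t_))
  }
  a <- pe_first(vol$data, pe)
  out <- warp_columns(a, array(t_, dim(a)), -d, interp)
  image_volume(pe_back(array(out, dim(a)), pe), vol$affine, pe)
}

#' Synthesize an adjustable level of geometric warping
#'
#' Applies a scaled version of the full distortion: the displacement is
#' `lambda` times the displacement a readout with echo spacing
#' `spec$esp_eff` would produce. `lambda = 0` returns the input unchanged;
#' `lambda = 1` reproduces [apply_distortion()] at the target echo spacing.
#' This allows a structural image to be warped retrospectively to any
#' desired distortion level, e.g. to match a functional acquisition.
#'
#' @param vol An [image_volume()].
#' @param field Off-resonance field (Hz), [image_volume()] or array.
#' @param spec A [warp_spec()].
#' @param ... Passed to [apply_distortion()].
#' @return The warped [image_volume()].
#' @export
synthesize_warp_level <- function(vol, field, spec, ...) {
  stopifnot(inherits(spec, "warp_spec"))
  if (spec$lambda == 0) return(vol)
  f <- if (inherits(field, "image_volume")) field$data else field
  apply_distortion(vol, f * spec$lambda, spec$esp_eff, spec$d, ...)
}

#' Warp specification
#'
#' @param lambda Warp fraction: 0 = undistorted, 1 = the full distortion of
#'   a readout with echo spacing `esp_eff`.
#' @param esp_eff Reference effective echo spacing (ms, > 0).
#' @param d PE polarity of the synthesized warp, +1 or -1.
#' @return A `warp_spec` list.
#' @export
warp_spec <- function(lambda, esp_eff, d = 1L) {
  if (!is.finite(lambda)) stop("lambda must be finite")
  if (!(esp_eff > 0)) stop("esp_eff must be positive")
  if (!(d %in% c(-1, 1))) stop("d must be +1 or -1")
  structure(list(lambda = as.numeric(lambda), esp_eff = as.numeric(esp_eff),
                 d = as.integer(d)), class = "warp_spec")
}

# separable Gaussian smoothing of a 3D array via per-axis banded matrices
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

smooth_matrix <- function(n, sigma) {
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    keep <- j >= 1L & j <= n
    w <- k[keep]
    M[i, j[keep]] <- w / sum(w)    # renormalised at the edges
  }
  M
}

smooth3d <- function(a, sigma) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  Ms <- lapply(d, smooth_matrix, sigma = sigma)
  # axis 1
  dim(a) <- c(d[1], d[2] * d[3])
  a <- Ms[[1]] %*% a
  dim(a) <- d
  # axis 2
  a <- aperm(a, c(2, 1, 3))
  dim(a) <- c(d[2], d[1] * d[3])
  a <- Ms[[2]] %*% a
  dim(a) <- c(d[2], d[1], d[3])
  a <- aperm(a, c(2, 1, 3))
  # axis 3
  a <- aperm(a, c(3, 1, 2))
  dim(a) <- c(d[3], d[1] * d[2])
  a <- Ms[[3]] %*% a
  dim(a) <- c(d[3], d[1], d[2])
  aperm(a, c(2, 3, 1))
}

#' Estimate the off-resonance field from a reversed-PE pair
#'
#' Symmetric multiscale 1-D registration of two magnitude volumes of the
#' same object acquired with opposite phase-encode polarity, in two stages.
#' First a demons-style stage: the displacement field `s` is iteratively
#' updated so that `vol_plus` unwarped by `-s` matches `vol_minus` unwarped
#' by `+s` (both with Jacobian intensity modulation, so that the residual
#' vanishes at the true field even in flat regions where the polarity pair
#' differs by intensity pile-up alone), with Gaussian smoothing of the
#' update (fluid-like) and of the accumulated field (diffusion-like) as
#' regularisation. Second, an optional Gauss-Newton refinement of the same
#' symmetric cost over a smooth tensor-product cubic B-spline field, with
#' Levenberg-Marquardt damping and a weak quadratic anchor to the first
#' stage; the spline parameterisation supplies the smoothness constraint
#' without the amplitude attenuation that repeated Gaussian smoothing
#' causes, and its derivative term exploits the Jacobian signal.
#'
#' The whole construction is exactly antisymmetric: swapping the inputs
#' negates the estimate. The returned field is `dB0 = s / (esp_eff * Npe)`
#' in Hz, zeroed outside the joint support of the two images.
#'
#' @param vol_plus,vol_minus [image_volume()]s acquired at PE polarity +1
#'   and -1 (magnitude; complex input is reduced to magnitude).
#' @param esp_eff Effective echo spacing in ms.
#' @param Npe PE matrix size (defaults to the PE dimension).
#' @param levels Image smoothing sigmas (voxels) per demons pyramid level,
#'   coarse to fine.
#' @param n_iter Demons iterations per level.
#' @param smooth_update,smooth_field Gaussian sigmas (voxels) applied to the
#'   incremental update and to the accumulated field each demons iteration.
#' @param max_step Maximum displacement update per iteration (voxels).
#' @param refine Logical; run the spline Gauss-Newton refinement
#'   (default TRUE; skipped with a log note on grids too large for the
#'   dense spline design matrix).
#' @param spline_spacing Knot spacing of the refinement spline (voxels).
#' @param gn_sigmas Image smoothing sigmas per refinement stage.
#' @param n_gn Gauss-Newton iterations per stage.
#' @param anchor Weight of the quadratic anchor tying the refined field to
#'   the demons initialisation.
#' @return [image_volume()] of off-resonance in Hz, with the displacement
#'   field (voxels) attached as attribute `"displacement"`.
#' @export
estimate_field_from_pair <- function(vol_plus, vol_minus, esp_eff,
                                     Npe = NULL,
                                     levels = c(3, 1.5, 0.5),
                                     n_iter = 40L,
                                     smooth_update = 1.5,
                                     smooth_field = 1.0,
                                     max_step = 0.75,
                                     refine = TRUE,
                                     spline_spacing = 4,
                                     gn_sigmas = c(3, 1.5, 0.75),
                                     n_gn = 6L,
                                     anchor = 0.01) {
  stopifnot(inherits(vol_plus, "image_volume"),
            inherits(vol_minus, "image_volume"))
  if (!identical(dim(vol_plus$data), dim(vol_minus$data)))
    stop("the two volumes are on different grids")
  pe <- vol_plus$pe_axis
  A0 <- Mod(vol_plus$data); B0 <- Mod(vol_minus$data)
  if (is.null(Npe)) Npe <- dim(A0)[pe]
  scale_ <- max(A0, B0)
  if (scale_ <= 0) stop("both input volumes are empty")
  A0 <- A0 / scale_; B0 <- B0 / scale_
  supp <- (A0 > 0.02) | (B0 > 0.02)
  if (!any(supp & (A0 > 0.02) & (B0 > 0.02)))
    stop("the two volumes have no overlapping support")
  d3 <- dim(A0)
  n_iter <- rep_len(n_iter, length(levels))
  smooth_update <- rep_len(smooth_update, length(levels))
  smooth_field <- rep_len(smooth_field, length(levels))
  s <- array(0, d3)                    # displacement (voxels), PE-native grid
  for (lv in seq_along(levels)) {
    sig <- levels[lv]
    A <- smooth3d(A0, sig); B <- smooth3d(B0, sig)
    for (it in seq_len(n_iter[lv])) {
      ds <- grad_pe(s, pe)
      # unwarp with Jacobian modulation so that at the true field the
      # residual vanishes even in flat regions (where the polarity pair
      # differs by intensity pile-up, not by visible displacement)
      Au <- warp_pe(A, s, -1, pe) * (1 + ds)
      Bu <- warp_pe(B, s, +1, pe) * (1 - ds)
      r <- Au - Bu
      g <- 0.5 * (grad_pe(Au, pe) + grad_pe(Bu, pe))
      den <- g^2 + r^2 / 4             # demons normalisation, step <= 1
      upd <- -0.5 * r * g / den
      upd[!is.finite(upd)] <- 0
      upd[abs(upd) > max_step] <- sign(upd[abs(upd) > max_step]) * max_step
      upd <- smooth3d(upd, smooth_update[lv])
      s <- smooth3d(s + upd, smooth_field[lv])
    }
  }
  if (refine) {
    s_ref <- refine_field_spline(A0, B0, s, pe, spacing = spline_spacing,
                                 sigmas = gn_sigmas, n_gn = n_gn,
                                 anchor = anchor)
    if (!is.null(s_ref)) s <- s_ref
  }
  s[!supp] <- 0
  fld <- image_volume(s / shift_per_hz(esp_eff, Npe), vol_plus$affine, pe)
  attr(fld, "displacement") <- s
  fld
}

# cubic B-spline basis (and PE derivative) on 1..n with the given knot
# spacing
spline_basis_1d <- function(n, spacing) {
  interior <- seq(1 + spacing, n - 1, by = spacing)
  kn <- c(rep(1, 4), interior, rep(n, 4))
  x <- seq_len(n)
  list(B = splines::splineDesign(kn, x, ord = 4),
       D = splines::splineDesign(kn, x, ord = 4, derivs = rep(1L, n)))
}

# Gauss-Newton / Levenberg-Marquardt refinement of the symmetric
# reversed-PE cost over a tensor-product cubic B-spline displacement
# field. Returns the refined displacement array, or NULL when the dense
# design matrix would be too large for the grid.
refine_field_spline <- function(A0, B0, s_init, pe, spacing = 4,
                                sigmas = c(3, 1.5, 0.75), n_gn = 6L,
                                anchor = 0.01) {
  d <- dim(A0)
  bases <- lapply(d, spline_basis_1d, spacing = spacing)
  ncoef <- prod(vapply(bases, function(b) ncol(b$B), 1L))
  if (ncoef > 2000L || prod(d) * ncoef > 5e8) {
    t1epi_log("info", "grid too large for dense spline refinement; ",
              "returning the demons field")
    return(NULL)
  }
  Bs <- lapply(bases, `[[`, "B")
  S <- kronecker(Bs[[3]], kronecker(Bs[[2]], Bs[[1]]))
  Dy <- Bs
  Dy[[pe]] <- bases[[pe]]$D
  Sy <- kronecker(Dy[[3]], kronecker(Dy[[2]], Dy[[1]]))
  StS <- crossprod(S)
  co0 <- as.vector(qr.solve(StS + 1e-8 * diag(ncol(S)),
                            crossprod(S, as.vector(s_init))))
  co <- co0
  cost_of <- function(co, A, B) {
    s <- array(S %*% co, d)
    ds <- grad_pe(s, pe)
    r <- warp_pe(A, s, -1, pe) * (1 + ds) - warp_pe(B, s, +1, pe) * (1 - ds)
    sum(r^2) + anchor * sum((StS %*% (co - co0)) * (co - co0))
  }
  for (sig in sigmas) {
    A <- smooth3d(A0, sig); B <- smooth3d(B0, sig)
    lam <- 1e-3
    cost <- cost_of(co, A, B)
    for (it in seq_len(n_gn)) {
      s <- array(S %*% co, d)
      ds <- grad_pe(s, pe)
      wA <- warp_pe(A, s, -1, pe); wB <- warp_pe(B, s, +1, pe)
      r <- as.vector(wA * (1 + ds) - wB * (1 - ds))
      P <- as.vector(grad_pe(wA, pe) * (1 + ds) + grad_pe(wB, pe) * (1 - ds))
      Q <- as.vector(wA + wB)
      D_ <- P * S + Q * Sy
      H <- crossprod(D_) + anchor * StS
      g <- as.vector(crossprod(D_, r)) + anchor *
        as.vector(StS %*% (co - co0))
      dH <- mean(diag(H))
      for (try_ in 1:6) {              # Levenberg-Marquardt damping
        delta <- as.vector(qr.solve(H + lam * dH * diag(ncol(H)), -g))
        cn <- cost_of(co + delta, A, B)
        if (cn < cost) {
          co <- co + delta; cost <- cn; lam <- max(lam / 3, 1e-6)
          break
        }
        lam <- lam * 8
      }
    }
  }
  array(S %*% co, d)
}

# fast linear pull-back warp used inside the estimation loop:
# out(y) = in(y - d*s(y)) (no Jacobian; residual symmetry is what matters)
warp_pe <- function(a, s, d, pe) {
  ap <- pe_first(a, pe)
  sp <- pe_first(s, pe)
  n <- dim(ap)[1L]
  m <- prod(dim(ap)[-1L])
  dim(ap) <- c(n, m); dim(sp) <- c(n, m)
  u <- seq_len(n) - d * sp
  u[u < 1] <- 1; u[u > n] <- n
  u0 <- pmin(floor(u), n - 1L)
  fu <- u - u0
  idx <- rep((seq_len(m) - 1L) * n, each = n)
  v <- ap[as.vector(u0) + idx] * (1 - as.vector(fu)) +
    ap[as.vector(u0) + 1L + idx] * as.vector(fu)
  pe_back(array(v, dim(pe_first(a, pe))), pe)
}

grad_pe <- function(a, pe) {
  ap <- pe_first(a, pe)
  d <- dim(ap)
  dim(ap) <- c(d[1], prod(d[-1]))
  g <- apply_grad1(ap)
  pe_back(array(g, d), pe)
}

#' Match a structural protocol's distortion to a functional acquisition
#'
#' The displacement per Hz of off-resonance is `esp_eff [s] * Npe` voxels.
#' Within a segmented readout the effective echo spacing scales inversely
#' with the segmentation factor (the per-train line spacing is fixed), so
#' the structural distortion level can be tuned by choosing the integer
#' segmentation that brings `esp_eff * Npe` closest to the functional
#' value. Errors when no integer segmentation achieves the tolerance,
#' listing the nearest feasible settings.
#'
#' @param p Structural [protocol_config()].
#' @param func_esp_eff Functional effective echo spacing (ms, > 0).
#' @param func_Npe Functional PE matrix size.
#' @param tol Relative tolerance on the displacement-per-Hz match
#'   (default 0.05).
#' @return A [protocol_config()] with adjusted `seg` and `esp_eff`;
#'   attributes `"seg"` and `"residual"` report the achieved segmentation
#'   and relative mismatch.
#' @export
match_echo_spacing <- function(p, func_esp_eff, func_Npe, tol = 0.05) {
  validate_protocol(p)
  if (!(func_esp_eff > 0)) stop("functional esp_eff must be positive")
  target <- shift_per_hz(func_esp_eff, func_Npe)
  esp_base <- p$esp_eff * p$seg        # per-train line spacing, seg-invariant
  disp <- function(seg) shift_per_hz(esp_base / seg, p$N[2])
  seg_ideal <- esp_base * 1e-3 * p$N[2] / (target * 1e0)
  cand <- sort(unique(pmax(1L, c(floor(seg_ideal), ceiling(seg_ideal),
                                 round(seg_ideal)))))
  resid <- abs(vapply(cand, disp, 1) - target) / target
  k <- which.min(resid)
  if (resid[k] > tol) {
    stop("no integer segmentation matches the functional distortion within ",
         "tolerance ", tol, "; nearest candidates: ",
         paste(sprintf("seg %d (residual %.3f)", cand, resid),
               collapse = ", "))
  }
  out <- p
  out$seg <- as.integer(cand[k])
  out$esp_eff <- esp_base / out$seg
  attr(out, "seg") <- out$seg
  attr(out, "residual") <- resid[k]
  out
}
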