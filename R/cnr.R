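#' Additive noise model for the per-image signals
#'
#' Noise on the two inversion-time signals is modelled as independent,
#' equal-variance, additive Gaussian with standard deviation `sigma` on each
#' of S1 and S2 (same units as the signal).
#'
#' @param sigma Per-image noise standard deviation (> 0).
#' @param independent Logical; the independence assumption flag (only
#'   independent noise is implemented).
#' @return A `noise_model` list.
#' @export
noise_model <- function(sigma, independent = TRUE) {
  if (!(sigma > 0)) stop("sigma must be positive")
  if (!isTRUE(independent))
    stop("only independent per-image noise is implemented")
  structure(list(sigma = as.numeric(sigma), independent = TRUE),
            class = "noise_model")
}

# UNI statistic on signed real signals and its analytic partial derivatives
uni_stat <- function(S1, S2) S1 * S2 / (S1^2 + S2^2)

uni_grad <- function(S1, S2) {
  den <- (S1^2 + S2^2)^2
  list(d1 = S2 * (S2^2 - S1^2) / den,
       d2 = S1 * (S1^2 - S2^2) / den)
}

#' First-order noise propagation through the UNI statistic
#'
#' Delta-method standard deviation of `UNI = S1*S2 / (S1^2 + S2^2)` under
#' independent additive noise of standard deviation `sigma` on each signal:
#' `sigma_UNI^2 = (dUNI/dS1)^2 sigma^2 + (dUNI/dS2)^2 sigma^2`, with
#' analytic partial derivatives.
#'
#' @param s A `signal_pair` from [steady_state_signals()], or a list/vector
#'   with elements `S1`, `S2` (signed real signals).
#' @param nm A [noise_model()].
#' @return The standard deviation of the UNI statistic (vectorised).
#' @examples
#' s <- steady_state_signals(protocol_config(), tissue_params("GM", 1800))
#' propagate_uni_noise(s, noise_model(0.01))
#' @export
propagate_uni_noise <- function(s, nm) {
  S1 <- s$S1; S2 <- s$S2
  if (any(S1 == 0 & S2 == 0))
    stop("UNI statistic undefined: both signals are zero")
  g <- uni_grad(S1, S2)
  nm$sigma * sqrt(g$d1^2 + g$d2^2)
}

#' Gray/white-matter CNR surface over the two flip angles
#'
#' Evaluates the contrast-to-noise ratio of the bias-cancelling statistic
#' between two tissues on a grid of block-1/block-2 excitation flip angles:
#' `CNR(a1, a2) = |UNI_GM - UNI_WM| / sqrt(sigma_UNI,GM^2 + sigma_UNI,WM^2)`
#' with each UNI from the steady-state Bloch signals at nominal B1 (= 1) and
#' the noise propagated by [propagate_uni_noise()]. With
#' `statistic = "difference"` the raw signal-pair difference
#' `sqrt(dS1^2 + dS2^2) / (sqrt(2) * sigma)` is used instead.
#'
#' @param p A [protocol_config()]; its `alpha1`/`alpha2` are overridden by
#'   the grid values.
#' @param gm,wm [tissue_params()] for the two tissues.
#' @param nm A [noise_model()].
#' @param alpha1_grid,alpha2_grid Flip-angle grids in degrees, within
#'   \\[0, 90\\] (default 1..45 in 1 degree steps).
#' @param statistic `"uni"` (default) or `"difference"`.
#' @return An object of class `cnr_surface`: list with `alpha1`, `alpha2`,
#'   matrix `cnr` (`alpha1` by `alpha2`) and the grid `argmax`.
#' @export
cnr_surface <- function(p, gm, wm, nm,
                        alpha1_grid = 1:45, alpha2_grid = 1:45,
                        statistic = c("uni", "difference")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(gm, "tissue_params"), inherits(wm, "tissue_params"),
            inherits(nm, "noise_model"))
  if (any(alpha1_grid < 0 | alpha1_grid > 90) ||
      any(alpha2_grid < 0 | alpha2_grid > 90))
    stop("flip-angle grids must lie within [0, 90] degrees")
  ev <- protocol_events(p)          # timing is flip-angle independent
  T1s <- c(gm$T1, wm$T1)
  M0s <- c(gm$M0, wm$M0)
  cnr <- matrix(0, length(alpha1_grid), length(alpha2_grid))
  for (i in seq_along(alpha1_grid)) {
    for (j in seq_along(alpha2_grid)) {
      pij <- p
      pij$alpha1 <- alpha1_grid[i]
      pij$alpha2 <- alpha2_grid[j]
      if (pij$alpha1 == 0 && pij$alpha2 == 0) { cnr[i, j] <- 0; next }
      m <- bloch_cycle_map_ev(pij, T1s, 1, ev)
      mz0 <- bloch_fixed_point(m)
      s1 <- M0s * (m$pre1$a * mz0 + m$pre1$b) * sin(pij$alpha1 * pi / 180)
      s2 <- M0s * (m$pre2$a * mz0 + m$pre2$b) * sin(pij$alpha2 * pi / 180)
      if (statistic == "uni") {
        u <- uni_stat(s1, s2)
        sd_u <- propagate_uni_noise(list(S1 = s1, S2 = s2), nm)
        cnr[i, j] <- abs(u[1] - u[2]) / sqrt(sum(sd_u^2))
      } else {
        cnr[i, j] <- sqrt((s1[1] - s1[2])^2 + (s2[1] - s2[2])^2) /
          (sqrt(2) * nm$sigma)
      }
    }
  }
  am <- surface_argmax(cnr, alpha1_grid, alpha2_grid)
  structure(list(alpha1 = alpha1_grid, alpha2 = alpha2_grid, cnr = cnr,
                 argmax = am, statistic = statistic),
            class = "cnr_surface")
}

# variant of bloch_cycle_map taking a precomputed event table (hot loop)
bloch_cycle_map_ev <- function(p, T1, b1, ev) {
  n <- max(length(T1), length(b1))
  T1 <- rep_len(as.numeric(T1), n)
  b1 <- rep_len(as.numeric(b1), n)
  c1 <- cos(p$alpha1 * pi / 180 * b1)
  c2 <- cos(p$alpha2 * pi / 180 * b1)
  a <- rep_len(1, n); b <- rep_len(0, n)
  pre <- vector("list", 2L)
  t_prev <- 0
  for (k in seq_len(nrow(ev))) {
    dt <- ev$time[k] - t_prev
    if (dt > 0) {
      E <- exp(-dt / T1)
      a <- E * a
      b <- E * b + (1 - E)
      t_prev <- ev$time[k]
    }
    if (ev$center[k]) pre[[ev$block[k]]] <- list(a = a, b = b)
    g <- switch(ev$event[k],
                inversion = rep_len(-p$eps_inv, n),
                excitation = if (ev$block[k] == 1L) c1 else c2)
    a <- g * a
    b <- g * b
  }
  E <- exp(-(p$TR_IR - t_prev) / T1)
  list(a = E * a, b = E * b + (1 - E),
       pre1 = pre[[1L]], pre2 = pre[[2L]], T1 = T1, b1 = b1)
}

# grid argmax with ties broken toward the smaller alpha1 + alpha2
# (then smaller alpha1)
surface_argmax <- function(cnr, a1, a2) {
  mx <- max(cnr)
  idx <- which(cnr >= mx - .Machine$double.eps * max(1, abs(mx)),
               arr.ind = TRUE)
  sums <- a1[idx[, 1]] + a2[idx[, 2]]
  ord <- order(sums, a1[idx[, 1]])
  k <- ord[1L]
  list(i = unname(idx[k, 1]), j = unname(idx[k, 2]),
       alpha1 = a1[idx[k, 1]], alpha2 = a2[idx[k, 2]], cnr = mx)
}

#' Optimal flip-angle pair from a CNR surface
#'
#' Returns the global grid maximum of the surface and refines it by a local
#' quadratic fit over the surrounding 3x3 neighbourhood (when the maximum is
#' interior and the fit is concave; otherwise the grid point is returned
#' unrefined). Grid ties are broken toward the smaller `alpha1 + alpha2`.
#' A soft plausibility check warns when the optimum falls at or below 10
#' degrees, since the two-inversion design is expected to favour flip angles
#' larger than conventional small-angle Look-Locker regimes.
#'
#' @param surface A `cnr_surface` from [cnr_surface()], or a plain list with
#'   `alpha1`, `alpha2`, `cnr`.
#' @return A list with `alpha1`, `alpha2` (degrees, refined), `cnr` (value
#'   at the grid argmax), and `grid` (the unrefined grid argmax).
#' @export
optimize_flip_angles <- function(surface) {
  a1 <- surface$alpha1; a2 <- surface$alpha2; z <- surface$cnr
  if (length(z) == 0L) stop("empty CNR surface")
  if (all(z == 0)) stop("no contrast: CNR surface is identically zero")
  am <- surface_argmax(z, a1, a2)
  ref <- c(am$alpha1, am$alpha2)
  i <- am$i; j <- am$j
  if (i > 1L && i < length(a1) && j > 1L && j < length(a2)) {
    ii <- (i - 1L):(i + 1L); jj <- (j - 1L):(j + 1L)
    g <- expand.grid(x = a1[ii], y = a2[jj])
    g$z <- as.vector(z[ii, jj])
    fit <- stats::lm(z ~ x + y + I(x^2) + I(y^2) + I(x * y), data = g)
    co <- stats::coef(fit)
    H <- matrix(c(2 * co["I(x^2)"], co["I(x * y)"],
                  co["I(x * y)"], 2 * co["I(y^2)"]), 2, 2)
    if (all(is.finite(H)) && H[1, 1] < 0 && det(H) > 0) {
      st <- -solve(H, c(co["x"], co["y"]))
      step <- c(a1[i + 1L] - a1[i], a2[j + 1L] - a2[j])
      if (abs(st[1] - a1[i]) <= step[1] && abs(st[2] - a2[j]) <= step[2])
        ref <- st
    }
  }
  if (ref[1] <= 10 && ref[2] <= 10)
    t1epi_log("warn", "optimal flip angles (", round(ref[1], 1), ", ",
              round(ref[2], 1), ") deg are in the small-angle regime; ",
              "check protocol timing")
  list(alpha1 = unname(ref[1]), alpha2 = unname(ref[2]), cnr = am$cnr,
       grid = c(alpha1 = am$alpha1, alpha2 = am$alpha2))
}

#' Export a CNR surface as a long data frame (CSV-ready)
#'
#' @param x A `cnr_surface`.
#' @param ... Unused.
#' @return Data frame with columns `alpha1`, `alpha2`, `cnr`.
#' @export
as.data.frame.cnr_surface <- function(x, ...) {
  data.frame(alpha1 = rep(x$alpha1, times = length(x$alpha2)),
             alpha2 = rep(x$alpha2, each = length(x$alpha1)),
             cnr = as.vector(x$cnr))
}
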