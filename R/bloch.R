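# Affine propagation of longitudinal magnetisation through one IR cycle.
#
# Between pulses Mz relaxes mono-exponentially towards M0; every pulse acts
# linearly on Mz (excitation: gain cos(alpha*b1); inversion: gain -eps_inv).
# The whole cycle is therefore an affine map Mz_end = a * Mz_start + b (in
# units of M0), accumulated here event by event. Coefficients are recorded
# just before the k-space-centre excitation of each block, which is where
# image contrast is set. All quantities are vectorised over voxels: T1 and
# b1 may be vectors of equal length (or length 1).
bloch_cycle_map <- function(p, T1, b1 = 1) {
  if (any(T1 <= 0)) stop("T1 must be positive")
  if (any(b1 < 0)) stop("b1 scale must be non-negative")
  ev <- protocol_events(p)
  m <- bloch_cycle_map_ev(p, T1, b1, ev)
  m$events <- ev
  m
}

# Steady-state Mz at cycle start (units of M0): fixed point of the affine
# one-cycle map, Mz* = b / (1 - a). Errors when no stable steady state
# exists (|a| >= 1).
bloch_fixed_point <- function(m) {
  if (any(abs(m$a) >= 1))
    stop("no stable steady state: one-cycle gain |a| >= 1 ",
         "(all-zero flip angles with a perfect inversion and no relaxation)")
  m$b / (1 - m$a)
}

#' Steady-state signals at both inversion times (vectorised)
#'
#' Computes the periodic steady state of the IR cycle exactly, as the fixed
#' point of the affine one-cycle magnetisation map, and reads out the signed
#' signal at the k-space-centre excitation of each block:
#' `S_i = M0 * Mz_pre_i * sin(alpha_i * b1)`, with `Mz_pre_i` in units of M0.
#' Signals are signed: before the post-inversion zero crossing they are
#' negative (phase-sensitive reconstruction assumed).
#'
#' @param p A [protocol_config()].
#' @param T1 Longitudinal relaxation times (ms); vectorised over voxels.
#' @param b1 Relative transmit (B1+) scale, 1 = nominal; vector or scalar.
#' @param M0 Equilibrium magnetisation; vector or scalar.
#' @return A list with numeric vectors `S1`, `S2` and the pre-pulse
#'   magnetisations `Mz1`, `Mz2` (units of M0).
#' @examples
#' p <- protocol_config()
#' bloch_signals(p, T1 = c(1200, 1800), b1 = 1)
#' @export
bloch_signals <- function(p, T1, b1 = 1, M0 = 1) {
  m <- bloch_cycle_map(p, T1, b1)
  mz0 <- bloch_fixed_point(m)
  mz1 <- m$pre1$a * mz0 + m$pre1$b
  mz2 <- m$pre2$a * mz0 + m$pre2$b
  s1 <- M0 * mz1 * sin(p$alpha1 * pi / 180 * m$b1)
  s2 <- M0 * mz2 * sin(p$alpha2 * pi / 180 * m$b1)
  list(S1 = s1, S2 = s2, Mz1 = mz1, Mz2 = mz2)
}

#' Steady-state signal pair for one tissue
#'
#' Convenience wrapper around [bloch_signals()] for a single
#' [tissue_params()] object.
#'
#' @param p A [protocol_config()].
#' @param t A [tissue_params()].
#' @param b1 Relative B1+ scale (scalar).
#' @return A list of class `signal_pair` with scalars `S1`, `S2`.
#' @examples
#' steady_state_signals(protocol_config(), tissue_params("GM", 1800, 0.8))
#' @export
steady_state_signals <- function(p, t, b1 = 1) {
  stopifnot(inherits(t, "tissue_params"), length(b1) == 1L)
  s <- bloch_signals(p, t$T1, b1, t$M0)
  structure(list(S1 = s$S1, S2 = s$S2, tissue = t$name), class = "signal_pair")
}

#' Longitudinal magnetisation trajectory over one steady-state IR cycle
#'
#' Samples Mz immediately before and after every pulse event plus dense
#' samples of the relaxation in between, starting from the exact periodic
#' steady state. The saw-tooth within each readout block reflects the
#' block-specific excitation flip angle.
#'
#' @param p A [protocol_config()].
#' @param t A [tissue_params()].
#' @param b1 Relative B1+ scale (scalar, > 0 allowed to be 0 for no
#'   excitation).
#' @param n_relax Dense samples per inter-event gap (default 4) in addition
#'   to the pre/post event samples.
#' @return A data frame of class `mz_trajectory` with columns `time` (ms),
#'   `Mz` (units of M0; multiply by `t$M0` for absolute units) and `event`
#'   (`"inversion"`, `"excitation-block-1"`, `"excitation-block-2"`,
#'   `"recovery"`).
#' @examples
#' tr <- simulate_mz_trajectory(protocol_config(), tissue_params("GM", 1800))
#' range(tr$Mz)
#' @export
simulate_mz_trajectory <- function(p, t, b1 = 1, n_relax = 4L) {
  stopifnot(inherits(t, "tissue_params"), length(b1) == 1L, b1 >= 0)
  m <- bloch_cycle_map(p, t$T1, b1)
  mz <- bloch_fixed_point(m)
  ev <- m$events
  c1 <- cos(p$alpha1 * pi / 180 * b1)
  c2 <- cos(p$alpha2 * pi / 180 * b1)
  times <- numeric(0); mzs <- numeric(0); tags <- character(0)
  t_prev <- 0
  add <- function(ti, zi, tg) {
    times <<- c(times, ti); mzs <<- c(mzs, zi); tags <<- c(tags, tg)
  }
  relax_to <- function(t_to, tag) {
    if (t_to <= t_prev) return(invisible())
    ts <- seq(t_prev, t_to, length.out = n_relax + 2L)[-1L]
    zs <- 1 - (1 - mz) * exp(-(ts - t_prev) / t$T1)
    for (i in seq_along(ts)) add(ts[i], zs[i], tag)
    mz <<- zs[length(zs)]
    t_prev <<- t_to
    invisible()
  }
  add(0, mz, "recovery")                 # cycle start = steady state
  for (k in seq_len(nrow(ev))) {
    tag <- switch(as.character(ev$block[k]), "0" = "recovery",
                  "1" = "excitation-block-1", "2" = "excitation-block-2")
    relax_to(ev$time[k], if (ev$block[k] == 0L) "recovery" else tag)
    g <- switch(ev$event[k], inversion = -p$eps_inv,
                excitation = if (ev$block[k] == 1L) c1 else c2)
    tag_ev <- if (ev$event[k] == "inversion") "inversion" else tag
    mz <- g * mz
    add(ev$time[k], mz, tag_ev)          # post-pulse sample
  }
  relax_to(p$TR_IR, "recovery")
  if (abs(mzs[length(mzs)] - mzs[1L]) > 1e-8 * max(1, abs(mzs[1L])))
    stop("steady-state periodicity violated beyond tolerance; ",
         "the one-cycle map is ill-conditioned for this protocol")
  out <- data.frame(time = times, Mz = mzs, event = tags)
  class(out) <- c("mz_trajectory", "data.frame")
  out
}

#' Fit an apparent mono-exponential relaxation rate to a trajectory window
#'
#' Fits `Mz(t) = A - B * exp(-R1app * t)` to the pre-pulse samples of a
#' magnetisation trajectory inside a time window, by separable least
#' squares (golden-section search over the rate, linear solve for A and B).
#' Used to compare the driven recovery under a pulse train with the
#' small-flip-angle Look-Locker closed form
#' `R1app = 1/T1 - log(cos(alpha)) / TR_exc`.
#'
#' @param traj An `mz_trajectory` from [simulate_mz_trajectory()].
#' @param window Numeric length-2 time window (ms) to fit within.
#' @param events Event tags to fit on (default: the excitation samples).
#' @return List with `R1app` (1/ms), `T1app` (ms), `A`, `B` and the residual
#'   standard deviation `sigma`.
#' @export
fit_apparent_rate <- function(traj, window = NULL,
                              events = c("excitation-block-1",
                                         "excitation-block-2")) {
  d <- traj[traj$event %in% events, ]
  if (!is.null(window)) d <- d[d$time >= window[1] & d$time <= window[2], ]
  # keep pre-pulse samples only: at each pulse time the first of the two
  # samples (relaxation endpoint) precedes the post-pulse sample
  d <- d[!duplicated(d$time), ]
  if (nrow(d) < 5L) stop("too few samples in the fit window")
  rss <- function(r) {
    x <- exp(-r * d$time)
    f <- stats::lm.fit(cbind(1, x), d$Mz)
    sum(f$residuals^2)
  }
  opt <- stats::optimize(rss, interval = c(1e-6, 0.1), tol = 1e-12)
  r <- opt$minimum
  x <- exp(-r * d$time)
  f <- stats::lm.fit(cbind(1, x), d$Mz)
  list(R1app = r, T1app = 1 / r, A = f$coefficients[1],
       B = -f$coefficients[2],
       sigma = sqrt(opt$objective / max(1, nrow(d) - 3)))
}
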