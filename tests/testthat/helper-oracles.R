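# Independent oracles used to validate the analytic implementations.

# Brute-force steady state: iterate consecutive IR cycles event by event
# from thermal equilibrium (Mz = M0), using only the published event
# schedule and elementary relaxation/rotation steps. Returns the signal
# pair and pre-pulse magnetisations of the final cycle.
brute_force_signals <- function(p, T1, b1 = 1, M0 = 1, n_cycles = 500) {
  ev <- protocol_events(p)
  c1 <- cos(p$alpha1 * pi / 180 * b1)
  c2 <- cos(p$alpha2 * pi / 180 * b1)
  mz <- 1
  pre <- c(NA_real_, NA_real_)
  for (cyc in seq_len(n_cycles)) {
    t_prev <- 0
    for (k in seq_len(nrow(ev))) {
      dt <- ev$time[k] - t_prev
      if (dt > 0) {
        mz <- 1 - (1 - mz) * exp(-dt / T1)
        t_prev <- ev$time[k]
      }
      if (ev$center[k]) pre[ev$block[k]] <- mz
      g <- if (ev$event[k] == "inversion") -p$eps_inv
           else if (ev$block[k] == 1L) c1 else c2
      mz <- g * mz
    }
    mz <- 1 - (1 - mz) * exp(-(p$TR_IR - t_prev) / T1)
  }
  list(S1 = M0 * pre[1] * sin(p$alpha1 * pi / 180 * b1),
       S2 = M0 * pre[2] * sin(p$alpha2 * pi / 180 * b1),
       Mz1 = pre[1], Mz2 = pre[2])
}

# central-difference gradient of a scalar function of (S1, S2)
central_diff_grad <- function(f, S1, S2, h = 1e-6) {
  c((f(S1 + h, S2) - f(S1 - h, S2)) / (2 * h),
    (f(S1, S2 + h) - f(S1, S2 - h)) / (2 * h))
}
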