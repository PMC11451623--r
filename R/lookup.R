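#' Build a T1 lookup table from the forward Bloch model
#'
#' Tabulates a signal statistic of the two inversion-time signals as a
#' function of T1, for a set of relative B1+ scales, using the exact
#' steady-state Bloch signals. The default statistic is the signed real
#' ratio `S1 / S2`; the bias-cancelling `UNI` statistic
#' `S1*S2 / (S1^2 + S2^2)` is available as an alternative, and a
#' magnitude-only mode (`|S1| / |S2|`, reduced valid range) supports
#' magnitude input data. For each B1 scale the table is trimmed to the
#' longest contiguous strictly monotone run of the statistic over T1 (the
#' ratio statistic has a pole at the S2 zero crossing); the common valid T1
#' range across B1 scales is kept and any trimming is logged.
#'
#' @param p A [protocol_config()].
#' @param t1_range Length-2 T1 range in ms, within (0, 10000].
#' @param t1_step T1 grid step in ms.
#' @param b1_grid Strictly increasing grid of relative B1+ scales.
#' @param statistic `"ratio"` (default) or `"uni"`.
#' @param magnitude Logical; use magnitude signals (default FALSE: signed,
#'   phase-sensitive).
#' @return An object of class `t1_lookup`: list with `T1` (ms grid), `b1`
#'   (grid), `stat` (matrix, T1 by b1), `statistic`, `magnitude`,
#'   `increasing` (per-b1 direction of monotonicity) and `protocol_id`.
#' @examples
#' tab <- build_lookup_table(protocol_config(), t1_range = c(600, 3000),
#'                           t1_step = 50, b1_grid = c(0.9, 1, 1.1))
#' range(tab$T1)
#' @export
build_lookup_table <- function(p, t1_range = c(300, 5000), t1_step = 10,
                               b1_grid = seq(0.7, 1.3, by = 0.1),
                               statistic = c("ratio", "uni"),
                               magnitude = FALSE) {
  statistic <- match.arg(statistic)
  if (!(t1_range[1] > 0 && t1_range[2] <= 10000 && t1_range[2] > t1_range[1]))
    stop("T1 range must lie within (0, 10000] ms")
  if (any(diff(b1_grid) <= 0) || any(b1_grid <= 0))
    stop("b1 grid must be strictly increasing and positive")
  T1 <- seq(t1_range[1], t1_range[2], by = t1_step)
  grid <- expand.grid(T1 = T1, b1 = b1_grid)
  s <- bloch_signals(p, grid$T1, grid$b1)
  S1 <- s$S1; S2 <- s$S2
  if (magnitude) { S1 <- abs(S1); S2 <- abs(S2) }
  val <- switch(statistic,
                ratio = S1 / S2,
                uni = uni_stat(S1, S2))
  stat <- matrix(val, nrow = length(T1), ncol = length(b1_grid))
  # longest strictly monotone finite run per b1 curve, then the common range
  runs <- apply(stat, 2L, longest_monotone_run)
  lo <- max(vapply(runs, `[[`, 1L, "from"))
  hi <- min(vapply(runs, `[[`, 1L, "to"))
  if (hi - lo + 1L < 3L)
    stop("no common strictly monotone T1 range across the B1 grid; ",
         "the statistic is unusable for this protocol")
  if (lo > 1L || hi < length(T1))
    t1epi_log("info", "lookup table trimmed to monotone T1 range [",
              T1[lo], ", ", T1[hi], "] ms")
  stat <- stat[lo:hi, , drop = FALSE]
  T1 <- T1[lo:hi]
  inc <- apply(stat, 2L, function(v) v[length(v)] > v[1L])
  structure(list(T1 = T1, b1 = b1_grid, stat = stat,
                 statistic = statistic, magnitude = magnitude,
                 increasing = inc, protocol_id = protocol_id(p)),
            class = "t1_lookup")
}

# short id capturing every protocol field that affects the signals
protocol_id <- function(p) {
  paste0("TI", p$TI1, "-", p$TI2, "_TR", p$TR_IR,
         "_FA", p$alpha1, "-", p$alpha2, "_seg", p$seg, "_Rz", p$Rz,
         "_N", paste(p$N, collapse = "x"), "_eps", p$eps_inv,
         "_TRexc", if (is.null(p$TR_exc)) "auto" else p$TR_exc)
}

# indices (from, to) of the longest contiguous run where v is finite and
# strictly monotone (either direction)
longest_monotone_run <- function(v) {
  n <- length(v)
  d <- diff(v)
  ok <- is.finite(d) & d != 0
  sgn <- sign(d)
  best <- c(from = 1L, to = 1L)
  i <- 1L
  while (i <= n - 1L) {
    if (!ok[i]) { i <- i + 1L; next }
    j <- i
    while (j + 1L <= n - 1L && ok[j + 1L] && sgn[j + 1L] == sgn[i]) j <- j + 1L
    if (j + 1L - i > best["to"] - best["from"])
      best <- c(from = i, to = j + 1L)
    i <- j + 1L
  }
  as.list(best)
}

#' @export
print.t1_lookup <- function(x, ...) {
  cat("T1 lookup table (", x$statistic,
      if (x$magnitude) ", magnitude" else ", signed", ")\n", sep = "")
  cat(sprintf("  T1: %g..%g ms (%d nodes), B1: %g..%g (%d curves)\n",
              min(x$T1), max(x$T1), length(x$T1),
              min(x$b1), max(x$b1), length(x$b1)))
  cat("  protocol:", x$protocol_id, "\n")
  invisible(x)
}

#' Export a lookup table as a long data frame (CSV-ready)
#' @param x A `t1_lookup`.
#' @param ... Unused.
#' @return Data frame with columns `T1_ms`, `b1`, `stat`.
#' @export
as.data.frame.t1_lookup <- function(x, ...) {
  data.frame(T1_ms = rep(x$T1, times = length(x$b1)),
             b1 = rep(x$b1, each = length(x$T1)),
             stat = as.vector(x$stat))
}

# validity flags for T1 maps
.t1_flags <- c(in_range = 0L, clamped_low = 1L, clamped_high = 2L,
               no_signal = 3L)

#' Invert a lookup table: statistic value to T1
#'
#' Monotone (Fritsch-Carlson) interpolation of the tabulated
#' statistic-to-T1 relation. B1 values between tabulated curves are handled
#' by inverting the two bracketing curves and interpolating the resulting
#' T1 linearly in B1. Statistic values beyond a curve's range are clamped
#' to the corresponding end of the T1 range and flagged; `NaN`/`NA`
#' statistics yield the no-signal flag rather than an error. B1 values
#' outside the tabulated hull are clamped to the hull with a warning.
#'
#' @param table A `t1_lookup` from [build_lookup_table()].
#' @param value Statistic value(s), vectorised.
#' @param b1 Relative B1+ scale(s), scalar or same length as `value`.
#' @return A list with `T1` (ms) and integer `flag` (0 in-range, 1 clamped
#'   at the low-T1 end, 2 clamped at the high-T1 end, 3 no signal).
#' @examples
#' tab <- build_lookup_table(protocol_config(), t1_range = c(600, 3000),
#'                           t1_step = 50, b1_grid = c(0.9, 1, 1.1))
#' s <- bloch_signals(protocol_config(), 1500)
#' invert_lookup(tab, s$S1 / s$S2, 1)
#' @export
invert_lookup <- function(table, value, b1 = 1) {
  stopifnot(inherits(table, "t1_lookup"))
  n <- max(length(value), length(b1))
  value <- rep_len(as.numeric(value), n)
  b1 <- rep_len(as.numeric(b1), n)
  out_hull <- b1 < min(table$b1) - 1e-9 | b1 > max(table$b1) + 1e-9
  frac_out <- mean(out_hull, na.rm = TRUE)
  if (frac_out > 0.01) {
    warning(sprintf("%.1f%% of B1 values lie outside the tabulated hull and were clamped",
                    100 * frac_out))
  } else if (frac_out > 0) {
    t1epi_log("info", "a few B1 values outside the tabulated hull were clamped")
  }
  b1 <- pmin(pmax(b1, min(table$b1)), max(table$b1))
  T1 <- rep(NA_real_, n)
  flag <- rep(.t1_flags[["no_signal"]], n)
  usable <- is.finite(value)
  if (!any(usable)) return(list(T1 = T1, flag = flag))
  # per-b1-curve monotone inverse interpolators
  invs <- lapply(seq_along(table$b1), function(k) {
    s <- table$stat[, k]
    if (table$increasing[k]) {
      list(f = stats::splinefun(s, table$T1, method = "monoH.FC"),
           lo = s[1L], hi = s[length(s)])
    } else {
      list(f = stats::splinefun(rev(s), rev(table$T1), method = "monoH.FC"),
           lo = s[length(s)], hi = s[1L])
    }
  })
  invert_one_curve <- function(k, v) {
    iv <- invs[[k]]
    out <- iv$f(pmin(pmax(v, iv$lo), iv$hi))
    low <- v < iv$lo; high <- v > iv$hi
    # statistic below curve range maps to the T1 end the curve attains there
    t_at_lo <- if (table$increasing[k]) table$T1[1L] else table$T1[length(table$T1)]
    t_at_hi <- if (table$increasing[k]) table$T1[length(table$T1)] else table$T1[1L]
    out[low] <- t_at_lo
    out[high] <- t_at_hi
    fl <- integer(length(v))
    fl[out <= table$T1[1L]] <- .t1_flags[["clamped_low"]]
    fl[out >= table$T1[length(table$T1)]] <- .t1_flags[["clamped_high"]]
    fl[!(low | high)] <- .t1_flags[["in_range"]]
    list(T1 = out, flag = fl)
  }
  idx_hi <- findInterval(b1[usable], table$b1, all.inside = TRUE)
  w <- (b1[usable] - table$b1[idx_hi]) /
    ifelse(length(table$b1) > 1L,
           table$b1[pmin(idx_hi + 1L, length(table$b1))] - table$b1[idx_hi],
           1)
  w[!is.finite(w)] <- 0
  vals <- value[usable]
  t1a <- numeric(length(vals)); t1b <- numeric(length(vals))
  fla <- integer(length(vals)); flb <- integer(length(vals))
  for (k in unique(idx_hi)) {
    sel <- idx_hi == k
    ra <- invert_one_curve(k, vals[sel])
    rb <- invert_one_curve(min(k + 1L, length(table$b1)), vals[sel])
    t1a[sel] <- ra$T1; fla[sel] <- ra$flag
    t1b[sel] <- rb$T1; flb[sel] <- rb$flag
  }
  T1u <- (1 - w) * t1a + w * t1b
  flu <- ifelse(w < 0.5, fla, flb)          # flag from the nearer B1 curve
  flu[fla == 0L & flb == 0L] <- 0L
  T1[usable] <- T1u
  flag[usable] <- flu
  list(T1 = T1, flag = flag)
}

# trilinear interpolation of a 3D array at continuous 1-based voxel
# coordinates (matrix n x 3); outside the grid the nearest edge is used
trilinear <- function(a, xyz) {
  d <- dim(a)
  cl <- function(v, n) pmin(pmax(v, 1), n)
  x <- cl(xyz[, 1], d[1]); y <- cl(xyz[, 2], d[2]); z <- cl(xyz[, 3], d[3])
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  z0 <- pmin(floor(z), d[3] - 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  at <- function(i, j, k) a[cbind(i, j, k)]
  v000 <- at(x0, y0, z0);     v100 <- at(x0 + 1, y0, z0)
  v010 <- at(x0, y0 + 1, z0); v110 <- at(x0 + 1, y0 + 1, z0)
  v001 <- at(x0, y0, z0 + 1); v101 <- at(x0 + 1, y0, z0 + 1)
  v011 <- at(x0, y0 + 1, z0 + 1); v111 <- at(x0 + 1, y0 + 1, z0 + 1)
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
    (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
    (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
    (v011 * (1 - fx) + v111 * fx) * fy * fz
}

#' Resample a volume onto a target grid (trilinear)
#'
#' Maps every target voxel centre through the target affine to world space
#' and back through the source affine, then interpolates trilinearly. Used
#' to bring a low-resolution B1+ map onto the image grid.
#'
#' @param src An [image_volume()] (3D, real).
#' @param target_dim Integer target dimensions (length 3).
#' @param target_affine 4x4 voxel-to-world affine of the target grid.
#' @return An [image_volume()] on the target grid.
#' @export
resample_trilinear <- function(src, target_dim, target_affine) {
  stopifnot(inherits(src, "image_volume"), length(dim(src$data)) == 3L)
  ijk <- as.matrix(expand.grid(i = seq_len(target_dim[1]) - 1,
                               j = seq_len(target_dim[2]) - 1,
                               k = seq_len(target_dim[3]) - 1))
  world <- cbind(ijk, 1) %*% t(target_affine)
  svox <- world %*% t(solve(src$affine))
  vals <- trilinear(src$data, svox[, 1:3] + 1)  # 0-based -> 1-based
  image_volume(array(vals, target_dim), target_affine, src$pe_axis)
}

#' Voxelwise T1 map from a pair of inversion-time volumes
#'
#' Computes the table's statistic per voxel from the TI1/TI2 volumes
#' (phase-sensitive for complex data: the signed ratio is the real
#' projection `Re(S1 * Conj(S2)) / |S2|^2`), then inverts the lookup table
#' at the local B1+ scale. Background voxels (zero combined magnitude)
#' receive the no-signal flag and no T1 value.
#'
#' @param vol1,vol2 [image_volume()]s at TI1 and TI2 on congruent grids
#'   (real signed or complex).
#' @param table A `t1_lookup`.
#' @param b1map Optional [image_volume()] of relative B1+; resampled to the
#'   image grid by trilinear interpolation when dimensions differ. `NULL`
#'   assumes nominal B1 (= 1) everywhere.
#' @param min_signal_frac Voxels whose combined signal magnitude falls
#'   below this fraction of the robust (99th percentile) magnitude are
#'   flagged no-signal (default 0.05); zero-signal voxels are always
#'   flagged. Set to 0 to disable background masking.
#' @return An object of class `t1_map`: list with `t1` (an
#'   [image_volume()], ms; `NA` where not estimable) and `mask` (integer
#'   array: 0 in-range, 1 clamped low, 2 clamped high, 3 no signal).
#' @export
estimate_t1_map <- function(vol1, vol2, table, b1map = NULL,
                            min_signal_frac = 0.05) {
  stopifnot(inherits(vol1, "image_volume"), inherits(vol2, "image_volume"))
  if (!identical(dim(vol1$data), dim(vol2$data)))
    stop("TI1 and TI2 volumes are on different grids")
  d <- dim(vol1$data)
  if (is.null(b1map)) {
    b1 <- rep(1, prod(d))
  } else {
    stopifnot(inherits(b1map, "image_volume"))
    if (!identical(dim(b1map$data), d))
      b1map <- resample_trilinear(b1map, d, vol1$affine)
    if (!identical(dim(b1map$data), d))
      stop("B1 map could not be resampled to the image grid")
    b1 <- as.vector(b1map$data)
  }
  s1 <- as.vector(vol1$data); s2 <- as.vector(vol2$data)
  pw <- Mod(s1)^2 + Mod(s2)^2
  if (table$magnitude) {
    s1 <- Mod(s1); s2 <- Mod(s2)
    val <- switch(table$statistic, ratio = s1 / s2, uni = uni_stat(s1, s2))
  } else if (is.complex(vol1$data) || is.complex(vol2$data)) {
    val <- switch(table$statistic,
                  ratio = Re(s1 * Conj(s2)) / Mod(s2)^2,
                  uni = Re(Conj(s1) * s2) / pw)
  } else {
    val <- switch(table$statistic, ratio = s1 / s2, uni = uni_stat(s1, s2))
  }
  mag <- sqrt(pw)
  thr <- min_signal_frac * stats::quantile(mag, 0.99, na.rm = TRUE,
                                           names = FALSE)
  nosig <- mag <= thr | !is.finite(pw)
  val[nosig] <- NA_real_
  # background voxels carry no signal; their (possibly extrapolated) B1 is
  # irrelevant and must not trigger hull warnings
  b1u <- ifelse(nosig | b1 <= 0, 1, b1)
  inv <- invert_lookup(table, val, b1u)
  inv$flag[nosig | b1 <= 0] <- .t1_flags[["no_signal"]]
  inv$T1[inv$flag == .t1_flags[["no_signal"]]] <- NA_real_
  t1 <- image_volume(array(inv$T1, d), vol1$affine, vol1$pe_axis)
  structure(list(t1 = t1, mask = array(inv$flag, d)), class = "t1_map")
}

#' Modal T1 per tissue from a T1 map
#'
#' Kernel-density mode of the in-range T1 values inside each tissue mask.
#' The bandwidth follows Silverman's rule of thumb (`stats::bw.nrd0`); with
#' (near-)constant values the common value is returned directly. The mode
#' is the density-grid maximum; exact ties are broken toward the lower T1
#' (the first grid maximum on the ascending grid).
#'
#' @param t1map A `t1_map` from [estimate_t1_map()].
#' @param masks Named list of logical arrays (one per tissue) congruent
#'   with the map.
#' @param min_voxels Minimum in-range voxels required per tissue
#'   (default 100).
#' @return Named numeric vector of modal T1 values (ms).
#' @export
histogram_peaks <- function(t1map, masks, min_voxels = 100L) {
  stopifnot(inherits(t1map, "t1_map"), is.list(masks))
  vapply(masks, function(m) {
    if (!identical(dim(m), dim(t1map$mask)))
      stop("tissue mask grid does not match the T1 map")
    x <- t1map$t1$data[m & t1map$mask == .t1_flags[["in_range"]]]
    x <- x[is.finite(x)]
    if (length(x) < min_voxels)
      stop("fewer than ", min_voxels, " in-range voxels in a tissue mask")
    if (stats::sd(x) < 1e-9) return(x[1L])
    de <- stats::density(x, bw = "nrd0")
    de$x[which.max(de$y)]
  }, numeric(1))
}
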