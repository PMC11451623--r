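#' Sequence protocol configuration
#'
#' Bundles the timing, flip-angle and sampling parameters of a two-inversion
#' segmented 3D-EPI acquisition. One inversion-recovery (IR) cycle contains an
#' adiabatic inversion pulse followed by two readout blocks, one per inversion
#' time; the whole volume acquisition is repeated `n_combo` times with all
#' combinations of reversed read and phase-encode gradient polarity.
#'
#' @param TI1,TI2 Inversion times in ms, measured from the inversion pulse to
#'   the k-space-centre excitation of readout block 1 and 2.
#' @param TR_IR Duration of one inversion-recovery cycle in ms.
#' @param alpha1,alpha2 Nominal excitation flip angles (degrees) for the two
#'   readout blocks.
#' @param seg Segmentation factor: shots (IR cycles) per volume per inversion
#'   time.
#' @param Rz CAIPI undersampling factor along kz.
#' @param pF Phase partial Fourier fraction (e.g. 6/8 = 0.75).
#' @param N Integer matrix size triple `c(Nx, Ny, Nz)` (read, phase, partition).
#' @param n_combo Number of read/phase polarity combinations acquired
#'   (default 4: both read polarities crossed with both phase polarities).
#' @param eps_inv Inversion efficiency in (0, 1]; 1 = complete inversion.
#' @param esp_eff Effective echo spacing along the phase-encode axis in ms
#'   (time between adjacent ky lines after segmentation/undersampling; with
#'   `N[2]` it sets the geometric distortion in voxels per Hz off-resonance).
#' @param TR_exc Excitation pulse spacing within a readout block in ms, or
#'   `NULL` to derive it by evenly packing both blocks into the IR cycle
#'   (see [protocol_events()]).
#'
#' @return An object of class `protocol_config` (a validated list).
#' @examples
#' p <- protocol_config()
#' p$seg
#' @export
protocol_config <- function(TI1 = 800, TI2 = 2700, TR_IR = 3800,
                            alpha1 = 16, alpha2 = 12,
                            seg = 14L, Rz = 3L, pF = 6 / 8,
                            N = c(232L, 232L, 186L),
                            n_combo = 4L, eps_inv = 1.0,
                            esp_eff = 0.07, TR_exc = NULL) {
  p <- list(TI1 = as.numeric(TI1), TI2 = as.numeric(TI2),
            TR_IR = as.numeric(TR_IR),
            alpha1 = as.numeric(alpha1), alpha2 = as.numeric(alpha2),
            seg = as.integer(seg), Rz = as.integer(Rz), pF = as.numeric(pF),
            N = as.integer(N), n_combo = as.integer(n_combo),
            eps_inv = as.numeric(eps_inv), esp_eff = as.numeric(esp_eff),
            TR_exc = if (is.null(TR_exc)) NULL else as.numeric(TR_exc))
  class(p) <- "protocol_config"
  validate_protocol(p)
  p
}

#' Validate a protocol configuration
#'
#' Checks the invariants every downstream operation relies on and stops with
#' an informative message on the first violation.
#'
#' @param p A `protocol_config`.
#' @return `p`, invisibly.
#' @export
validate_protocol <- function(p) {
  stopifnot(inherits(p, "protocol_config"))
  if (!(p$TI1 > 0 && p$TI2 > p$TI1 && p$TR_IR > p$TI2))
    stop("protocol invariant violated: need 0 < TI1 < TI2 < TR_IR (got TI1=",
         p$TI1, ", TI2=", p$TI2, ", TR_IR=", p$TR_IR, ")")
  if (p$seg < 1L) stop("segmentation factor seg must be a positive integer")
  if (p$Rz < 1L) stop("kz undersampling Rz must be a positive integer")
  if (!(p$pF > 0.5 && p$pF <= 1)) stop("partial Fourier fraction pF must lie in (0.5, 1]")
  if (!(p$eps_inv > 0 && p$eps_inv <= 1)) stop("inversion efficiency eps_inv must lie in (0, 1]")
  if (p$alpha1 < 0 || p$alpha1 > 90 || p$alpha2 < 0 || p$alpha2 > 90)
    stop("flip angles must lie in [0, 90] degrees")
  if (length(p$N) != 3L || any(p$N < 1L)) stop("matrix size N must be a positive integer triple")
  if (!(p$esp_eff > 0)) stop("effective echo spacing esp_eff must be positive")
  if (!is.null(p$TR_exc) && p$TR_exc <= 0) stop("TR_exc must be positive")
  invisible(p)
}

#' @export
print.protocol_config <- function(x, ...) {
  cat("Two-inversion 3D-EPI protocol\n")
  cat(sprintf("  TI1/TI2/TR_IR : %g / %g / %g ms\n", x$TI1, x$TI2, x$TR_IR))
  cat(sprintf("  flip angles   : %g / %g deg\n", x$alpha1, x$alpha2))
  cat(sprintf("  matrix        : %d x %d x %d, seg %d, Rz %d, pF %g\n",
              x$N[1], x$N[2], x$N[3], x$seg, x$Rz, x$pF))
  cat(sprintf("  polarity combos %d, eps_inv %g, esp_eff %g ms\n",
              x$n_combo, x$eps_inv, x$esp_eff))
  invisible(x)
}

# Number of excitations per readout block: one kz plane per pulse after
# CAIPI undersampling.
n_excitations <- function(p) as.integer(ceiling(p$N[3] / p$Rz))

# Default excitation spacing: the largest spacing (minus a 1 ms guard) that
# keeps block 1 after the inversion, block 2 after block 1, and block 2
# inside the IR cycle, with the k-space-centre pulse at the block centre.
default_TR_exc <- function(p) {
  ne <- n_excitations(p)
  ic <- ne %/% 2L                      # 0-based index of the centre pulse
  guard <- 1                           # ms
  bounds <- c(
    if (ic > 0L) (p$TI1 - guard) / ic else Inf,
    if (ne > 1L) (p$TI2 - p$TI1 - guard) / (ne - 1L) else Inf,
    if (ne - 1L - ic > 0L) (p$TR_IR - p$TI2 - guard) / (ne - 1L - ic) else Inf
  )
  tr <- min(bounds)
  if (!is.finite(tr)) tr <- min(p$TI1, p$TI2 - p$TI1, p$TR_IR - p$TI2) / 2
  if (tr <= 0) stop("cannot fit excitation blocks into the IR cycle; ",
                    "increase TI spacing or reduce the matrix size")
  tr
}

#' Event schedule of one inversion-recovery cycle
#'
#' Expands a protocol into the ordered pulse events of a single IR cycle:
#' the inversion at t = 0 followed by two blocks of equally spaced
#' excitations. The k-space-centre excitation of block *i* falls at TI*i*;
#' within a block the centre pulse is the middle one (linear kz ordering).
#'
#' @param p A `protocol_config`.
#' @return A data frame with columns `time` (ms), `event`
#'   (`"inversion"`, `"excitation"`), `block` (0 for the inversion, 1/2 for
#'   the readout blocks), and `center` (logical, the k-space-centre pulse).
#' @export
protocol_events <- function(p) {
  validate_protocol(p)
  ne <- n_excitations(p)
  tr_exc <- if (is.null(p$TR_exc)) default_TR_exc(p) else p$TR_exc
  ic <- ne %/% 2L
  offs <- (seq_len(ne) - 1L - ic) * tr_exc
  t1 <- p$TI1 + offs
  t2 <- p$TI2 + offs
  ev <- data.frame(
    time = c(0, t1, t2),
    event = c("inversion", rep("excitation", 2L * ne)),
    block = c(0L, rep(1L, ne), rep(2L, ne)),
    center = c(FALSE, seq_len(ne) == ic + 1L, seq_len(ne) == ic + 1L)
  )
  if (any(ev$time[-1] <= 0) || any(diff(ev$time) <= 0) ||
      max(ev$time) >= p$TR_IR)
    stop("excitation blocks do not fit inside the IR cycle; ",
         "adjust TR_exc, TIs or TR_IR")
  attr(ev, "TR_exc") <- tr_exc
  ev
}

#' Timing report for a protocol
#'
#' Accounts for the loop structure: `seg` IR cycles per volume per polarity
#' combination, `ceiling(Nz/Rz)` excitations per readout block, and
#' `ceiling(Ny * pF / seg)` echoes per excitation. The echo time is the time
#' from the echo-train start to the ky = 0 echo; with partial Fourier the
#' ky = 0 line sits `(pF - 1/2) * Ny` acquired lines into the asymmetric
#' coverage, i.e. `ceiling((pF - 1/2) * Ny / seg)` echoes into each train.
#' All formulas are recorded in the returned object so that any deviation
#' from a vendor's echo-train accounting is visible rather than hidden.
#'
#' @param p A `protocol_config`.
#' @return An object of class `timing_report`: a list with `TA` (total
#'   acquisition time, s), `n_IR_cycles` (per polarity combination), `n_exc`
#'   (excitations per readout block), `ETL` (echoes per excitation),
#'   `TE` (ms), `esp_readout` (echo spacing within one train, ms) and a
#'   `formulas` character vector.
#' @examples
#' compute_timing(protocol_config())
#' @export
compute_timing <- function(p) {
  validate_protocol(p)
  n_ir <- p$seg
  ta <- p$n_combo * n_ir * p$TR_IR / 1000
  ne <- n_excitations(p)
  etl <- as.integer(ceiling(p$N[2] * p$pF / p$seg))
  # within one interleaved train, adjacent echoes are seg ky-lines apart,
  # so the per-train echo spacing is seg * esp_eff
  esp_train <- p$seg * p$esp_eff
  n_to_center <- as.integer(ceiling((p$pF - 0.5) * p$N[2] / p$seg))
  te <- n_to_center * esp_train
  rep_ <- list(
    TA = ta, n_IR_cycles = n_ir, n_exc = ne, ETL = etl, TE = te,
    esp_readout = esp_train, n_combo = p$n_combo, TR_IR = p$TR_IR,
    formulas = c(
      TA = sprintf("TA = n_combo * seg * TR_IR = %d * %d * %g ms = %g s",
                   p$n_combo, p$seg, p$TR_IR, ta),
      n_exc = sprintf("n_exc = ceil(Nz / Rz) = ceil(%d / %d) = %d",
                      p$N[3], p$Rz, ne),
      ETL = sprintf("ETL = ceil(Ny * pF / seg) = ceil(%d * %g / %d) = %d",
                    p$N[2], p$pF, p$seg, etl),
      TE = sprintf("TE = ceil((pF - 1/2) * Ny / seg) * seg * esp_eff = %d * %g ms = %g ms",
                   n_to_center, esp_train, te)
    )
  )
  class(rep_) <- "timing_report"
  rep_
}

#' @export
print.timing_report <- function(x, ...) {
  cat("Acquisition timing report\n")
  cat(sprintf("  total acquisition time : %.1f s (%.0f:%05.2f min)\n",
              x$TA, x$TA %/% 60, x$TA %% 60))
  cat(sprintf("  IR cycles per polarity combination : %d\n", x$n_IR_cycles))
  cat(sprintf("  excitations per readout block      : %d\n", x$n_exc))
  cat(sprintf("  echo train length                  : %d\n", x$ETL))
  cat(sprintf("  echo time                          : %.2f ms\n", x$TE))
  cat("  formulas:\n")
  for (f in x$formulas) cat("    ", f, "\n", sep = "")
  invisible(x)
}

#' Export a timing report as a data frame (CSV-ready)
#'
#' @param x A `timing_report`.
#' @param ... Unused.
#' @return A two-column data frame of quantities and values.
#' @export
as.data.frame.timing_report <- function(x, ...) {
  data.frame(quantity = c("TA_s", "n_IR_cycles", "n_exc", "ETL", "TE_ms",
                          "esp_readout_ms"),
             value = c(x$TA, x$n_IR_cycles, x$n_exc, x$ETL, x$TE,
                       x$esp_readout))
}

#' Tissue relaxation parameters
#'
#' @param name Tissue label.
#' @param T1 Longitudinal relaxation time in ms (> 0).
#' @param M0 Equilibrium magnetisation / proton density, arbitrary units (> 0).
#' @return A `tissue_params` list.
#' @examples
#' tissue_params("GM", 1800, 0.8)
#' @export
tissue_params <- function(name, T1, M0 = 1) {
  if (T1 <= 0) stop("T1 must be positive")
  if (M0 <= 0) stop("M0 must be positive")
  structure(list(name = name, T1 = as.numeric(T1), M0 = as.numeric(M0)),
            class = "tissue_params")
}

#' Default simulation tissue parameters at 7T
#'
#' Nominal values used by the phantom generator and design examples; they
#' are simulation defaults, not measured reference values.
#'
#' @return Named list of `tissue_params` for CSF, GM and WM.
#' @export
default_tissues <- function() {
  list(CSF = tissue_params("CSF", 4000, 1.0),
       GM  = tissue_params("GM", 1800, 0.80),
       WM  = tissue_params("WM", 1200, 0.65))
}
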