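# Minimal logging used across the package. Levels: debug < info < warn.
.log_levels <- c(debug = 1L, info = 2L, warn = 3L)
.t1epi_env <- new.env(parent = emptyenv())
.t1epi_env$log_level <- "info"

#' Set the package log level
#' @param level One of `"debug"`, `"info"`, `"warn"`.
#' @return The previous level, invisibly.
#' @export
set_log_level <- function(level = c("info", "debug", "warn")) {
  level <- match.arg(level)
  old <- .t1epi_env$log_level
  .t1epi_env$log_level <- level
  invisible(old)
}

t1epi_log <- function(level, ...) {
  if (.log_levels[[level]] >= .log_levels[[.t1epi_env$log_level]])
    message("[", level, "] ", ...)
  invisible(NULL)
}

#' Image volume container
#'
#' A 3D or 4D array (real or complex) together with its voxel-to-world
#' affine (mm) and the identified phase-encode axis. Arrays are ordered
#' (x, y, z[, t]); the phase-encode axis is y (axis 2) by default, matching
#' in-plane phase-encode reversal.
#'
#' @param data 3D or 4D numeric or complex array.
#' @param affine 4x4 voxel-to-world transform (mm); must be invertible.
#' @param pe_axis Phase-encode axis index in 1..3.
#' @return An object of class `image_volume`.
#' @examples
#' v <- image_volume(array(0, c(8, 8, 8)))
#' dim(v$data)
#' @export
image_volume <- function(data, affine = diag(4), pe_axis = 2L) {
  if (!(length(dim(data)) %in% c(3L, 4L)))
    stop("image data must be a 3D or 4D array (got ",
         length(dim(data)), " dimensions)")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be a 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps)
    stop("affine must be invertible")
  pe_axis <- as.integer(pe_axis)
  if (!(pe_axis %in% 1:3)) stop("pe_axis must be 1, 2 or 3")
  structure(list(data = data, affine = affine, pe_axis = pe_axis),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("image_volume: ", paste(dim(x$data), collapse = " x "),
      if (is.complex(x$data)) " (complex)" else "",
      ", PE axis ", x$pe_axis, "\n", sep = "")
  invisible(x)
}

# path handling: stem strips .nii / .nii.gz
nifti_stem <- function(path) sub("\\.nii(\\.gz)?$", "", path)

sidecar_path <- function(path) paste0(nifti_stem(path), ".json")

#' Read a NIfTI volume (real or complex pair)
#'
#' Reads a NIfTI-1/2 file into an [image_volume()]. If a JSON sidecar
#' written by [save_nifti()] is present it restores the phase-encode axis
#' annotation and, for complex volumes, reconstructs complex data from the
#' `<stem>_real.nii.gz` / `<stem>_imag.nii.gz` pair (the path may name the
#' stem, the sidecar, or the real part).
#'
#' @param path Path to a NIfTI file, or the stem of a complex pair.
#' @param pe_axis Phase-encode axis to assume when no sidecar is present.
#' @return An [image_volume()].
#' @export
load_nifti <- function(path, pe_axis = 2L) {
  stem <- nifti_stem(sub("\\.json$", "", path))
  sc <- paste0(stem, ".json")
  meta <- if (file.exists(sc)) jsonlite::read_json(sc) else NULL
  if (!is.null(meta) && isTRUE(meta$complex)) {
    fre <- find_nifti(paste0(stem, "_real"))
    fim <- find_nifti(paste0(stem, "_imag"))
    re <- read_nifti_array(fre)
    im <- read_nifti_array(fim)
    if (!identical(dim(re$data), dim(im$data)))
      stop("real and imaginary parts have mismatched dimensions")
    return(image_volume(re$data + 1i * im$data, re$affine,
                        pe_axis = meta$pe_axis %||% pe_axis))
  }
  f <- if (file.exists(path) && !grepl("\\.json$", path)) path
       else find_nifti(stem)
  v <- read_nifti_array(f)
  image_volume(v$data, v$affine,
               pe_axis = if (!is.null(meta)) meta$pe_axis %||% pe_axis
                         else pe_axis)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

find_nifti <- function(stem) {
  for (ext in c(".nii.gz", ".nii")) {
    f <- paste0(stem, ext)
    if (file.exists(f)) return(f)
  }
  stop("NIfTI file not found: ", stem, "[.nii|.nii.gz]")
}

read_nifti_array <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  if (nd > 4L) stop("volumes with more than 4 dimensions are not supported")
  if (nd < 3L) stop("expected a 3D or 4D volume, got ", nd, " dimensions")
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  a <- array(as.numeric(img), dim = dim(img))
  list(data = a, affine = matrix(aff[1:4, 1:4], 4, 4))
}

#' Write an image volume to NIfTI
#'
#' Real volumes are written as a single file plus a JSON sidecar carrying
#' the phase-encode axis. Complex volumes are written as a portable
#' real/imaginary NIfTI pair (`<stem>_real`, `<stem>_imag`) with the
#' sidecar noting the pairing; [load_nifti()] reassembles them.
#'
#' @param vol An [image_volume()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return The main output path (the sidecar for complex pairs), invisibly.
#' @export
save_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  if (!all(is.finite(Mod(vol$data))))
    stop("refusing to write non-finite voxel values")
  stem <- nifti_stem(path)
  ext <- if (grepl("\\.nii$", path)) ".nii" else ".nii.gz"
  meta <- list(pe_axis = vol$pe_axis, complex = is.complex(vol$data))
  if (is.complex(vol$data)) {
    write_nifti_array(Re(vol$data), vol$affine, paste0(stem, "_real", ext))
    write_nifti_array(Im(vol$data), vol$affine, paste0(stem, "_imag", ext))
  } else {
    write_nifti_array(vol$data, vol$affine, paste0(stem, ext))
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

write_nifti_array <- function(a, affine, path) {
  img <- RNifti::asNifti(a, datatype = "double")
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# run configuration

.config_keys <- list(
  # protocol (required unless a default is listed)
  ti1 = "numeric", ti2 = "numeric", tr_ir = "numeric",
  alpha1 = "numeric", alpha2 = "numeric",
  seg = "integer", rz = "integer", pf = "numeric",
  nx = "integer", ny = "integer", nz = "integer",
  n_combo = "integer", eps_inv = "numeric", esp_eff = "numeric",
  tr_exc = "numeric",
  # run
  seed = "integer", out_dir = "character", log_level = "character",
  pe_axis = "integer"
)

.config_required <- c("ti1", "ti2", "tr_ir", "alpha1", "alpha2",
                      "seg", "rz", "pf", "nx", "ny", "nz")

.config_defaults <- list(n_combo = 4L, eps_inv = 1.0, esp_eff = 0.07,
                         tr_exc = NA_real_, seed = 1L, out_dir = ".",
                         log_level = "info", pe_axis = 2L)

#' Read a run configuration file
#'
#' Parses a plain-text `key = value` file (one pair per line, `#` comments)
#' into a validated run configuration holding a [protocol_config()], the
#' random seed, output directory and log level. Unknown keys are an error;
#' fields with open defaults (polarity combinations, inversion efficiency,
#' effective echo spacing, excitation spacing, seed, output settings) fall
#' back to documented defaults and each fallback is flagged in the log.
#'
#' @param path Path to the configuration file. The package ships a default
#'   protocol at `system.file("extdata", "default_protocol.cfg",
#'   package = "t1epi")`.
#' @return An object of class `run_config`: a list with elements
#'   `protocol`, `seed`, `out_dir`, `log_level`, `pe_axis`.
#' @examples
#' cfg <- load_config(system.file("extdata", "default_protocol.cfg",
#'                                package = "t1epi"))
#' cfg$protocol$seg
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    stop("empty config file; required keys: ",
         paste(.config_required, collapse = ", "))
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, 1L) != 3L]
  if (length(bad) > 0L)
    stop("malformed config line(s): ", paste(bad, collapse = "; "))
  keys <- tolower(vapply(kv, `[`, "", 2L))
  vals <- vapply(kv, `[`, "", 3L)
  unknown <- setdiff(keys, names(.config_keys))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(keys))
    stop("duplicated config key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  missing <- setdiff(.config_required, keys)
  if (length(missing) > 0L)
    stop("missing required config key(s): ", paste(missing, collapse = ", "))
  cfg <- stats::setNames(as.list(vals), keys)
  for (k in names(cfg)) {
    cfg[[k]] <- switch(.config_keys[[k]],
                       numeric = as.numeric(cfg[[k]]),
                       integer = as.integer(cfg[[k]]),
                       character = cfg[[k]])
    if (.config_keys[[k]] != "character" && is.na(cfg[[k]]))
      stop("could not parse value for config key '", k, "'")
  }
  for (k in setdiff(names(.config_defaults), keys)) {
    cfg[[k]] <- .config_defaults[[k]]
    t1epi_log("info", "config key '", k, "' not given; using default ",
              format(cfg[[k]]))
  }
  proto <- protocol_config(
    TI1 = cfg$ti1, TI2 = cfg$ti2, TR_IR = cfg$tr_ir,
    alpha1 = cfg$alpha1, alpha2 = cfg$alpha2,
    seg = cfg$seg, Rz = cfg$rz, pF = cfg$pf,
    N = c(cfg$nx, cfg$ny, cfg$nz),
    n_combo = cfg$n_combo, eps_inv = cfg$eps_inv, esp_eff = cfg$esp_eff,
    TR_exc = if (is.na(cfg$tr_exc)) NULL else cfg$tr_exc)
  if (!cfg$log_level %in% names(.log_levels))
    stop("log_level must be one of: ", paste(names(.log_levels), collapse = ", "))
  structure(list(protocol = proto, seed = cfg$seed, out_dir = cfg$out_dir,
                 log_level = cfg$log_level, pe_axis = cfg$pe_axis),
            class = "run_config")
}
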