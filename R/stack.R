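#' Calibrated fluorescence image stack
#'
#' A `calibrated_stack` carries the voxel intensities of one confocal channel
#' together with its physical in-plane calibration and the biological role the
#' channel plays in the analysis (which antibody/dye it represents). All
#' downstream area measurements are derived from `pixel_size_um`, never from
#' file metadata.
#'
#' Voxels are stored as a `ny x nx x nz` array (a plain matrix is accepted and
#' treated as a single-plane stack). Intensities must be finite and
#' non-negative.
#'
#' @param voxels Numeric matrix (`ny x nx`) or 3-D array (`ny x nx x nz`) of
#'   non-negative intensities.
#' @param pixel_size_um Physical edge length of one pixel in micrometres
#'   (isotropic in-plane), `> 0`.
#' @param channel_role One of `"plaque_6e10"`, `"plaque_mex04"`,
#'   `"microglia"`, `"lamp1"`, `"cd68"`, `"tau_total"`, `"tau_phospho"`.
#' @return An object of class `calibrated_stack` with fields `voxels`
#'   (always a 3-D array), `pixel_size_um` and `channel_role`.
#' @examples
#' st <- calibrated_stack(matrix(runif(64), 8, 8), 0.62, "microglia")
#' dim(st$voxels)
#' @export
calibrated_stack <- function(voxels, pixel_size_um, channel_role) {
  channel_role <- match.arg(channel_role, channel_roles())
  if (is.matrix(voxels)) {
    voxels <- array(voxels, dim = c(dim(voxels), 1L))
  }
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a matrix or a 3-D array (y, x, z)")
  }
  if (any(dim(voxels) < 1L)) stop("all stack extents must be >= 1")
  storage.mode(voxels) <- "double"
  if (anyNA(voxels) || any(!is.finite(voxels))) {
    stop("stack intensities must be finite")
  }
  if (any(voxels < 0)) stop("stack intensities must be non-negative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be a single positive number")
  }
  structure(
    list(voxels = voxels, pixel_size_um = as.numeric(pixel_size_um),
         channel_role = channel_role),
    class = "calibrated_stack"
  )
}

#' Channel roles understood by the pipeline
#' @return Character vector of valid `channel_role` values.
#' @export
channel_roles <- function() {
  c("plaque_6e10", "plaque_mex04", "microglia", "lamp1", "cd68",
    "tau_total", "tau_phospho")
}

#' @export
print.calibrated_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<calibrated_stack> role=%s  %d x %d px, %d plane(s), %.4g um/px\n",
    x$channel_role, d[1], d[2], d[3], x$pixel_size_um))
  invisible(x)
}

#' @export
dim.calibrated_stack <- function(x) dim(x$voxels)

n_planes <- function(stack) dim(stack$voxels)[3]

#' Binary mask with physical calibration
#'
#' Thresholded foreground of an image or stack. `bits` must be logical and
#' keeps the exact shape of its source (2-D for projections, 3-D per-plane
#' for stacks).
#'
#' @param bits Logical matrix or 3-D array.
#' @param pixel_size_um Inherited pixel calibration in micrometres.
#' @return Object of class `binary_mask`.
#' @export
binary_mask <- function(bits, pixel_size_um) {
  if (!is.logical(bits)) stop("`bits` must be logical")
  if (!(is.matrix(bits) || (is.array(bits) && length(dim(bits)) == 3L))) {
    stop("`bits` must be a matrix or a 3-D array")
  }
  if (anyNA(bits)) stop("mask bits must not contain NA")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be positive")
  }
  structure(list(bits = bits, pixel_size_um = as.numeric(pixel_size_um)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$bits)
  cat(sprintf("<binary_mask> %s px, %d foreground, %.4g um/px\n",
              paste(d, collapse = " x "), sum(x$bits), x$pixel_size_um))
  invisible(x)
}

#' Maximum z-projection
#'
#' Collapses a stack to a 2-D image by taking, at every (y, x) position, the
#' maximum intensity across planes. This is the projection used for plaque
#' and Tau area-fraction measurements.
#'
#' @param stack A [calibrated_stack()].
#' @return Numeric matrix with attribute `pixel_size_um`.
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "calibrated_stack"))
  v <- stack$voxels
  d <- dim(v)
  out <- matrix(v[, , 1L], d[1], d[2])
  if (d[3] > 1L) for (z in 2:d[3]) {
    out <- pmax(out, matrix(v[, , z], d[1], d[2]))
  }
  attr(out, "pixel_size_um") <- stack$pixel_size_um
  out
}

#' Sum z-projection
#'
#' Collapses a stack by summing intensities across planes (used for the
#' background-subtracted homeostatic-marker intensity readout). Accumulation
#' is in double precision, so integer-valued inputs cannot overflow.
#'
#' @inheritParams max_project
#' @return Numeric matrix with attribute `pixel_size_um`.
#' @export
sum_project <- function(stack) {
  stopifnot(inherits(stack, "calibrated_stack"))
  v <- stack$voxels
  d <- dim(v)
  out <- matrix(v[, , 1L], d[1], d[2])
  if (d[3] > 1L) for (z in 2:d[3]) {
    out <- out + matrix(v[, , z], d[1], d[2])
  }
  attr(out, "pixel_size_um") <- stack$pixel_size_um
  out
}
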