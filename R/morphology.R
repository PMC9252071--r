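#' Morphological dilation by a physical radius
#'
#' Dilates a binary mask with a Euclidean disc of radius `radius_um`: an
#' output pixel is foreground iff the in-plane distance from its centre to
#' the nearest input foreground pixel centre is at most `radius_um`. This is
#' the operation used to grow plaque masks by 25 um (neuritic-damage halo)
#' and 5 um (plaque-associated microglia halo). For 3-D masks the dilation
#' is applied independently per z-plane; z-spacing never enters. The input
#' is always a subset of the output, and the result is monotone in
#' `radius_um`.
#'
#' @param mask A [binary_mask()] (2-D or 3-D).
#' @param radius_um Dilation radius in micrometres, `>= 0`. Radius 0 (or any
#'   radius smaller than one pixel) returns the mask unchanged.
#' @return A [binary_mask()] of the same shape.
#' @export
dilate_physical <- function(mask, radius_um) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!is.numeric(radius_um) || length(radius_um) != 1L || radius_um < 0) {
    stop("`radius_um` must be a single non-negative number")
  }
  r_px <- radius_um / mask$pixel_size_um
  kern <- disc_kernel(r_px)
  if (is.null(kern) || !any(mask$bits)) return(mask)
  bits <- mask$bits
  if (is.matrix(bits)) {
    out <- dilate_plane(bits, kern)
  } else {
    out <- bits
    for (z in seq_len(dim(bits)[3])) {
      out[, , z] <- dilate_plane(bits[, , z], kern)
    }
  }
  binary_mask(out, mask$pixel_size_um)
}

# Euclidean disc structuring element: offsets with dx^2 + dy^2 <= r^2
# (small tolerance so exact lattice radii are included). NULL when the disc
# contains only the origin.
disc_kernel <- function(r_px) {
  r <- floor(r_px + 1e-9)
  if (r < 1) return(NULL)
  off <- -r:r
  k <- outer(off^2, off^2, "+") <= r_px^2 + 1e-9
  storage.mode(k) <- "double"
  k
}

dilate_plane <- function(bits, kern) {
  out <- EBImage::dilate(matrix(as.numeric(bits), nrow(bits)), kern)
  matrix(as.vector(out) > 0.5, nrow(bits))
}

#' Pixelwise mask algebra
#'
#' Combines two masks of identical shape and calibration: `"and"` gives the
#' colocalized foreground (the binary equivalent of multiplying binarized
#' channels), `"subtract"` removes the second mask's foreground from the
#' first (e.g., non-microglial LAMP1 = LAMP1 subtract microglia).
#'
#' @param a,b [binary_mask()] objects with identical shape and
#'   `pixel_size_um`.
#' @param op `"and"` or `"subtract"`.
#' @return A [binary_mask()].
#' @export
mask_algebra <- function(a, b, op = c("and", "subtract")) {
  op <- match.arg(op)
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  if (!identical(dim(a$bits), dim(b$bits))) {
    stop("mask shapes differ")
  }
  if (a$pixel_size_um != b$pixel_size_um) stop("mask calibrations differ")
  bits <- if (op == "and") a$bits & b$bits else a$bits & !b$bits
  binary_mask(bits, a$pixel_size_um)
}
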