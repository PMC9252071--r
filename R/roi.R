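#' Anatomical region of interest
#'
#' A 2-D polygon, in pixel coordinates, restricting every metric to an
#' anatomical region (subiculum, CA1, ...). Vertices are `(y, x)` pairs in
#' the same coordinate system as pixel centres (pixel `[r, c]` has centre
#' `(y = r, x = c)`). The polygon must be simple (non-self-intersecting)
#' and have at least three vertices.
#'
#' @param polygon Numeric matrix with two columns `(y, x)` (or an object
#'   coercible to one), ordered vertices.
#' @param name Anatomical label, e.g. `"subiculum"`.
#' @return Object of class `roi`.
#' @export
roi <- function(polygon, name = "roi") {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 3L) {
    stop("`polygon` must be an n x 2 (y, x) matrix with n >= 3")
  }
  if (anyNA(polygon) || any(!is.finite(polygon))) {
    stop("polygon vertices must be finite")
  }
  storage.mode(polygon) <- "double"
  colnames(polygon) <- c("y", "x")
  if (!polygon_is_simple(polygon)) {
    stop("polygon is self-intersecting; the ROI must be a simple polygon")
  }
  structure(list(polygon = polygon, name = as.character(name)),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> '%s', %d vertices\n", x$name, nrow(x$polygon)))
  invisible(x)
}

# O(n^2) proper-intersection test between non-adjacent edges; adequate for
# hand-drawn anatomical outlines (tens of vertices).
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  seg <- cbind(poly, poly[c(2:n, 1L), ])
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]  # edge n is adjacent to edge 1
    for (j in js) {
      if (segments_cross(seg[i, ], seg[j, ])) return(FALSE)
    }
  }
  TRUE
}

segments_cross <- function(s1, s2) {
  d <- function(ay, ax, by, bx, cy, cx) {
    (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  }
  d1 <- d(s1[1], s1[2], s1[3], s1[4], s2[1], s2[2])
  d2 <- d(s1[1], s1[2], s1[3], s1[4], s2[3], s2[4])
  d3 <- d(s2[1], s2[2], s2[3], s2[4], s1[1], s1[2])
  d4 <- d(s2[1], s2[2], s2[3], s2[4], s1[3], s1[4])
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Rasterize an ROI to a pixel mask
#'
#' Pixel-centre membership under the even-odd rule; pixel centres lying
#' exactly on a polygon edge count as inside. This fixed convention makes
#' ROI areas (the denominators of every area-fraction metric)
#' deterministic and testable.
#'
#' @param region An [roi()].
#' @param dim Integer vector `c(ny, nx)` of the target image.
#' @return Logical `ny x nx` matrix.
#' @export
roi_pixel_mask <- function(region, dim) {
  stopifnot(inherits(region, "roi"))
  ny <- dim[1]; nx <- dim[2]
  poly <- region$polygon
  ys <- rep(seq_len(ny), times = nx)
  xs <- rep(seq_len(nx), each = ny)
  matrix(points_in_polygon(ys, xs, poly), ny, nx)
}

points_in_polygon <- function(py, px, poly) {
  n <- nrow(poly)
  span <- max(max(poly[, 1]) - min(poly[, 1]),
              max(poly[, 2]) - min(poly[, 2]), 1)
  eps <- 1e-9 * span
  inside <- rep(FALSE, length(py))
  onedge <- rep(FALSE, length(py))
  j <- n
  for (i in seq_len(n)) {
    y1 <- poly[j, 1]; x1 <- poly[j, 2]
    y2 <- poly[i, 1]; x2 <- poly[i, 2]
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    within <- px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    onedge <- onedge | (abs(cross) <= eps * span & within)
    crosses <- (y1 > py) != (y2 > py)
    if (any(crosses)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & px < xint)
    }
    j <- i
  }
  inside | onedge
}

#' Restrict an image, stack or mask to an ROI
#'
#' Pixels outside the polygon are set to 0 (intensities) or `FALSE`
#' (masks). The ROI's pixel area is attached as attribute `roi_px` for use
#' as the denominator of area fractions; a polygon whose interior contains
#' no pixel centres yields an empty result with attribute `roi_empty =
#' TRUE`. The ROI must lie within the image bounds.
#'
#' @param x A [calibrated_stack()], [binary_mask()], or numeric matrix.
#' @param region An [roi()].
#' @return Same type as `x`, with attributes `roi_px` and `roi_empty`.
#' @export
restrict_to_roi <- function(x, region) {
  stopifnot(inherits(region, "roi"))
  d <- if (inherits(x, "calibrated_stack")) dim(x$voxels)
       else if (inherits(x, "binary_mask")) dim(x$bits)
       else dim(x)
  if (is.null(d)) stop("`x` must be a matrix, stack or mask")
  poly <- region$polygon
  if (any(poly[, 1] < 0.5) || any(poly[, 1] > d[1] + 0.5) ||
      any(poly[, 2] < 0.5) || any(poly[, 2] > d[2] + 0.5)) {
    stop(sprintf("ROI '%s' extends outside the %d x %d image",
                 region$name, d[1], d[2]))
  }
  m <- roi_pixel_mask(region, d[1:2])
  roi_px <- sum(m)
  apply_plane <- function(plane, zero) {
    plane[!m] <- zero
    plane
  }
  if (inherits(x, "calibrated_stack")) {
    v <- x$voxels
    for (z in seq_len(dim(v)[3])) v[, , z] <- apply_plane(v[, , z], 0)
    out <- calibrated_stack(v, x$pixel_size_um, x$channel_role)
  } else if (inherits(x, "binary_mask")) {
    b <- x$bits
    if (is.matrix(b)) {
      b <- apply_plane(b, FALSE)
    } else {
      for (z in seq_len(dim(b)[3])) b[, , z] <- apply_plane(b[, , z], FALSE)
    }
    out <- binary_mask(b, x$pixel_size_um)
  } else {
    out <- apply_plane(x, 0)
  }
  attr(out, "roi_px") <- roi_px
  attr(out, "roi_empty") <- roi_px == 0L
  out
}

#' Rectangular ROI helper
#'
#' Axis-aligned rectangle covering pixel centres `y1..y2` x `x1..x2`
#' (inclusive). Convenient for whole-image regions and tests.
#'
#' @param y1,y2,x1,x2 Pixel bounds (inclusive).
#' @param name Region name.
#' @return An [roi()].
#' @export
rect_roi <- function(y1, y2, x1, x2, name = "rect") {
  roi(rbind(c(y1 - 0.49, x1 - 0.49), c(y1 - 0.49, x2 + 0.49),
            c(y2 + 0.49, x2 + 0.49), c(y2 + 0.49, x1 - 0.49)),
      name = name)
}
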