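#' Plaque analysis parameters
#'
#' The three fixed physical constants of the plaque readouts: the particle
#' size cut-off (50 um^2), the neuritic-damage halo (25 um dilation of
#' detected plaques) and the plaque-association halo for microglia (5 um).
#'
#' @param min_plaque_area_um2 Particle-analysis size cut-off in um^2.
#' @param neurite_halo_um Plaque dilation radius for the LAMP1 ratio, um.
#' @param microglia_assoc_halo_um Plaque dilation radius for the
#'   plaque-associated microglia fraction, um.
#' @return Object of class `plaque_params`.
#' @export
plaque_params <- function(min_plaque_area_um2 = 50,
                          neurite_halo_um = 25,
                          microglia_assoc_halo_um = 5) {
  stopifnot(min_plaque_area_um2 > 0, neurite_halo_um > 0,
            microglia_assoc_halo_um > 0)
  structure(list(min_plaque_area_um2 = min_plaque_area_um2,
                 neurite_halo_um = neurite_halo_um,
                 microglia_assoc_halo_um = microglia_assoc_halo_um),
            class = "plaque_params")
}

# ---- internal helpers -----------------------------------------------------

# Pool ROI pixels of all planes, build the 256-bin histogram, threshold.
roi_stack_threshold <- function(stack, roi_mask, method) {
  v <- stack$voxels
  px <- v[rep(roi_mask, dim(v)[3])]
  auto_threshold(px, method = method)
}

# Per-plane binarization of a stack against one threshold, ROI-restricted.
roi_stack_mask <- function(stack, roi_mask, thr) {
  v <- stack$voxels
  bits <- v > thr$threshold
  bits <- bits & array(roi_mask, dim = dim(v))
  binary_mask(bits, stack$pixel_size_um)
}

check_same_geometry <- function(...) {
  stacks <- list(...)
  d1 <- dim(stacks[[1]]$voxels)
  p1 <- stacks[[1]]$pixel_size_um
  for (s in stacks[-1]) {
    if (!identical(dim(s$voxels), d1)) stop("stack shapes differ")
    if (s$pixel_size_um != p1) stop("stack calibrations differ")
  }
  invisible(TRUE)
}

metric_result <- function(values, flag = "") {
  c(values, list(flag = flag))
}

# ---- plaque burden --------------------------------------------------------

#' Plaque burden: area fraction, count and mean size
#'
#' Maximum z-projection of the amyloid channel, automatic Otsu threshold
#' computed from the ROI's 256-bin histogram, binarization, and ROI
#' restriction. The area fraction is the number of suprathreshold pixels
#' over all ROI pixels (all suprathreshold pixels count, not only retained
#' particles); plaque count and mean size come from 8-connected particle
#' analysis with the physical size cut-off.
#'
#' @param plaque_stack [calibrated_stack()] with a plaque channel role.
#' @param region [roi()] to restrict the analysis to.
#' @param params [plaque_params()].
#' @return List with `area_fraction`, `count`, `mean_size_um2` and `flag`
#'   (`""` when clean, otherwise the degeneracy reason; degenerate
#'   thresholds report all three values as 0).
#' @export
plaque_burden <- function(plaque_stack, region, params = plaque_params()) {
  stopifnot(inherits(plaque_stack, "calibrated_stack"))
  proj <- max_project(plaque_stack)
  m <- roi_pixel_mask(region, dim(proj))
  roi_px <- sum(m)
  if (roi_px == 0L) {
    return(metric_result(list(area_fraction = 0, count = 0L,
                              mean_size_um2 = 0), "empty_roi"))
  }
  thr <- auto_threshold(proj[m], "otsu")
  if (thr$degenerate) {
    return(metric_result(list(area_fraction = 0, count = 0L,
                              mean_size_um2 = 0), "degenerate_threshold"))
  }
  fg <- (proj > thr$threshold) & m
  lab <- label_particles(binary_mask(fg, plaque_stack$pixel_size_um),
                         params$min_plaque_area_um2)
  mean_size <- if (lab$n > 0L) mean(lab$areas_um2) else 0
  flag <- if (lab$n == 0L) "no_particles" else ""
  metric_result(list(area_fraction = sum(fg) / roi_px,
                     count = lab$n, mean_size_um2 = mean_size), flag)
}

# ---- MeX04 / 6E10 ---------------------------------------------------------

#' Dense-core amyloid area and MeX04/6E10 ratio
#'
#' The MeX04 channel is thresholded with the Kapur maximum-entropy
#' algorithm, the 6E10 channel with Otsu; both are maximum-projected and
#' ROI-restricted. Returns the MeX04 area fraction and the ratio of MeX04
#' to 6E10 suprathreshold pixel counts.
#'
#' @param mex04_stack,e6e10_stack [calibrated_stack()]s sharing shape and
#'   calibration.
#' @param region [roi()].
#' @return List with `mex04_area_fraction`, `ratio` (NA with a flag when
#'   the 6E10 foreground is empty) and `flag`.
#' @export
mex04_ratio <- function(mex04_stack, e6e10_stack, region) {
  check_same_geometry(mex04_stack, e6e10_stack)
  pm <- max_project(mex04_stack)
  pe <- max_project(e6e10_stack)
  m <- roi_pixel_mask(region, dim(pm))
  roi_px <- sum(m)
  if (roi_px == 0L) {
    return(metric_result(list(mex04_area_fraction = 0, ratio = NA_real_),
                         "empty_roi"))
  }
  thr_m <- auto_threshold(pm[m], "maxentropy")
  thr_e <- auto_threshold(pe[m], "otsu")
  flag <- ""
  mex_fg <- if (thr_m$degenerate) 0L else sum(pm > thr_m$threshold & m)
  if (thr_m$degenerate) flag <- "degenerate_mex04_threshold"
  e_fg <- if (thr_e$degenerate) 0L else sum(pe > thr_e$threshold & m)
  ratio <- if (e_fg == 0L) NA_real_ else mex_fg / e_fg
  if (e_fg == 0L) flag <- paste0(flag, if (nzchar(flag)) ";",
                                 "zero_6e10_foreground")
  metric_result(list(mex04_area_fraction = mex_fg / roi_px, ratio = ratio),
                flag)
}

# ---- LAMP1 neuritic damage ------------------------------------------------

#' Plaque-associated neuritic damage (LAMP1/plaque ratio)
#'
#' Implements, plane by plane, the dystrophic-neurite readout: the plaque
#' stack is thresholded and binarized per z-plane (one Otsu threshold from
#' the pooled ROI histogram), particles below the size cut-off are removed,
#' and the retained plaques are dilated by the 25-um halo. LAMP1 and
#' microglia stacks are thresholded the same way; microglial LAMP1 is
#' subtracted (LAMP1 AND NOT microglia) and the remainder intersected with
#' the dilated plaque halo. The ratio is the summed colocalized pixel count
#' over the summed non-dilated plaque pixel count.
#'
#' @param plaque_stack,lamp1_stack,microglia_stack [calibrated_stack()]s
#'   sharing shape and calibration.
#' @param region [roi()].
#' @param params [plaque_params()].
#' @param denominator `"particles"` (default) divides by the size-filtered
#'   plaque pixels (the pixels that were dilated); `"all_thresholded"`
#'   divides by all suprathreshold plaque pixels.
#' @return List with `ratio` (NA with a flag when no plaque pixels) and
#'   `flag`.
#' @export
neuritic_damage_ratio <- function(plaque_stack, lamp1_stack,
                                  microglia_stack, region,
                                  params = plaque_params(),
                                  denominator = c("particles",
                                                  "all_thresholded")) {
  denominator <- match.arg(denominator)
  check_same_geometry(plaque_stack, lamp1_stack, microglia_stack)
  d <- dim(plaque_stack$voxels)
  m <- roi_pixel_mask(region, d[1:2])
  if (sum(m) == 0L) {
    return(metric_result(list(ratio = NA_real_), "empty_roi"))
  }
  thr_p <- roi_stack_threshold(plaque_stack, m, "otsu")
  thr_l <- roi_stack_threshold(lamp1_stack, m, "otsu")
  thr_g <- roi_stack_threshold(microglia_stack, m, "otsu")
  if (thr_p$degenerate) {
    return(metric_result(list(ratio = NA_real_), "degenerate_threshold"))
  }
  px <- plaque_stack$pixel_size_um
  num <- 0; den <- 0
  for (z in seq_len(d[3])) {
    pm <- (plaque_stack$voxels[, , z] > thr_p$threshold) & m
    lab <- label_particles(binary_mask(pm, px), params$min_plaque_area_um2)
    retained <- lab$labels > 0L
    den <- den + if (denominator == "particles") sum(retained) else sum(pm)
    if (!any(retained)) next
    halo <- dilate_physical(binary_mask(retained, px),
                            params$neurite_halo_um)$bits & m
    lamp <- !thr_l$degenerate &
      (lamp1_stack$voxels[, , z] > thr_l$threshold) & m
    mglia <- !thr_g$degenerate &
      (microglia_stack$voxels[, , z] > thr_g$threshold) & m
    num <- num + sum(lamp & !mglia & halo)
  }
  if (den == 0) {
    return(metric_result(list(ratio = NA_real_), "zero_plaque_pixels"))
  }
  metric_result(list(ratio = num / den), "")
}

# ---- microglia metrics ----------------------------------------------------

#' Microglial coverage fraction
#'
#' Per-plane thresholded (pooled-ROI Otsu) and binarized microglial stack;
#' coverage is the summed foreground pixel count over `ROI pixels x
#' planes`.
#'
#' @param microglia_stack [calibrated_stack()].
#' @param region [roi()].
#' @return List with `coverage` and `flag`.
#' @export
microglia_coverage <- function(microglia_stack, region) {
  stopifnot(inherits(microglia_stack, "calibrated_stack"))
  d <- dim(microglia_stack$voxels)
  m <- roi_pixel_mask(region, d[1:2])
  if (sum(m) == 0L) {
    return(metric_result(list(coverage = 0), "empty_roi"))
  }
  thr <- roi_stack_threshold(microglia_stack, m, "otsu")
  if (thr$degenerate) {
    return(metric_result(list(coverage = 0), "degenerate_threshold"))
  }
  fg <- roi_stack_mask(microglia_stack, m, thr)
  metric_result(list(coverage = sum(fg$bits) / (sum(m) * d[3])), "")
}

#' Plaque-associated microglia fraction
#'
#' The per-plane thresholded plaque mask is dilated by the 5-um
#' association halo; the fraction is the colocalized microglia pixel count
#' over all microglial pixels, summed over planes.
#'
#' @param plaque_stack,microglia_stack [calibrated_stack()]s sharing shape
#'   and calibration.
#' @param region [roi()].
#' @param params [plaque_params()].
#' @return List with `fraction` (NA + flag when no microglial pixels) and
#'   `flag`.
#' @export
plaque_associated_microglia <- function(plaque_stack, microglia_stack,
                                        region,
                                        params = plaque_params()) {
  check_same_geometry(plaque_stack, microglia_stack)
  d <- dim(plaque_stack$voxels)
  m <- roi_pixel_mask(region, d[1:2])
  if (sum(m) == 0L) {
    return(metric_result(list(fraction = NA_real_), "empty_roi"))
  }
  thr_p <- roi_stack_threshold(plaque_stack, m, "otsu")
  thr_g <- roi_stack_threshold(microglia_stack, m, "otsu")
  if (thr_g$degenerate) {
    return(metric_result(list(fraction = NA_real_),
                         "degenerate_microglia_threshold"))
  }
  px <- plaque_stack$pixel_size_um
  num <- 0; den <- 0
  for (z in seq_len(d[3])) {
    mg <- (microglia_stack$voxels[, , z] > thr_g$threshold) & m
    den <- den + sum(mg)
    if (thr_p$degenerate) next
    pm <- (plaque_stack$voxels[, , z] > thr_p$threshold) & m
    if (!any(pm)) next
    halo <- dilate_physical(binary_mask(pm, px),
                            params$microglia_assoc_halo_um)$bits & m
    num <- num + sum(mg & halo)
  }
  if (den == 0) {
    return(metric_result(list(fraction = NA_real_), "zero_microglia_pixels"))
  }
  metric_result(list(fraction = num / den), "")
}

#' CD68-positive microglia fraction
#'
#' Colocalization of the binarized CD68 and microglia stacks (pixelwise
#' AND), divided by total microglial pixels, summed over planes.
#'
#' @param cd68_stack,microglia_stack [calibrated_stack()]s sharing shape
#'   and calibration.
#' @param region [roi()].
#' @return List with `fraction` (NA + flag when no microglial pixels) and
#'   `flag`.
#' @export
cd68_in_microglia <- function(cd68_stack, microglia_stack, region) {
  check_same_geometry(cd68_stack, microglia_stack)
  d <- dim(cd68_stack$voxels)
  m <- roi_pixel_mask(region, d[1:2])
  if (sum(m) == 0L) {
    return(metric_result(list(fraction = NA_real_), "empty_roi"))
  }
  thr_c <- roi_stack_threshold(cd68_stack, m, "otsu")
  thr_g <- roi_stack_threshold(microglia_stack, m, "otsu")
  if (thr_g$degenerate) {
    return(metric_result(list(fraction = NA_real_),
                         "degenerate_microglia_threshold"))
  }
  mg <- roi_stack_mask(microglia_stack, m, thr_g)$bits
  den <- sum(mg)
  if (den == 0) {
    return(metric_result(list(fraction = NA_real_), "zero_microglia_pixels"))
  }
  num <- if (thr_c$degenerate) 0 else
    sum(roi_stack_mask(cd68_stack, m, thr_c)$bits & mg)
  metric_result(list(fraction = num / den), "")
}

#' Background-subtracted mean intensity
#'
#' The homeostatic-marker intensity readout: the stack is sum-projected,
#' Otsu-thresholded on the whole projection, and the sub-threshold region
#' is taken as background. The background mean is subtracted from the
#' projection (clamped at 0) and the result averaged over suprathreshold
#' pixels inside the ROI. With `suprathreshold_only = FALSE` the mean is
#' taken over all ROI pixels instead.
#'
#' @param stack [calibrated_stack()].
#' @param region [roi()].
#' @param suprathreshold_only Restrict the final mean to suprathreshold
#'   pixels (default) or average over the whole ROI.
#' @return List with `mean_intensity` and `flag` (degenerate threshold or
#'   no suprathreshold ROI pixels report 0 with a flag).
#' @export
background_subtracted_intensity <- function(stack, region,
                                            suprathreshold_only = TRUE) {
  stopifnot(inherits(stack, "calibrated_stack"))
  proj <- sum_project(stack)
  m <- roi_pixel_mask(region, dim(proj))
  if (sum(m) == 0L) {
    return(metric_result(list(mean_intensity = 0), "empty_roi"))
  }
  thr <- auto_threshold(as.vector(proj), "otsu")
  if (thr$degenerate) {
    return(metric_result(list(mean_intensity = 0), "degenerate_threshold"))
  }
  background <- mean(proj[proj <= thr$threshold])
  corrected <- pmax(proj - background, 0)
  sel <- if (suprathreshold_only) (proj > thr$threshold) & m else m
  if (!any(sel)) {
    return(metric_result(list(mean_intensity = 0),
                         "no_suprathreshold_roi_pixels"))
  }
  metric_result(list(mean_intensity = mean(corrected[sel])), "")
}

# ---- Tau ------------------------------------------------------------------

#' Phospho-Tau / total-Tau area-fraction ratio
#'
#' Both channels are maximum-projected, Otsu-thresholded on the ROI
#' histogram and ROI-restricted; area fractions are computed as in
#' [plaque_burden()] but with no size cut-off, and the ratio is
#' phospho-epitope fraction over total-Tau fraction.
#'
#' @param phospho_stack,total_tau_stack [calibrated_stack()]s sharing
#'   shape and calibration.
#' @param region [roi()].
#' @return List with `phospho_fraction`, `total_fraction`, `ratio` (NA +
#'   flag when the total-Tau area is zero) and `flag`.
#' @export
tau_epitope_ratio <- function(phospho_stack, total_tau_stack, region) {
  check_same_geometry(phospho_stack, total_tau_stack)
  pp <- max_project(phospho_stack)
  pt <- max_project(total_tau_stack)
  m <- roi_pixel_mask(region, dim(pp))
  roi_px <- sum(m)
  if (roi_px == 0L) {
    return(metric_result(list(phospho_fraction = 0, total_fraction = 0,
                              ratio = NA_real_), "empty_roi"))
  }
  thr_p <- auto_threshold(pp[m], "otsu")
  thr_t <- auto_threshold(pt[m], "otsu")
  p_fg <- if (thr_p$degenerate) 0L else sum(pp > thr_p$threshold & m)
  t_fg <- if (thr_t$degenerate) 0L else sum(pt > thr_t$threshold & m)
  flag <- ""
  if (thr_p$degenerate) flag <- "degenerate_phospho_threshold"
  ratio <- if (t_fg == 0L) NA_real_ else p_fg / t_fg
  if (t_fg == 0L) flag <- paste0(flag, if (nzchar(flag)) ";",
                                 "zero_total_tau_area")
  metric_result(list(phospho_fraction = p_fg / roi_px,
                     total_fraction = t_fg / roi_px, ratio = ratio), flag)
}

# ---- report assembly ------------------------------------------------------

#' Long-format metric report rows
#'
#' Flattens a metric result (the named list returned by the metric
#' functions) into one row per scalar, the long CSV format the pipeline
#' writes: `image, region, metric, value, flag`.
#'
#' @param image_id Image identifier.
#' @param region_name Region name.
#' @param metric_name Metric family name (prefixed to each scalar).
#' @param result A metric result list with a `flag` element.
#' @return `data.frame` with columns image, region, metric, value, flag.
#' @export
metric_report_rows <- function(image_id, region_name, metric_name, result) {
  flag <- result$flag
  vals <- result[setdiff(names(result), "flag")]
  data.frame(
    image = image_id,
    region = region_name,
    metric = paste(metric_name, names(vals), sep = "."),
    value = vapply(vals, function(v) as.numeric(v)[1], numeric(1)),
    flag = flag,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
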