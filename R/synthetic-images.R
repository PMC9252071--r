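#' Synthetic fluorescence scene specification
#'
#' Describes a multi-channel confocal-like scene emulating the study
#' material: amyloid plaques as bright compact discs with a faint diffuse
#' skirt, a dense-core (MeX04-positive) centre, microglial blobs that
#' overlap plaque margins, LAMP1 annuli concentric with plaques and partly
#' overlapping microglia, and CD68 puncta inside microglia, on a noisy
#' background. All randomness is fixed by `seed`.
#'
#' Noise is Gaussian with shot-noise scaling: the per-pixel standard
#' deviation is `noise_sd * sqrt(I_clean / background_mean)`, i.e.
#' `noise_sd` is the background's Gaussian noise SD and brighter
#' structures are proportionally noisier, as in photon-limited confocal
#' data. The scene's signal-to-noise ratio is defined at the plaque core:
#' `SNR = (core_intensity - background_mean) / sd(core)` with
#' `sd(core) = noise_sd * sqrt(core_intensity / background_mean)`.
#' [noise_sd_for_snr()] converts a target SNR to the `noise_sd` field.
#'
#' @param shape `c(y, x, z)` image extents in pixels (default
#'   `c(256, 256, 4)`).
#' @param pixel_size_um Pixel calibration (default 1 um/px).
#' @param n_plaques Number of plaques above the 50-um^2 particle cut-off.
#' @param plaque_radius_um Range of plaque core radii in um.
#' @param n_small_plaques Number of planted sub-cut-off plaques
#'   (radius `small_plaque_radius_um`, area below 50 um^2).
#' @param small_plaque_radius_um Radius of the sub-cut-off plaques.
#' @param core_intensity,halo_intensity 6E10 plaque disc and diffuse-skirt
#'   intensities; the skirt spans radii `R..halo_scale*R` and is designed
#'   to sit below any sensible threshold.
#' @param halo_scale Outer skirt radius as a multiple of the core radius.
#' @param mex04_radius_frac Dense-core radius as a fraction of the plaque
#'   radius (MeX04 channel).
#' @param mex04_intensity MeX04 core intensity.
#' @param n_microglia Number of microglial blobs; half are seeded at
#'   plaque rims so microglia overlap plaque margins.
#' @param microglia_radius_um Range of microglial blob lobe radii.
#' @param microglia_intensity Microglia channel intensity.
#' @param lamp1_width_um LAMP1 annulus width beyond the plaque radius.
#' @param lamp1_intensity LAMP1 channel intensity.
#' @param cd68_per_microglia CD68 puncta per microglial blob.
#' @param cd68_radius_um CD68 punctum radius.
#' @param cd68_intensity CD68 channel intensity.
#' @param background_mean Background intensity level.
#' @param noise_sd Background Gaussian noise SD (see Details).
#' @param seed Integer seed fixing all randomness.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(shape = c(256L, 256L, 4L),
                       pixel_size_um = 1,
                       n_plaques = 8L,
                       plaque_radius_um = c(6, 14),
                       n_small_plaques = 3L,
                       small_plaque_radius_um = 3,
                       core_intensity = 1000,
                       halo_intensity = 490,
                       halo_scale = 1.4,
                       mex04_radius_frac = 0.6,
                       mex04_intensity = 900,
                       n_microglia = 14L,
                       microglia_radius_um = c(3, 6),
                       microglia_intensity = 800,
                       lamp1_width_um = 6,
                       lamp1_intensity = 850,
                       cd68_per_microglia = 3L,
                       cd68_radius_um = 1.5,
                       cd68_intensity = 900,
                       background_mean = 400,
                       noise_sd = 25,
                       seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 1L), pixel_size_um > 0,
            all(plaque_radius_um > 0), small_plaque_radius_um > 0,
            core_intensity > background_mean,
            mex04_intensity > background_mean,
            microglia_intensity > background_mean,
            lamp1_intensity > background_mean,
            cd68_intensity > background_mean,
            noise_sd >= 0, background_mean > 0)
  spec <- as.list(environment())
  structure(spec, class = "scene_spec")
}

#' Background noise SD achieving a target plaque-core SNR
#'
#' Inverts the scene noise model: for a target
#' `SNR = (core - background) / sd(core)` with shot-noise scaling
#' `sd(core) = noise_sd * sqrt(core / background)`, returns the
#' background `noise_sd` to put in [scene_spec()].
#'
#' @param snr Target signal-to-noise ratio at the plaque core.
#' @param core_intensity,background_mean Scene intensity levels.
#' @return Background Gaussian noise SD.
#' @export
noise_sd_for_snr <- function(snr, core_intensity = 1000,
                             background_mean = 400) {
  (core_intensity - background_mean) /
    (snr * sqrt(core_intensity / background_mean))
}

disc_mask <- function(ny, nx, cy, cx, r) {
  ys <- seq_len(ny); xs <- seq_len(nx)
  outer((ys - cy)^2, (xs - cx)^2, "+") <= r^2
}

#' Render a synthetic scene
#'
#' Draws the scene deterministically from the spec's seed and returns the
#' channel stacks together with the noiseless geometric ground truth.
#' Geometry is constant across z-planes (only the noise differs), so the
#' per-plane truth masks are the 2-D masks replicated.
#'
#' @param spec A [scene_spec()].
#' @return List with `stacks` (named list of [calibrated_stack()]s with
#'   roles `plaque_6e10`, `plaque_mex04`, `microglia`, `lamp1`, `cd68`)
#'   and `truth`: 2-D logical masks per channel, the plaque table
#'   (centre, radius, area), and directly computed reference metrics
#'   (`area_fraction`, `count`, `mean_size_um2`, `mex04_6e10_ratio`) for
#'   a whole-image ROI.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  ny <- spec$shape[1]; nx <- spec$shape[2]; nz <- spec$shape[3]
  px <- spec$pixel_size_um
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  # --- plaque placement: rejection sampling, no overlap of skirts -------
  n_all <- spec$n_plaques + spec$n_small_plaques
  radii_um <- c(stats::runif(spec$n_plaques, spec$plaque_radius_um[1],
                             spec$plaque_radius_um[2]),
                rep(spec$small_plaque_radius_um, spec$n_small_plaques))
  radii <- radii_um / px
  outer_r <- radii * spec$halo_scale + spec$lamp1_width_um / px
  centres <- matrix(NA_real_, n_all, 2)
  if (any(2 * outer_r + 4 > min(ny, nx))) {
    stop("scene objects do not fit within the image; ",
         "shrink the plaque radii or enlarge the image")
  }
  for (i in seq_len(n_all)) {
    for (try in 1:400) {
      cy <- stats::runif(1, outer_r[i] + 2, ny - outer_r[i] - 1)
      cx <- stats::runif(1, outer_r[i] + 2, nx - outer_r[i] - 1)
      if (i == 1L) break
      prev <- seq_len(i - 1L)
      d <- sqrt((centres[prev, 1] - cy)^2 + (centres[prev, 2] - cx)^2)
      if (all(d > outer_r[prev] + outer_r[i] + 2)) break
      if (try == 400) stop("could not place plaques; reduce their number")
    }
    centres[i, ] <- c(cy, cx)
  }

  plaque <- matrix(FALSE, ny, nx)
  skirt <- matrix(FALSE, ny, nx)
  mex04 <- matrix(FALSE, ny, nx)
  lamp1 <- matrix(FALSE, ny, nx)
  for (i in seq_len(n_all)) {
    cy <- centres[i, 1]; cx <- centres[i, 2]; r <- radii[i]
    d2 <- outer((seq_len(ny) - cy)^2, (seq_len(nx) - cx)^2, "+")
    core <- d2 <= r^2
    plaque <- plaque | core
    skirt <- skirt | (d2 <= (spec$halo_scale * r)^2 & !core)
    mex04 <- mex04 | (d2 <= (spec$mex04_radius_frac * r)^2)
    lamp1 <- lamp1 |
      (d2 <= (r + spec$lamp1_width_um / px)^2 & d2 > r^2)
  }
  skirt <- skirt & !plaque

  # --- microglia: lobed blobs, half seeded at plaque rims ----------------
  microglia <- matrix(FALSE, ny, nx)
  rim_n <- min(spec$n_microglia %/% 2L, spec$n_plaques)
  for (i in seq_len(spec$n_microglia)) {
    if (i <= rim_n) {
      k <- i  # one blob per rim of the first big plaques
      ang <- stats::runif(1, 0, 2 * pi)
      cy <- centres[k, 1] + radii[k] * sin(ang)
      cx <- centres[k, 2] + radii[k] * cos(ang)
    } else {
      cy <- stats::runif(1, 8, ny - 8)
      cx <- stats::runif(1, 8, nx - 8)
    }
    for (lobe in 1:4) {
      lr <- stats::runif(1, spec$microglia_radius_um[1],
                         spec$microglia_radius_um[2]) / px
      ly <- cy + stats::rnorm(1, 0, 3 / px)
      lx <- cx + stats::rnorm(1, 0, 3 / px)
      ly <- min(max(ly, lr + 1), ny - lr)
      lx <- min(max(lx, lr + 1), nx - lr)
      microglia <- microglia | disc_mask(ny, nx, ly, lx, lr)
    }
  }

  # --- CD68 puncta inside microglia --------------------------------------
  cd68 <- matrix(FALSE, ny, nx)
  inside <- which(microglia, arr.ind = TRUE)
  n_puncta <- spec$cd68_per_microglia * spec$n_microglia
  if (nrow(inside) > 0L && n_puncta > 0L) {
    pick <- inside[sample.int(nrow(inside), min(n_puncta, nrow(inside))),
                   , drop = FALSE]
    for (j in seq_len(nrow(pick))) {
      cd68 <- cd68 | disc_mask(ny, nx, pick[j, 1], pick[j, 2],
                               spec$cd68_radius_um / px)
    }
  }

  # --- compose clean channels and add shot-scaled Gaussian noise ---------
  clean <- list(
    plaque_6e10 = spec$background_mean +
      (spec$core_intensity - spec$background_mean) * plaque +
      (spec$halo_intensity - spec$background_mean) * skirt,
    plaque_mex04 = spec$background_mean +
      (spec$mex04_intensity - spec$background_mean) * mex04,
    microglia = spec$background_mean +
      (spec$microglia_intensity - spec$background_mean) * microglia,
    lamp1 = spec$background_mean +
      (spec$lamp1_intensity - spec$background_mean) * lamp1,
    cd68 = spec$background_mean +
      (spec$cd68_intensity - spec$background_mean) * cd68
  )
  stacks <- lapply(names(clean), function(role) {
    base <- clean[[role]]
    sd_map <- spec$noise_sd * sqrt(base / spec$background_mean)
    v <- array(0, dim = c(ny, nx, nz))
    for (z in seq_len(nz)) {
      v[, , z] <- pmax(base + stats::rnorm(ny * nx, 0, 1) * sd_map, 0)
    }
    calibrated_stack(v, px, role)
  })
  names(stacks) <- names(clean)

  big <- seq_len(spec$n_plaques)
  plaque_table <- data.frame(
    y = centres[, 1], x = centres[, 2],
    radius_um = radii_um,
    area_px = vapply(seq_len(n_all), function(i) {
      sum(disc_mask(ny, nx, centres[i, 1], centres[i, 2], radii[i]))
    }, numeric(1)),
    above_cutoff = seq_len(n_all) %in% big
  )
  plaque_table$area_um2 <- plaque_table$area_px * px^2

  truth <- list(
    masks = list(plaque = plaque, skirt = skirt, mex04 = mex04,
                 microglia = microglia, lamp1 = lamp1, cd68 = cd68),
    plaques = plaque_table,
    area_fraction = sum(plaque) / (ny * nx),
    count = sum(plaque_table$above_cutoff),
    mean_size_um2 = mean(plaque_table$area_um2[plaque_table$above_cutoff]),
    mex04_6e10_ratio = sum(mex04) / sum(plaque)
  )
  list(stacks = stacks, truth = truth)
}

#' Write a rendered scene to disk
#'
#' Saves each channel as a multi-page 16-bit TIFF (intensities rounded;
#' the synthetic intensity scale fits comfortably) plus the ground-truth
#' plaque table and reference metrics as CSVs, for use by the
#' command-line pipeline.
#'
#' @param scene The list returned by [render_scene()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written TIFF paths.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(scene$stacks), function(role) {
    p <- file.path(dir, paste0(role, ".tif"))
    write_stack_tiff(scene$stacks[[role]], p)
    p
  }, character(1))
  utils::write.csv(scene$truth$plaques,
                   file.path(dir, "truth_plaques.csv"), row.names = FALSE)
  ref <- data.frame(
    metric = c("area_fraction", "count", "mean_size_um2",
               "mex04_6e10_ratio"),
    value = c(scene$truth$area_fraction, scene$truth$count,
              scene$truth$mean_size_um2, scene$truth$mex04_6e10_ratio)
  )
  utils::write.csv(ref, file.path(dir, "truth_metrics.csv"),
                   row.names = FALSE)
  invisible(paths)
}
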