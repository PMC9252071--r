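# Fixtures are generated in code (helper-oracles.R); every composed metric
# is checked against a literal pixel-loop transcription of its measurement
# sequence, plus the forced-geometry and degenerate cases.

test_that("plaque burden recovers forced geometry exactly", {
  # 100 x 100 ROI (10,000 px) containing one disc of known area at 1 um/px
  n <- 100
  d2 <- outer((1:n - 50)^2, (1:n - 50)^2, "+")
  disc <- d2 <= 130  # 405 px, well above the 50 um^2 cut-off
  img <- 100 + 900 * disc
  st <- calibrated_stack(matrix(img, n, n), 1, "plaque_6e10")
  out <- plaque_burden(st, full_roi(n))
  expect_equal(out$area_fraction, sum(disc) / n^2)
  expect_identical(out$count, 1L)
  expect_equal(out$mean_size_um2, sum(disc))
  expect_identical(out$flag, "")
})

test_that("plaque burden flags blank images and reports zeros", {
  st <- calibrated_stack(matrix(7, 32, 32), 1, "plaque_6e10")
  out <- plaque_burden(st, full_roi(32))
  expect_equal(out$area_fraction, 0)
  expect_identical(out$count, 0L)
  expect_equal(out$mean_size_um2, 0)
  expect_identical(out$flag, "degenerate_threshold")
})

test_that("mex04 ratio handles identical, empty and nested core cases", {
  n <- 64
  d2 <- outer((1:n - 32)^2, (1:n - 32)^2, "+")
  core <- d2 <= 6^2
  outer_m <- d2 <= 10^2
  mk <- function(mask) {
    calibrated_stack(matrix(100 + 800 * mask, n, n), 1, "plaque_6e10")
  }
  # identical masks -> ratio 1
  same <- mex04_ratio(mk(outer_m), mk(outer_m), full_roi(n))
  expect_equal(same$ratio, 1)
  # blank MeX04 -> area fraction 0 (degenerate flag, not an error)
  blank <- mex04_ratio(mk(outer_m & FALSE), mk(outer_m), full_roi(n))
  expect_equal(blank$mex04_area_fraction, 0)
  expect_match(blank$flag, "degenerate_mex04")
  # nested cores of known area -> area quotient, against the naive oracle
  nested <- mex04_ratio(mk(core), mk(outer_m), full_roi(n))
  expect_equal(nested$ratio,
               oracle_area_quotient(matrix(100 + 800 * core, n, n),
                                    matrix(100 + 800 * outer_m, n, n),
                                    method_num = "maxentropy"))
  expect_equal(nested$ratio, sum(core) / sum(outer_m))
  # zero 6E10 foreground -> missing with flag
  zero6 <- mex04_ratio(mk(core), mk(outer_m & FALSE), full_roi(n))
  expect_true(is.na(zero6$ratio))
  expect_match(zero6$flag, "zero_6e10")
})

test_that("neuritic damage ratio matches the pixel-loop oracle on fixtures", {
  fx <- make_metric_fixture(seed = 21)
  px <- 1
  got <- neuritic_damage_ratio(
    as_stack(fx$plaque, "plaque_6e10"),
    as_stack(fx$lamp1, "lamp1"),
    as_stack(fx$microglia, "microglia"),
    full_roi(64)
  )
  want <- oracle_neuritic_ratio(fx$plaque, fx$lamp1, fx$microglia, px)
  expect_equal(got$ratio, want)
  expect_identical(got$flag, "")
})

test_that("neuritic damage ratio trivial cases: empty or microglial LAMP1", {
  fx <- make_metric_fixture(seed = 22, noise = 0)
  blank_lamp <- array(100, dim(fx$lamp1))
  out <- neuritic_damage_ratio(
    as_stack(fx$plaque, "plaque_6e10"),
    as_stack(blank_lamp, "lamp1"),
    as_stack(fx$microglia, "microglia"),
    full_roi(64)
  )
  expect_equal(out$ratio, 0)

  # LAMP1 entirely within the microglia mask: subtraction removes all
  mg_all <- fx$microglia
  lamp_in_mg <- array(100 + 800 * (fx$masks$lamp1 & fx$masks$microglia),
                      dim(fx$lamp1))
  out2 <- neuritic_damage_ratio(
    as_stack(fx$plaque, "plaque_6e10"),
    as_stack(lamp_in_mg, "lamp1"),
    as_stack(mg_all, "microglia"),
    full_roi(64)
  )
  expect_equal(out2$ratio, 0)

  # no plaque signal -> missing with flag
  out3 <- neuritic_damage_ratio(
    as_stack(array(100, dim(fx$plaque)), "plaque_6e10"),
    as_stack(fx$lamp1, "lamp1"),
    as_stack(fx$microglia, "microglia"),
    full_roi(64)
  )
  expect_true(is.na(out3$ratio))
  expect_match(out3$flag, "degenerate|zero_plaque")
})

test_that("neuritic damage ratio is monotone in the halo radius", {
  fx <- make_metric_fixture(seed = 23)
  st <- list(p = as_stack(fx$plaque, "plaque_6e10"),
             l = as_stack(fx$lamp1, "lamp1"),
             g = as_stack(fx$microglia, "microglia"))
  halos <- c(2, 5, 10, 25)
  vals <- vapply(halos, function(h) {
    neuritic_damage_ratio(st$p, st$l, st$g, full_roi(64),
                          plaque_params(neurite_halo_um = h))$ratio
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("microglia coverage covers the degenerate-to-full range and oracle", {
  blank <- calibrated_stack(array(5, c(16, 16, 3)), 1, "microglia")
  expect_equal(microglia_coverage(blank, full_roi(16))$coverage, 0)

  # two-level ROI: the signal block's share of the ROI, identical per plane
  m <- array(100, c(16, 16, 3)); m[8:12, 8:12, ] <- 900
  st <- calibrated_stack(m, 1, "microglia")
  r <- rect_roi(6, 14, 6, 14)  # 81 px ROI containing the 25 px block
  expect_equal(microglia_coverage(st, r)$coverage, 25 / 81)
  # near-full coverage: all ROI pixels but one are foreground
  m2 <- array(900, c(16, 16, 3)); m2[1, 1, ] <- 100
  st2 <- calibrated_stack(m2, 1, "microglia")
  expect_equal(microglia_coverage(st2, full_roi(16))$coverage,
               255 / 256)
  # an ROI with no intensity contrast is flagged degenerate, coverage 0
  deg <- microglia_coverage(st, rect_roi(9, 11, 9, 11))
  expect_equal(deg$coverage, 0)
  expect_identical(deg$flag, "degenerate_threshold")

  fx <- make_metric_fixture(seed = 24)
  got <- microglia_coverage(as_stack(fx$microglia, "microglia"),
                            full_roi(64))$coverage
  t <- oracle_threshold(as.vector(fx$microglia), "otsu")
  expect_equal(got, sum(fx$microglia > t) / (64 * 64 * 1))
})

test_that("plaque-associated microglia matches the oracle; halo 0 is pure overlap", {
  fx <- make_metric_fixture(seed = 25)
  p <- as_stack(fx$plaque, "plaque_6e10")
  g <- as_stack(fx$microglia, "microglia")
  got <- plaque_associated_microglia(p, g, full_roi(64))
  want <- oracle_assoc_fraction(fx$plaque, fx$microglia, 1, 5)
  expect_equal(got$fraction, want)

  # tiny halo (< 1 px) degenerates to plain overlap
  tiny <- plaque_associated_microglia(
    p, g, full_roi(64), plaque_params(microglia_assoc_halo_um = 1e-6))
  tp <- oracle_threshold(as.vector(fx$plaque), "otsu")
  tg <- oracle_threshold(as.vector(fx$microglia), "otsu")
  pm <- fx$plaque[, , 1] > tp; mg <- fx$microglia[, , 1] > tg
  expect_equal(tiny$fraction, sum(pm & mg) / sum(mg))

  # no plaques -> 0; no microglia -> missing
  none <- plaque_associated_microglia(
    as_stack(array(100, dim(fx$plaque)), "plaque_6e10"), g, full_roi(64))
  expect_equal(none$fraction, 0)
  nog <- plaque_associated_microglia(
    p, as_stack(array(100, dim(fx$plaque)), "microglia"), full_roi(64))
  expect_true(is.na(nog$fraction))
})

test_that("CD68-in-microglia fraction: trivial containment and oracle", {
  fx <- make_metric_fixture(seed = 26)
  g <- as_stack(fx$microglia, "microglia")
  # CD68 blank -> 0
  blank <- cd68_in_microglia(
    as_stack(array(100, dim(fx$cd68)), "cd68"), g, full_roi(64))
  expect_equal(blank$fraction, 0)
  # CD68 superset of microglia -> 1
  sup <- array(100 + 800 * (fx$masks$microglia | fx$masks$cd68),
               dim(fx$cd68))
  expect_equal(cd68_in_microglia(as_stack(sup, "cd68"), g,
                                 full_roi(64))$fraction, 1)
  # fixture vs oracle
  got <- cd68_in_microglia(as_stack(fx$cd68, "cd68"), g, full_roi(64))
  want <- oracle_overlap_fraction(fx$cd68, fx$microglia)
  expect_equal(got$fraction, want)
})

test_that("background-subtracted intensity recovers s - b on forced regions", {
  n <- 40
  img <- matrix(50, n, n)
  img[10:25, 10:25] <- 210
  st <- calibrated_stack(matrix(img, n, n), 1, "microglia")
  out <- background_subtracted_intensity(st, full_roi(n))
  expect_equal(out$mean_intensity, 160)
  expect_identical(out$flag, "")

  flat <- calibrated_stack(matrix(80, n, n), 1, "microglia")
  out2 <- background_subtracted_intensity(flat, full_roi(n))
  expect_equal(out2$mean_intensity, 0)
  expect_identical(out2$flag, "degenerate_threshold")

  # seeded two-level fixture: result close to the analytic difference
  set.seed(31)
  sig <- matrix(FALSE, n, n); sig[5:20, 22:38] <- TRUE
  noisy <- pmax(60 + 300 * sig + rnorm(n * n, 0, 5), 0)
  st3 <- calibrated_stack(matrix(noisy, n, n), 1, "microglia")
  out3 <- background_subtracted_intensity(st3, full_roi(n))
  expect_lt(abs(out3$mean_intensity - 300), 10)
})

test_that("tau epitope ratio: equality, emptiness and nested areas", {
  n <- 64
  d2 <- outer((1:n - 32)^2, (1:n - 32)^2, "+")
  big <- d2 <= 14^2; small <- d2 <= 9^2
  mk <- function(mask, role) {
    calibrated_stack(matrix(90 + 700 * mask, n, n), 1, role)
  }
  same <- tau_epitope_ratio(mk(big, "tau_phospho"), mk(big, "tau_total"),
                            full_roi(n))
  expect_equal(same$ratio, 1)

  blank <- tau_epitope_ratio(mk(big & FALSE, "tau_phospho"),
                             mk(big, "tau_total"), full_roi(n))
  expect_equal(blank$phospho_fraction, 0)

  nested <- tau_epitope_ratio(mk(small, "tau_phospho"),
                              mk(big, "tau_total"), full_roi(n))
  expect_equal(nested$ratio, sum(small) / sum(big))
  expect_equal(nested$ratio,
               oracle_area_quotient(matrix(90 + 700 * small, n, n),
                                    matrix(90 + 700 * big, n, n)))

  none <- tau_epitope_ratio(mk(small, "tau_phospho"),
                            mk(big & FALSE, "tau_total"), full_roi(n))
  expect_true(is.na(none$ratio))
  expect_match(none$flag, "zero_total_tau")
})

test_that("fractions stay in [0, 1] and metrics are affine-intensity invariant", {
  fx <- make_metric_fixture(seed = 27)
  r <- full_roi(64)
  p <- as_stack(fx$plaque, "plaque_6e10")
  g <- as_stack(fx$microglia, "microglia")
  l <- as_stack(fx$lamp1, "lamp1")
  c68 <- as_stack(fx$cd68, "cd68")

  vals <- c(
    plaque_burden(p, r)$area_fraction,
    microglia_coverage(g, r)$coverage,
    plaque_associated_microglia(p, g, r)$fraction,
    cd68_in_microglia(c68, g, r)$fraction
  )
  expect_true(all(vals >= 0 & vals <= 1))

  # global affine rescale a*I + b leaves every mask-based metric unchanged
  resc <- function(st) calibrated_stack(2.5 * st$voxels + 40,
                                        st$pixel_size_um, st$channel_role)
  expect_equal(plaque_burden(resc(p), r)$area_fraction, vals[1])
  expect_equal(microglia_coverage(resc(g), r)$coverage, vals[2])
  expect_equal(plaque_associated_microglia(resc(p), resc(g), r)$fraction,
               vals[3])
  expect_equal(cd68_in_microglia(resc(c68), resc(g), r)$fraction, vals[4])
  expect_equal(
    neuritic_damage_ratio(resc(p), resc(l), resc(g), r)$ratio,
    neuritic_damage_ratio(p, l, g, r)$ratio
  )
})

test_that("metric report rows flatten results into the long format", {
  fx <- make_metric_fixture(seed = 28)
  out <- plaque_burden(as_stack(fx$plaque, "plaque_6e10"), full_roi(64))
  rows <- metric_report_rows("img1", "subiculum", "plaque_burden", out)
  expect_identical(nrow(rows), 3L)
  expect_identical(rows$metric,
                   c("plaque_burden.area_fraction", "plaque_burden.count",
                     "plaque_burden.mean_size_um2"))
  expect_true(all(rows$image == "img1" & rows$region == "subiculum"))
})
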