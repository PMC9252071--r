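# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorized code paths: plain loops, naive exhaustive
# searches, and literal transcriptions of the measurement sequences.

# 8-connected flood fill
oracle_flood_fill <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  k <- 0L
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (m[i, j] && lab[i, j] == 0L) {
      k <- k + 1L
      queue <- list(c(i, j))
      lab[i, j] <- k
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (dy in -1:1) for (dx in -1:1) {
          y <- p[1] + dy; x <- p[2] + dx
          if (y >= 1 && y <= nrow(m) && x >= 1 && x <= ncol(m) &&
              m[y, x] && lab[y, x] == 0L) {
            lab[y, x] <- k
            queue[[length(queue) + 1L]] <- c(y, x)
          }
        }
      }
    }
  }
  lab
}

# Euclidean dilation by exhaustive distance check (pixel units)
oracle_dilate <- function(m, r_px) {
  fg <- which(m, arr.ind = TRUE)
  out <- matrix(FALSE, nrow(m), ncol(m))
  if (nrow(fg) == 0L) return(out)
  for (y in seq_len(nrow(m))) for (x in seq_len(ncol(m))) {
    out[y, x] <- any((fg[, 1] - y)^2 + (fg[, 2] - x)^2 <= r_px^2 + 1e-9)
  }
  out
}

# Naive exhaustive Otsu: try every split, recompute class stats from scratch
oracle_otsu_split <- function(counts, edges) {
  B <- length(counts)
  mid <- (edges[-1] + edges[-(B + 1)]) / 2
  p <- counts / sum(counts)
  best <- -Inf; best_k <- NA_integer_
  for (k in 1:(B - 1)) {
    w0 <- sum(p[1:k]); w1 <- sum(p[(k + 1):B])
    if (w0 <= 0 || w1 <= 0) next
    m0 <- sum(p[1:k] * mid[1:k]) / w0
    m1 <- sum(p[(k + 1):B] * mid[(k + 1):B]) / w1
    s <- w0 * w1 * (m0 - m1)^2
    if (s > best + 1e-12) { best <- s; best_k <- k }
  }
  edges[best_k + 1L]
}

# Naive exhaustive Kapur maximum-entropy split
oracle_kapur_split <- function(counts, edges) {
  B <- length(counts)
  p <- counts / sum(counts)
  best <- -Inf; best_k <- NA_integer_
  ent <- function(q) {
    q <- q[q > 0]; q <- q / sum(q)
    -sum(q * log(q))
  }
  for (k in 1:(B - 1)) {
    P0 <- sum(p[1:k]); P1 <- sum(p[(k + 1):B])
    if (P0 <= 0 || P1 <= 0) next
    h <- ent(p[1:k]) + ent(p[(k + 1):B])
    if (h > best + 1e-12) { best <- h; best_k <- k }
  }
  edges[best_k + 1L]
}

# Shorthand: threshold a pixel vector the way the pipeline does, but through
# the naive split searches above.
oracle_threshold <- function(pixels, method) {
  h <- intensity_histogram(pixels)
  if (method == "otsu") oracle_otsu_split(h$counts, h$bin_edges)
  else oracle_kapur_split(h$counts, h$bin_edges)
}

# Literal per-plane transcription of the LAMP1 dystrophic-neurite sequence:
# threshold/binarize each channel, size-filter plaque particles, dilate by
# the halo, subtract microglial LAMP1, count colocalized pixels.
oracle_neuritic_ratio <- function(plaque, lamp1, microglia, px_um,
                                  min_area_um2 = 50, halo_um = 25) {
  nz <- dim(plaque)[3]
  tp <- oracle_threshold(as.vector(plaque), "otsu")
  tl <- oracle_threshold(as.vector(lamp1), "otsu")
  tg <- oracle_threshold(as.vector(microglia), "otsu")
  num <- 0; den <- 0
  for (z in seq_len(nz)) {
    pm <- plaque[, , z] > tp
    lab <- oracle_flood_fill(pm)
    if (max(lab) > 0) {
      areas <- tabulate(lab) * px_um^2
      retained <- lab > 0 & areas[pmax(lab, 1)] >= min_area_um2
    } else {
      retained <- pm & FALSE
    }
    den <- den + sum(retained)
    halo <- oracle_dilate(retained, halo_um / px_um)
    lamp_m <- lamp1[, , z] > tl
    mg_m <- microglia[, , z] > tg
    non_mg_lamp <- lamp_m & !mg_m
    num <- num + sum(non_mg_lamp & halo)
  }
  if (den == 0) return(NA_real_)
  num / den
}

oracle_assoc_fraction <- function(plaque, microglia, px_um, halo_um) {
  nz <- dim(plaque)[3]
  tp <- oracle_threshold(as.vector(plaque), "otsu")
  tg <- oracle_threshold(as.vector(microglia), "otsu")
  num <- 0; den <- 0
  for (z in seq_len(nz)) {
    pm <- plaque[, , z] > tp
    mg <- microglia[, , z] > tg
    halo <- oracle_dilate(pm, halo_um / px_um)
    num <- num + sum(mg & halo)
    den <- den + sum(mg)
  }
  if (den == 0) return(NA_real_)
  num / den
}

oracle_overlap_fraction <- function(a, b, ...) {
  # |A and B| / |B| after independent thresholding, summed over planes
  ta <- oracle_threshold(as.vector(a), "otsu")
  tb <- oracle_threshold(as.vector(b), "otsu")
  num <- 0; den <- 0
  for (z in seq_len(dim(a)[3])) {
    am <- a[, , z] > ta
    bm <- b[, , z] > tb
    num <- num + sum(am & bm)
    den <- den + sum(bm)
  }
  if (den == 0) return(NA_real_)
  num / den
}

oracle_area_quotient <- function(num_img, den_img, method_num = "otsu") {
  tn <- oracle_threshold(as.vector(num_img), method_num)
  td <- oracle_threshold(as.vector(den_img), "otsu")
  sum(num_img > tn) / sum(den_img > td)
}

# Fixture: a deterministic 64 x 64 single-plane three-channel scene with a
# plaque disc, LAMP1 annulus and microglia stripe, mild seeded noise.
make_metric_fixture <- function(seed = 1, noise = 8) {
  set.seed(seed)
  n <- 64
  d2 <- outer((1:n - 32)^2, (1:n - 30)^2, "+")
  plaque_m <- d2 <= 5^2
  lamp_m <- d2 > 5^2 & d2 <= 12^2
  mg_m <- matrix(FALSE, n, n); mg_m[, 28:40] <- TRUE
  cd_m <- matrix(FALSE, n, n); cd_m[20:26, 30:36] <- TRUE
  mk <- function(mask, hi) {
    pmax(100 + (hi - 100) * mask + rnorm(n * n, 0, noise), 0)
  }
  list(
    plaque = array(mk(plaque_m, 1000), c(n, n, 1)),
    lamp1 = array(mk(lamp_m, 900), c(n, n, 1)),
    microglia = array(mk(mg_m, 800), c(n, n, 1)),
    cd68 = array(mk(cd_m, 850), c(n, n, 1)),
    masks = list(plaque = plaque_m, lamp1 = lamp_m, microglia = mg_m,
                 cd68 = cd_m)
  )
}

as_stack <- function(arr, role, px = 1) calibrated_stack(arr, px, role)

full_roi <- function(ny = 64, nx = ny) rect_roi(1, ny, 1, nx, "all")
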