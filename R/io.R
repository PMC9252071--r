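#' Read a multi-page TIFF as a calibrated stack
#'
#' Pages become z-planes. Pixel values are read natively (`as.is`), so
#' 8/16-bit files yield their integer intensities. The pixel size always
#' comes from the caller/configuration, never from file metadata.
#'
#' @param path TIFF file.
#' @param pixel_size_um Pixel calibration in micrometres.
#' @param channel_role Channel role (see [channel_roles()]).
#' @return A [calibrated_stack()].
#' @export
read_stack_tiff <- function(path, pixel_size_um, channel_role) {
  if (!file.exists(path)) stop("TIFF not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # grey written as RGB
    p
  })
  v <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) v[, , z] <- pages[[z]]
  calibrated_stack(v, pixel_size_um, channel_role)
}

#' Write a calibrated stack as a 16-bit multi-page TIFF
#'
#' Intensities are rounded and clamped to the 16-bit range.
#'
#' @param stack A [calibrated_stack()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_stack_tiff <- function(stack, path) {
  v <- stack$voxels
  pages <- lapply(seq_len(dim(v)[3]), function(z) {
    m <- round(pmin(pmax(v[, , z], 0), 65535))
    m / 65535  # writeTIFF stores [0,1] scaled to the sample depth
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Export a binary mask as an 8-bit TIFF (0/255) for visual audit
#'
#' @param mask A [binary_mask()] (2-D, or 3-D written page-per-plane).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_mask_tiff <- function(mask, path) {
  b <- mask$bits
  if (is.matrix(b)) b <- array(b, dim = c(dim(b), 1L))
  pages <- lapply(seq_len(dim(b)[3]), function(z) {
    matrix(as.numeric(b[, , z]), dim(b)[1])
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read region-of-interest polygons from JSON
#'
#' The file maps region names to lists of `(y, x)` vertex pairs:
#' `{"subiculum": [[y1, x1], [y2, x2], ...], ...}`.
#'
#' @param path JSON file.
#' @return Named list of [roi()] objects.
#' @export
read_roi_json <- function(path) {
  if (!file.exists(path)) stop("ROI file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (!is.list(raw) || is.null(names(raw))) {
    stop("ROI JSON must map region names to vertex lists")
  }
  lapply(stats::setNames(names(raw), names(raw)), function(nm) {
    roi(as.matrix(raw[[nm]]), name = nm)
  })
}

#' Write ROIs to JSON
#' @param rois Named list of [roi()] objects.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_roi_json <- function(rois, path) {
  payload <- lapply(rois, function(r) unname(as.matrix(r$polygon)))
  jsonlite::write_json(payload, path, digits = NA)
  invisible(path)
}

#' Read a gene-by-cell count matrix with group labels
#'
#' Accepts either a Matrix Market triplet directory (`matrix.mtx` +
#' `genes.tsv` + `barcodes.tsv`) or a dense CSV with gene symbols in the
#' first column and cell ids as header. Group (and optional cluster)
#' labels come from a two/three-column CSV (`cell_id, group[, cluster]`).
#'
#' @param counts_path Directory containing the MTX triplet, or a CSV
#'   file.
#' @param labels_path Label CSV; optional (defaults to one group).
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_path, labels_path = NULL) {
  if (dir.exists(counts_path)) {
    mtx <- file.path(counts_path, "matrix.mtx")
    genes <- file.path(counts_path, "genes.tsv")
    cells <- file.path(counts_path, "barcodes.tsv")
    for (f in c(mtx, genes, cells)) {
      if (!file.exists(f)) stop("missing file: ", f)
    }
    counts <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
    gene_symbols <- readLines(genes)
    cell_ids <- readLines(cells)
  } else {
    if (!file.exists(counts_path)) stop("counts not found: ", counts_path)
    df <- utils::read.csv(counts_path, check.names = FALSE)
    gene_symbols <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "integer"
    counts <- Matrix::Matrix(m, sparse = TRUE)
    cell_ids <- colnames(df)[-1]
  }
  group <- NULL; cluster <- NULL
  if (!is.null(labels_path)) {
    lab <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
    idx <- match(cell_ids, lab[[1]])
    if (anyNA(idx)) stop("label CSV is missing some cell ids")
    group <- lab[[2]][idx]
    if (ncol(lab) >= 3L) cluster <- lab[[3]][idx]
  }
  count_matrix(counts, gene_symbols = gene_symbols, cell_ids = cell_ids,
               cell_group = group, cell_cluster = cluster)
}
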