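#' Synthetic count-matrix specification
#'
#' Describes a negative-binomial gene-by-cell count matrix with
#' mitochondrial and ribosomal gene families, planted low-quality cells
#' of the three QC failure types (low feature count, excessive total
#' counts, high mitochondrial fraction) and planted marker genes with a
#' known fold change between two cell groups. All randomness is fixed by
#' `seed`.
#'
#' @param n_genes Total genes, including the mito/ribo families.
#' @param n_cells Named vector of cells per group (default
#'   `c(control = 150, plx = 150)`).
#' @param mean_log,sd_log Log-normal parameters of per-gene baseline
#'   means.
#' @param dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param n_mito,n_ribo Numbers of `mt-`/`Rps`/`Rpl` genes.
#' @param mito_share Fraction of a healthy cell's expression carried by
#'   the mitochondrial family (default 1%, several standard deviations
#'   below the 5% cap so healthy cells never straddle it).
#' @param n_low_feature,n_high_count,n_high_mito Planted failing cells of
#'   each type (split across groups in order).
#' @param low_feature_depth Library-depth multiplier of low-feature cells
#'   (default 0.08, driving detected features well below 200).
#' @param high_count_factor Library-depth multiplier of high-count cells
#'   (default 8, far beyond mean + 3 SD).
#' @param high_mito_share Mitochondrial share of high-mito cells
#'   (default 0.25, far above the 5% cap).
#' @param n_markers Number of planted marker genes (drawn from genes at
#'   or above the median baseline mean).
#' @param marker_fold Fold change of markers in the second group
#'   (default 4).
#' @param seed Integer seed.
#' @return Object of class `matrix_spec`.
#' @export
matrix_spec <- function(n_genes = 500L,
                        n_cells = c(control = 150L, plx = 150L),
                        mean_log = log(1.5), sd_log = 1,
                        dispersion = 2,
                        n_mito = 10L, n_ribo = 20L,
                        mito_share = 0.01,
                        n_low_feature = 0L, n_high_count = 0L,
                        n_high_mito = 0L,
                        low_feature_depth = 0.08,
                        high_count_factor = 8,
                        high_mito_share = 0.25,
                        n_markers = 0L, marker_fold = 4,
                        seed = 1L) {
  stopifnot(n_genes > n_mito + n_ribo, all(n_cells > 0),
            length(n_cells) == 2L, !is.null(names(n_cells)),
            dispersion > 0, mito_share > 0, mito_share < 1,
            high_mito_share > mito_share, marker_fold > 0)
  spec <- as.list(environment())
  structure(spec, class = "matrix_spec")
}

#' Sample a synthetic count matrix with planted QC failures and markers
#'
#' Counts are negative-binomial around per-gene log-normal means, scaled
#' per cell by a depth factor. Mitochondrial genes receive a fixed share
#' of each cell's expression (`mito_share`, or `high_mito_share` for
#' planted high-mito cells); planted low-feature and high-count cells get
#' shrunken/inflated depth factors. Marker genes have their means
#' multiplied by `marker_fold` in the second group.
#'
#' @param spec A [matrix_spec()].
#' @return List with `matrix` (a [count_matrix()]), `cell_truth`
#'   (`data.frame`: cell id, group, planted type) and `marker_truth`
#'   (`data.frame`: gene, fold change, up group).
#' @export
sample_matrix <- function(spec) {
  stopifnot(inherits(spec, "matrix_spec"))
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  groups <- names(spec$n_cells)
  n_cells <- sum(spec$n_cells)
  cell_group <- rep(groups, times = spec$n_cells)
  cell_ids <- sprintf("cell%04d", seq_len(n_cells))

  n_plain <- spec$n_genes - spec$n_mito - spec$n_ribo
  genes <- c(sprintf("Gene%04d", seq_len(n_plain)),
             sprintf("mt-G%02d", seq_len(spec$n_mito)),
             c(sprintf("Rps%02d", seq_len(ceiling(spec$n_ribo / 2))),
               sprintf("Rpl%02d", seq_len(floor(spec$n_ribo / 2)))))
  is_mito <- startsWith(genes, "mt-")

  base_mean <- stats::rlnorm(spec$n_genes, spec$mean_log, spec$sd_log)
  # give the mito family exactly its expression share
  non_mito_total <- sum(base_mean[!is_mito])
  base_mean[is_mito] <- non_mito_total * spec$mito_share /
    ((1 - spec$mito_share) * spec$n_mito)

  # planted markers among the plain genes, upregulated in the 2nd group;
  # drawn from genes at or above the median baseline mean, so a planted
  # marker is a clearly detected transcript rather than a near-zero one
  marker_idx <- integer(0)
  if (spec$n_markers > 0L) {
    eligible <- which(base_mean[seq_len(n_plain)] >=
                        stats::median(base_mean[seq_len(n_plain)]))
    marker_idx <- sample(eligible, spec$n_markers)
  }

  # planted failing cells, assigned round-robin across groups
  planted <- rep("ok", n_cells)
  pool <- seq_len(n_cells)
  take <- function(n) {
    sel <- pool[seq_len(n)]
    pool <<- setdiff(pool, sel)
    sel
  }
  # interleave groups so each group receives planted cells
  pool <- order(stats::ave(seq_len(n_cells), cell_group,
                           FUN = seq_along))
  low_idx <- take(spec$n_low_feature)
  high_idx <- take(spec$n_high_count)
  mito_idx <- take(spec$n_high_mito)
  planted[low_idx] <- "low_feature"
  planted[high_idx] <- "high_count"
  planted[mito_idx] <- "high_mito"

  depth <- rep(1, n_cells)
  depth[low_idx] <- spec$low_feature_depth
  depth[high_idx] <- spec$high_count_factor

  counts <- matrix(0L, spec$n_genes, n_cells)
  for (j in seq_len(n_cells)) {
    mu <- base_mean
    if (cell_group[j] == groups[2] && length(marker_idx)) {
      mu[marker_idx] <- mu[marker_idx] * spec$marker_fold
    }
    if (planted[j] == "high_mito") {
      share <- spec$high_mito_share
      mu[is_mito] <- sum(mu[!is_mito]) * share /
        ((1 - share) * spec$n_mito)
    }
    counts[, j] <- stats::rnbinom(spec$n_genes,
                                  mu = mu * depth[j],
                                  size = spec$dispersion)
  }

  cm <- count_matrix(counts, gene_symbols = genes, cell_ids = cell_ids,
                     cell_group = cell_group)
  list(
    matrix = cm,
    cell_truth = data.frame(cell_id = cell_ids, group = cell_group,
                            planted = planted, stringsAsFactors = FALSE),
    marker_truth = if (length(marker_idx)) {
      data.frame(gene = genes[marker_idx], fold_change = spec$marker_fold,
                 up_group = groups[2], stringsAsFactors = FALSE)
    } else {
      data.frame(gene = character(0), fold_change = numeric(0),
                 up_group = character(0))
    }
  )
}

#' Write a sampled count matrix to disk
#'
#' Matrix Market sparse triplet plus genes/barcodes TSVs, the label CSV
#' the pipeline consumes, and the planted-cell/marker truth tables.
#'
#' @param sampled The list returned by [sample_matrix()].
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_counts <- function(sampled, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cm <- sampled$matrix
  Matrix::writeMM(cm$counts, file.path(dir, "matrix.mtx"))
  writeLines(cm$gene_symbols, file.path(dir, "genes.tsv"))
  writeLines(cm$cell_ids, file.path(dir, "barcodes.tsv"))
  labels <- data.frame(cell_id = cm$cell_ids, group = cm$cell_group)
  if (!is.null(cm$cell_cluster)) labels$cluster <- cm$cell_cluster
  utils::write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  utils::write.csv(sampled$cell_truth, file.path(dir, "truth_cells.csv"),
                   row.names = FALSE)
  utils::write.csv(sampled$marker_truth,
                   file.path(dir, "truth_markers.csv"), row.names = FALSE)
  invisible(dir)
}
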