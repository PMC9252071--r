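#' Gene-by-cell count matrix container
#'
#' Wraps a (sparse-capable) genes x cells integer count matrix with unique
#' gene symbols and cell ids, per-cell group labels (e.g. control vs
#' PLX-repopulated) and optional cluster labels.
#'
#' @param counts Integer matrix or `Matrix::dgCMatrix`, genes in rows.
#' @param gene_symbols Unique gene symbols (defaults to rownames).
#' @param cell_ids Unique cell identifiers (defaults to colnames).
#' @param cell_group Per-cell categorical label (character/factor), length
#'   `ncol(counts)`.
#' @param cell_cluster Optional per-cell cluster label.
#' @return Object of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_symbols = rownames(counts),
                         cell_ids = colnames(counts),
                         cell_group = NULL, cell_cluster = NULL) {
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  if (!methods::is(counts, "sparseMatrix")) {
    stop("`counts` must be a matrix or sparse Matrix")
  }
  counts <- methods::as(counts, "CsparseMatrix")
  if (any(counts@x < 0) || any(counts@x != round(counts@x))) {
    stop("counts must be non-negative integers")
  }
  if (is.null(gene_symbols) || is.null(cell_ids)) {
    stop("gene symbols and cell ids are required")
  }
  gene_symbols <- as.character(gene_symbols)
  cell_ids <- as.character(cell_ids)
  if (length(gene_symbols) != nrow(counts)) stop("gene symbol length mismatch")
  if (length(cell_ids) != ncol(counts)) stop("cell id length mismatch")
  if (anyDuplicated(gene_symbols)) stop("gene symbols must be unique")
  if (anyDuplicated(cell_ids)) stop("cell ids must be unique")
  if (is.null(cell_group)) cell_group <- rep("all", ncol(counts))
  cell_group <- as.character(cell_group)
  if (length(cell_group) != ncol(counts)) stop("cell_group length mismatch")
  if (!is.null(cell_cluster)) {
    cell_cluster <- as.character(cell_cluster)
    if (length(cell_cluster) != ncol(counts)) {
      stop("cell_cluster length mismatch")
    }
  }
  dimnames(counts) <- list(gene_symbols, cell_ids)
  structure(list(counts = counts, gene_symbols = gene_symbols,
                 cell_ids = cell_ids, cell_group = cell_group,
                 cell_cluster = cell_cluster),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d cells, groups: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$cell_group), collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Quality-control parameters
#'
#' The rule-based QC thresholds: genes detected in fewer than
#' `min_cells_per_gene` cells and ribosomal genes are dropped; cells with
#' fewer than `min_features_per_cell` detected genes, more than
#' `mean + max_counts_sd_mult * SD` total transcripts (mean/SD per group),
#' or more than `max_mito_fraction` mitochondrial counts are removed.
#'
#' @param min_cells_per_gene Gene detection floor (default 3 cells).
#' @param min_features_per_cell Unique-feature floor per cell (default 200).
#' @param max_counts_sd_mult SD multiplier of the transcript cap (default 3).
#' @param max_mito_fraction Mitochondrial count fraction cap (default 0.05).
#' @param mito_prefix Symbol prefix identifying mitochondrial genes
#'   (mouse convention `"mt-"`, matched case-insensitively).
#' @param ribo_prefixes Symbol prefixes identifying ribosomal genes
#'   (case-insensitive, default `c("Rps", "Rpl")`).
#' @return Object of class `qc_params`.
#' @export
qc_params <- function(min_cells_per_gene = 3L,
                      min_features_per_cell = 200L,
                      max_counts_sd_mult = 3,
                      max_mito_fraction = 0.05,
                      mito_prefix = "mt-",
                      ribo_prefixes = c("Rps", "Rpl")) {
  stopifnot(min_cells_per_gene > 0, min_features_per_cell > 0,
            max_counts_sd_mult > 0,
            max_mito_fraction > 0, max_mito_fraction < 1)
  structure(list(min_cells_per_gene = as.integer(min_cells_per_gene),
                 min_features_per_cell = as.integer(min_features_per_cell),
                 max_counts_sd_mult = max_counts_sd_mult,
                 max_mito_fraction = max_mito_fraction,
                 mito_prefix = mito_prefix,
                 ribo_prefixes = ribo_prefixes),
            class = "qc_params")
}

starts_with_any <- function(x, prefixes) {
  xl <- tolower(x)
  hit <- rep(FALSE, length(x))
  for (p in tolower(prefixes)) hit <- hit | startsWith(xl, p)
  hit
}

#' Rule-based QC filtering of a count matrix
#'
#' Applies the gene-level exclusions first (ribosomal genes by symbol
#' prefix, genes detected in too few cells), then computes per-cell totals,
#' unique-feature counts and mitochondrial fractions on the gene-filtered
#' matrix and removes failing cells. The transcript cap
#' (`mean + k * SD` of total counts) is computed per group over the cells
#' that survive the other cell criteria, so planted low-quality cells do
#' not distort it.
#'
#' @param x A [count_matrix()].
#' @param params [qc_params()].
#' @return List with `matrix` (the filtered [count_matrix()]) and `report`
#'   (a `data.frame` of cells/genes in and out per criterion plus the
#'   per-group caps used). Errors if nothing survives; warns and skips the
#'   mitochondrial criterion when no mitochondrial genes are present.
#' @export
qc_filter <- function(x, params = qc_params()) {
  stopifnot(inherits(x, "count_matrix"))
  counts <- x$counts
  genes <- x$gene_symbols

  ribo <- starts_with_any(genes, params$ribo_prefixes)
  detected_in <- Matrix::rowSums(counts > 0)
  low_detect <- detected_in < params$min_cells_per_gene
  keep_gene <- !ribo & !low_detect
  if (!any(keep_gene)) stop("no genes survive the gene-level filters")
  counts <- counts[keep_gene, , drop = FALSE]
  genes <- genes[keep_gene]

  mito <- starts_with_any(genes, params$mito_prefix)
  total_counts <- Matrix::colSums(counts)
  n_features <- Matrix::colSums(counts > 0)
  if (any(mito)) {
    mito_frac <- Matrix::colSums(counts[mito, , drop = FALSE]) /
      pmax(total_counts, 1)
    mito_fail <- mito_frac > params$max_mito_fraction
    mito_skipped <- FALSE
  } else {
    warning("no mitochondrial genes found; mitochondrial criterion skipped")
    mito_frac <- rep(NA_real_, ncol(counts))
    mito_fail <- rep(FALSE, ncol(counts))
    mito_skipped <- TRUE
  }
  feature_fail <- n_features < params$min_features_per_cell

  # transcript cap per group, over cells passing the other criteria
  group <- x$cell_group
  cap_fail <- rep(FALSE, ncol(counts))
  caps <- vapply(unique(group), function(g) {
    in_g <- group == g
    ref <- in_g & !feature_fail & !mito_fail
    if (sum(ref) < 2L) return(Inf)
    mean(total_counts[ref]) +
      params$max_counts_sd_mult * stats::sd(total_counts[ref])
  }, numeric(1))
  for (g in unique(group)) {
    in_g <- group == g
    cap_fail[in_g] <- total_counts[in_g] > caps[[g]]
  }

  keep_cell <- !feature_fail & !cap_fail & !mito_fail
  if (!any(keep_cell)) stop("no cells survive the QC filters")

  report <- data.frame(
    criterion = c("ribosomal_gene", "low_detection_gene",
                  "low_feature_cell", "high_count_cell", "high_mito_cell",
                  "cells_in", "cells_out", "genes_in", "genes_out"),
    removed = c(sum(ribo), sum(low_detect & !ribo),
                sum(feature_fail), sum(cap_fail), sum(mito_fail),
                ncol(x$counts), sum(keep_cell),
                length(x$gene_symbols), sum(keep_gene)),
    stringsAsFactors = FALSE
  )
  attr(report, "transcript_caps") <- caps
  attr(report, "mito_criterion_skipped") <- mito_skipped

  filtered <- count_matrix(
    counts[, keep_cell, drop = FALSE],
    gene_symbols = genes,
    cell_ids = x$cell_ids[keep_cell],
    cell_group = x$cell_group[keep_cell],
    cell_cluster = if (!is.null(x$cell_cluster)) x$cell_cluster[keep_cell]
  )
  cell_status <- data.frame(
    cell_id = x$cell_ids,
    group = x$cell_group,
    total_counts = total_counts,
    n_features = n_features,
    mito_fraction = mito_frac,
    fail_features = feature_fail,
    fail_counts_cap = cap_fail,
    fail_mito = mito_fail,
    kept = keep_cell,
    stringsAsFactors = FALSE
  )
  list(matrix = filtered, report = report, cell_status = cell_status)
}

#' Library-size log-normalization
#'
#' Scales each cell to `scale_factor` total counts and applies
#' `log(1 + x)` (natural log), the convention under which the
#' log-fold-change gates of marker detection are expressed.
#'
#' @param x A [count_matrix()] or genes x cells (sparse) matrix.
#' @param scale_factor Per-cell target sum (default 10,000).
#' @return Sparse genes x cells matrix of normalized expression.
#' @export
log_normalize <- function(x, scale_factor = 1e4) {
  counts <- if (inherits(x, "count_matrix")) x$counts else x
  tot <- Matrix::colSums(counts)
  tot[tot == 0] <- 1
  scaled <- counts %*% Matrix::Diagonal(x = scale_factor / tot)
  dimnames(scaled) <- dimnames(counts)
  out <- scaled
  out@x <- log1p(out@x)
  out
}

#' Marker-detection parameters
#'
#' @param min_abs_logfc Natural-log fold-change gate; genes with
#'   `|logFC| <= min_abs_logfc` are not tested (default 0.25).
#' @param padj_threshold BH-adjusted significance level (default 0.05).
#' @param scale_factor Normalization target sum (default 10,000).
#' @param pseudocount Pseudocount in the fold-change means (default 1).
#' @return Object of class `marker_params`.
#' @export
marker_params <- function(min_abs_logfc = 0.25, padj_threshold = 0.05,
                          scale_factor = 1e4, pseudocount = 1) {
  stopifnot(min_abs_logfc >= 0, padj_threshold > 0, padj_threshold < 1)
  structure(list(min_abs_logfc = min_abs_logfc,
                 padj_threshold = padj_threshold,
                 scale_factor = scale_factor, pseudocount = pseudocount),
            class = "marker_params")
}

#' Wilcoxon rank-sum marker detection with log-fold-change gating
#'
#' For each gene the natural-log fold change between groups is
#' `log(mean(expm1(normA)) + pseudocount) - log(mean(expm1(normB)) +
#' pseudocount)`. Genes passing the `|logFC|` gate are tested with the
#' two-sided Wilcoxon rank-sum test (normal approximation with tie
#' correction, no continuity correction); Benjamini-Hochberg adjustment is
#' applied across the tested genes only, mirroring the single-cell
#' convention. Constant genes get p = 1.
#'
#' @param norm_expr Genes x cells normalized matrix (from
#'   [log_normalize()]).
#' @param cells_a,cells_b Column indices or cell ids of the two groups
#'   (non-empty, disjoint interpretation is the caller's responsibility).
#' @param params [marker_params()].
#' @return `data.frame` (one row per gene): `gene`, `avg_logFC`, `mean_a`,
#'   `mean_b`, `tested`, `p_val`, `p_val_adj`, `significant`.
#' @export
wilcoxon_markers <- function(norm_expr, cells_a, cells_b,
                             params = marker_params()) {
  if (is.character(cells_a)) cells_a <- match(cells_a, colnames(norm_expr))
  if (is.character(cells_b)) cells_b <- match(cells_b, colnames(norm_expr))
  if (length(cells_a) == 0L || length(cells_b) == 0L) {
    stop("both groups must be non-empty")
  }
  if (anyNA(cells_a) || anyNA(cells_b)) stop("unknown cell ids")
  if (length(cells_a) < 3L || length(cells_b) < 3L) {
    warning("a group has fewer than 3 cells; p-values are unreliable")
  }
  A <- as.matrix(norm_expr[, cells_a, drop = FALSE])
  B <- as.matrix(norm_expr[, cells_b, drop = FALSE])
  mean_a <- rowMeans(expm1(A))
  mean_b <- rowMeans(expm1(B))
  logfc <- log(mean_a + params$pseudocount) -
    log(mean_b + params$pseudocount)
  tested <- abs(logfc) > params$min_abs_logfc
  p <- rep(NA_real_, length(logfc))
  if (any(tested)) {
    p[tested] <- ranksum_p(A[tested, , drop = FALSE],
                           B[tested, , drop = FALSE])
  }
  padj <- rep(NA_real_, length(logfc))
  padj[tested] <- stats::p.adjust(p[tested], method = "BH")
  genes <- rownames(norm_expr) %||% as.character(seq_along(logfc))
  data.frame(
    gene = genes,
    avg_logFC = logfc,
    mean_a = mean_a,
    mean_b = mean_b,
    tested = tested,
    p_val = p,
    p_val_adj = padj,
    significant = tested & !is.na(padj) & padj < params$padj_threshold,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

# Vectorized two-sided rank-sum p-values (normal approximation with tie
# correction, no continuity correction) for each row of cbind(A, B).
ranksum_p <- function(A, B) {
  na <- ncol(A); nb <- ncol(B); n <- na + nb
  X <- cbind(A, B)
  vapply(seq_len(nrow(X)), function(i) {
    x <- X[i, ]
    r <- rank(x)
    W <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    mu <- na * nb / 2
    ties <- table(x)
    sigma2 <- (na * nb / 12) *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- (W - mu) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  }, numeric(1))
}

#' Cluster proportions per group
#'
#' For each cell group, the fraction of cells in each cluster out of all
#' cells of that group. Proportions within a group sum to exactly 1.
#'
#' @param cell_cluster Per-cell cluster labels.
#' @param cell_group Per-cell group labels (same length).
#' @return `data.frame` with columns `group`, `cluster`, `n`,
#'   `proportion`.
#' @export
cluster_proportions <- function(cell_cluster, cell_group) {
  if (length(cell_cluster) != length(cell_group)) {
    stop("label vectors differ in length")
  }
  if (length(cell_cluster) == 0L) stop("no cells")
  tab <- table(group = as.character(cell_group),
               cluster = as.character(cell_cluster))
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df)[names(df) == "Freq"] <- "n"
  totals <- stats::ave(df$n, df$group, FUN = sum)
  df$proportion <- df$n / totals
  df[order(df$group, df$cluster), c("group", "cluster", "n", "proportion")]
}

#' Hypergeometric overrepresentation test
#'
#' Upper-tail hypergeometric probability of observing at least the
#' realized overlap between a query gene list and each annotation set,
#' drawing `|query|` genes from the universe, with BH adjustment across
#' sets. The query must be a subset of the universe.
#'
#' @param query Character vector of query genes (e.g. significant
#'   markers).
#' @param universe Character vector of all testable genes.
#' @param sets Named list of character vectors (annotation gene sets).
#' @return `data.frame` with `set`, `set_size` (in universe), `overlap`,
#'   `p_val`, `p_val_adj`.
#' @export
hypergeometric_enrichment <- function(query, universe, sets) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  missing <- setdiff(query, universe)
  if (length(missing) > 0L) {
    stop("query genes absent from universe: ",
         paste(missing, collapse = ", "))
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("`sets` must be a named list")
  }
  N <- length(universe); q <- length(query)
  res <- lapply(names(sets), function(nm) {
    s <- intersect(unique(as.character(sets[[nm]])), universe)
    k <- length(intersect(query, s))
    # P(X >= k) for X ~ Hypergeom(white = |s|, black = N - |s|, drawn = q)
    p <- stats::phyper(k - 1L, length(s), N - length(s), q,
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), overlap = k, p_val = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_val_adj <- stats::p.adjust(out$p_val, method = "BH")
  out
}
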