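# QC-rule fidelity, normalization, rank-sum markers, proportions and the
# hypergeometric overrepresentation test.

make_qc_fixture <- function() {
  # 12 genes x 8 cells, hand-built so every criterion is exercised
  genes <- c("Gene1", "Gene2", "Gene3", "Gene4", "Gene5", "Gene6",
             "mt-Nd1", "mt-Co1", "Rps1", "Rpl2", "Rare1", "Rare2")
  counts <- matrix(10L, length(genes), 8,
                   dimnames = list(genes, paste0("c", 1:8)))
  counts["Rare1", ] <- 0L; counts["Rare1", 1] <- 3L      # detected in 1 cell
  counts["Rare2", ] <- 0L; counts["Rare2", 1:2] <- 1L    # detected in 2
  counts["mt-Nd1", ] <- 1L; counts["mt-Co1", ] <- 1L     # ~3% mito baseline
  counts["mt-Nd1", 3] <- 30L                              # cell 3: high mito
  count_matrix(counts, cell_group = rep(c("a", "b"), each = 4))
}

test_that("qc_filter applies gene filters then cell filters, per the rules", {
  cm <- make_qc_fixture()
  res <- qc_filter(cm, qc_params(min_features_per_cell = 5L))
  kept_genes <- res$matrix$gene_symbols
  # ribosomal genes excluded by prefix, low-detection genes by count
  expect_false(any(c("Rps1", "Rpl2", "Rare1", "Rare2") %in% kept_genes))
  expect_true(all(c("Gene1", "mt-Nd1") %in% kept_genes))
  # cell 3 exceeds the 5% mitochondrial cap
  expect_false("c3" %in% res$matrix$cell_ids)
  expect_equal(res$report$removed[res$report$criterion == "high_mito_cell"], 1)
})

test_that("planted low-feature and high-mito cells are removed at the stated thresholds", {
  set.seed(42)
  n_genes <- 300
  genes <- c(sprintf("G%03d", 1:290), sprintf("mt-%02d", 1:10))
  base <- matrix(rpois(n_genes * 40, 3) + 1L, n_genes, 40)  # dense, healthy
  # cell 1: 150 unique features only
  base[151:n_genes, 1] <- 0L
  base[1:150, 1] <- 1L
  # cell 2: 8% mito counts
  base[, 2] <- 2L
  mito_target <- round(0.08 * sum(base[, 2]) / (1 - 0.08) / 10)
  base[291:300, 2] <- as.integer(mito_target)
  cm <- count_matrix(base, gene_symbols = genes,
                     cell_ids = sprintf("c%02d", 1:40),
                     cell_group = rep("g", 40))
  res <- qc_filter(cm)
  expect_false("c01" %in% res$matrix$cell_ids)  # < 200 features
  expect_false("c02" %in% res$matrix$cell_ids)  # > 5% mito
  expect_true(all(sprintf("c%02d", 3:40) %in% res$matrix$cell_ids))
})

test_that("qc_filter matches an independent per-criterion loop oracle", {
  sm <- sample_matrix(matrix_spec(n_low_feature = 10L, n_high_count = 5L,
                                  n_high_mito = 5L, seed = 13))
  cm <- sm$matrix
  p <- qc_params()
  res <- qc_filter(cm, p)

  # oracle: dense loops over the raw matrix, same rule text
  dense <- as.matrix(cm$counts)
  genes <- cm$gene_symbols
  ribo <- grepl("^(rps|rpl)", tolower(genes))
  detected <- rowSums(dense > 0)
  keep_gene <- !ribo & detected >= 3
  dense <- dense[keep_gene, ]
  genes <- genes[keep_gene]
  mito <- grepl("^mt-", tolower(genes))
  keep_cell <- rep(TRUE, ncol(dense))
  totals <- colSums(dense)
  feats <- colSums(dense > 0)
  mfrac <- colSums(dense[mito, , drop = FALSE]) / totals
  fail_f <- feats < 200
  fail_m <- mfrac > 0.05
  fail_c <- rep(FALSE, ncol(dense))
  for (g in unique(cm$cell_group)) {
    sel <- cm$cell_group == g & !fail_f & !fail_m
    cap <- mean(totals[sel]) + 3 * sd(totals[sel])
    fail_c[cm$cell_group == g] <- totals[cm$cell_group == g] > cap
  }
  keep_cell <- !fail_f & !fail_m & !fail_c

  expect_identical(res$matrix$cell_ids, cm$cell_ids[keep_cell])
  expect_identical(res$matrix$gene_symbols, genes)
  # every planted failure removed, for the planted reason
  st <- res$cell_status
  planted <- sm$cell_truth$planted
  expect_true(all(!st$kept[planted != "ok"]))
  expect_true(all(st$fail_features[planted == "low_feature"]))
  expect_true(all(st$fail_counts_cap[planted == "high_count"]))
  expect_true(all(st$fail_mito[planted == "high_mito"]))
})

test_that("qc_filter is idempotent on a stable matrix and errors when empty", {
  sm <- sample_matrix(matrix_spec(seed = 5))
  once <- qc_filter(sm$matrix)
  twice <- qc_filter(once$matrix)
  expect_identical(twice$matrix$cell_ids, once$matrix$cell_ids)
  expect_identical(twice$matrix$gene_symbols, once$matrix$gene_symbols)

  tiny <- count_matrix(matrix(1L, 4, 3,
                              dimnames = list(paste0("g", 1:4),
                                              paste0("c", 1:3))),
                       cell_group = rep("x", 3))
  expect_error(suppressWarnings(qc_filter(tiny)), "no cells survive")
})

test_that("qc_filter warns and skips the mito criterion without mito genes", {
  set.seed(9)
  m <- matrix(rpois(300 * 20, 5) + 1L, 300, 20,
              dimnames = list(sprintf("G%03d", 1:300),
                              sprintf("c%02d", 1:20)))
  cm <- count_matrix(m, cell_group = rep("x", 20))
  expect_warning(res <- qc_filter(cm), "mitochondrial")
  expect_true(attr(res$report, "mito_criterion_skipped"))
  expect_identical(ncol(res$matrix$counts), 20L)
})

test_that("log normalization matches its definition", {
  counts <- Matrix::Matrix(matrix(c(0L, 10L, 0L, 90L, 0L, 0L), 3, 2,
                                  dimnames = list(paste0("g", 1:3),
                                                  c("c1", "c2"))),
                           sparse = TRUE)
  norm <- log_normalize(counts, 1e4)
  # zero counts stay zero
  expect_equal(norm[1, 1], 0)
  expect_equal(norm[3, 1], 0)
  expect_equal(norm[2, 2], 0)
  # a cell with a single expressed gene maps it to log(1 + scale factor)
  expect_equal(norm[2, 1], log1p(1e4))
  expect_equal(norm[1, 2], log1p(1e4))
  # loop oracle on a random matrix
  set.seed(14)
  m <- matrix(rpois(50, 4), 10, 5,
              dimnames = list(paste0("g", 1:10), paste0("c", 1:5)))
  n2 <- as.matrix(log_normalize(Matrix::Matrix(m, sparse = TRUE), 100))
  for (j in 1:5) for (i in 1:10) {
    expect_equal(n2[i, j], log1p(m[i, j] / sum(m[, j]) * 100))
  }
})

test_that("rank-sum statistic and p agree with exact enumeration on 8 cells", {
  # 2 groups x 4 cells, 5 genes, no ties
  set.seed(77)
  X <- matrix(c(1.2, 3.4, 2.2, 5.1, 0.3, 0.9, 0.1, 0.6,
                4.1, 4.9, 5.3, 6.0, 1.0, 2.0, 2.5, 3.3,
                0.4, 1.4, 2.4, 3.1, 0.2, 1.1, 2.1, 3.0,
                7.1, 6.2, 5.5, 4.4, 3.2, 2.6, 1.9, 0.8,
                2.9, 3.8, 1.8, 0.7, 4.6, 5.8, 6.6, 7.7), 5, 8, byrow = TRUE,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:8)))
  norm <- Matrix::Matrix(X, sparse = TRUE)
  res <- suppressWarnings(
    wilcoxon_markers(norm, 1:4, 5:8, marker_params(min_abs_logfc = 0)))

  combs <- utils::combn(8, 4)
  for (g in 1:5) {
    x <- X[g, ]
    W_obs <- sum(rank(x)[1:4]) - 4 * 5 / 2
    # exact permutation two-sided p for the rank-sum statistic
    Ws <- apply(combs, 2, function(ix) sum(rank(x)[ix]) - 10)
    p_exact <- mean(abs(Ws - 8) >= abs(W_obs - 8))
    p_wt <- stats::wilcox.test(x[1:4], x[5:8], exact = TRUE)$p.value
    expect_equal(p_exact, p_wt)  # enumeration agrees with the exact test
    # our normal approximation matches R's and tracks the exact p closely
    p_norm <- stats::wilcox.test(x[1:4], x[5:8], exact = FALSE,
                                 correct = FALSE)$p.value
    expect_equal(res$p_val[g], p_norm)
    # the tie-corrected normal approximation tracks the exact p at n = 8
    # only to the accuracy the approximation allows
    expect_lt(abs(res$p_val[g] - p_exact), 0.15)
  }
})

test_that("marker gating excludes small fold changes and identical groups", {
  set.seed(15)
  m <- matrix(rpois(200 * 40, 5), 200, 40,
              dimnames = list(sprintf("g%03d", 1:200),
                              sprintf("c%02d", 1:40)))
  norm <- log_normalize(Matrix::Matrix(m, sparse = TRUE))
  # identical groups (same cells on both sides): nothing significant
  same <- wilcoxon_markers(norm[, c(1:20, 1:20)], 1:20, 21:40)
  expect_identical(sum(same$significant), 0L)
  expect_true(all(abs(same$avg_logFC) < 1e-12))

  # a gene whose |logFC| is below the gate is never tested, however strong
  x <- norm
  x[1, 21:40] <- x[1, 21:40] + 0.05  # systematic but tiny shift
  res <- wilcoxon_markers(x, 1:20, 21:40)
  expect_false(res$tested[1])
  expect_true(is.na(res$p_val[1]))
  # BH is computed over tested genes only
  expect_identical(sum(!is.na(res$p_val_adj)), sum(res$tested))
})

test_that("cluster proportions sum to one per group and match a loop oracle", {
  expect_equal(cluster_proportions(rep("k1", 5), rep("g", 5))$proportion, 1)
  two <- cluster_proportions(rep(c("k1", "k2"), 10), rep("g", 20))
  expect_equal(two$proportion, c(0.5, 0.5))

  set.seed(16)
  cl <- sample(paste0("k", 1:4), 200, replace = TRUE)
  gr <- sample(c("ctrl", "plx"), 200, replace = TRUE)
  tab <- cluster_proportions(cl, gr)
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$proportion[i],
                 sum(cl == tab$cluster[i] & gr == tab$group[i]) /
                   sum(gr == tab$group[i]))
  }
  sums <- tapply(tab$proportion, tab$group, sum)
  expect_true(all(sums == 1))
})

test_that("hypergeometric enrichment reproduces the closed-form tail", {
  universe <- paste0("g", 1:20)
  sets <- list(hit = paste0("g", 1:5), none = paste0("g", 16:20))
  query <- paste0("g", c(1:4, 10))
  res <- hypergeometric_enrichment(query, universe, sets)
  # direct tail summation: P(X >= 4), |set|=5, universe 20, draw 5
  p_direct <- sum(vapply(4:5, function(k) {
    choose(5, k) * choose(15, 5 - k) / choose(20, 5)
  }, numeric(1)))
  expect_equal(res$p_val[res$set == "hit"], p_direct)
  # disjoint set -> upper tail at k = 0 is 1
  expect_equal(res$p_val[res$set == "none"],
               sum(vapply(0:5, function(k) {
                 choose(5, k) * choose(15, 5 - k) / choose(20, 5)
               }, numeric(1))))
  expect_equal(res$p_val[res$set == "none"], 1)
  # query = set = universe -> p = 1
  all_same <- hypergeometric_enrichment(universe, universe,
                                        list(s = universe))
  expect_equal(all_same$p_val, 1)
  expect_error(
    hypergeometric_enrichment(c("g1", "zz"), universe, sets), "zz")
})
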