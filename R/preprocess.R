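# Quality control, normalization, variable-gene selection, multi-resolution
# graph clustering and one-vs-rest rank-sum marker calling for gene x cell
# count matrices.

#' Filter low-quality cells
#'
#' A cell is kept iff `umi_min <= total UMI <= umi_max`, detected genes
#' `> min_genes`, and mitochondrial fraction `< max_mito_frac`.
#' Mitochondrial genes are recognized by a case-sensitive symbol prefix.
#' The UMI rule is exposed as a min/max pair so either direction of the
#' total-count guard can be enforced.
#'
#' @param counts Gene-by-cell count matrix (dense or sparse, with dimnames).
#' @param umi_max Upper total-UMI bound (doublet guard). Default 50000.
#' @param umi_min Lower total-UMI bound. Default 0 (disabled).
#' @param min_genes Cells must have strictly more detected genes than this.
#' @param max_mito_frac Cells must have a mitochondrial fraction strictly
#'   below this.
#' @param mito_prefix Symbol prefix identifying mitochondrial genes.
#' @return Character vector of kept cell ids (a subset of `colnames(counts)`).
#' @export
filter_cells <- function(counts, umi_max = 50000, umi_min = 0,
                         min_genes = 200, max_mito_frac = 0.25,
                         mito_prefix = "MT-") {
  counts <- as_count_matrix(counts)
  if (ncol(counts) == 0 || nrow(counts) == 0) stop("empty count matrix", call. = FALSE)
  stopifnot(umi_max > 0, min_genes > 0, max_mito_frac > 0)
  umi <- Matrix::colSums(counts)
  n_genes <- Matrix::colSums(counts > 0)
  mito <- startsWith(rownames(counts), mito_prefix)
  mito_frac <- if (any(mito)) {
    Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(umi, 1)
  } else {
    rep(0, ncol(counts))
  }
  keep <- umi >= umi_min & umi <= umi_max & n_genes > min_genes &
    mito_frac < max_mito_frac
  colnames(counts)[keep]
}

#' Library-size log-normalize counts
#'
#' `value = log(1 + count / libsize * scale)`. Zeros are preserved exactly,
#' so sparsity is untouched.
#'
#' @param counts Gene-by-cell count matrix.
#' @param scale Scale factor (default 1e4).
#' @return Sparse normalized matrix with the same dimnames.
#' @export
log_normalize <- function(counts, scale = 1e4) {
  counts <- as_count_matrix(counts)
  libsize <- Matrix::colSums(counts)
  if (any(libsize == 0)) {
    stop("zero library size: run filter_cells() first", call. = FALSE)
  }
  out <- counts
  # per-column scaling of the non-zero slots of the CsparseMatrix
  col_of <- rep(seq_len(ncol(counts)), diff(counts@p))
  out@x <- log1p(counts@x / libsize[col_of] * scale)
  out
}

#' Select highly variable genes
#'
#' Genes are binned into equal-frequency bins of mean expression; the
#' dispersion (variance / mean) is z-scored within each bin and the top `n`
#' genes by standardized dispersion are returned. Constant genes are never
#' selected. Ties are broken by gene order in the matrix, making the
#' selection deterministic.
#'
#' @param norm Normalized gene-by-cell matrix.
#' @param n Number of genes to return.
#' @param n_bins Number of mean-expression bins (default 20).
#' @return Character vector of `min(n, #non-constant genes)` gene symbols.
#' @export
select_hvg <- function(norm, n = 2000, n_bins = 20) {
  stopifnot(n >= 1, n <= nrow(norm))
  mu <- Matrix::rowMeans(norm)
  ex2 <- Matrix::rowMeans(norm^2)
  v <- (ex2 - mu^2) * ncol(norm) / max(1, ncol(norm) - 1)
  variable <- v > 1e-12
  if (!any(variable)) stop("all genes constant", call. = FALSE)
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- ggplot2::cut_number(rank(mu, ties.method = "first"),
                              n = min(n_bins, sum(variable)))
  z <- stats::ave(disp, bins, FUN = function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(rep(0, length(x)))
    (x - mean(x)) / s
  })
  z[!variable] <- -Inf
  ord <- order(-z, seq_along(z))
  sel <- ord[seq_len(min(n, sum(variable)))]
  rownames(norm)[sort(sel)]
}

#' Multi-resolution graph clustering
#'
#' Cells are embedded by PCA on scaled highly variable genes, connected in a
#' shared-nearest-neighbor graph (Jaccard-weighted kNN), and partitioned by
#' Leiden community detection under a modularity objective, once per
#' requested resolution. Deterministic given `seed`.
#'
#' @param norm Normalized gene-by-cell matrix.
#' @param resolutions Numeric vector of positive resolution parameters.
#' @param seed Integer seed.
#' @param n_pcs Number of principal components (default 30, capped by data).
#' @param k Neighbors for the kNN graph (default 15).
#' @param hvg_n Number of variable genes used for the embedding.
#' @return Tibble with a `cell` column and one integer label column
#'   `res_<r>` per resolution.
#' @export
cluster_multires <- function(norm, resolutions, seed = 1L, n_pcs = 30,
                             k = 15, hvg_n = 2000) {
  stopifnot(ncol(norm) >= 2, all(resolutions > 0))
  if (ncol(norm) <= k) stop("fewer cells than neighbors parameter", call. = FALSE)
  hv <- select_hvg(norm, n = min(hvg_n, nrow(norm)))
  x <- as.matrix(Matrix::t(norm[hv, , drop = FALSE]))
  x <- scale(x)
  x[!is.finite(x)] <- 0
  n_pcs <- min(n_pcs, ncol(x) - 1, nrow(x) - 1)
  pcs <- stats::prcomp(x, center = FALSE, scale. = FALSE, rank. = n_pcs)$x
  g <- snn_graph(pcs, k = k)
  out <- tibble::tibble(cell = colnames(norm))
  for (r in resolutions) {
    cl <- withr::with_seed(derive_seed(seed, paste0("leiden", r)), {
      igraph::cluster_leiden(g, objective_function = "modularity",
                             resolution = r, n_iterations = 10)
    })
    out[[sprintf("res_%g", r)]] <- as.integer(igraph::membership(cl))
  }
  out
}

# shared-nearest-neighbor graph with Jaccard edge weights
snn_graph <- function(emb, k = 15) {
  n <- nrow(emb)
  d <- as.matrix(stats::dist(emb))
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k + 1)]))  # incl. self
  adj <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k + 1),
    j = as.vector(t(nn)),
    x = 1, dims = c(n, n)
  )
  shared <- Matrix::tcrossprod(adj)
  jac <- shared / (2 * (k + 1) - shared)
  jac <- methods::as(jac, "CsparseMatrix")
  jac@x[jac@x < 1 / 15] <- 0  # prune weak links, Seurat-style
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' One-vs-rest rank-sum cluster markers
#'
#' Per cluster and gene: a two-sided Wilcoxon rank-sum test of the cluster's
#' cells versus all other cells (mid-ranks, normal approximation with tie and
#' continuity correction, matching `wilcox.test(correct = TRUE)`),
#' `log2FC = log2((mean(expm1(in)) + eps) / (mean(expm1(out)) + eps))`, the
#' fractions of expressing cells inside and outside, and Benjamini-Hochberg
#' adjustment within each cluster's family of tests.
#'
#' @param norm Normalized gene-by-cell matrix.
#' @param labels Cluster labels, one per cell (vector or factor).
#' @param eps Pseudocount in the fold-change ratio.
#' @param min_cells Clusters with fewer cells are skipped with a warning.
#' @return Tibble with columns `cluster`, `gene`, `log2fc`, `pct_in`,
#'   `pct_out`, `p`, `padj`.
#' @export
rank_markers <- function(norm, labels, eps = 1e-9, min_cells = 3) {
  stopifnot(ncol(norm) == length(labels))
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2) stop("need >= 2 clusters", call. = FALSE)
  small <- names(tab)[tab < min_cells]
  if (length(small)) {
    warning("skipping clusters with < ", min_cells, " cells: ",
            paste(small, collapse = ", "))
  }
  keep_cl <- setdiff(names(tab), small)
  if (length(keep_cl) < 2) stop("fewer than 2 usable clusters", call. = FALSE)

  keep_cells <- labels %in% keep_cl
  x <- as.matrix(norm[, keep_cells, drop = FALSE])
  labels <- labels[keep_cells]
  ranks <- t(apply(x, 1, rank))  # mid-ranks per gene
  # tie correction term per gene: sum(t^3 - t) over tied groups
  ties <- apply(x, 1, function(v) {
    tt <- tabulate(match(v, unique(v)))
    sum(tt^3 - tt)
  })
  expm1_x <- expm1(x)
  ind <- stats::model.matrix(~ 0 + factor(labels, levels = keep_cl))
  colnames(ind) <- keep_cl
  n1 <- colSums(ind)
  rank_sums <- ranks %*% ind                # gene x cluster
  mean_in <- (expm1_x %*% ind) %*% diag(1 / n1, length(n1))
  pct_in_m <- ((x > 0) %*% ind) %*% diag(1 / n1, length(n1))
  tot_expm1 <- rowSums(expm1_x)
  tot_pct <- rowSums(x > 0)
  n_used <- sum(n1)

  res <- purrr::map_dfr(seq_along(keep_cl), function(ci) {
    cl <- keep_cl[ci]
    n_in <- n1[[ci]]
    n_out <- n_used - n_in
    r1 <- rank_sums[, ci]
    u <- r1 - n_in * (n_in + 1) / 2
    mu_u <- n_in * n_out / 2
    sigma2 <- n_in * n_out / 12 *
      ((n_used + 1) - ties / (n_used * (n_used - 1)))
    z_num <- u - mu_u
    corr <- sign(z_num) * 0.5
    z <- (z_num - corr) / sqrt(pmax(sigma2, .Machine$double.eps))
    p <- pmin(1, 2 * stats::pnorm(-abs(z)))
    p[sigma2 <= 0] <- 1
    m_in <- mean_in[, ci]
    m_out <- (tot_expm1 - m_in * n_in) / n_out
    tibble::tibble(
      cluster = cl,
      gene = rownames(x),
      log2fc = as.numeric(log2((m_in + eps) / (m_out + eps))),
      pct_in = as.numeric(pct_in_m[, ci]),
      pct_out = as.numeric((tot_pct - pct_in_m[, ci] * n_in) / n_out),
      p = as.numeric(p),
      padj = as.numeric(stats::p.adjust(p, method = "BH"))
    )
  })
  res
}
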