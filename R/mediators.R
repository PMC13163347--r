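# Simplified ligand-receptor communication scoring with permutation
# significance, network signaling roles, and ridge drug-sensitivity
# imputation. The communication score is deliberately simple -- product of
# sender ligand mean and receiver receptor mean, multi-subunit complexes
# combined by their limiting (minimum) subunit -- with significance from
# label permutation; cofactor modulation is not modelled.

#' Ligand-receptor communication scores with permutation p-values
#'
#' For every ordered (sender, receiver) cluster pair and ligand-receptor
#' pair: `score = lig(sender) * rec(receiver)` where a complex's expression
#' in a cluster is the minimum of its subunit mean expressions (absent
#' subunits count as zero). Significance comes from `n_perm` global
#' permutations of the cell labels:
#' `p = (1 + #(permuted >= observed)) / (n_perm + 1)`.
#'
#' @param norm Normalized gene-by-cell matrix.
#' @param labels Cluster label per cell.
#' @param pairs Tibble from [read_lr_pairs()] (columns `pair`,
#'   `ligand_subunits`, `receptor_subunits` list-columns).
#' @param min_cells Clusters smaller than this are excluded (default 50).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return Tibble `sender`, `receiver`, `pair`, `score`, `p_value`.
#' @export
lr_communication <- function(norm, labels, pairs, min_cells = 50,
                             n_perm = 1000, seed = 1L) {
  stopifnot(ncol(norm) == length(labels))
  labels <- as.character(labels)
  tab <- table(labels)
  clusters <- sort(names(tab)[tab >= min_cells])
  if (length(clusters) < 2) {
    stop("need >= 2 clusters after the min_cells filter", call. = FALSE)
  }
  keep <- labels %in% clusters
  genes_needed <- unique(unlist(c(pairs$ligand_subunits,
                                  pairs$receptor_subunits)))
  present <- intersect(genes_needed, rownames(norm))
  usable <- vapply(seq_len(nrow(pairs)), function(i) {
    any(pairs$ligand_subunits[[i]] %in% present) &&
      any(pairs$receptor_subunits[[i]] %in% present)
  }, logical(1))
  if (any(!usable)) {
    message("pairs with no subunit present skipped: ",
            paste(pairs$pair[!usable], collapse = ", "))
  }
  pairs <- pairs[usable, , drop = FALSE]
  if (nrow(pairs) == 0) stop("no usable ligand-receptor pair", call. = FALSE)
  x <- as.matrix(norm[present, keep, drop = FALSE])
  lab <- labels[keep]

  cluster_means <- function(lab_vec) {
    ind <- stats::model.matrix(~ 0 + factor(lab_vec, levels = clusters))
    sweep(x %*% ind, 2, colSums(ind), "/")
  }
  complex_expr <- function(means, subunits) {
    # limiting-subunit semantics; absent subunits are zero expression
    vapply(seq_along(clusters), function(ci) {
      vals <- ifelse(subunits %in% rownames(means), means[match(
        subunits, rownames(means)), ci], 0)
      min(vals)
    }, double(1))
  }
  score_all <- function(lab_vec) {
    means <- cluster_means(lab_vec)
    rownames(means) <- present
    out <- array(0, c(nrow(pairs), length(clusters), length(clusters)))
    for (i in seq_len(nrow(pairs))) {
      lig <- complex_expr(means, pairs$ligand_subunits[[i]])
      rec <- complex_expr(means, pairs$receptor_subunits[[i]])
      out[i, , ] <- outer(lig, rec)
    }
    out
  }

  obs <- score_all(lab)
  exceed <- array(0L, dim(obs))
  withr::with_seed(derive_seed(seed, "lr_perm"), {
    for (b in seq_len(n_perm)) {
      perm <- score_all(sample(lab))
      exceed <- exceed + (perm >= obs)
    }
  })
  pmat <- (1 + exceed) / (n_perm + 1)
  grid <- expand.grid(pair_i = seq_len(nrow(pairs)),
                      sender = seq_along(clusters),
                      receiver = seq_along(clusters))
  tibble::tibble(
    sender = clusters[grid$sender],
    receiver = clusters[grid$receiver],
    pair = pairs$pair[grid$pair_i],
    score = obs[cbind(grid$pair_i, grid$sender, grid$receiver)],
    p_value = pmat[cbind(grid$pair_i, grid$sender, grid$receiver)]
  ) |>
    dplyr::arrange(.data$sender, .data$receiver, .data$pair)
}

#' Summarize significant interactions per cluster pair
#'
#' @param result Tibble from [lr_communication()].
#' @param p_max Significance threshold (default 0.05).
#' @return Tibble `sender`, `receiver`, `n_interactions`, `strength`
#'   (count and summed score of significant pairs; zeros when none).
#' @export
interaction_summary <- function(result, p_max = 0.05) {
  stopifnot(nrow(result) > 0)
  result |>
    dplyr::group_by(.data$sender, .data$receiver) |>
    dplyr::summarise(
      n_interactions = sum(.data$p_value < p_max),
      strength = sum(.data$score[.data$p_value < p_max]),
      .groups = "drop"
    )
}

#' Outgoing and incoming signaling strength per cluster
#'
#' Weighted out-strength (row sums) and in-strength (column sums) of a
#' directed interaction matrix; self-loops are kept unless
#' `exclude_self = TRUE`.
#'
#' @param mat Square non-negative weighted interaction matrix
#'   (senders in rows, receivers in columns).
#' @param exclude_self Drop the diagonal before summing (default FALSE).
#' @return Tibble `cluster`, `outgoing`, `incoming`.
#' @export
signaling_roles <- function(mat, exclude_self = FALSE) {
  m <- as.matrix(mat)
  stopifnot(nrow(m) == ncol(m))
  if (any(m < 0)) stop("negative interaction weights", call. = FALSE)
  if (exclude_self) diag(m) <- 0
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  tibble::tibble(cluster = ids, outgoing = unname(rowSums(m)),
                 incoming = unname(colSums(m)))
}

#' Ridge-regression drug-sensitivity imputation
#'
#' Per drug, ridge coefficients minimize `||y - X b||^2 + lambda ||b||^2`
#' over training cell lines, with features standardized on training
#' statistics; `lambda = "cv"` selects lambda by 10-fold cross-validated
#' mean squared error over a log-spaced grid.
#'
#' @param train_expr Cell-line-by-gene training expression matrix.
#' @param train_resp Cell-line-by-drug training response matrix.
#' @param test_expr Sample-by-gene expression matrix to impute for.
#' @param lambda `"cv"` or a non-negative number.
#' @param folds CV folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @param min_genes Minimum size of the shared gene space (default 100).
#' @return Tibble with `sample` plus one predicted-response column per drug.
#' @export
ridge_sensitivity <- function(train_expr, train_resp, test_expr,
                              lambda = "cv", folds = 10, seed = 1L,
                              min_genes = 100) {
  xtr <- as.matrix(train_expr)
  xte <- as.matrix(test_expr)
  y <- as.matrix(train_resp)
  if (is.null(colnames(y))) colnames(y) <- paste0("drug", seq_len(ncol(y)))
  shared <- intersect(colnames(xtr), colnames(xte))
  if (length(shared) < min_genes) {
    stop(sprintf("shared gene space too small (%d < %d)",
                 length(shared), min_genes), call. = FALSE)
  }
  xtr <- xtr[, shared, drop = FALSE]
  xte <- xte[, shared, drop = FALSE]
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2, stats::sd)
  ok <- sdv > 0
  xtr <- sweep(sweep(xtr[, ok, drop = FALSE], 2, mu[ok]), 2, sdv[ok], "/")
  xte <- sweep(sweep(xte[, ok, drop = FALSE], 2, mu[ok]), 2, sdv[ok], "/")
  n <- nrow(xtr)
  p <- ncol(xtr)
  fit_beta <- function(xx, yy, lam) {
    solve(crossprod(xx) + diag(lam, p), crossprod(xx, yy))
  }
  lambdas <- if (identical(lambda, "cv")) {
    if (n < folds) stop("fewer training lines than folds", call. = FALSE)
    10^seq(-3, 4, length.out = 30)
  } else {
    assert_scalar_number(lambda, "lambda", 0)
    lambda
  }
  preds <- matrix(NA_real_, nrow(xte), ncol(y),
                  dimnames = list(rownames(xte), colnames(y)))
  chosen <- stats::setNames(double(ncol(y)), colnames(y))
  fold_id <- withr::with_seed(derive_seed(seed, "ridge_cv"),
                              sample(rep_len(seq_len(folds), n)))
  for (d in seq_len(ncol(y))) {
    yd <- y[, d]
    ybar <- mean(yd)
    lam <- if (length(lambdas) > 1) {
      cv_err <- vapply(lambdas, function(l) {
        errs <- vapply(seq_len(folds), function(f) {
          tr <- fold_id != f
          b <- fit_beta(xtr[tr, , drop = FALSE], yd[tr] - mean(yd[tr]),
                        max(l, 1e-10))
          pred <- xtr[!tr, , drop = FALSE] %*% b + mean(yd[tr])
          mean((yd[!tr] - pred)^2)
        }, double(1))
        mean(errs)
      }, double(1))
      lambdas[[which.min(cv_err)]]
    } else {
      lambdas
    }
    chosen[[d]] <- lam
    b <- fit_beta(xtr, yd - ybar, max(lam, 0))
    preds[, d] <- xte %*% b + ybar
  }
  out <- tibble::as_tibble(preds)
  out <- dplyr::bind_cols(
    tibble::tibble(sample = rownames(xte) %||% as.character(seq_len(nrow(xte)))),
    out
  )
  attr(out, "lambda") <- chosen
  out
}

#' Correlation between gene expression and predicted sensitivity
#'
#' @param expression Numeric vector of per-sample expression.
#' @param sensitivity Numeric vector of predicted sensitivities.
#' @return Tibble `r`, `p_value`, `n`; `r` is `NA` when either vector has
#'   zero variance.
#' @export
expr_sensitivity_correlation <- function(expression, sensitivity) {
  stopifnot(length(expression) == length(sensitivity))
  n <- length(expression)
  if (n < 4) stop("need >= 4 samples", call. = FALSE)
  if (stats::sd(expression) == 0 || stats::sd(sensitivity) == 0) {
    message("zero-variance input; correlation undefined")
    return(tibble::tibble(r = NA_real_, p_value = NA_real_, n = n))
  }
  ct <- stats::cor.test(expression, sensitivity, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = n)
}
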