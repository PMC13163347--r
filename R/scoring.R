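# Signature and activity scoring engines: expression-bin-matched module
# scores, top-rank AUC activity, single-sample rank-weighted enrichment,
# univariate-linear-model TF activity, chi-square specificity ranking, and
# hypergeometric over-representation.

#' Control-bin-matched module score
#'
#' Genes are binned by average expression into `n_bins` equal-frequency
#' bins; for every signature gene, `n_ctrl` control genes are drawn from its
#' bin (without replacement where the bin allows, the gene itself excluded).
#' The score of a unit is the mean expression of the signature genes minus
#' the mean expression of the pooled control draw.
#'
#' @param norm Normalized gene-by-unit matrix (units are cells or samples).
#' @param genes Character vector, the signature.
#' @param n_bins Expression bins (default 25).
#' @param n_ctrl Control genes drawn per signature gene (default 100).
#' @param seed Integer seed for the control draw.
#' @return Named numeric vector of per-unit scores.
#' @export
module_score <- function(norm, genes, n_bins = 25, n_ctrl = 100, seed = 1L) {
  present <- intersect(genes, rownames(norm))
  if (length(present) == 0) stop("signature entirely absent from matrix",
                                 call. = FALSE)
  if (length(present) < 0.5 * length(genes)) {
    warning("fewer than 50% of signature genes present (",
            length(present), "/", length(genes), ")")
  }
  avg <- Matrix::rowMeans(norm)
  n_bins <- min(n_bins, nrow(norm))
  bins <- ggplot2::cut_number(rank(avg, ties.method = "first"), n = n_bins)
  bin_members <- split(rownames(norm), bins)
  ctrl <- withr::with_seed(derive_seed(seed, "module_score"), {
    unlist(lapply(present, function(gn) {
      pool <- setdiff(bin_members[[as.character(bins[[match(gn, rownames(norm))]])]],
                      gn)
      if (length(pool) == 0) return(character())
      sample(pool, min(n_ctrl, length(pool)), replace = FALSE)
    }), use.names = FALSE)
  })
  sig_mean <- Matrix::colMeans(norm[present, , drop = FALSE])
  ctrl_mean <- if (length(ctrl)) {
    # means respect draw multiplicity across signature genes
    Matrix::colSums(norm[unique(ctrl), , drop = FALSE] *
                      as.vector(table(factor(ctrl, levels = unique(ctrl))))) /
      length(ctrl)
  } else {
    rep(0, ncol(norm))
  }
  stats::setNames(as.numeric(sig_mean - ctrl_mean), colnames(norm))
}

#' Top-rank AUC activity score
#'
#' Per unit, genes are ranked by decreasing expression (ties broken by a
#' seeded random order); the recovery curve of signature genes within the
#' top `top_frac` of the ranking is integrated and normalized by its
#' maximum, giving an AUC in `[0, 1]`.
#'
#' @param norm Normalized gene-by-unit matrix.
#' @param genes Signature gene vector (must be a subset of the universe).
#' @param top_frac Fraction of the ranking integrated (default 0.05).
#' @param seed Integer seed for tie breaking.
#' @return Named numeric vector of per-unit AUCs.
#' @export
auc_score <- function(norm, genes, top_frac = 0.05, seed = 1L) {
  if (length(genes) > nrow(norm)) {
    stop("signature larger than the gene universe", call. = FALSE)
  }
  m <- floor(top_frac * nrow(norm))
  if (m < 2) stop("top_frac * n_genes must be >= 2", call. = FALSE)
  x <- as.matrix(norm)
  in_set <- rownames(x) %in% genes
  s <- sum(in_set)
  max_area <- sum(pmin(seq_len(m), s))
  withr::with_seed(derive_seed(seed, "auc_score"), {
    aucs <- apply(x, 2, function(v) {
      rk <- rank(-v, ties.method = "random")
      hit_ranks <- rk[in_set]
      y <- cumsum(tabulate(hit_ranks[hit_ranks <= m], nbins = m))
      sum(y) / max_area
    })
  })
  stats::setNames(as.numeric(aucs), colnames(norm))
}

#' Single-sample rank-weighted enrichment score
#'
#' Per sample, genes are ranked by decreasing expression; the enrichment
#' score is the sum over all ranks of the difference between the weighted
#' in-set ECDF (weights `|rank statistic|^alpha`) and the uniform
#' out-of-set ECDF. With `normalize = TRUE`, scores are divided by the
#' cohort-wide score range.
#'
#' @param expr Gene-by-sample expression matrix.
#' @param genes Signature gene vector (>= 2 genes must be present).
#' @param alpha Rank-weight exponent (default 0.25).
#' @param normalize Cohort-range normalization flag.
#' @return Named numeric vector of per-sample enrichment scores.
#' @export
ssgsea_score <- function(expr, genes, alpha = 0.25, normalize = FALSE) {
  x <- as.matrix(expr)
  if (nrow(x) < 2) stop("degenerate single-gene universe", call. = FALSE)
  in_set <- rownames(x) %in% genes
  if (sum(in_set) < 2) stop("fewer than 2 signature genes present", call. = FALSE)
  n <- nrow(x)
  es <- apply(x, 2, function(v) {
    ord <- order(v, decreasing = TRUE)
    hit <- in_set[ord]
    # rank statistic = n..1 down the ordering
    w <- (n:1)^alpha * hit
    p_in <- cumsum(w) / sum(w)
    p_out <- cumsum(!hit) / (n - sum(hit))
    sum(p_in - p_out)
  })
  if (normalize) {
    rng <- max(es) - min(es)
    if (rng > 0) es <- es / rng
  }
  stats::setNames(as.numeric(es), colnames(x))
}

#' Univariate-linear-model TF activity
#'
#' For every transcription factor, a unit's expression profile is regressed
#' on the TF's target-weight vector over the full gene universe (genes
#' outside the regulon carry weight 0); the activity is the slope t-value.
#' Regulons with fewer than `min_targets` targets present in the matrix are
#' dropped with a warning.
#'
#' @param expr Gene-by-unit expression matrix.
#' @param network Regulon tibble (`tf`, `target`, `weight`), as from
#'   [read_regulons()].
#' @param min_targets Minimum targets present per TF (default 5).
#' @return TF-by-unit matrix of t-values.
#' @export
ulm_activity <- function(expr, network, min_targets = 5) {
  stopifnot(all(c("tf", "target", "weight") %in% names(network)))
  x <- as.matrix(expr)
  g <- nrow(x)
  net <- network[network$target %in% rownames(x), , drop = FALSE]
  n_targets <- table(net$tf)
  keep <- names(n_targets)[n_targets >= min_targets]
  dropped <- setdiff(unique(network$tf), keep)
  if (length(dropped)) {
    warning("regulons with < ", min_targets, " targets dropped: ",
            paste(dropped, collapse = ", "))
  }
  if (length(keep) == 0) stop("no regulon large enough", call. = FALSE)
  w <- matrix(0, g, length(keep), dimnames = list(rownames(x), keep))
  net <- net[net$tf %in% keep, , drop = FALSE]
  w[cbind(match(net$target, rownames(x)), match(net$tf, keep))] <- net$weight
  if (any(apply(w, 2, stats::sd) == 0)) {
    stop("zero-variance weight vector", call. = FALSE)
  }
  yc <- x - matrix(colMeans(x), g, ncol(x), byrow = TRUE)
  wc <- w - matrix(colMeans(w), g, length(keep), byrow = TRUE)
  sxx <- colSums(wc^2)                      # per TF
  sxy <- t(wc) %*% yc                       # TF x unit
  syy <- colSums(yc^2)                      # per unit
  beta <- sxy / sxx
  rss <- outer(rep(1, length(keep)), syy) - beta * sxy
  rss <- pmax(rss, 0)
  se <- sqrt(rss / (g - 2) / sxx)
  tval <- beta / se
  tval[beta == 0 & rss == 0] <- 0           # flat unit: slope 0, t 0
  dimnames(tval) <- list(keep, colnames(x))
  tval
}

#' Chi-square specificity ranking of TFs
#'
#' Per TF, a group-by-(high/low) contingency table of unit-level activity
#' indicators is tested with Pearson's chi-square (no continuity
#' correction); TFs are returned sorted by statistic, largest first. TFs
#' with a zero margin are skipped.
#'
#' @param indicators Tidy tibble with columns `tf`, `group` and `high`
#'   (logical or 0/1), one row per (TF, unit).
#' @return Tibble `tf`, `statistic`, `df`, `p_value`, sorted by statistic.
#' @export
tf_specificity_rank <- function(indicators) {
  stopifnot(all(c("tf", "group", "high") %in% names(indicators)))
  out <- purrr::map_dfr(split(indicators, indicators$tf), function(d) {
    if (length(unique(d$group)) < 2) return(NULL)
    tab <- table(d$group, factor(as.integer(d$high), levels = 0:1))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NULL)
    chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    tibble::tibble(tf = d$tf[[1]], statistic = unname(chi$statistic),
                   df = unname(chi$parameter), p_value = chi$p.value)
  })
  dplyr::arrange(out, dplyr::desc(.data$statistic))
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric p-value of the overlap between a query gene
#' set and every collection set, restricted to a common universe, with
#' Benjamini-Hochberg q-values. Rows are retained iff `p < p_max` and
#' `q < q_max`, sorted by p.
#'
#' @param query Query gene vector (must be a subset of `universe`).
#' @param universe Background gene vector.
#' @param collections Named list of gene sets (e.g. from [read_gmt()]).
#' @param p_max,q_max Retention cutoffs (defaults 0.05 / 0.2).
#' @return Tibble `set`, `overlap`, `set_size`, `query_size`, `p_value`,
#'   `q_value`, `genes` (list-column of overlapping genes).
#' @export
hypergeom_enrich <- function(query, universe, collections,
                             p_max = 0.05, q_max = 0.2) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  query <- unique(query)
  if (!all(query %in% universe)) {
    stop("query must be a subset of the universe", call. = FALSE)
  }
  n_u <- length(universe)
  n_q <- length(query)
  rows <- purrr::map_dfr(names(collections), function(nm) {
    set <- intersect(unique(collections[[nm]]), universe)
    ov <- intersect(query, set)
    k <- length(ov)
    p <- stats::phyper(k - 1, length(set), n_u - length(set), n_q,
                       lower.tail = FALSE)
    tibble::tibble(set = nm, overlap = k, set_size = length(set),
                   query_size = n_q, p_value = p, genes = list(ov))
  })
  rows$q_value <- stats::p.adjust(rows$p_value, method = "BH")
  rows <- rows[rows$p_value < p_max & rows$q_value < q_max, , drop = FALSE]
  rows <- rows[order(rows$p_value), ]
  rows[, c("set", "overlap", "set_size", "query_size", "p_value",
           "q_value", "genes")]
}

#' Score a collection of regulon gene sets per sample
#'
#' Regulons here are small TF + ligand/receptor gene sets (often 2-3
#' genes). Rank-based enrichment is unstable at that size, so sets with
#' fewer than `min_es_size` genes are scored by their mean expression;
#' larger sets use [ssgsea_score()].
#'
#' @param expr Gene-by-sample expression matrix.
#' @param regulons Named list of gene vectors.
#' @param min_es_size Minimum set size for rank-based scoring (default 4).
#' @param alpha Passed to [ssgsea_score()].
#' @return Tibble with `patient` (sample ids) plus one score column per
#'   regulon.
#' @export
score_regulons <- function(expr, regulons, min_es_size = 4, alpha = 0.25) {
  x <- as.matrix(expr)
  out <- tibble::tibble(patient = colnames(x))
  for (nm in names(regulons)) {
    genes <- intersect(regulons[[nm]], rownames(x))
    if (length(genes) == 0) {
      warning("regulon '", nm, "' absent from matrix; skipped")
      next
    }
    out[[nm]] <- if (length(genes) < min_es_size) {
      as.numeric(colMeans(x[genes, , drop = FALSE]))
    } else {
      unname(ssgsea_score(x, genes, alpha = alpha))
    }
  }
  out
}
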