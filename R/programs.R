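# Gene-element (meta-program) discovery: marker-set collection across
# samples and resolutions, Jaccard similarity with greedy de-duplication,
# resampled consensus clustering with PAC model selection, recurrence-based
# signatures, per-cell state assignment and CNV aggregation by state.

#' Collect filtered marker sets across samples and resolutions
#'
#' Per (sample, resolution, cluster): mitochondrial-prefixed genes, genes
#' with `padj >= padj_max`, `log2fc <= 0`, or expressed in `<= min_pct` of
#' the cluster's cells are dropped; survivors are ranked by ascending
#' `padj`, ties by descending `log2fc`, and truncated to `top_n`.
#'
#' @param markers Marker tibble as from [rank_markers()], optionally with
#'   `sample` and `resolution` columns identifying the clustering run.
#' @param mito_prefix Mitochondrial symbol prefix.
#' @param padj_max Adjusted-p threshold (exclusive).
#' @param min_pct Minimum fraction of expressing cells (exclusive).
#' @param top_n Maximum genes per set.
#' @return Named list of ordered gene vectors; names are
#'   `sample.resolution.cluster` ids. Sets that end up empty are dropped
#'   with a message.
#' @export
collect_marker_sets <- function(markers, mito_prefix = "MT-",
                                padj_max = 0.05, min_pct = 0.2,
                                top_n = 200) {
  stopifnot(all(c("cluster", "gene", "log2fc", "pct_in", "padj") %in%
                  names(markers)))
  df <- tibble::as_tibble(markers)
  if (!"sample" %in% names(df)) df$sample <- "s1"
  if (!"resolution" %in% names(df)) df$resolution <- 1
  keep <- !startsWith(df$gene, mito_prefix) &
    df$padj < padj_max & df$log2fc > 0 & df$pct_in > min_pct
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$sample, df$resolution, df$cluster, df$padj, -df$log2fc), ]
  ids <- paste(df$sample, df$resolution, df$cluster, sep = ".")
  all_ids <- unique(ids)
  sets <- lapply(split(df$gene, factor(ids, levels = all_ids)), function(g) {
    utils::head(unique(g), top_n)
  })
  empty <- lengths(sets) == 0
  if (any(empty)) {
    message(sum(empty), " marker sets empty after filtering; dropped")
    sets <- sets[!empty]
  }
  sets
}

#' Jaccard similarity matrix over marker sets
#'
#' Sets with fewer than `min_size` genes are removed first; remaining sets
#' are greedily de-duplicated in input order (a set is dropped when its
#' Jaccard index with any earlier retained set exceeds `dedup_threshold`).
#'
#' @param sets Named list of gene vectors.
#' @param min_size Minimum set size.
#' @param dedup_threshold Redundancy threshold (exclusive).
#' @return List with `similarity` (symmetric matrix, unit diagonal) and
#'   `retained` (surviving set names).
#' @export
jaccard_matrix <- function(sets, min_size = 20, dedup_threshold = 0.95) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  sets <- sets[lengths(sets) >= min_size]
  if (length(sets) == 0) stop("all sets removed by the size filter", call. = FALSE)
  jac <- function(a, b) {
    i <- length(intersect(a, b))
    i / (length(a) + length(b) - i)
  }
  retained <- character()
  for (nm in names(sets)) {
    dup <- any(vapply(retained,
                      function(r) jac(sets[[r]], sets[[nm]]) > dedup_threshold,
                      logical(1)))
    if (!dup) retained <- c(retained, nm)
  }
  if (length(retained) == 0) stop("all sets removed", call. = FALSE)
  n <- length(retained)
  sim <- matrix(1, n, n, dimnames = list(retained, retained))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        sim[i, j] <- sim[j, i] <- jac(sets[[retained[i]]], sets[[retained[j]]])
      }
    }
  }
  list(similarity = sim, retained = retained)
}

pac_score <- function(consensus, window = c(0.1, 0.9)) {
  v <- consensus[upper.tri(consensus)]
  mean(v > window[[1]] & v < window[[2]])
}

#' Consensus clustering of marker-set similarity profiles
#'
#' Rows of the similarity matrix are the feature vectors. For each `k`,
#' `n_resamples` random subsamples of the rows are clustered by k-means
#' (optionally on L2-normalized profiles, the spherical option); the
#' consensus matrix records how often two sets co-cluster among resamples
#' containing both. `k` is chosen by the minimum proportion of ambiguous
#' clustering (PAC, fraction of consensus entries inside `pac_window`),
#' ties to the smaller `k`. Degenerate convention: when no `k` reaches an
#' unambiguous consensus (minimum PAC above `max_pac`) or the PAC profile
#' is flat (range below `flat_tol`) -- both symptoms of structureless
#' input -- the smallest `k` is returned. The final partition cuts an
#' average-linkage tree on `1 - consensus`.
#'
#' @param similarity Symmetric similarity matrix with unit diagonal
#'   (as from [jaccard_matrix()]).
#' @param k_range Candidate numbers of programs.
#' @param n_resamples Resamples per `k`.
#' @param subsample_frac Fraction of rows per resample.
#' @param seed Integer seed.
#' @param spherical L2-normalize profiles before k-means (default TRUE).
#' @param pac_window Lower/upper consensus bounds defining ambiguity.
#' @param flat_tol PAC range below which the profile counts as flat.
#' @param max_pac Ambiguity ceiling above which a minimum PAC does not
#'   support any clustering structure.
#' @return Object of class `consensus_programs`: list with `programs`
#'   (tibble `set`, `program`), `k`, `pac` (tibble `k`, `pac`) and
#'   `consensus` (matrix for the chosen `k`).
#' @export
consensus_programs <- function(similarity, k_range = 2:20, n_resamples = 50,
                               subsample_frac = 0.8, seed = 1L,
                               spherical = TRUE, pac_window = c(0.1, 0.9),
                               flat_tol = 0.01, max_pac = 0.5) {
  stopifnot(is.matrix(similarity), nrow(similarity) == ncol(similarity))
  if (max(abs(similarity - t(similarity))) > 1e-8 ||
      max(abs(diag(similarity) - 1)) > 1e-8) {
    stop("similarity must be symmetric with unit diagonal", call. = FALSE)
  }
  n <- nrow(similarity)
  ids <- rownames(similarity) %||% as.character(seq_len(n))
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range >= n)) {
    warning("k_range truncated to the number of sets minus one")
    k_range <- k_range[k_range < n]
  }
  stopifnot(length(k_range) >= 1, all(k_range >= 2))
  feat <- similarity
  if (spherical) {
    nrm <- sqrt(rowSums(feat^2))
    feat <- feat / pmax(nrm, .Machine$double.eps)
  }
  m <- max(2L, as.integer(round(subsample_frac * n)))
  consensus_list <- list()
  pac <- double(length(k_range))
  for (ki in seq_along(k_range)) {
    k <- k_range[[ki]]
    hits <- matrix(0, n, n)
    both <- matrix(0, n, n)
    withr::with_seed(derive_seed(seed, paste0("consensus", k)), {
      for (b in seq_len(n_resamples)) {
        idx <- sample.int(n, m)
        sub <- feat[idx, , drop = FALSE]
        n_distinct <- nrow(unique(sub))
        cl <- if (n_distinct <= k) {
          # degenerate: not enough distinct profiles to split
          rep(1L, length(idx))
        } else {
          suppressWarnings(
            stats::kmeans(sub, centers = k, nstart = 3, iter.max = 50)$cluster
          )
        }
        same <- outer(cl, cl, "==") * 1
        hits[idx, idx] <- hits[idx, idx] + same
        both[idx, idx] <- both[idx, idx] + 1
      }
    })
    cons <- ifelse(both > 0, hits / both, 0)
    diag(cons) <- 1
    dimnames(cons) <- list(ids, ids)
    consensus_list[[as.character(k)]] <- cons
    pac[[ki]] <- pac_score(cons, pac_window)
  }
  k_chosen <- if (max(pac) - min(pac) < flat_tol || min(pac) > max_pac) {
    k_range[[1]]
  } else {
    k_range[[which.min(pac)]]  # which.min ties to the smaller k
  }
  cons <- consensus_list[[as.character(k_chosen)]]
  hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
  cl <- stats::cutree(hc, k = k_chosen)
  programs <- tibble::tibble(set = ids,
                             program = sprintf("GE%d", unname(cl)))
  structure(list(programs = programs, k = k_chosen,
                 pac = tibble::tibble(k = k_range, pac = pac),
                 consensus = cons),
            class = "consensus_programs")
}

#' Print a `consensus_programs` summary
#' @param x Object to print.
#' @param ... Unused.
#' @method print consensus_programs
#' @export
print.consensus_programs <- function(x, ...) {
  cat(sprintf("consensus_programs: %d sets in %d programs (PAC-selected k)\n",
              nrow(x$programs), x$k))
  print(table(x$programs$program))
  invisible(x)
}

#' @describeIn consensus_programs Tidy the set-to-program assignment.
#' @param x A `consensus_programs` object.
#' @param ... Unused.
#' @method tidy consensus_programs
#' @export
tidy.consensus_programs <- function(x, ...) x$programs

#' Recurrence-based program signatures
#'
#' Within each program, genes are ranked by the fraction of member marker
#' sets that contain them; genes with recurrence `>= min_recurrence` are
#' retained, capped at `top_n` (ties broken alphabetically).
#'
#' @param programs A `consensus_programs` object or a tibble
#'   (`set`, `program`).
#' @param sets The named list of marker sets the programs were built from.
#' @param min_recurrence Minimum member-set fraction.
#' @param top_n Signature size cap.
#' @return Named list of signature gene vectors (one per program). Programs
#'   with empty signatures are kept as zero-length vectors with a warning.
#' @export
program_signatures <- function(programs, sets, min_recurrence = 0.25,
                               top_n = 50) {
  if (inherits(programs, "consensus_programs")) programs <- programs$programs
  stopifnot(all(c("set", "program") %in% names(programs)),
            all(programs$set %in% names(sets)))
  out <- lapply(split(programs$set, programs$program), function(members) {
    genes <- unlist(lapply(sets[members], unique), use.names = FALSE)
    rec <- table(genes) / length(members)
    rec <- rec[rec >= min_recurrence]
    rec <- rec[order(-rec, names(rec))]
    utils::head(names(rec), top_n)
  })
  empty <- lengths(out) == 0
  if (any(empty)) {
    warning("programs with empty signatures: ",
            paste(names(out)[empty], collapse = ", "))
  }
  out
}

#' Assign each cell its dominant program state
#'
#' Row-wise argmax over per-cell program scores; exact ties go to the
#' lexicographically smallest program id.
#'
#' @param scores Data frame with a `cell` column and one score column per
#'   program, or a cells-by-programs matrix with rownames.
#' @return Tibble with `cell` and `state`.
#' @export
assign_states <- function(scores) {
  if (is.data.frame(scores)) {
    stopifnot("cell" %in% names(scores))
    cells <- as.character(scores$cell)
    x <- as.matrix(scores[, setdiff(names(scores), "cell"), drop = FALSE])
  } else {
    x <- as.matrix(scores)
    cells <- rownames(x) %||% as.character(seq_len(nrow(x)))
  }
  if (any(!is.finite(x) & is.na(x))) {
    if (any(rowSums(!is.na(x)) == 0)) stop("all-missing score row", call. = FALSE)
  }
  ord <- order(colnames(x))
  x <- x[, ord, drop = FALSE]
  idx <- apply(x, 1, function(row) which(row == max(row, na.rm = TRUE))[[1]])
  tibble::tibble(cell = cells, state = colnames(x)[idx])
}

#' Aggregate copy-number signal by program state
#'
#' Arithmetic mean of the centered CNV signal of each gene within each
#' state; positive means flag amplification, negative means deletion. The
#' five most amplified and five most deleted genes per state are reported.
#'
#' @param cnv Genes-by-cells matrix of centered CNV values.
#' @param states Data frame (`cell`, `state`) as from [assign_states()], or
#'   a named vector.
#' @return List with `means` (long tibble: `state`, `gene`, `mean_cnv`) and
#'   `top` (tibble of top amplified/deleted genes per state).
#' @export
aggregate_cnv <- function(cnv, states) {
  x <- as.matrix(cnv)
  if (!all(is.finite(x))) stop("non-finite CNV values", call. = FALSE)
  if (is.data.frame(states)) {
    st <- stats::setNames(as.character(states$state), as.character(states$cell))
  } else {
    st <- states
  }
  missing <- setdiff(colnames(x), names(st))
  if (length(missing)) stop("states do not cover all cells", call. = FALSE)
  st <- st[colnames(x)]
  means <- purrr::map_dfr(sort(unique(st)), function(s) {
    cols <- which(st == s)
    tibble::tibble(state = s, gene = rownames(x),
                   mean_cnv = unname(rowMeans(x[, cols, drop = FALSE])))
  })
  top <- means |>
    dplyr::group_by(.data$state) |>
    dplyr::arrange(dplyr::desc(.data$mean_cnv), .by_group = TRUE) |>
    dplyr::summarise(
      amplified = list(utils::head(.data$gene[.data$mean_cnv > 0], 5)),
      deleted = list(utils::head(rev(.data$gene[.data$mean_cnv < 0]), 5)),
      .groups = "drop"
    )
  list(means = means, top = top)
}
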