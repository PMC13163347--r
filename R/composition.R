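# Patient-level composition analytics: normalized subpopulation frequencies,
# innate/adaptive immune balance, Ro/e tissue-preference ratios,
# correlation-based co-occurrence module (CM) discovery, and dominant-module
# assignment per patient.

#' Patient-by-subpopulation composition matrix
#'
#' Normalized frequency of each subpopulation per patient, computed after
#' excluding cells labelled `unknown_label`. Patients left with no counted
#' cells are dropped with a warning.
#'
#' @param cell_meta Data frame with one row per cell.
#' @param level Name of the column holding the subpopulation label.
#' @param patient_col Name of the patient id column.
#' @param unknown_label Label marking unclassified cells (excluded before
#'   closure). Default `"unknown"`.
#' @return Tibble with a `patient` column and one frequency column per
#'   subpopulation; rows sum to 1.
#' @export
composition_from_cells <- function(cell_meta, level,
                                   patient_col = "patient",
                                   unknown_label = "unknown") {
  stopifnot(is.data.frame(cell_meta), level %in% names(cell_meta),
            patient_col %in% names(cell_meta))
  df <- tibble::tibble(
    patient = as.character(cell_meta[[patient_col]]),
    subpop = as.character(cell_meta[[level]])
  )
  counted <- df$subpop != unknown_label
  dropped <- setdiff(unique(df$patient), unique(df$patient[counted]))
  if (length(dropped)) {
    warning("patients with only '", unknown_label, "' cells dropped: ",
            paste(dropped, collapse = ", "))
  }
  df <- df[counted, , drop = FALSE]
  wide <- df |>
    dplyr::count(.data$patient, .data$subpop) |>
    dplyr::group_by(.data$patient) |>
    dplyr::mutate(freq = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select(!"n") |>
    tidyr::pivot_wider(names_from = "subpop", values_from = "freq",
                       values_fill = 0)
  wide[, c("patient", sort(setdiff(names(wide), "patient")))]
}

#' Innate versus adaptive immune balance
#'
#' Innate immunity is represented by myeloid cells, adaptive immunity by
#' T and B cells. Per patient, the two proportions are normalized over the
#' patient's immune cells; when a grouping column is given, Welch two-sample
#' t-tests compare the innate proportion between every pair of groups.
#'
#' @param cell_meta Data frame with one row per cell.
#' @param lineage_col Column holding lineage labels.
#' @param innate_lineages Lineage labels counted as innate (myeloid).
#' @param adaptive_lineages Lineage labels counted as adaptive (T + B).
#' @param patient_col Patient id column.
#' @param group_col Optional column defining patient groups to compare.
#' @return List with `proportions` (tibble: patient, innate, adaptive,
#'   group if given) and `tests` (tibble of pairwise Welch t-tests, empty
#'   when no group is given).
#' @export
immune_balance <- function(cell_meta, lineage_col = "lineage",
                           innate_lineages = "Myeloid",
                           adaptive_lineages = c("T", "B"),
                           patient_col = "patient", group_col = NULL) {
  stopifnot(lineage_col %in% names(cell_meta))
  lin <- as.character(cell_meta[[lineage_col]])
  cls <- dplyr::case_when(
    lin %in% innate_lineages ~ "innate",
    lin %in% adaptive_lineages ~ "adaptive",
    TRUE ~ NA_character_
  )
  df <- tibble::tibble(patient = as.character(cell_meta[[patient_col]]),
                       class = cls)
  df <- df[!is.na(df$class), , drop = FALSE]
  if (nrow(df) == 0) stop("no immune cells found", call. = FALSE)
  props <- df |>
    dplyr::count(.data$patient, .data$class) |>
    dplyr::group_by(.data$patient) |>
    dplyr::mutate(prop = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select(!"n") |>
    tidyr::pivot_wider(names_from = "class", values_from = "prop",
                       values_fill = 0)
  for (col in c("innate", "adaptive")) {
    if (!col %in% names(props)) props[[col]] <- 0
  }
  props <- props[, c("patient", "innate", "adaptive")]
  tests <- tibble::tibble(group1 = character(), group2 = character(),
                          statistic = double(), p_value = double())
  if (!is.null(group_col)) {
    stopifnot(group_col %in% names(cell_meta))
    grp <- cell_meta |>
      dplyr::distinct(patient = as.character(.data[[patient_col]]),
                      group = as.character(.data[[group_col]]))
    props <- dplyr::left_join(props, grp, by = "patient")
    groups <- sort(unique(props$group))
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    tests <- purrr::map_dfr(pairs, function(pr) {
      a <- props$innate[props$group == pr[[1]]]
      b <- props$innate[props$group == pr[[2]]]
      if (length(a) < 2 || length(b) < 2) {
        return(tibble::tibble(group1 = pr[[1]], group2 = pr[[2]],
                              statistic = NA_real_, p_value = NA_real_))
      }
      tt <- stats::t.test(a, b)
      tibble::tibble(group1 = pr[[1]], group2 = pr[[2]],
                     statistic = unname(tt$statistic),
                     p_value = tt$p.value)
    })
  }
  list(proportions = props, tests = tests)
}

#' Ro/e observed-over-expected preference ratio
#'
#' For a contingency table of cell counts (e.g. subpopulation by driver
#' subtype), `Ro/e(i, j) = O(i, j) / E(i, j)` with
#' `E = row_total * col_total / grand_total`. Values above 1 flag preference
#' of row category i for column category j. Significance of the whole table
#' comes from Pearson's chi-square test. Entries with a zero margin are
#' reported as missing, never as 0.
#'
#' @param cell_meta Data frame with one row per cell (or per observation).
#' @param row_level,col_level Column names defining the table rows/columns.
#' @return Long tibble with columns named after `row_level` and `col_level`
#'   plus `observed`, `expected`, `roe`; attributes `statistic`, `df` and
#'   `p_value` carry the chi-square test of the table.
#' @export
roe <- function(cell_meta, row_level, col_level) {
  stopifnot(row_level %in% names(cell_meta), col_level %in% names(cell_meta))
  tab <- table(as.character(cell_meta[[row_level]]),
               as.character(cell_meta[[col_level]]))
  if (sum(tab) == 0) stop("empty contingency table", call. = FALSE)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  expected <- outer(rs, cs) / sum(tab)
  ratio <- ifelse(expected > 0, tab / expected, NA_real_)
  chi <- if (nrow(tab) > 1 && ncol(tab) > 1 && all(rs > 0) && all(cs > 0)) {
    suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  } else {
    list(statistic = NA_real_, parameter = NA_real_, p.value = NA_real_)
  }
  out <- tibble::as_tibble(as.data.frame(as.table(ratio),
                                         stringsAsFactors = FALSE))
  names(out) <- c(row_level, col_level, "roe")
  out$observed <- as.vector(tab)
  out$expected <- as.vector(expected)
  out <- out[, c(row_level, col_level, "observed", "expected", "roe")]
  attr(out, "statistic") <- unname(chi$statistic)
  attr(out, "df") <- unname(chi$parameter)
  attr(out, "p_value") <- unname(chi$p.value)
  class(out) <- c("roe_table", class(out))
  out
}

#' Co-occurrence cellular modules from a composition matrix
#'
#' Pairwise Pearson correlations between subpopulation frequencies across
#' patients are converted to the distance `1 - r` and clustered
#' agglomeratively with Ward linkage (`ward.D2`); the tree is cut into `k`
#' modules `CM1..CMk`. Correlation p-values use
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`. `1 - r` (not `1 - |r|`) keeps
#' anti-correlated subpopulations in different modules. With `k = "auto"`
#' the cut maximizing the mean silhouette width over `k in 2..10` is chosen.
#'
#' @param comp Composition tibble from [composition_from_cells()] or
#'   [simulate_composition()] (a `patient` column plus frequency columns).
#' @param k Number of modules, or `"auto"`.
#' @param linkage Hierarchical linkage method (default `"ward.D2"`).
#' @return An object of class `cm_partition`: list with `partition` (tibble
#'   `subpop`, `module`), `correlation`, `p_value`, `padj` matrices, the
#'   `hclust` tree and `k`.
#' @export
cooccurrence_modules <- function(comp, k = 5, linkage = "ward.D2") {
  stopifnot(is.data.frame(comp), "patient" %in% names(comp))
  x <- as.matrix(comp[, setdiff(names(comp), "patient"), drop = FALSE])
  if (nrow(x) < 3) stop("need >= 3 patients", call. = FALSE)
  zv <- apply(x, 2, stats::sd) == 0
  if (any(zv)) {
    warning("zero-variance subpopulations excluded: ",
            paste(colnames(x)[zv], collapse = ", "))
    x <- x[, !zv, drop = FALSE]
  }
  n <- nrow(x)
  r <- stats::cor(x)
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA
  padj <- matrix(stats::p.adjust(p, method = "BH"), nrow(p), ncol(p),
                 dimnames = dimnames(p))
  hc <- stats::hclust(stats::as.dist(1 - r), method = linkage)
  if (identical(k, "auto")) {
    ks <- 2:min(10, ncol(x) - 1)
    sil <- vapply(ks, function(kk) {
      cl <- stats::cutree(hc, k = kk)
      mean(cluster::silhouette(cl, stats::as.dist(1 - r))[, 3])
    }, double(1))
    k <- ks[[which.max(sil)]]
  }
  if (k > ncol(x)) stop("k exceeds the number of clustered subpopulations",
                        call. = FALSE)
  cl <- stats::cutree(hc, k = k)
  partition <- tibble::tibble(subpop = names(cl),
                              module = sprintf("CM%d", unname(cl)))
  structure(list(partition = partition, correlation = r, p_value = p,
                 padj = padj, tree = hc, k = as.integer(k)),
            class = "cm_partition")
}

#' Print a `cm_partition` summary
#' @param x Object to print.
#' @param ... Unused.
#' @method print cm_partition
#' @export
print.cm_partition <- function(x, ...) {
  cat(sprintf("cm_partition: %d subpopulations in %d modules\n",
              nrow(x$partition), x$k))
  print(table(x$partition$module))
  invisible(x)
}

#' @describeIn cooccurrence_modules Tidy the module partition.
#' @param x A `cm_partition`.
#' @param ... Unused.
#' @method tidy cm_partition
#' @export
tidy.cm_partition <- function(x, ...) x$partition

#' Dominant cellular module per patient
#'
#' Member-subpopulation frequencies are summed per module, renormalized
#' across modules, and the module with the highest share is the patient's
#' dominant TIME type. Exact ties go to the lexicographically smallest
#' module id.
#'
#' @param comp Composition tibble (`patient` column + frequency columns).
#' @param partition A `cm_partition` or a two-column data frame
#'   (`subpop`, `module`).
#' @return Tibble with `patient`, `module` (dominant) and `share` (the
#'   renormalized dominant-module share).
#' @export
dominant_module <- function(comp, partition) {
  if (inherits(partition, "cm_partition")) partition <- partition$partition
  stopifnot(all(c("subpop", "module") %in% names(partition)))
  subpops <- setdiff(names(comp), "patient")
  missing <- setdiff(subpops, partition$subpop)
  if (length(missing)) stop("partition does not cover: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  x <- as.matrix(comp[, subpops, drop = FALSE])
  modules <- sort(unique(partition$module))
  sums <- vapply(modules, function(m) {
    cols <- partition$subpop[partition$module == m]
    cols <- intersect(cols, subpops)
    if (length(cols)) rowSums(x[, cols, drop = FALSE]) else rep(0, nrow(x))
  }, double(nrow(x)))
  sums <- matrix(sums, nrow = nrow(x), dimnames = list(NULL, modules))
  tot <- rowSums(sums)
  if (any(tot == 0)) stop("patient with all-zero module sums", call. = FALSE)
  shares <- sums / tot
  # ties resolved to the lexicographically smallest module id: max.col on
  # the reversed column order picks the first of the sorted names
  idx <- apply(shares, 1, function(row) which(row == max(row))[[1]])
  tibble::tibble(
    patient = comp$patient,
    module = modules[idx],
    share = shares[cbind(seq_len(nrow(shares)), idx)]
  )
}
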