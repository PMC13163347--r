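# Readers and writers for the plain-text formats the pipeline exchanges:
# 10x-style MTX triplets, dense CSV count matrices, GMT gene-set files,
# regulon and ligand-receptor tables, survival CSV.

#' Read a gene-by-cell count matrix
#'
#' Accepts either a directory containing a 10x-style triplet
#' (`matrix.mtx`, `features.tsv`, `barcodes.tsv`) or a dense CSV file whose
#' first column holds gene symbols and whose remaining columns are cells.
#' Symbols and barcodes are preserved verbatim and never case-mapped.
#'
#' @param path Directory (MTX triplet) or CSV file path.
#' @return A sparse `dgCMatrix` with gene rownames and cell colnames.
#' @export
read_counts <- function(path) {
  stopifnot(is.character(path), length(path) == 1)
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    feat <- file.path(path, "features.tsv")
    bc <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, feat, bc)) {
      if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
    }
    m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
    features <- readr::read_tsv(feat, col_names = FALSE, show_col_types = FALSE,
                                progress = FALSE)
    barcodes <- readr::read_tsv(bc, col_names = FALSE, show_col_types = FALSE,
                                progress = FALSE)
    if (nrow(features) != nrow(m)) {
      stop(sprintf("features.tsv has %d rows but matrix has %d rows",
                   nrow(features), nrow(m)), call. = FALSE)
    }
    if (nrow(barcodes) != ncol(m)) {
      stop(sprintf("barcodes.tsv has %d rows but matrix has %d columns",
                   nrow(barcodes), ncol(m)), call. = FALSE)
    }
    rownames(m) <- features[[1]]
    colnames(m) <- barcodes[[1]]
    as_count_matrix(m)
  } else if (file.exists(path)) {
    df <- utils::read.csv(path, check.names = FALSE, row.names = 1)
    as_count_matrix(as.matrix(df))
  } else {
    stop("path does not exist: ", path, call. = FALSE)
  }
}

#' Write a count matrix as a 10x-style MTX triplet
#'
#' @param counts Gene-by-cell matrix (dense or sparse) with dimnames.
#' @param dir Output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_counts_10x <- function(counts, dir) {
  counts <- as_count_matrix(counts)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble::tibble(x = rownames(counts)),
                   file.path(dir, "features.tsv"), col_names = FALSE)
  readr::write_tsv(tibble::tibble(x = colnames(counts)),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  invisible(dir)
}

#' Read a GMT gene-set collection
#'
#' Each tab-separated line is `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate genes within a set are dropped with a warning; empty sets are
#' rejected with the offending line number.
#'
#' @param path GMT file path.
#' @return Named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path)
    return(stats::setNames(list(), character()))
  }
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop(sprintf("malformed GMT line %d (needs name, description, >=1 gene)", i),
           call. = FALSE)
    }
    genes <- parts[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) {
      stop(sprintf("empty gene set on GMT line %d", i), call. = FALSE)
    }
    if (anyDuplicated(genes)) {
      warning(sprintf("duplicate genes in set '%s' deduplicated", parts[[1]]))
      genes <- unique(genes)
    }
    sets[[parts[[1]]]] <- genes
  }
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets Named list of character gene vectors.
#' @param path Output file path.
#' @param description Description field, recycled across sets.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a ligand-receptor pair table
#'
#' CSV with columns `pair`, `ligand` and `receptor`; multi-subunit complexes
#' are pipe-separated (e.g. `ITGA6|ITGB4`).
#'
#' @param path CSV file path.
#' @return Tibble with list-columns `ligand_subunits`, `receptor_subunits`.
#' @export
read_lr_pairs <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("pair", "ligand", "receptor") %in% names(df)))
  tibble::tibble(
    pair = df$pair,
    ligand_subunits = strsplit(df$ligand, "|", fixed = TRUE),
    receptor_subunits = strsplit(df$receptor, "|", fixed = TRUE)
  )
}

#' Read a regulon network table
#'
#' CSV with columns `tf`, `target`, `weight`. Duplicate (tf, target) edges
#' are rejected.
#'
#' @param path CSV file path.
#' @return Tibble with columns `tf`, `target`, `weight`.
#' @export
read_regulons <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("tf", "target", "weight") %in% names(df)))
  if (anyDuplicated(df[, c("tf", "target")])) {
    stop("duplicate (tf, target) pairs in regulon table", call. = FALSE)
  }
  if (!all(is.finite(df$weight))) stop("non-finite regulon weights", call. = FALSE)
  tibble::as_tibble(df[, c("tf", "target", "weight")])
}

#' Read a survival table
#'
#' CSV with at least `patient`, `time`, `event`; extra covariate columns
#' (age, stage, sex, ...) are carried through.
#'
#' @param path CSV file path.
#' @return Tibble of survival records.
#' @export
read_survival <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_survival(df)
}

validate_survival <- function(df) {
  stopifnot(all(c("patient", "time", "event") %in% names(df)))
  if (anyDuplicated(df$patient)) stop("duplicate patient ids", call. = FALSE)
  if (any(df$time <= 0)) stop("non-positive survival times", call. = FALSE)
  if (!all(df$event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  tibble::as_tibble(df)
}
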