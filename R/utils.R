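# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from a global seed
#'
#' One global seed governs a whole run; each stochastic stage draws its own
#' sub-seed so stages are independently reproducible. Kept below 2^31 - 1.
#'
#' @param seed Global integer seed.
#' @param stage Character stage name.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  # cheap string hash, stable across platforms
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483647L)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a finite number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

# coerce a counts input (matrix / dgCMatrix / data.frame) to dgCMatrix
as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(counts, "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix must carry gene rownames and cell colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("duplicate cell ids", call. = FALSE)
  if (any(counts@x < 0)) stop("negative counts", call. = FALSE)
  counts
}

# significance stars used throughout figure-style tables
p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}
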