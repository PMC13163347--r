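# Synthetic cohort generator. Produces the three data layers the analysis
# consumes -- patient x subpopulation composition with planted co-occurring
# modules, negative-binomial counts with planted overexpressed gene programs,
# and survival times driven by planted regulon coefficients -- together with
# the ground truth needed for recovery tests.

#' Configuration for a synthetic cohort
#'
#' Defaults describe the reference simulation exercised throughout the test
#' suite: 200 patients over 30 subpopulations grouped into 5 co-occurrence
#' modules (latent within-module correlation 0.8, logistic-normal noise sd
#' 0.1), 3,000 cancer cells across 10 pseudo-samples expressing 5 planted
#' 60-gene programs at log-fold effect ln(4) over a 1,000-gene universe, and
#' exponential survival with independent censoring.
#'
#' @param n_patients Number of patients.
#' @param subtype_labels Named numeric vector of driver-subtype proportions
#'   (must sum to 1); patients are assigned subtypes by these proportions.
#' @param n_subpops Number of cell subpopulations (>= 2).
#' @param n_modules Number of planted co-occurrence modules (>= 2);
#'   subpopulations are dealt round-robin into modules.
#' @param within_module_corr Latent Gaussian correlation shared by
#'   subpopulations of the same module, in `[0, 1)`.
#' @param composition_noise_sd Sd of independent logistic-normal noise added
#'   on top of the module factors.
#' @param n_cells Total cancer cells.
#' @param n_samples Number of pseudo-samples the cells are spread over.
#' @param n_genes Size of the gene universe.
#' @param n_programs Number of planted expression programs.
#' @param genes_per_program Genes per planted program (disjoint sets).
#' @param program_log_fc Natural-log fold effect applied to a program's genes
#'   in cells of that program.
#' @param libsize_log_mean,libsize_log_sd Log-normal library-size parameters.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); `0` gives the Poisson limit.
#' @param baseline_rate Baseline event rate (events per time unit, > 0).
#' @param censor_rate Independent exponential censoring rate (>= 0; 0 means
#'   no censoring).
#' @param seed Integer seed governing the whole cohort; stages derive their
#'   own sub-seeds via [derive_seed()].
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 200,
                          subtype_labels = c(EGFR = 0.3, `EGFR-BM` = 0.2,
                                             KRAS = 0.25, ROS1 = 0.15,
                                             ALK = 0.1),
                          n_subpops = 30,
                          n_modules = 5,
                          within_module_corr = 0.8,
                          composition_noise_sd = 0.1,
                          n_cells = 3000,
                          n_samples = 10,
                          n_genes = 1000,
                          n_programs = 5,
                          genes_per_program = 60,
                          program_log_fc = log(4),
                          libsize_log_mean = log(5000),
                          libsize_log_sd = 0.3,
                          nb_dispersion = 0.4,
                          baseline_rate = 0.1,
                          censor_rate = 0.05,
                          seed = 1L) {
  assert_scalar_number(n_patients, "n_patients", 2)
  assert_scalar_number(n_subpops, "n_subpops", 2)
  assert_scalar_number(n_modules, "n_modules", 2)
  if (n_modules > n_subpops) stop("more modules than subpopulations", call. = FALSE)
  assert_scalar_number(within_module_corr, "within_module_corr", 0)
  if (within_module_corr >= 1) {
    stop("within_module_corr must be < 1 (degenerate covariance)", call. = FALSE)
  }
  assert_scalar_number(composition_noise_sd, "composition_noise_sd", 0)
  assert_scalar_number(nb_dispersion, "nb_dispersion", 0)
  assert_scalar_number(baseline_rate, "baseline_rate")
  if (baseline_rate <= 0) stop("baseline_rate must be > 0", call. = FALSE)
  assert_scalar_number(censor_rate, "censor_rate", 0)
  if (abs(sum(subtype_labels) - 1) > 1e-8) {
    stop("subtype proportions must sum to 1", call. = FALSE)
  }
  if (n_programs * genes_per_program > n_genes) {
    stop("program genes exceed the gene universe", call. = FALSE)
  }
  structure(list(
    n_patients = as.integer(n_patients),
    subtype_labels = subtype_labels,
    n_subpops = as.integer(n_subpops),
    n_modules = as.integer(n_modules),
    within_module_corr = within_module_corr,
    composition_noise_sd = composition_noise_sd,
    n_cells = as.integer(n_cells),
    n_samples = as.integer(n_samples),
    n_genes = as.integer(n_genes),
    n_programs = as.integer(n_programs),
    genes_per_program = as.integer(genes_per_program),
    program_log_fc = program_log_fc,
    libsize_log_mean = libsize_log_mean,
    libsize_log_sd = libsize_log_sd,
    nb_dispersion = nb_dispersion,
    baseline_rate = baseline_rate,
    censor_rate = censor_rate,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

planted_partition <- function(config) {
  subpops <- sprintf("Sub%02d", seq_len(config$n_subpops))
  modules <- sprintf("CM%d", rep_len(seq_len(config$n_modules), config$n_subpops))
  stats::setNames(modules, subpops)
}

#' Simulate a patient-by-subpopulation composition matrix
#'
#' Latent abundances are drawn from a logistic-normal model: subpopulations
#' of the same planted module share a Gaussian factor with loading
#' `sqrt(within_module_corr)`, independent noise supplies the rest of the
#' unit latent variance, extra `composition_noise_sd` jitter is added, and
#' rows are closed to the simplex by softmax.
#'
#' @param config A [cohort_config()].
#' @return List with `composition` (tibble, `patient` + one column per
#'   subpopulation, rows summing to 1), `meta` (patient, subtype) and
#'   `truth` (named module assignment per subpopulation).
#' @export
simulate_composition <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  part <- planted_partition(config)
  subpops <- names(part)
  rho <- config$within_module_corr
  withr::with_seed(derive_seed(config$seed, "composition"), {
    subtype <- sample(names(config$subtype_labels), config$n_patients,
                      replace = TRUE, prob = config$subtype_labels)
    fac <- matrix(stats::rnorm(config$n_patients * config$n_modules),
                  config$n_patients, config$n_modules,
                  dimnames = list(NULL, unique(part)))
    eps <- matrix(stats::rnorm(config$n_patients * config$n_subpops),
                  config$n_patients, config$n_subpops)
    jit <- matrix(stats::rnorm(config$n_patients * config$n_subpops,
                               sd = config$composition_noise_sd),
                  config$n_patients, config$n_subpops)
  })
  latent <- sqrt(rho) * fac[, part, drop = FALSE] + sqrt(1 - rho) * eps + jit
  expo <- exp(latent)
  comp <- expo / rowSums(expo)
  colnames(comp) <- subpops
  patients <- sprintf("P%03d", seq_len(config$n_patients))
  list(
    composition = dplyr::bind_cols(tibble::tibble(patient = patients),
                                   tibble::as_tibble(comp)),
    meta = tibble::tibble(patient = patients, subtype = subtype),
    truth = part
  )
}

#' Simulate a count matrix with planted expression programs
#'
#' Gene baseline means follow a log-normal; cells carry log-normal library
#' sizes; counts are negative binomial. Cells assigned to program `p` have
#' the means of `p`'s genes multiplied by `exp(program_log_fc)`. Cells are
#' spread evenly over pseudo-samples with every program present in every
#' sample, so per-sample clustering can recover the programs.
#'
#' @param config A [cohort_config()].
#' @param cell_programs Optional character vector (length `n_cells`) mapping
#'   each cell to a program id (`"GE1"`, ...) or `NA` for background; by
#'   default cells are dealt evenly across the planted programs.
#' @return List with `counts` (sparse gene x cell matrix), `cell_meta`
#'   (tibble: cell, sample, program) and `truth` (list: `program_genes`
#'   named list, `cell_states`).
#' @export
simulate_expression <- function(config, cell_programs = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  prog_ids <- sprintf("GE%d", seq_len(config$n_programs))
  prog_genes <- split(
    genes[seq_len(config$n_programs * config$genes_per_program)],
    rep(prog_ids, each = config$genes_per_program)
  )[prog_ids]
  cells <- sprintf("C%05d", seq_len(config$n_cells))
  sample_id <- sprintf("S%02d", rep_len(seq_len(config$n_samples), config$n_cells))
  if (is.null(cell_programs)) {
    # cycle programs in blocks of n_samples so every pseudo-sample holds a
    # balanced mix of all programs (samples are dealt round-robin)
    idx <- ((ceiling(seq_len(config$n_cells) / config$n_samples) - 1) %%
              config$n_programs) + 1
    cell_programs <- prog_ids[idx]
  }
  stopifnot(length(cell_programs) == config$n_cells)
  bad <- setdiff(stats::na.omit(unique(cell_programs)), prog_ids)
  if (length(bad)) stop("unknown program ids: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  withr::with_seed(derive_seed(config$seed, "expression"), {
    base_mu <- stats::rlnorm(config$n_genes, meanlog = 0, sdlog = 1)
    libsize <- stats::rlnorm(config$n_cells, config$libsize_log_mean,
                             config$libsize_log_sd)
    counts <- matrix(0L, config$n_genes, config$n_cells,
                     dimnames = list(genes, cells))
    lfc <- matrix(0, config$n_genes, config$n_programs,
                  dimnames = list(genes, prog_ids))
    for (p in prog_ids) lfc[prog_genes[[p]], p] <- config$program_log_fc
    rel <- base_mu / sum(base_mu)
    for (j in seq_len(config$n_cells)) {
      mult <- if (is.na(cell_programs[[j]])) 1 else exp(lfc[, cell_programs[[j]]])
      mu_j <- rel * mult
      mu_j <- mu_j / sum(mu_j) * libsize[[j]]
      counts[, j] <- if (config$nb_dispersion <= 0) {
        stats::rpois(config$n_genes, mu_j)
      } else {
        stats::rnbinom(config$n_genes, size = 1 / config$nb_dispersion, mu = mu_j)
      }
    }
  })
  list(
    counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
    cell_meta = tibble::tibble(cell = cells, sample = sample_id,
                               program = cell_programs),
    truth = list(program_genes = prog_genes, cell_states = cell_programs)
  )
}

#' Simulate survival records from regulon scores
#'
#' Event times are exponential with rate
#' `baseline_rate * exp(sum(beta_i * score_i))`; censoring times are
#' independent exponentials with rate `censor_rate` (no censoring when 0).
#'
#' @param scores Data frame or matrix of per-patient regulon scores; a
#'   `patient` column is used for ids when present, otherwise rownames or
#'   `P001...` are used.
#' @param betas Named numeric vector of true log-hazard coefficients; names
#'   must be score columns. Columns not named get coefficient 0.
#' @param config A [cohort_config()] (supplies rates and seed).
#' @return List with `records` (tibble: patient, time, event, age) and
#'   `truth` (the beta vector).
#' @export
simulate_survival <- function(scores, betas, config) {
  stopifnot(inherits(config, "cohort_config"))
  df <- tibble::as_tibble(as.data.frame(scores))
  patient <- if ("patient" %in% names(df)) {
    as.character(df$patient)
  } else {
    sprintf("P%03d", seq_len(nrow(df)))
  }
  df <- df[, setdiff(names(df), "patient"), drop = FALSE]
  missing <- setdiff(names(betas), names(df))
  if (length(missing)) stop("betas name absent score columns: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  x <- as.matrix(df[, names(betas), drop = FALSE])
  lp <- if (length(betas)) drop(x %*% betas) else rep(0, nrow(df))
  if (!all(is.finite(lp))) stop("non-finite linear predictor", call. = FALSE)
  withr::with_seed(derive_seed(config$seed, "survival"), {
    t_event <- stats::rexp(length(lp), rate = config$baseline_rate * exp(lp))
    t_cens <- if (config$censor_rate > 0) {
      stats::rexp(length(lp), rate = config$censor_rate)
    } else {
      rep(Inf, length(lp))
    }
    age <- round(stats::rnorm(length(lp), mean = 65, sd = 8))
  })
  time <- pmin(t_event, t_cens)
  list(
    records = tibble::tibble(
      patient = patient,
      time = time,
      event = as.integer(t_event <= t_cens),
      age = age
    ),
    truth = betas
  )
}

#' Write a full synthetic cohort to disk
#'
#' Emits the 10x-style MTX triplet, cell-metadata TSV, composition CSV,
#' survival CSV and a ground-truth JSON next to each other.
#'
#' @param config A [cohort_config()].
#' @param dir Output directory.
#' @return Invisible character vector of written paths.
#' @export
write_cohort <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  comp <- simulate_composition(config)
  expr <- simulate_expression(config)
  betas <- stats::setNames(
    rep(c(0.5, 0), c(2, config$n_modules - 2))[seq_len(config$n_modules)],
    paste0("regulon_", sprintf("CM%d", seq_len(config$n_modules)))
  )
  scores <- comp$composition
  names(scores)[-1] <- paste0("score_", names(scores)[-1])
  mod_scores <- tibble::tibble(patient = comp$composition$patient)
  for (m in unique(comp$truth)) {
    cols <- names(comp$truth)[comp$truth == m]
    # z-scored module-share sums play the role of regulon enrichment scores
    mod_scores[[paste0("regulon_", m)]] <-
      as.numeric(scale(rowSums(comp$composition[, cols, drop = FALSE])))
  }
  surv <- simulate_survival(mod_scores, betas, config)
  write_counts_10x(expr$counts, file.path(dir, "counts"))
  readr::write_tsv(expr$cell_meta, file.path(dir, "cell_meta.tsv"))
  readr::write_csv(comp$composition, file.path(dir, "composition.csv"))
  readr::write_csv(surv$records, file.path(dir, "survival.csv"))
  truth <- list(
    module_partition = as.list(comp$truth),
    program_genes = expr$truth$program_genes,
    true_coefficients = as.list(surv$truth)
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(list.files(dir, recursive = TRUE, full.names = TRUE))
}
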