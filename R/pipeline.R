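# End-to-end orchestration over a synthetic cohort, with a JSON run
# manifest recording the configuration, per-stage seeds and output
# checksums so any run can be reproduced bit for bit.

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the stages in dependency order: simulate, qc, cluster, markers,
#' modules (co-occurrence + dominant module + Ro/e), programs (marker-set
#' collection, Jaccard, consensus, signatures, per-cell states),
#' communicate (ligand-receptor scores on program states), and riskmodel
#' (univariate + LASSO Cox on regulon scores, RS, median stratification,
#' time-dependent ROC). All randomness derives from `config$seed`, so an
#' identical configuration reproduces identical outputs.
#'
#' @param config A [cohort_config()].
#' @param outdir Output directory (created).
#' @param resolutions Clustering resolutions used per pseudo-sample.
#' @param horizons Time-dependent ROC horizons (same unit as the simulated
#'   survival times).
#' @return The run manifest (list), invisibly written to
#'   `outdir/manifest.json`.
#' @export
run_pipeline <- function(config = cohort_config(), outdir,
                         resolutions = c(0.1, 0.4, 0.8, 1.2),
                         horizons = c(1, 2, 3)) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("timeatlas")),
    seed = config$seed,
    config = unclass(config),
    stages = list()
  )
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  # -- simulate ------------------------------------------------------------
  write_cohort(config, file.path(outdir, "cohort"))
  comp <- simulate_composition(config)
  expr <- simulate_expression(config)
  manifest$stages$simulate <- list(seed = derive_seed(config$seed, "composition"))
  write_manifest()

  # -- qc ------------------------------------------------------------------
  kept <- filter_cells(expr$counts, min_genes = min(200, nrow(expr$counts) / 5))
  counts <- expr$counts[, kept, drop = FALSE]
  cell_meta <- expr$cell_meta[match(kept, expr$cell_meta$cell), , drop = FALSE]
  norm <- log_normalize(counts)
  manifest$stages$qc <- list(n_cells_kept = length(kept))
  write_manifest()

  # -- cluster + markers (per pseudo-sample) -------------------------------
  samples <- split(cell_meta$cell, cell_meta$sample)
  marker_tables <- list()
  for (s in names(samples)) {
    cells_s <- samples[[s]]
    if (length(cells_s) < 50) next
    norm_s <- norm[, cells_s, drop = FALSE]
    labs <- cluster_multires(norm_s, resolutions,
                             seed = derive_seed(config$seed, paste0("clust", s)),
                             k = min(15, length(cells_s) - 1))
    for (r in resolutions) {
      col <- sprintf("res_%g", r)
      if (length(unique(labs[[col]])) < 2) next
      mk <- rank_markers(norm_s, labs[[col]])
      mk$sample <- s
      mk$resolution <- r
      marker_tables[[paste(s, r)]] <- mk
    }
  }
  markers <- dplyr::bind_rows(marker_tables)
  readr::write_tsv(markers, file.path(outdir, "markers.tsv"))
  manifest$stages$cluster <- list(resolutions = resolutions,
                                  n_marker_rows = nrow(markers))
  write_manifest()

  # -- modules -------------------------------------------------------------
  cm <- cooccurrence_modules(comp$composition, k = config$n_modules)
  dom <- dominant_module(comp$composition, cm)
  dom <- dplyr::left_join(dom, comp$meta, by = "patient")
  roe_tab <- roe(dom, "module", "subtype")
  readr::write_tsv(cm$partition, file.path(outdir, "modules.tsv"))
  readr::write_csv(dom, file.path(outdir, "dominant_module.csv"))
  readr::write_csv(roe_tab, file.path(outdir, "roe.csv"))
  manifest$stages$modules <- list(k = cm$k)
  write_manifest()

  # -- programs ------------------------------------------------------------
  sets <- collect_marker_sets(markers)
  jm <- jaccard_matrix(sets)
  cp <- consensus_programs(jm$similarity,
                           k_range = 2:min(12, nrow(jm$similarity) - 1),
                           seed = derive_seed(config$seed, "consensus"))
  sigs <- program_signatures(cp, sets)
  write_gmt(sigs[lengths(sigs) > 0], file.path(outdir, "programs.gmt"))
  prog_scores <- tibble::tibble(cell = colnames(norm))
  for (nm in names(sigs)) {
    if (length(sigs[[nm]]) == 0) next
    prog_scores[[nm]] <- unname(module_score(
      norm, sigs[[nm]], seed = derive_seed(config$seed, paste0("score", nm))))
  }
  states <- assign_states(prog_scores)
  readr::write_tsv(states, file.path(outdir, "cell_states.tsv"))
  manifest$stages$programs <- list(k = cp$k, n_sets = nrow(cp$programs))
  write_manifest()

  # -- communicate ---------------------------------------------------------
  # synthetic ligand-receptor pairs drawn from the planted program genes
  pair_genes <- unlist(lapply(expr$truth$program_genes, utils::head, 2),
                       use.names = FALSE)
  n_pair <- floor(length(pair_genes) / 2)
  pairs <- tibble::tibble(
    pair = sprintf("LR%d", seq_len(n_pair)),
    ligand_subunits = as.list(pair_genes[2 * seq_len(n_pair) - 1]),
    receptor_subunits = as.list(pair_genes[2 * seq_len(n_pair)])
  )
  comm <- lr_communication(norm, states$state, pairs,
                           min_cells = 50, n_perm = 200,
                           seed = derive_seed(config$seed, "lr"))
  summ <- interaction_summary(comm)
  readr::write_csv(comm, file.path(outdir, "communication.csv"))
  readr::write_csv(summ, file.path(outdir, "interaction_summary.csv"))
  manifest$stages$communicate <- list(n_pairs = n_pair)
  write_manifest()

  # -- survival / riskmodel ------------------------------------------------
  mod_scores <- tibble::tibble(patient = comp$composition$patient)
  for (m in sort(unique(comp$truth))) {
    cols <- names(comp$truth)[comp$truth == m]
    # z-scored module-share sums play the role of regulon enrichment scores
    mod_scores[[paste0("regulon_", m)]] <-
      as.numeric(scale(rowSums(comp$composition[, cols, drop = FALSE])))
  }
  betas <- stats::setNames(
    rep(c(0.5, 0), c(2, config$n_modules - 2))[seq_len(config$n_modules)],
    paste0("regulon_", sprintf("CM%d", seq_len(config$n_modules))))
  surv <- simulate_survival(mod_scores, betas, config)
  model <- fit_risk_model(mod_scores, surv$records,
                          seed = derive_seed(config$seed, "riskmodel"))
  rs <- risk_score(mod_scores, model)
  rs <- stratify_median(rs)
  troc <- time_roc(rs$rs, surv$records, horizons)
  readr::write_csv(rs, file.path(outdir, "risk_scores.csv"))
  readr::write_csv(troc, file.path(outdir, "time_roc.csv"))
  jsonlite::write_json(
    list(regulons = model$regulons,
         coefficients = as.list(model$coefficients),
         lambda = model$lambda, status = model$status,
         seed = model$seed, folds = model$folds),
    file.path(outdir, "risk_model.json"), auto_unbox = TRUE, digits = NA)
  manifest$stages$riskmodel <- list(status = model$status,
                                    n_selected = length(model$coefficients))

  files <- setdiff(list.files(outdir, recursive = TRUE),
                   "manifest.json")
  manifest$outputs <- as.list(tools::md5sum(file.path(outdir, files)))
  names(manifest$outputs) <- files
  write_manifest()
  invisible(manifest)
}
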