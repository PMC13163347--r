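# Survival analytics: Kaplan-Meier, log-rank, maximally selected cutpoint,
# Cox hazard ratios with covariates, cohort splitting, median risk
# stratification, IPCW time-dependent ROC, module-level survival screens
# and infiltration correlations. Partial-likelihood fitting delegates to
# the survival package (Efron tie handling).

surv_object <- function(records) {
  records <- validate_survival(records)
  survival::Surv(records$time, records$event)
}

#' Kaplan-Meier estimate of the survival function
#'
#' Product-limit estimator; `S(0) = 1` with right-continuous steps at event
#' times.
#'
#' @param records Survival tibble (`patient`, `time`, `event`, ...).
#' @return Tibble `time`, `n_risk`, `n_event`, `n_censor`, `survival`,
#'   starting with the `(0, 1)` anchor row.
#' @export
km_estimate <- function(records) {
  if (nrow(records) < 1) stop("no records", call. = FALSE)
  fit <- survival::survfit(surv_object(records) ~ 1)
  tibble::tibble(
    time = c(0, fit$time),
    n_risk = c(fit$n, fit$n.risk),
    n_event = c(0, fit$n.event),
    n_censor = c(0, fit$n.censor),
    survival = c(1, fit$surv)
  )
}

#' Log-rank test between groups
#'
#' @param records Survival tibble.
#' @param group Vector of group labels aligned with `records`, or the name
#'   of a column in `records`.
#' @return Tibble `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(records, group) {
  records <- validate_survival(records)
  g <- if (is.character(group) && length(group) == 1 &&
           group %in% names(records)) {
    records[[group]]
  } else {
    group
  }
  stopifnot(length(g) == nrow(records))
  if (length(unique(g)) < 2) stop("need >= 2 groups", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(records$time, records$event) ~ g)
  df <- length(sd$n) - 1
  tibble::tibble(statistic = sd$chisq, df = df,
                 p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Maximally selected survival cutpoint
#'
#' Every candidate cutoff (midpoints of consecutive sorted unique scores
#' leaving both groups with at least `minprop * n` patients) is scored by
#' the standardized two-group log-rank statistic; the cutoff maximizing the
#' absolute standardized statistic is returned (ties to the smallest
#' cutoff). An optional permutation p-value re-maximizes over permuted
#' scores.
#'
#' @param score Numeric score per patient, aligned with `records`.
#' @param records Survival tibble.
#' @param minprop Minimum group proportion (default 0.1).
#' @param n_perm Permutations for the p-value (0 = skip).
#' @param seed Integer seed for the permutation p-value.
#' @return Object of class `surv_cutpoint`: list with `cutpoint`,
#'   `statistic` (max |standardized log-rank z|), `candidates` tibble and
#'   optional `p_value`.
#' @export
optimal_cutpoint <- function(score, records, minprop = 0.1, n_perm = 0,
                             seed = 1L) {
  records <- validate_survival(records)
  stopifnot(length(score) == nrow(records))
  if (stats::sd(score) == 0) stop("score has zero variance", call. = FALSE)
  n <- length(score)
  max_stat <- function(sc) {
    u <- sort(unique(sc))
    cands <- (u[-1] + u[-length(u)]) / 2
    sizes_hi <- vapply(cands, function(ct) sum(sc > ct), double(1))
    ok <- sizes_hi >= minprop * n & (n - sizes_hi) >= minprop * n
    if (!any(ok)) return(NULL)
    cands <- cands[ok]
    z <- vapply(cands, function(ct) {
      lr_z(records$time, records$event, sc > ct)
    }, double(1))
    list(cands = cands, z = z)
  }
  obs <- max_stat(score)
  if (is.null(obs)) stop("no candidate cutoff satisfies minprop", call. = FALSE)
  best <- which.max(abs(obs$z))
  out <- structure(list(
    cutpoint = obs$cands[[best]],
    statistic = abs(obs$z[[best]]),
    candidates = tibble::tibble(cutoff = obs$cands, statistic = abs(obs$z)),
    p_value = NA_real_
  ), class = "surv_cutpoint")
  if (n_perm > 0) {
    stat_obs <- out$statistic
    exceed <- withr::with_seed(derive_seed(seed, "cutpoint_perm"), {
      sum(vapply(seq_len(n_perm), function(b) {
        ms <- max_stat(sample(score))
        if (is.null(ms)) return(FALSE)
        max(abs(ms$z)) >= stat_obs
      }, logical(1)))
    })
    out$p_value <- (1 + exceed) / (n_perm + 1)
  }
  out
}

# standardized log-rank z for a binary split (O - E) / sqrt(V)
lr_z <- function(time, event, high) {
  sd <- survival::survdiff(survival::Surv(time, event) ~ high)
  o_minus_e <- sd$obs[[2]] - sd$exp[[2]]
  v <- if (is.matrix(sd$var)) sd$var[2, 2] else sd$var
  o_minus_e / sqrt(max(v, .Machine$double.eps))
}

#' Print a `surv_cutpoint` summary
#' @param x Object to print.
#' @param ... Unused.
#' @method print surv_cutpoint
#' @export
print.surv_cutpoint <- function(x, ...) {
  cat(sprintf("surv_cutpoint: cutoff %.4g, max standardized statistic %.3f\n",
              x$cutpoint, x$statistic))
  if (!is.na(x$p_value)) cat(sprintf("permutation p = %.4g\n", x$p_value))
  invisible(x)
}

#' @describeIn optimal_cutpoint One-row summary.
#' @param x A `surv_cutpoint` object.
#' @param ... Unused.
#' @method glance surv_cutpoint
#' @export
glance.surv_cutpoint <- function(x, ...) {
  tibble::tibble(cutpoint = x$cutpoint, statistic = x$statistic,
                 p_value = x$p_value)
}

#' Cox proportional-hazards ratio for a score or group
#'
#' Partial-likelihood fit (Efron ties) of the exposure plus covariates;
#' returns the exposure's hazard ratio, Wald confidence interval and the
#' direction label used for prognostic classification: `"Worse survival"`
#' when HR > 1, `"Better survival"` when HR < 1.
#'
#' @param records Survival tibble containing the covariate columns.
#' @param exposure Numeric or two-level vector aligned with `records`, or a
#'   column name in `records`.
#' @param covariates Character vector of covariate column names
#'   (default `"age"`; use `character()` for none).
#' @param min_events Minimum number of events required (default 5).
#' @return Tibble `term`, `beta`, `hr`, `ci_low`, `ci_high`, `p_value`,
#'   `direction` (one row for the exposure).
#' @export
cox_hr <- function(records, exposure, covariates = "age", min_events = 5) {
  records <- validate_survival(records)
  if (sum(records$event) < min_events) {
    stop("fewer than ", min_events, " events", call. = FALSE)
  }
  df <- as.data.frame(records)
  if (is.character(exposure) && length(exposure) == 1) {
    stopifnot(exposure %in% names(df))
    df$.exposure <- df[[exposure]]
  } else {
    stopifnot(length(exposure) == nrow(df))
    df$.exposure <- exposure
  }
  covariates <- intersect(covariates, names(df))
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~ .exposure",
    if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""
  ))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  if (!is.null(fit$fail)) stop("Cox fit failed to converge", call. = FALSE)
  s <- summary(fit)
  i <- grep("^\\.exposure", rownames(s$coefficients))[[1]]
  beta <- s$coefficients[i, "coef"]
  hr <- unname(exp(beta))
  tibble::tibble(
    term = if (is.character(exposure) && length(exposure) == 1) exposure else "exposure",
    beta = unname(beta),
    hr = hr,
    ci_low = unname(s$conf.int[i, "lower .95"]),
    ci_high = unname(s$conf.int[i, "upper .95"]),
    p_value = unname(s$coefficients[i, "Pr(>|z|)"]),
    direction = ifelse(hr > 1, "Worse survival", "Better survival")
  )
}

#' Random train/validation split
#'
#' `floor(train_frac * n)` indices go to training, the rest to validation;
#' sampling is uniform without replacement and seeded. 917 patients at 7:3
#' give the (641, 276) split used for prognostic model training.
#'
#' @param n Number of patients.
#' @param train_frac Training fraction in (0, 1) (default 0.7).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_cohort <- function(n, train_frac = 0.7, seed = 1L) {
  stopifnot(n >= 2)
  if (train_frac <= 0 || train_frac >= 1) {
    stop("train_frac must be in (0, 1)", call. = FALSE)
  }
  n_train <- floor(train_frac * n)
  train <- withr::with_seed(derive_seed(seed, "split"),
                            sort(sample.int(n, n_train)))
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Median risk stratification
#'
#' High risk iff the score strictly exceeds the median; values equal to the
#' median are assigned to the low-risk group (deterministic convention).
#'
#' @param rs Numeric risk scores, or a data frame with an `rs` column.
#' @return Character vector (`"high"`/`"low"`), or the input tibble with a
#'   `risk_group` column appended.
#' @export
stratify_median <- function(rs) {
  if (is.data.frame(rs)) {
    stopifnot("rs" %in% names(rs), nrow(rs) >= 2)
    rs$risk_group <- stratify_median(rs$rs)
    return(tibble::as_tibble(rs))
  }
  stopifnot(length(rs) >= 2)
  ifelse(rs > stats::median(rs), "high", "low")
}

#' IPCW time-dependent ROC AUC
#'
#' Cumulative-case / dynamic-control AUC at each horizon with inverse
#' probability of censoring weights from the Kaplan-Meier estimator of the
#' censoring distribution. Cases are patients with an event at or before
#' the horizon (weighted by `1/G(T-)`); controls are patients still at risk
#' beyond it. Tied markers count 1/2.
#'
#' @param rs Numeric marker (risk score) per patient.
#' @param records Survival tibble.
#' @param horizons Numeric vector of evaluation times.
#' @return Tibble `horizon`, `auc`, `n_cases`, `n_controls` (AUC `NA` with
#'   a warning for horizons beyond follow-up).
#' @export
time_roc <- function(rs, records, horizons) {
  records <- validate_survival(records)
  stopifnot(length(rs) == nrow(records))
  t <- records$time
  d <- records$event
  # censoring KM: G(t) = P(C > t)
  gfit <- survival::survfit(survival::Surv(t, 1 - d) ~ 1)
  g_at <- function(times) {
    # left limit G(t-)
    vapply(times, function(tt) {
      idx <- gfit$time < tt
      if (!any(idx)) 1 else min(gfit$surv[idx])
    }, double(1))
  }
  purrr::map_dfr(horizons, function(h) {
    case <- t <= h & d == 1
    ctrl <- t > h
    if (sum(case) < 1 || sum(ctrl) < 1) {
      warning("horizon ", h, " has no cases or no controls; AUC missing")
      return(tibble::tibble(horizon = h, auc = NA_real_,
                            n_cases = sum(case), n_controls = sum(ctrl)))
    }
    w <- 1 / pmax(g_at(t[case]), .Machine$double.eps)
    mc <- rs[case]
    mk <- rs[ctrl]
    conc <- vapply(seq_along(mc), function(i) {
      sum(mc[[i]] > mk) + 0.5 * sum(mc[[i]] == mk)
    }, double(1))
    auc <- sum(w * conc) / (sum(w) * length(mk))
    tibble::tibble(horizon = h, auc = auc,
                   n_cases = sum(case), n_controls = sum(ctrl))
  })
}

#' Module-level survival screen on bulk expression
#'
#' Per module, the mean expression of its marker genes (those present in
#' the bulk matrix; modules with under half their markers present are
#' skipped) defines a per-patient score, split at the maximally selected
#' cutpoint and tested by log-rank.
#'
#' @param bulk Gene-by-patient bulk expression matrix; columns must match
#'   `records$patient`.
#' @param module_markers Named list of marker gene vectors (typically the
#'   top 30 per module).
#' @param records Survival tibble.
#' @param minprop Passed to [optimal_cutpoint()].
#' @return Tibble `module`, `n_markers_used`, `cutpoint`, `n_high`,
#'   `n_low`, `statistic`, `p_value`, `status`.
#' @export
module_survival <- function(bulk, module_markers, records, minprop = 0.1) {
  records <- validate_survival(records)
  x <- as.matrix(bulk)
  stopifnot(!is.null(colnames(x)))
  x <- x[, records$patient, drop = FALSE]
  purrr::map_dfr(names(module_markers), function(m) {
    genes <- intersect(module_markers[[m]], rownames(x))
    row <- tibble::tibble(module = m, n_markers_used = length(genes),
                          cutpoint = NA_real_, n_high = NA_integer_,
                          n_low = NA_integer_, statistic = NA_real_,
                          p_value = NA_real_, status = "ok")
    if (length(genes) < 0.5 * length(module_markers[[m]])) {
      row$status <- "skipped: marker overlap < 50%"
      return(row)
    }
    score <- colMeans(x[genes, , drop = FALSE])
    if (stats::sd(score) == 0) {
      row$status <- "skipped: zero-variance score"
      return(row)
    }
    cp <- tryCatch(optimal_cutpoint(score, records, minprop = minprop),
                   error = function(e) NULL)
    if (is.null(cp)) {
      row$status <- "skipped: no admissible cutpoint"
      return(row)
    }
    grp <- ifelse(score > cp$cutpoint, "high", "low")
    lr <- logrank_test(records, grp)
    row$cutpoint <- cp$cutpoint
    row$n_high <- sum(grp == "high")
    row$n_low <- sum(grp == "low")
    row$statistic <- lr$statistic
    row$p_value <- lr$p_value
    row
  })
}

#' Correlation of risk/regulon scores with immune infiltration
#'
#' Pairwise Pearson correlations between every score column and every
#' infiltration column over shared patients, with t-based p-values and the
#' conventional significance stars (* p<0.05, ** p<0.01, *** p<0.001).
#'
#' @param scores Tibble with `patient` plus score columns (RS and regulons).
#' @param infiltration Tibble with `patient` plus cell-type fraction columns.
#' @return Tibble `score`, `cell_type`, `r`, `p_value`, `stars`, `n`;
#'   zero-variance pairs yield `NA`.
#' @export
infiltration_correlation <- function(scores, infiltration) {
  stopifnot("patient" %in% names(scores), "patient" %in% names(infiltration))
  shared <- intersect(scores$patient, infiltration$patient)
  if (length(shared) < 4) stop("fewer than 4 shared samples", call. = FALSE)
  s <- scores[match(shared, scores$patient), , drop = FALSE]
  f <- infiltration[match(shared, infiltration$patient), , drop = FALSE]
  score_cols <- setdiff(names(s), "patient")
  cell_cols <- setdiff(names(f), "patient")
  grid <- expand.grid(score = score_cols, cell_type = cell_cols,
                      stringsAsFactors = FALSE)
  purrr::pmap_dfr(grid, function(score, cell_type) {
    a <- s[[score]]
    b <- f[[cell_type]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      return(tibble::tibble(score = score, cell_type = cell_type,
                            r = NA_real_, p_value = NA_real_,
                            stars = NA_character_, n = length(shared)))
    }
    ct <- stats::cor.test(a, b, method = "pearson")
    tibble::tibble(score = score, cell_type = cell_type,
                   r = unname(ct$estimate), p_value = ct$p.value,
                   stars = p_stars(ct$p.value), n = length(shared))
  })
}
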