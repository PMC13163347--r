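test_that("Kaplan-Meier estimates match risk-set enumeration", {
  # no events: flat at 1
  rec0 <- tibble::tibble(patient = letters[1:4], time = c(1, 2, 3, 4),
                         event = 0L)
  km0 <- km_estimate(rec0)
  expect_true(all(km0$survival == 1))
  # 4 subjects, deaths at 1 and 2, no censoring beyond
  rec <- tibble::tibble(patient = letters[1:4], time = c(1, 2, 3, 4),
                        event = c(1L, 1L, 0L, 0L))
  km <- km_estimate(rec)
  expect_equal(km$survival[km$time == 2], 3 / 4 * 2 / 3)
  expect_true(all(diff(km$survival) <= 1e-12))
  # uncensored: 1 - S equals the empirical event CDF; oracle agreement
  rec2 <- sim_records(40, censor_rate = 0, seed = 4)
  km2 <- km_estimate(rec2)
  oracle <- km_oracle(rec2$time, rec2$event)
  for (i in seq_len(nrow(oracle))) {
    expect_equal(km2$survival[km2$time == oracle$time[i]], oracle$surv[i],
                 tolerance = 1e-10)
  }
  ecdf_t <- ecdf(rec2$time)
  expect_equal(1 - km2$survival[-1], ecdf_t(km2$time[-1]), tolerance = 1e-10)
  expect_error(km_estimate(tibble::tibble(patient = "a", time = 0,
                                          event = 1L)), "non-positive")
})

test_that("log-rank equals the risk-set-enumeration oracle on small fixtures", {
  # identical groups give statistic 0, p 1
  base <- tibble::tibble(patient = paste0("p", 1:8),
                         time = rep(c(1, 2, 3, 4), 2),
                         event = rep(c(1L, 0L, 1L, 1L), 2))
  same <- logrank_test(base, rep(c("A", "B"), each = 4))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  # random small fixtures vs brute force, two and three groups
  for (seed in 1:5) {
    rec <- sim_records(18, seed = seed)
    g2 <- rep(c("A", "B"), 9)
    got <- logrank_test(rec, g2)
    ref <- logrank_oracle(rec$time, rec$event, g2)
    expect_equal(got$statistic, ref$chisq, tolerance = 1e-10)
    expect_equal(got$p_value, ref$p, tolerance = 1e-10)
    g3 <- rep(c("A", "B", "C"), 6)
    got3 <- logrank_test(rec, g3)
    ref3 <- logrank_oracle(rec$time, rec$event, g3)
    expect_equal(got3$statistic, ref3$chisq, tolerance = 1e-10)
  }
  expect_error(logrank_test(base, rep("A", 8)), "2 groups")
})

test_that("the maximally selected cutpoint lands between separated score ranges", {
  # early deaths at low scores, censored survivors at high scores
  rec <- tibble::tibble(patient = paste0("p", 1:20),
                        time = c(runif(10, 0.1, 1), rep(10, 10)),
                        event = c(rep(1L, 10), rep(0L, 10)))
  score <- c(runif(10, 0, 0.3), runif(10, 0.7, 1))
  cp <- optimal_cutpoint(score, rec, minprop = 0.2)
  expect_gt(cp$cutpoint, 0.3)
  expect_lt(cp$cutpoint, 0.7)
  # minprop = 0.5 leaves only the median split
  rec10 <- sim_records(10, seed = 2)
  sc10 <- seq(0.1, 1, 0.1)
  cp2 <- optimal_cutpoint(sc10, rec10, minprop = 0.5)
  expect_identical(nrow(cp2$candidates), 1L)
  expect_equal(cp2$cutpoint, 0.55)
  expect_error(optimal_cutpoint(rep(1, 10), rec10), "variance")
})

test_that("Cox hazard ratios recover planted effects and label directions", {
  set.seed(12)
  n <- 2000
  bin <- rep(0:1, n / 2)
  tt <- rexp(n, 0.1 * exp(log(2) * bin))
  cc <- rexp(n, 0.02)
  rec <- tibble::tibble(patient = paste0("p", 1:n), time = pmin(tt, cc),
                        event = as.integer(tt <= cc),
                        age = round(rnorm(n, 65, 8)), bin = bin)
  fit <- cox_hr(rec, "bin")
  expect_gte(fit$hr, 1.7)
  expect_lte(fit$hr, 2.3)
  expect_identical(fit$direction, "Worse survival")
  # null covariate
  rec$noise <- rnorm(n)
  fit0 <- cox_hr(rec, "noise")
  expect_gte(fit0$hr, 0.9)
  expect_lte(fit0$hr, 1.1)
  # protective exposure labelled better survival
  rec$prot <- -rec$bin
  expect_identical(cox_hr(rec, "prot")$direction, "Better survival")
  expect_error(cox_hr(rec[rec$event == 0, ][1:10, ], "bin"), "events")
})

test_that("cohort splitting reproduces the 7:3 arithmetic exactly", {
  for (seed in c(1, 7, 99)) {
    sp <- split_cohort(917, 0.7, seed = seed)
    expect_identical(length(sp$train), 641L)
    expect_identical(length(sp$test), 276L)
    expect_identical(sort(c(sp$train, sp$test)), 1:917)
    expect_length(intersect(sp$train, sp$test), 0)
  }
  sp10 <- split_cohort(10, 0.7, seed = 1)
  expect_identical(lengths(sp10), c(train = 7L, test = 3L))
  expect_error(split_cohort(10, 1.2), "train_frac")
})

test_that("risk model fitting screens, selects and degrades gracefully", {
  set.seed(5)
  n <- 400
  x <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("R", 1:6)))
  lp <- 0.8 * x[, 1] + 0.5 * x[, 2]
  tt <- rexp(n, 0.1 * exp(lp))
  cc <- rexp(n, 0.03)
  rec <- tibble::tibble(patient = sprintf("p%04d", 1:n),
                        time = pmin(tt, cc), event = as.integer(tt <= cc))
  scores <- dplyr::bind_cols(tibble::tibble(patient = rec$patient),
                             tibble::as_tibble(x))
  m <- fit_risk_model(scores, rec, seed = 3)
  expect_true("R1" %in% m$regulons)
  # the regulon equal to the linear predictor dominates the univariate screen
  scores$LPexact <- lp
  m2 <- fit_risk_model(scores, rec, seed = 3)
  expect_identical(
    m2$univariate$regulon[which.min(m2$univariate$p_value)], "LPexact")
  # single survivor: coefficient equals the unpenalized Cox estimate
  scores1 <- scores[, c("patient", "R1", "R2")]
  m3 <- fit_risk_model(scores1, rec, p_uni = 1e-6, seed = 3)
  if (m3$status == "single") {
    ref <- survival::coxph(survival::Surv(rec$time, rec$event) ~ x[, 1])
    expect_equal(unname(m3$coefficients), unname(coef(ref)), tolerance = 1e-4)
  }
  # all-noise candidates usually yield an empty or tiny model
  noise <- scores
  noise$LPexact <- NULL
  noise[, -1] <- matrix(rnorm(n * 6), n, 6)
  m4 <- fit_risk_model(noise, rec, seed = 4)
  expect_true(m4$status %in% c("empty", "single", "ok"))
  tidy_m <- tidy(m)
  expect_named(tidy_m, c("term", "estimate"))
  expect_identical(glance(m)$n_selected, length(m$coefficients))
})

test_that("the risk score is a linear dot product", {
  model <- structure(list(regulons = c("a", "b"),
                          coefficients = c(a = 1, b = -1),
                          lambda = 0, status = "ok"),
                     class = "risk_model")
  sc <- tibble::tibble(patient = "p1", a = 2, b = 3)
  expect_equal(risk_score(sc, model)$rs, -1)
  set.seed(6)
  sc9 <- dplyr::bind_cols(
    tibble::tibble(patient = paste0("p", 1:5)),
    tibble::as_tibble(matrix(rnorm(45), 5, 9,
                             dimnames = list(NULL, paste0("r", 1:9)))))
  cf <- rnorm(9)
  mod9 <- structure(list(regulons = paste0("r", 1:9),
                         coefficients = setNames(cf, paste0("r", 1:9)),
                         lambda = 0, status = "ok"), class = "risk_model")
  expect_equal(risk_score(sc9, mod9)$rs,
               as.numeric(as.matrix(sc9[, -1]) %*% cf), tolerance = 1e-12)
  # linearity under scaling
  sc9b <- sc9
  sc9b[, -1] <- sc9b[, -1] * 3
  expect_equal(risk_score(sc9b, mod9)$rs, 3 * risk_score(sc9, mod9)$rs,
               tolerance = 1e-12)
  expect_error(risk_score(sc9[, 1:5], mod9), "missing regulon")
})

test_that("median stratification assigns ties to the low-risk group", {
  expect_identical(stratify_median(c(1, 2, 3, 4)),
                   c("low", "low", "high", "high"))
  expect_identical(stratify_median(rep(2, 5)), rep("low", 5))
  df <- tibble::tibble(patient = letters[1:4], rs = c(1, 2, 3, 4))
  out <- stratify_median(df)
  expect_identical(out$risk_group, c("low", "low", "high", "high"))
})

test_that("time-dependent AUC matches brute-force pair counting when uncensored", {
  # perfect ordering: all cases score above all controls
  rec <- tibble::tibble(patient = paste0("p", 1:8),
                        time = c(0.5, 1, 1.5, 2, 5, 6, 7, 8),
                        event = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L))
  rs_perfect <- -rec$time
  tr <- time_roc(rs_perfect, rec, horizons = c(3, 4.5))
  expect_equal(tr$auc, c(1, 1))
  # toy vs explicit pair counting
  rs <- c(3, 1, 4, 2, 0.5, 2.5, 1.5, 0.2)
  tr2 <- time_roc(rs, rec, horizons = 3)
  cases <- which(rec$time <= 3)
  ctrls <- which(rec$time > 3)
  conc <- sum(outer(rs[cases], rs[ctrls], ">") +
                0.5 * outer(rs[cases], rs[ctrls], "=="))
  expect_equal(tr2$auc, conc / (length(cases) * length(ctrls)),
               tolerance = 1e-12)
  # a null marker sits near 0.5 at scale
  recn <- sim_records(2000, seed = 9)
  trn <- time_roc(rnorm(2000), recn, horizons = quantile(recn$time, 0.3))
  expect_gte(trn$auc, 0.45)
  expect_lte(trn$auc, 0.55)
  expect_warning(time_roc(rs, rec, horizons = 100), "missing")
})

test_that("module survival screens planted prognostic modules", {
  set.seed(10)
  n <- 400
  genes <- paste0("g", 1:60)
  bulk <- matrix(rnorm(60 * n), 60, n,
                 dimnames = list(genes, sprintf("p%04d", 1:n)))
  # module 1 genes share a prognostic patient-level factor
  fac <- rnorm(n)
  bulk[1:20, ] <- bulk[1:20, ] * 0.3 + matrix(fac, 20, n, byrow = TRUE)
  tt <- rexp(n, 0.1 * exp(1 * fac))
  cc <- rexp(n, 0.05)
  rec <- tibble::tibble(patient = colnames(bulk), time = pmin(tt, cc),
                        event = as.integer(tt <= cc))
  markers <- list(CM1 = genes[1:20], CM2 = genes[21:40],
                  CMconst = c("absent1", "absent2"))
  ms <- module_survival(bulk, markers, rec)
  expect_lt(ms$p_value[ms$module == "CM1"], 0.01)
  expect_match(ms$status[ms$module == "CMconst"], "skipped")
  # score equals the plain row mean of present markers
  expect_equal(ms$n_markers_used[ms$module == "CM1"], 20)
  # constant module is skipped with zero-variance status
  bulk2 <- bulk
  bulk2[21:40, ] <- 1
  ms2 <- module_survival(bulk2, markers["CM2"], rec)
  expect_match(ms2$status, "zero-variance")
})

test_that("infiltration correlations reproduce hand-computed r and stars", {
  set.seed(13)
  n <- 50
  scores <- tibble::tibble(patient = paste0("p", 1:n), rs = rnorm(n))
  infil <- tibble::tibble(patient = paste0("p", 1:n),
                          dup = scores$rs, other = rnorm(n),
                          flat = rep(1, n))
  res <- infiltration_correlation(scores, infil)
  expect_equal(res$r[res$cell_type == "dup"], 1, tolerance = 1e-12)
  ref <- cor.test(scores$rs, infil$other)
  got <- res[res$cell_type == "other", ]
  expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  expect_true(is.na(res$r[res$cell_type == "flat"]))
  expect_identical(res$stars[res$cell_type == "dup"], "***")
})
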