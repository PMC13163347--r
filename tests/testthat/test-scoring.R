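test_that("module score is zero on constant matrices and matches a manual oracle", {
  m <- Matrix::Matrix(matrix(3, 30, 5, dimnames = list(paste0("g", 1:30),
                                                       paste0("c", 1:5))),
                      sparse = TRUE)
  sc <- module_score(m, c("g1", "g2", "g3"), n_bins = 5, n_ctrl = 10, seed = 1)
  expect_equal(unname(sc), rep(0, 5))

  # toy matrix: replicate the documented procedure independently
  x <- matrix(seq_len(15), 5, 3,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:3)))
  xm <- Matrix::Matrix(x, sparse = TRUE)
  genes <- c("g1", "g4")
  seed <- 7
  got <- module_score(xm, genes, n_bins = 2, n_ctrl = 2, seed = seed)
  avg <- rowMeans(x)
  bins <- ggplot2::cut_number(rank(avg, ties.method = "first"), n = 2)
  bin_members <- split(rownames(x), bins)
  ctrl <- withr::with_seed(derive_seed(seed, "module_score"), {
    unlist(lapply(genes, function(gn) {
      pool <- setdiff(bin_members[[as.character(bins[[match(gn, rownames(x))]])]], gn)
      sample(pool, min(2, length(pool)), replace = FALSE)
    }), use.names = FALSE)
  })
  manual <- colMeans(x[genes, ]) - colMeans(x[ctrl, , drop = FALSE])
  expect_equal(got, manual, tolerance = 1e-12)
})

test_that("bin-matched controls make the expected module score vanish", {
  set.seed(2)
  x <- matrix(rlnorm(200 * 20), 200, 20,
              dimnames = list(paste0("g", 1:200), paste0("c", 1:20)))
  xm <- Matrix::Matrix(x, sparse = TRUE)
  avg <- rowMeans(x)
  bins <- ggplot2::cut_number(rank(avg, ties.method = "first"), n = 4)
  bin1 <- rownames(x)[bins == levels(bins)[1]]
  scores <- vapply(1:100, function(s) {
    mean(module_score(xm, bin1, n_bins = 4, n_ctrl = 30, seed = s))
  }, double(1))
  expect_lt(abs(mean(scores)), 0.02)
})

test_that("AUC activity spans its extremes and matches step-curve integration", {
  x <- matrix(0, 20, 1, dimnames = list(paste0("g", 1:20), "c1"))
  x[, 1] <- 20:1  # g1 highest
  xm <- Matrix::Matrix(x, sparse = TRUE)
  # top 25% = 5 genes; set occupying the whole top
  expect_equal(unname(auc_score(xm, paste0("g", 1:5), top_frac = 0.25)), 1)
  expect_equal(unname(auc_score(xm, paste0("g", 16:20), top_frac = 0.25)), 0)
  # brute-force integration for a scattered set
  genes <- c("g2", "g4", "g9")
  got <- auc_score(xm, genes, top_frac = 0.5)
  m <- 10
  hits <- sort(match(genes, paste0("g", 1:20)))  # expression = rank here
  y <- cumsum(tabulate(hits[hits <= m], nbins = m))
  expect_equal(unname(got), sum(y) / sum(pmin(1:10, 3)))
  expect_error(auc_score(xm, paste0("x", 1:30)), "larger")
})

test_that("ssGSEA-style scores are monotone and match a running-sum oracle", {
  set.seed(3)
  x <- matrix(rnorm(10 * 3), 10, 3,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:3)))
  x[, 3] <- x[, 1]  # identical samples
  genes <- c("g2", "g5", "g8")
  es <- ssgsea_score(x, genes, alpha = 0.25)
  expect_equal(es[["s3"]], es[["s1"]], tolerance = 1e-12)
  # independent oracle
  for (s in 1:2) {
    v <- x[, s]
    ord <- order(v, decreasing = TRUE)
    hit <- rownames(x)[ord] %in% genes
    w <- (10:1)^0.25 * hit
    ref <- sum(cumsum(w) / sum(w) - cumsum(!hit) / sum(!hit))
    expect_equal(unname(es[s]), ref, tolerance = 1e-12)
  }
  # moving a set gene from bottom to top strictly increases ES
  v <- sort(rnorm(10), decreasing = TRUE)
  lowx <- matrix(v, 10, 1, dimnames = list(paste0("g", 1:10), "s"))
  es_low <- ssgsea_score(cbind(lowx, lowx), c("g9", "g10"))[[1]]
  es_high <- ssgsea_score(cbind(lowx, lowx), c("g1", "g10"))[[1]]
  expect_gt(es_high, es_low)
})

test_that("ULM activities equal closed-form OLS t-values", {
  set.seed(4)
  g <- 30
  x <- matrix(rnorm(g * 4), g, 4,
              dimnames = list(paste0("g", 1:g), paste0("u", 1:4)))
  net <- tibble::tibble(tf = rep(c("TF1", "TF2"), each = 8),
                        target = paste0("g", c(1:8, 10:17)),
                        weight = rnorm(16))
  act <- ulm_activity(x, net, min_targets = 5)
  w1 <- setNames(rep(0, g), rownames(x))
  w1[net$target[net$tf == "TF1"]] <- net$weight[net$tf == "TF1"]
  for (u in 1:4) {
    fit <- summary(lm(x[, u] ~ w1))
    expect_equal(act["TF1", u], fit$coefficients["w1", "t value"],
                 tolerance = 1e-8)
  }
  # a profile proportional to the weights maximizes its own TF's t-value
  prop <- w1 + rnorm(g, sd = 1e-8)
  xp <- cbind(x, prop = prop)
  actp <- ulm_activity(xp, net, min_targets = 5)
  expect_identical(rownames(actp)[which.max(actp[, "prop"])], "TF1")
  # flat profile gives t = 0
  x0 <- cbind(x, zero = rep(0, g))
  act0 <- ulm_activity(x0, net, min_targets = 5)
  expect_equal(unname(act0[, "zero"]), c(0, 0))
  net_small <- dplyr::bind_rows(
    net[net$tf == "TF1", ],
    tibble::tibble(tf = "TF3", target = paste0("g", 20:22), weight = 1))
  expect_warning(ulm_activity(x, net_small, min_targets = 5), "TF3")
})

test_that("chi-square specificity ranking follows the textbook statistic", {
  ind <- tibble::tibble(
    tf = rep(c("TFa", "TFb"), each = 40),
    group = rep(rep(c("CM2", "CM5"), each = 20), 2),
    high = c(rep(c(1, 0), c(20, 20)),       # perfect separation
             rep(c(1, 0), 20))              # identical distribution
  )
  rk <- tf_specificity_rank(ind)
  expect_identical(rk$tf[1], "TFa")
  expect_equal(rk$statistic[rk$tf == "TFa"], 40)
  expect_equal(rk$statistic[rk$tf == "TFb"], 0)
  # textbook sum((O-E)^2/E) on an arbitrary 2x2
  ind2 <- tibble::tibble(tf = "x",
                         group = rep(c("a", "b"), c(30, 30)),
                         high = c(rep(1, 20), rep(0, 10), rep(1, 5), rep(0, 25)))
  tab <- table(ind2$group, ind2$high)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(tf_specificity_rank(ind2)$statistic,
               sum((tab - e)^2 / e), tolerance = 1e-12)
})

test_that("hypergeometric enrichment matches exact tail probabilities", {
  universe <- paste0("g", 1:20)
  sets <- list(hit = paste0("g", 1:5), other = paste0("g", 10:14),
               off = paste0("g", 16:20))
  res <- hypergeom_enrich(paste0("g", 1:5), universe, sets,
                          p_max = 1.1, q_max = 1.1)
  expect_equal(res$p_value[res$set == "hit"], 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(res$p_value[res$set == "off"], 1)  # disjoint: P(X >= 0) = 1
  # enumeration oracle for every set
  for (nm in names(sets)) {
    k <- length(intersect(paste0("g", 1:5), sets[[nm]]))
    ref <- sum(dhyper(k:5, 5, 15, 5))
    expect_equal(res$p_value[res$set == nm], ref, tolerance = 1e-12)
  }
  # gene relabelling leaves p-values unchanged
  relab <- setNames(paste0("x", 1:20), universe)
  res2 <- hypergeom_enrich(relab[paste0("g", 1:5)], relab,
                           lapply(sets, function(s) unname(relab[s])),
                           p_max = 1.1, q_max = 1.1)
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-15)
  # default cutoffs retain only significant rows, sorted by p
  strict <- hypergeom_enrich(paste0("g", 1:5), universe, sets)
  expect_identical(strict$set, "hit")
  expect_error(hypergeom_enrich("g1", character(), sets), "empty universe")
})

test_that("small regulons are scored by mean expression, large ones by rank ES", {
  set.seed(5)
  x <- matrix(rlnorm(50 * 6), 50, 6,
              dimnames = list(paste0("g", 1:50), paste0("p", 1:6)))
  regs <- list(small = c("g1", "g2"), big = paste0("g", 10:19))
  sc <- score_regulons(x, regs)
  expect_equal(sc$small, unname(colMeans(x[c("g1", "g2"), ])),
               tolerance = 1e-12)
  expect_equal(sc$big, unname(ssgsea_score(x, paste0("g", 10:19))),
               tolerance = 1e-12)
})
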