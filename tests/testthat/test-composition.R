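test_that("composition frequencies match brute-force tabulation and exclude unknowns", {
  meta <- tibble::tibble(
    patient = c(rep("p1", 10), rep("p2", 5), rep("p3", 2)),
    subpop = c(rep("A", 6), rep("B", 4), rep("A", 3), rep("unknown", 2),
               rep("unknown", 2))
  )
  expect_warning(comp <- composition_from_cells(meta, "subpop"), "p3")
  expect_equal(unlist(comp[comp$patient == "p1", c("A", "B")]),
               c(A = 0.6, B = 0.4))
  expect_equal(comp$A[comp$patient == "p2"], 1)
  # random fixture vs direct table() tabulation
  set.seed(5)
  meta2 <- tibble::tibble(patient = sample(paste0("p", 1:6), 300, TRUE),
                          subpop = sample(LETTERS[1:4], 300, TRUE))
  comp2 <- composition_from_cells(meta2, "subpop")
  tab <- prop.table(table(meta2$patient, meta2$subpop), margin = 1)
  for (p in rownames(tab)) {
    expect_equal(unlist(comp2[comp2$patient == p, colnames(tab)]),
                 tab[p, ][colnames(tab)], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("immune balance proportions and Welch t agree with closed forms", {
  meta <- tibble::tibble(
    patient = rep(paste0("p", 1:6), each = 10),
    lineage = c(rep("Myeloid", 10),                      # p1 all innate
                rep(c("Myeloid", "T"), 5),               # p2 50/50
                rep(c("Myeloid", "B"), c(3, 7)),
                rep(c("Myeloid", "T"), c(8, 2)),
                rep(c("Myeloid", "B"), c(2, 8)),
                rep(c("Myeloid", "T"), c(7, 3))),
    group = rep(c("g1", "g2"), each = 30)
  )
  ib <- immune_balance(meta, group_col = "group")
  expect_equal(ib$proportions$innate[ib$proportions$patient == "p1"], 1)
  expect_equal(ib$proportions$innate[ib$proportions$patient == "p2"], 0.5)
  expect_equal(rowSums(ib$proportions[, c("innate", "adaptive")]),
               rep(1, 6), ignore_attr = TRUE)
  a <- ib$proportions$innate[ib$proportions$group == "g1"]
  b <- ib$proportions$innate[ib$proportions$group == "g2"]
  ref <- t.test(a, b)
  expect_equal(ib$tests$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ib$tests$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("Ro/e equals O/E from margin products", {
  uni <- tibble::tibble(r = rep(c("a", "b"), each = 20),
                        c = rep(rep(c("x", "y"), each = 10), 2))
  ro <- roe(uni, "r", "c")
  expect_equal(ro$roe, rep(1, 4))

  skewed <- tibble::tibble(
    r = rep(c("a", "a", "b", "b"), c(30, 10, 10, 30)),
    c = rep(c("x", "y", "x", "y"), c(30, 10, 10, 30)))
  ro2 <- roe(skewed, "r", "c")
  lookup <- setNames(ro2$roe, paste(ro2$r, ro2$c))
  expect_equal(unname(lookup[c("a x", "a y", "b x", "b y")]),
               c(1.5, 0.5, 0.5, 1.5))
  expect_equal(attr(ro2, "statistic"),
               unname(chisq.test(table(skewed$r, skewed$c),
                                 correct = FALSE)$statistic))

  # random 5x4 tables vs brute force, and conservation of expected counts
  set.seed(8)
  for (i in 1:5) {
    df <- tibble::tibble(r = sample(letters[1:5], 400, TRUE),
                         c = sample(LETTERS[1:4], 400, TRUE))
    tab <- table(df$r, df$c)
    ro3 <- roe(df, "r", "c")
    for (j in seq_len(nrow(ro3))) {
      e <- sum(tab[ro3$r[j], ]) * sum(tab[, ro3$c[j]]) / sum(tab)
      expect_equal(ro3$roe[j], tab[ro3$r[j], ro3$c[j]] / e,
                   tolerance = 1e-12)
    }
    expect_equal(sum(ro3$expected), sum(tab), tolerance = 1e-9)
  }
  # single-column table is identically 1
  one <- tibble::tibble(r = sample(letters[1:4], 50, TRUE), c = "only")
  expect_equal(roe(one, "r", "c")$roe, rep(1, 4))
})

test_that("module discovery recovers perfect blocks and planted partitions", {
  # two perfectly correlated column blocks
  set.seed(2)
  base <- matrix(rnorm(40), 20, 2)
  x <- cbind(base[, 1], base[, 1] * 2, base[, 2], base[, 2] * 3)
  colnames(x) <- c("A1", "A2", "B1", "B2")
  comp <- dplyr::bind_cols(tibble::tibble(patient = paste0("p", 1:20)),
                           tibble::as_tibble(x))
  cm <- cooccurrence_modules(comp, k = 2)
  part <- setNames(cm$partition$module, cm$partition$subpop)
  expect_identical(part[["A1"]], part[["A2"]])
  expect_identical(part[["B1"]], part[["B2"]])
  expect_false(part[["A1"]] == part[["B1"]])

  # p-value formula vs cor.test
  ct <- cor.test(x[, 1], x[, 3])
  expect_equal(cm$p_value["A1", "B1"], ct$p.value, tolerance = 1e-12)

  # k = number of subpopulations gives singletons
  cm_all <- cooccurrence_modules(comp, k = 4)
  expect_identical(length(unique(cm_all$partition$module)), 4L)

  # invariance to patient row order
  cm_perm <- cooccurrence_modules(comp[sample(20), ], k = 2)
  expect_identical(cm$partition, cm_perm$partition)

  # planted synthetic cohort
  cfg <- cohort_config(n_patients = 200, n_subpops = 30, n_modules = 5,
                       within_module_corr = 0.8,
                       composition_noise_sd = 0.1, seed = 1)
  cs <- simulate_composition(cfg)
  cm5 <- cooccurrence_modules(cs$composition, k = 5)
  truth <- cs$truth[cm5$partition$subpop]
  expect_gte(ari(cm5$partition$module, truth), 0.9)

  expect_error(cooccurrence_modules(comp, k = 10), "exceeds")
})

test_that("dominant module assignment is a renormalized argmax with tie rule", {
  part <- tibble::tibble(subpop = c("A", "B", "C"),
                         module = c("CM1", "CM1", "CM2"))
  comp <- tibble::tibble(patient = c("p1", "p2"),
                         A = c(0.3, 0.25), B = c(0.3, 0.25), C = c(0.4, 0.5))
  dm <- dominant_module(comp, part)
  expect_identical(dm$module, c("CM1", "CM1"))  # p2: exact tie -> CM1
  expect_equal(dm$share[1], 0.6)
  # invariance to uniform row rescaling
  comp2 <- comp
  comp2[, -1] <- comp2[, -1] * 7
  expect_identical(dominant_module(comp2, part)$module, dm$module)
  # brute force on a random fixture
  set.seed(3)
  x <- matrix(runif(10 * 6), 10, 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  part2 <- tibble::tibble(subpop = paste0("s", 1:6),
                          module = rep(c("CM1", "CM2", "CM3"), each = 2))
  compr <- dplyr::bind_cols(tibble::tibble(patient = paste0("p", 1:10)),
                            tibble::as_tibble(x / rowSums(x)))
  dm2 <- dominant_module(compr, part2)
  for (i in 1:10) {
    sums <- c(CM1 = sum(x[i, 1:2]), CM2 = sum(x[i, 3:4]), CM3 = sum(x[i, 5:6]))
    expect_identical(dm2$module[i], names(which.max(sums)))
  }
})
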