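# Shared fixtures and independent oracles used across the suite.

# small deterministic count matrix with dimnames
toy_counts <- function(n_genes = 20, n_cells = 30, seed = 1,
                       gene_prefix = "G") {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_genes * n_cells, lambda = 5), n_genes, n_cells,
                dimnames = list(paste0(gene_prefix, seq_len(n_genes)),
                                paste0("c", seq_len(n_cells))))
    Matrix::Matrix(m, sparse = TRUE)
  })
}

# adjusted Rand index between two label vectors
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# brute-force Kaplan-Meier by explicit risk-set enumeration
km_oracle <- function(time, event) {
  times <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = 0, surv = 1)
  for (tt in times) {
    n_risk <- sum(time >= tt)
    d <- sum(time == tt & event == 1)
    s <- s * (1 - d / n_risk)
    out <- rbind(out, data.frame(time = tt, surv = s))
  }
  out
}

# brute-force log-rank chi-square by risk-set enumeration (g groups)
logrank_oracle <- function(time, event, group) {
  groups <- sort(unique(group))
  g <- length(groups)
  times <- sort(unique(time[event == 1]))
  o <- e <- numeric(g)
  vmat <- matrix(0, g, g)
  for (tt in times) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    d <- sum(time == tt & event == 1)
    nj <- vapply(groups, function(gr) sum(at_risk & group == gr), double(1))
    dj <- vapply(groups, function(gr) sum(time == tt & event == 1 & group == gr),
                 double(1))
    o <- o + dj
    e <- e + d * nj / n
    if (n > 1) {
      for (i in seq_len(g)) for (j in seq_len(g)) {
        delta <- as.numeric(i == j)
        vmat[i, j] <- vmat[i, j] +
          d * (n - d) / (n - 1) * nj[i] * (delta - nj[j] / n) / n
      }
    }
  }
  z <- (o - e)[-1]
  v <- vmat[-1, -1, drop = FALSE]
  chisq <- drop(t(z) %*% solve(v) %*% z)
  list(chisq = chisq, df = g - 1,
       p = pchisq(chisq, g - 1, lower.tail = FALSE))
}

# a small survival tibble generator
sim_records <- function(n, rate = 0.2, censor_rate = 0.1, lp = 0, seed = 1) {
  withr::with_seed(seed, {
    tt <- rexp(n, rate * exp(lp))
    cc <- if (censor_rate > 0) rexp(n, censor_rate) else rep(Inf, n)
    tibble::tibble(patient = sprintf("p%04d", seq_len(n)),
                   time = pmin(tt, cc), event = as.integer(tt <= cc),
                   age = round(rnorm(n, 65, 8)))
  })
}
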