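# Independent brute-force oracles: explicit element-by-element loops,
# sharing no code with the package internals.

oracle_po <- function(tab, w) {
  n <- sum(tab)
  s <- 0
  for (i in seq_len(nrow(tab)))
    for (j in seq_len(ncol(tab)))
      s <- s + w[i, j] * tab[i, j] / n
  s
}

oracle_pe <- function(tab, w) {
  n <- sum(tab)
  ri <- numeric(nrow(tab)); cj <- numeric(ncol(tab))
  for (i in seq_len(nrow(tab))) ri[i] <- sum(tab[i, ]) / n
  for (j in seq_len(ncol(tab))) cj[j] <- sum(tab[, j]) / n
  s <- 0
  for (i in seq_len(nrow(tab)))
    for (j in seq_len(ncol(tab)))
      s <- s + w[i, j] * ri[i] * cj[j]
  s
}

oracle_kappa <- function(tab, w) {
  po <- oracle_po(tab, w); pe <- oracle_pe(tab, w)
  (po - pe) / (1 - pe)
}

# Fleiss large-sample SE by direct summation
oracle_se <- function(tab, w) {
  n <- sum(tab)
  k <- nrow(tab)
  ri <- sapply(seq_len(k), function(i) sum(tab[i, ]) / n)
  cj <- sapply(seq_len(k), function(j) sum(tab[, j]) / n)
  pe <- oracle_pe(tab, w)
  wbar_i <- sapply(seq_len(k), function(i) sum(cj * w[i, ]))
  wbar_j <- sapply(seq_len(k), function(j) sum(ri * w[, j]))
  s <- 0
  for (i in seq_len(k))
    for (j in seq_len(k))
      s <- s + ri[i] * cj[j] * (w[i, j] - (wbar_i[i] + wbar_j[j]))^2
  sqrt(max(s - pe^2, 0)) / ((1 - pe) * sqrt(n))
}

# random k x k count table with at least min_n observations and a
# non-degenerate margin structure
random_table <- function(k = 5, nmax = 50, min_n = 2) {
  repeat {
    n <- sample(min_n:nmax, 1)
    p <- rgamma(k * k, shape = 0.8)
    p <- p / sum(p)
    tab <- matrix(rmultinom(1, n, p), k, k)
    # skip tables where kappa is undefined (pe == 1 happens when all
    # mass sits in one diagonal cell)
    ri <- rowSums(tab) / n; cj <- colSums(tab) / n
    if (sum(ri * cj) < 1 - 1e-9) return(tab)
  }
}

fixture_tab <- function(name) {
  path <- system.file("extdata", name, package = "kappool")
  as_crosstab(as.matrix(utils::read.csv(path, check.names = FALSE)))
}

collapsed_tab <- function() fixture_tab("quis_collapsed_counts.csv")
lowest_tab <- function() fixture_tab("quis_period_lowest_counts.csv")
highest_tab <- function() fixture_tab("quis_period_highest_counts.csv")

# paired-rating long format from a count table, for round-trip tests
tab_to_pairs <- function(tab, period = 1) {
  k <- nrow(tab); labs <- rownames(tab)
  idx <- rep.int(seq_len(k * k), c(t(tab)))  # row-major expansion
  data.frame(period = period,
             rater1 = labs[(idx - 1L) %/% k + 1L],
             rater2 = labs[(idx - 1L) %% k + 1L],
             stringsAsFactors = FALSE)
}
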