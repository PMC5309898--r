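# Independent oracles used across the suite. These deliberately avoid the
# code paths (and, where possible, the library calls) they are checking.

# Two-sided Fisher exact p for a 2x2 table by exhaustive enumeration of all
# tables with the observed margins: sum the hypergeometric probabilities of
# every table no more probable than the observed one.
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  p_obs <- pr[xs == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Classic delete-one jackknife SE of a ratio-of-sums over equally sized
# blocks, written as the explicit leave-one-out recomputation.
jackknife_loo_oracle <- function(num, den) {
  g <- length(num)
  loo <- numeric(g)
  for (j in seq_len(g)) loo[j] <- sum(num[-j]) / sum(den[-j])
  sqrt((g - 1) / g * sum((loo - mean(loo))^2))
}

# long frequency tibble from a per-site data frame with one column per group
freq_tbl <- function(df, n_ind = 10, scaffold = "chr1") {
  groups <- names(df)
  n <- nrow(df)
  dplyr::bind_rows(lapply(groups, function(g) {
    tibble::tibble(scaffold = scaffold, pos = seq_len(n), group = g,
                   freq = df[[g]], n_ind = n_ind, n_alleles = 2L * n_ind)
  }))
}

# genotype tibble from a sites-by-samples dosage matrix
geno_tbl <- function(m, sample_names = paste0("s", seq_len(ncol(m))),
                     scaffold = "chr1", pos = seq_len(nrow(m))) {
  g <- tibble::tibble(scaffold = scaffold, pos = as.integer(pos),
                      ref = "A", alt = "T")
  for (j in seq_along(sample_names)) g[[sample_names[j]]] <- as.integer(m[, j])
  g
}

popmap_tbl <- function(...) {
  groups <- list(...)
  dplyr::bind_rows(lapply(names(groups), function(g) {
    tibble::tibble(sample = groups[[g]], group = g)
  }))
}
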