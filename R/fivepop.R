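#' Haploidize one sample of a genotype table
#'
#' Collapses a diploid sample to a haploid allele sequence: homozygous
#' sites give their allele, heterozygous sites get one allele chosen
#' uniformly at random (seeded), missing stays missing.
#'
#' @param geno Genotype tibble.
#' @param sample Sample column name.
#' @param seed Integer seed for the heterozygote draws.
#' @return Integer vector (one entry per site) with 0 = reference-like
#'   allele, 1 = alternate allele, `NA` = missing.
#' @export
haploidize <- function(geno, sample, seed = 1) {
  if (!sample %in% geno_samples(geno)) abort(paste0("sample not present: ", sample))
  d <- geno[[sample]]
  out <- integer(length(d))
  out[is.na(d)] <- NA_integer_
  out[!is.na(d) & d == 2] <- 1L
  het <- !is.na(d) & d == 1
  if (any(het)) {
    out[het] <- withr::with_seed(seed, rbinom(sum(het), 1, 0.5))
  }
  out
}

fivepop_patterns <- c("ABBAA", "BABAA", "ABABA", "BAABA",
                      "ABBBA", "BABBA", "BBABA", "BBBAA")

# classify each site into one of the eight five-taxon patterns (B = derived,
# i.e. different from the outgroup allele), "other" (usable but not one of
# the eight), or NA (missing data at any taxon, or polarization failure:
# the outgroup carries the alternate allele, so the site is excluded rather
# than re-polarized).
classify_fivepop_sites <- function(h1, h2, h3a, h3b, ho) {
  n <- length(h1)
  stopifnot(length(h2) == n, length(h3a) == n, length(h3b) == n, length(ho) == n)
  usable <- !(is.na(h1) | is.na(h2) | is.na(h3a) | is.na(h3b) | is.na(ho)) &
    ho == 0L
  usable[is.na(usable)] <- FALSE
  b <- cbind(h1 != ho, h2 != ho, h3a != ho, h3b != ho)
  lab <- rep(NA_character_, n)
  code <- b[, 1] * 1000L + b[, 2] * 100L + b[, 3] * 10L + b[, 4]
  map <- c(`110` = "ABBAA", `1010` = "BABAA", `101` = "ABABA", `1001` = "BAABA",
           `111` = "ABBBA", `1011` = "BABBA", `1101` = "BBABA", `1110` = "BBBAA")
  lab[usable] <- map[as.character(code[usable])]
  lab[usable & is.na(lab)] <- "other"
  lab
}

#' Count the eight five-taxon site patterns
#'
#' For haploid sequences over the quintet (P1, P2, P3a, P3b, O), counts the
#' eight biallelic patterns (outgroup ancestral, `B` = derived) needed for
#' the four partitioned D statistics, using only sites with no missing
#' data. Sites where no taxon, only one taxon, or all four ingroup taxa
#' carry the derived allele do not match any of the eight patterns and are
#' ignored.
#'
#' @param h1,h2,h3a,h3b,ho Haploid allele vectors (see [haploidize()]),
#'   aligned over the same sites; `ho` is the outgroup.
#' @return A list with `counts` (named integer vector over the eight
#'   patterns) and `n_sites_used` (sites matching one of the eight).
#' @export
count_patterns <- function(h1, h2, h3a, h3b, ho) {
  lab <- classify_fivepop_sites(h1, h2, h3a, h3b, ho)
  if (!any(!is.na(lab))) abort("no usable sites (missing data everywhere)")
  counts <- table(factor(lab, levels = fivepop_patterns))
  list(counts = setNames(as.integer(counts), fivepop_patterns),
       n_sites_used = sum(counts))
}

#' Partitioned D statistics from five-taxon pattern counts
#'
#' The four directional contrasts:
#' `D1 = (BABAA - ABBAA) / (BABAA + ABBAA)`,
#' `D2 = (BAABA - ABABA) / (BAABA + ABABA)`,
#' `D12 = (BABBA - ABBBA) / (BABBA + ABBBA)`,
#' `D3 = (BBBAA - BBABA) / (BBBAA + BBABA)`.
#' D12 > 0 indicates derived-allele sharing of P1 with both P3a and P3b
#' (gene flow from the P3 clade into P1); D3 contrasts sharing of the P1+P2
#' clade with P3a versus P3b (gene flow out of P1 into one P3 taxon). The
#' D1/D2 completions follow the partitioned-D convention of Eaton & Ree;
#' this mapping is isolated here so it can be revised in one place.
#'
#' @param counts Named count vector or the list from [count_patterns()].
#' @return A tibble with one row per statistic: `stat`, `d` (`NA` when the
#'   defining counts are both zero), `count_pos`, `count_neg`.
#' @export
partitioned_d <- function(counts) {
  if (is.list(counts)) counts <- counts$counts
  def <- tibble(
    stat = c("D1", "D2", "D12", "D3"),
    pos = c("BABAA", "BAABA", "BABBA", "BBBAA"),
    neg = c("ABBAA", "ABABA", "ABBBA", "BBABA")
  )
  def |>
    mutate(count_pos = as.numeric(counts[.data$pos]),
           count_neg = as.numeric(counts[.data$neg]),
           d = if_else(.data$count_pos + .data$count_neg > 0,
                       (.data$count_pos - .data$count_neg) /
                         (.data$count_pos + .data$count_neg),
                       NA_real_)) |>
    select("stat", "d", "count_pos", "count_neg")
}

#' Five-population directional gene-flow test with bootstrap z scores
#'
#' Counts the eight site patterns over (P1, P2, P3a, P3b, O), computes the
#' four partitioned D statistics, and obtains z scores from `n_boot`
#' bootstrap replicates in which sites are resampled with replacement
#' (implemented as an exactly equivalent multinomial resample of the
#' per-site pattern classes). A direction of gene flow is then called from
#' the D12/D3 decision rule (see [infer_direction()]).
#'
#' @inheritParams count_patterns
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param seed Integer seed for the bootstrap.
#' @param z_threshold Significance threshold on |z| (default 3).
#' @return An object of class `ht_fivepop`: pattern `counts`,
#'   `n_sites_used`, a `stats` tibble (d, z per statistic) and
#'   `direction_call`. `tidy()` returns the stats tibble.
#' @export
bootstrap_fivepop <- function(h1, h2, h3a, h3b, ho, n_boot = 100, seed = 1,
                              z_threshold = 3) {
  lab <- classify_fivepop_sites(h1, h2, h3a, h3b, ho)
  lab <- lab[!is.na(lab)]
  if (length(lab) == 0) abort("no usable sites (missing data everywhere)")
  cls <- factor(lab, levels = c(fivepop_patterns, "other"))
  obs_tab <- table(cls)
  counts <- setNames(as.integer(obs_tab[fivepop_patterns]), fivepop_patterns)
  obs <- partitioned_d(counts)
  boot_d <- withr::with_seed(seed, {
    draws <- rmultinom(n_boot, size = length(lab), prob = as.numeric(obs_tab) / length(lab))
    rownames(draws) <- levels(cls)
    apply(draws, 2, function(ct) {
      partitioned_d(setNames(as.numeric(ct[fivepop_patterns]), fivepop_patterns))$d
    })
  })
  boot_sd <- apply(boot_d, 1, sd, na.rm = TRUE)
  z <- obs$d / boot_sd
  degenerate <- !is.na(obs$d) & obs$d != 0 & (is.na(boot_sd) | boot_sd == 0)
  if (any(degenerate)) {
    z[degenerate] <- Inf * sign(obs$d[degenerate])
    warn("bootstrap s.d. = 0 with nonzero D; z reported as infinite")
  }
  stats <- obs |> mutate(boot_sd = boot_sd, z = z)
  res <- structure(list(counts = counts, n_sites_used = sum(counts),
                        n_sites_total = length(lab), stats = stats,
                        n_boot = n_boot, seed = seed,
                        z_threshold = z_threshold,
                        direction_call = NA_character_),
                   class = "ht_fivepop")
  res$direction_call <- infer_direction(res, z_threshold = z_threshold)
  res
}

#' Call the direction of gene flow from a five-population result
#'
#' Decision rule: a significant positive D12 with non-significant D3 means
#' the shared derived alleles entered P1 from the P3 clade (`P3->P1`); a
#' significant positive D3 with non-significant D12 means gene flow from P1
#' into P3a (`P1->P3a`); significant negative D3 with non-significant D12
#' means flow from P1 into P3b (`P1->P3b`); both significant is
#' `ambiguous`; neither is `none`.
#'
#' @param result An `ht_fivepop` object (or its `stats` tibble).
#' @param z_threshold Threshold on |z| (default 3).
#' @return One of `"P3->P1"`, `"P1->P3a"`, `"P1->P3b"`, `"ambiguous"`,
#'   `"none"`.
#' @export
infer_direction <- function(result, z_threshold = 3) {
  stats <- if (inherits(result, "ht_fivepop")) result$stats else result
  z12 <- stats$z[stats$stat == "D12"]
  z3 <- stats$z[stats$stat == "D3"]
  sig12 <- !is.na(z12) && z12 >= z_threshold
  sig3_pos <- !is.na(z3) && z3 >= z_threshold
  sig3_neg <- !is.na(z3) && z3 <= -z_threshold
  sig3 <- sig3_pos || sig3_neg
  if (sig12 && !sig3) return("P3->P1")
  if (sig3_pos && !sig12) return("P1->P3a")
  if (sig3_neg && !sig12) return("P1->P3b")
  if (sig12 && sig3) return("ambiguous")
  "none"
}

#' @export
print.ht_fivepop <- function(x, ...) {
  cat("Five-population test (", x$n_sites_used, " pattern sites of ",
      x$n_sites_total, " usable)\n", sep = "")
  print(as.data.frame(x$stats), row.names = FALSE)
  cat("direction call:", x$direction_call, "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ht_fivepop <- function(x, ...) {
  x$stats |> mutate(direction_call = x$direction_call)
}

#' @exportS3Method generics::glance
glance.ht_fivepop <- function(x, ...) {
  tibble(n_sites_used = x$n_sites_used, n_boot = x$n_boot,
         direction_call = x$direction_call)
}

#' Run the five-population test over a panel of P1 individuals
#'
#' Each P1 individual is haploidized (a fresh seeded draw per individual)
#' and tested separately against the fixed P2/P3a/P3b/outgroup individuals;
#' the per-individual results and the arithmetic mean of each D statistic
#' across individuals are returned.
#'
#' @param geno Genotype tibble.
#' @param p1_samples Character vector of P1 sample names (>= 1).
#' @param p2,p3a,p3b,outgroup Single sample names for the other roles.
#' @param n_boot,seed,z_threshold Passed to [bootstrap_fivepop()].
#' @return A list with `results` (one `ht_fivepop` per P1 individual) and
#'   `mean` (tibble of mean D per statistic across individuals).
#' @export
run_fivepop_panel <- function(geno, p1_samples, p2, p3a, p3b, outgroup,
                              n_boot = 100, seed = 1, z_threshold = 3) {
  if (length(p1_samples) < 1) abort("need >= 1 P1 sample")
  base_seed <- (as.numeric(seed) * 1000) %% (2^31 - 100)
  fixed_seeds <- base_seed + seq_len(4)
  h2 <- haploidize(geno, p2, fixed_seeds[1])
  h3a <- haploidize(geno, p3a, fixed_seeds[2])
  h3b <- haploidize(geno, p3b, fixed_seeds[3])
  ho <- haploidize(geno, outgroup, fixed_seeds[4])
  results <- purrr::imap(setNames(p1_samples, p1_samples), function(s, nm) {
    i <- match(s, p1_samples)
    h1 <- haploidize(geno, s, base_seed + 10 + i)
    bootstrap_fivepop(h1, h2, h3a, h3b, ho, n_boot = n_boot,
                      seed = seed + i, z_threshold = z_threshold)
  })
  mean_d <- purrr::map(results, ~ .x$stats |> select("stat", "d")) |>
    bind_rows(.id = "p1_sample") |>
    group_by(.data$stat) |>
    summarise(mean_d = mean(.data$d, na.rm = TRUE), .groups = "drop")
  list(results = results, mean = mean_d)
}
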