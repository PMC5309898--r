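# Weir & Cockerham (1984) variance components for biallelic SNPs across r
# populations, vectorized over sites. Inputs are site x population matrices
# of sample sizes (diploid individuals), alt-allele frequencies, and
# observed heterozygote proportions.
wc84_components <- function(n_mat, p_mat, h_mat) {
  r_eff <- rowSums(n_mat > 0)
  n_mat[n_mat == 0] <- NA
  nbar <- rowMeans(n_mat, na.rm = TRUE)
  sum_n <- rowSums(n_mat, na.rm = TRUE)
  nc <- (sum_n - rowSums(n_mat^2, na.rm = TRUE) / sum_n) / (r_eff - 1)
  pbar <- rowSums(n_mat * p_mat, na.rm = TRUE) / sum_n
  s2 <- rowSums(n_mat * (p_mat - pbar)^2, na.rm = TRUE) / ((r_eff - 1) * nbar)
  hbar <- rowSums(n_mat * h_mat, na.rm = TRUE) / sum_n
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r_eff - 1) / r_eff * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r_eff - 1) / r_eff * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  tibble(a = a, b = b, c = c_, pbar = pbar, hbar = hbar, r_eff = r_eff)
}

#' Per-SNP global FST among species (Weir & Cockerham 1984)
#'
#' Multi-population theta per SNP across all species in `species`;
#' negative estimates are retained (not clamped). Sites monomorphic across
#' all species, or with fewer than two species called, get `NA`.
#'
#' @param geno Genotype tibble.
#' @param popmap Population map.
#' @param species Character vector of group names to treat as the species
#'   set (default: all groups in `popmap`).
#' @return A tibble per site: `scaffold`, `pos`, `fst`, the WC84 variance
#'   components `a`, `b`, `c`, the weighted mean frequency `pbar` and mean
#'   observed heterozygosity `hbar`.
#' @export
global_fst <- function(geno, popmap, species = unique(popmap$group)) {
  if (length(species) < 2) abort("need >= 2 species for FST")
  m <- as.matrix(geno[intersect(geno_samples(geno), popmap$sample)])
  mats <- purrr::map(species, function(g) {
    gm <- m[, popmap$sample[popmap$group == g], drop = FALSE]
    n <- rowSums(!is.na(gm))
    list(n = n,
         p = rowSums(gm, na.rm = TRUE) / (2 * pmax(n, 1)),
         h = rowSums(gm == 1, na.rm = TRUE) / pmax(n, 1))
  })
  n_mat <- do.call(cbind, purrr::map(mats, "n"))
  p_mat <- do.call(cbind, purrr::map(mats, "p"))
  h_mat <- do.call(cbind, purrr::map(mats, "h"))
  comp <- wc84_components(n_mat, p_mat, h_mat)
  fst <- with(comp, a / (a + b + c))
  fst[comp$pbar == 0 | comp$pbar == 1 | comp$r_eff < 2] <- NA_real_
  tibble(scaffold = geno$scaffold, pos = geno$pos, fst = fst,
         a = comp$a, b = comp$b, c = comp$c, pbar = comp$pbar,
         hbar = comp$hbar)
}

#' Flag high-FST outlier SNPs against a neutral island-model null
#'
#' One-tailed (high-FST) P values per SNP. The default `"simulation"`
#' method simulates a finite-island neutral null matched on expected
#' heterozygosity bins: within each bin, null SNPs draw an ancestral
#' frequency resampled from the bin, per-deme frequencies from a
#' Balding-Nichols beta with F set to the data's overall multilocus theta,
#' and genotype samples of the observed sizes; the P value is the fraction
#' of null theta values at least as large as the observed one. The
#' `"quantile"` method instead flags the empirical top `p_threshold`
#' quantile (for pipelines where a simulated null is not wanted). This is
#' a deliberately simplified stand-in for hierarchical-coalescent outlier
#' machinery: the scientific content (a one-tailed P < 0.05 high-FST flag)
#' is preserved while the null stays transparent and seedable.
#'
#' @param fst_tbl Output of [global_fst()].
#' @param n_ind Typical number of diploid individuals per species used for
#'   the null genotype sampling.
#' @param n_pops Number of species (demes).
#' @param method `"simulation"` (default) or `"quantile"`.
#' @param p_threshold Significance threshold (default 0.05).
#' @param n_null Null SNPs per heterozygosity bin (default 2000).
#' @param n_bins Number of expected-heterozygosity bins (default 8; bins
#'   with fewer than 20 SNPs are merged with a warning).
#' @param seed Seed for the null simulation.
#' @return `fst_tbl` plus columns `p_fst` and `lv_outlier`.
#' @export
flag_outliers <- function(fst_tbl, n_ind, n_pops, method = c("simulation", "quantile"),
                          p_threshold = 0.05, n_null = 2000, n_bins = 8,
                          seed = 1) {
  method <- match.arg(method)
  ok <- !is.na(fst_tbl$fst)
  p_fst <- rep(NA_real_, nrow(fst_tbl))
  if (method == "quantile") {
    rk <- rank(-fst_tbl$fst[ok], ties.method = "average")
    p_fst[ok] <- rk / (sum(ok) + 1)
  } else {
    f0 <- sum(fst_tbl$a[ok]) / sum((fst_tbl$a + fst_tbl$b + fst_tbl$c)[ok])
    f0 <- min(max(f0, 1e-4), 0.99)
    he <- 2 * fst_tbl$pbar[ok] * (1 - fst_tbl$pbar[ok])
    bin_breaks <- unique(quantile(he, probs = seq(0, 1, length.out = n_bins + 1)))
    bin <- findInterval(he, bin_breaks, rightmost.closed = TRUE, all.inside = TRUE)
    tab <- table(bin)
    if (any(tab < 20) && length(tab) > 1) {
      warn("small heterozygosity bins merged for the FST null")
      while (any(table(bin) < 20) && length(unique(bin)) > 1) {
        tb <- table(bin)
        small <- as.integer(names(tb)[which.min(tb)])
        others <- setdiff(unique(bin), small)
        bin[bin == small] <- others[which.min(abs(others - small))]
      }
    }
    pv <- rep(NA_real_, sum(ok))
    pbar_ok <- fst_tbl$pbar[ok]
    fst_ok <- fst_tbl$fst[ok]
    for (bl in unique(bin)) {
      i <- bin == bl
      null_theta <- withr::with_seed(seed + bl, {
        p_anc <- sample(pbar_ok[i], n_null, replace = TRUE)
        sim_island_theta(p_anc, f0, n_pops, n_ind)
      })
      null_theta <- null_theta[!is.na(null_theta)]
      pv[i] <- (1 + vapply(fst_ok[i],
                           function(x) sum(null_theta >= x), numeric(1))) /
        (length(null_theta) + 1)
    }
    p_fst[ok] <- pv
  }
  fst_tbl |> mutate(p_fst = p_fst, lv_outlier = !is.na(p_fst) & p_fst < p_threshold)
}

# neutral island-model SNPs: Balding-Nichols deme frequencies around p_anc
# with drift f0, binomial sampling of 2*n_ind alleles and HWE heterozygotes;
# returns the WC84 theta of each simulated SNP.
sim_island_theta <- function(p_anc, f0, n_pops, n_ind) {
  n <- length(p_anc)
  pd <- matrix(rbeta(n * n_pops, p_anc * (1 - f0) / f0,
                     (1 - p_anc) * (1 - f0) / f0), nrow = n)
  counts <- matrix(rbinom(n * n_pops, 2 * n_ind, pd), nrow = n)
  p_obs <- counts / (2 * n_ind)
  h_obs <- matrix(rbinom(n * n_pops, n_ind, 2 * pd * (1 - pd)), nrow = n) / n_ind
  comp <- wc84_components(matrix(n_ind, n, n_pops), p_obs, h_obs)
  theta <- with(comp, a / (a + b + c))
  theta[comp$pbar == 0 | comp$pbar == 1] <- NA_real_
  theta
}

#' Classify SNPs into parental ancestry categories
#'
#' For SNPs segregating in the radiation (the "LV" species set), asks where
#' each of the two alleles is found in the two parental lineages:
#' category 1 = only one of the two LV alleles observed in the Congolese
#' and Upper Nile taxa together; 2 = both LV alleles observed within the
#' Congolese taxa; 3 = Congolese monomorphic while the Upper Nile taxa are
#' polymorphic and carry the other allele; 4 = Congolese and Upper Nile
#' each fixed for alternative LV alleles. The four categories are disjoint.
#' SNPs monomorphic in the LV set are dropped; SNPs with fewer than
#' `min_parental_individuals` called in either parental group are excluded
#' (`category` NA).
#'
#' @param freqs Long frequency tibble over the LV species groups and the
#'   two parental groups (alternate-allele scale is fine; categories only
#'   use presence/absence).
#' @param lv_groups Character vector of radiation species group names.
#' @param congolese,upper_nile Parental group names.
#' @param min_parental_individuals Minimum called individuals per parental
#'   group (default 3).
#' @return A tibble per retained SNP: `scaffold`, `pos`, `category`
#'   (factor "1".."4" or NA when excluded), parental frequencies `p_congo`,
#'   `p_nile` and call counts `n_congo`, `n_nile`.
#' @export
classify_categories <- function(freqs, lv_groups, congolese, upper_nile,
                                min_parental_individuals = 3) {
  lv <- freqs |>
    dplyr::filter(.data$group %in% lv_groups) |>
    group_by(.data$scaffold, .data$pos) |>
    summarise(
      alt_in_lv = sum(.data$freq * .data$n_alleles, na.rm = TRUE) > 0,
      ref_in_lv = sum((1 - .data$freq) * .data$n_alleles, na.rm = TRUE) > 0,
      .groups = "drop") |>
    dplyr::filter(.data$alt_in_lv & .data$ref_in_lv)
  par <- freqs |>
    dplyr::filter(.data$group %in% c(congolese, upper_nile)) |>
    mutate(group = if_else(.data$group == congolese, "congo", "nile")) |>
    select("scaffold", "pos", "group", "freq", "n_ind") |>
    tidyr::pivot_wider(names_from = "group", values_from = c("freq", "n_ind"))
  out <- lv |>
    inner_join(par, by = c("scaffold", "pos")) |>
    rename(p_congo = "freq_congo", p_nile = "freq_nile",
           n_congo = "n_ind_congo", n_nile = "n_ind_nile") |>
    mutate(
      enough = .data$n_congo >= min_parental_individuals &
        .data$n_nile >= min_parental_individuals,
      congo_has_alt = .data$p_congo > 0, congo_has_ref = .data$p_congo < 1,
      nile_has_alt = .data$p_nile > 0, nile_has_ref = .data$p_nile < 1,
      congo_poly = .data$congo_has_alt & .data$congo_has_ref,
      nile_poly = .data$nile_has_alt & .data$nile_has_ref,
      category = dplyr::case_when(
        !.data$enough ~ NA_character_,
        # only one LV allele in both parental groups combined
        !(.data$congo_has_alt | .data$nile_has_alt) |
          !(.data$congo_has_ref | .data$nile_has_ref) ~ "1",
        .data$congo_poly ~ "2",
        !.data$congo_poly & .data$nile_poly ~ "3",
        # congolese fixed one allele, nile fixed for the other
        (.data$p_congo == 0 & .data$p_nile == 1) |
          (.data$p_congo == 1 & .data$p_nile == 0) ~ "4",
        TRUE ~ NA_character_
      ),
      category = factor(.data$category, levels = c("1", "2", "3", "4"))
    ) |>
    select("scaffold", "pos", "category", "p_congo", "p_nile",
           "n_congo", "n_nile")
  out
}

#' Select the frequency-matched control SNP set (category 5)
#'
#' Weights the parental allele frequencies by the inferred ancestry
#' proportions (`f = p_congo * w_congo + p_nile * w_nile`), folds to a
#' weighted minor allele frequency `min(f, 1 - f)`, and flags sites whose
#' weighted MAF falls in `window` - excluding sites divergently fixed
#' between the parents (category 4). These controls have the same expected
#' initial allele frequency in the radiation as divergently fixed sites,
#' without being candidate incompatibility loci.
#'
#' @param cat_tbl Output of [classify_categories()].
#' @param w_congo,w_nile Ancestry weights (must sum to 1; defaults
#'   0.84/0.16).
#' @param window Inclusive weighted-MAF window (default `c(0.14, 0.18)`).
#' @return `cat_tbl` plus `weighted_maf` and logical `control`.
#' @export
select_control_set <- function(cat_tbl, w_congo = 0.84, w_nile = 0.16,
                               window = c(0.14, 0.18)) {
  if (abs(w_congo + w_nile - 1) > 1e-9) abort("w_congo + w_nile must equal 1")
  f <- cat_tbl$p_congo * w_congo + cat_tbl$p_nile * w_nile
  wmaf <- pmin(f, 1 - f)
  cat_tbl |>
    mutate(weighted_maf = wmaf,
           control = !is.na(wmaf) &
             wmaf >= window[1] & wmaf <= window[2] &
             (is.na(.data$category) | .data$category != "4"))
}

#' Outlier enrichment across ancestry categories
#'
#' Per category: SNP count, outlier count and proportion, plus a two-sided
#' Fisher exact P value for the 2x2 table (outlier x category membership)
#' of each category against the reference category (default the
#' frequency-matched control set, "5").
#'
#' @param cat_tbl Category tibble with a `control` column (see
#'   [select_control_set()]).
#' @param outliers Logical vector (or tibble from [flag_outliers()], matched
#'   on scaffold/pos) marking high-FST outlier SNPs.
#' @param reference Reference category for the Fisher tests (default "5",
#'   the control set).
#' @return An object of class `ht_enrichment`; `tidy()` gives the
#'   per-category table (`category`, `n_snps`, `n_outliers`,
#'   `outlier_proportion`, `p_vs_reference`).
#' @export
enrichment <- function(cat_tbl, outliers, reference = "5") {
  if (is.data.frame(outliers)) {
    cat_tbl <- cat_tbl |>
      left_join(select(outliers, "scaffold", "pos", "lv_outlier"),
                by = c("scaffold", "pos"))
    outliers <- cat_tbl$lv_outlier
  }
  stopifnot(length(outliers) == nrow(cat_tbl))
  member <- list(
    "1" = !is.na(cat_tbl$category) & cat_tbl$category == "1",
    "2" = !is.na(cat_tbl$category) & cat_tbl$category == "2",
    "3" = !is.na(cat_tbl$category) & cat_tbl$category == "3",
    "4" = !is.na(cat_tbl$category) & cat_tbl$category == "4",
    "5" = if ("control" %in% names(cat_tbl)) cat_tbl$control else
      rep(FALSE, nrow(cat_tbl))
  )
  tab <- purrr::imap(member, function(m, nm) {
    tibble(category = nm, n_snps = sum(m, na.rm = TRUE),
           n_outliers = sum(outliers & m, na.rm = TRUE))
  }) |>
    bind_rows() |>
    mutate(outlier_proportion = if_else(.data$n_snps > 0,
                                        .data$n_outliers / .data$n_snps, NA_real_))
  if (!reference %in% tab$category || tab$n_snps[tab$category == reference] == 0) {
    warn("empty reference category; Fisher tests skipped")
    tab$p_vs_reference <- NA_real_
  } else {
    ref_m <- member[[reference]]
    ref_out <- sum(outliers & ref_m, na.rm = TRUE)
    ref_non <- sum(ref_m, na.rm = TRUE) - ref_out
    tab$p_vs_reference <- purrr::map2_dbl(tab$category, tab$n_snps, function(cat, n) {
      if (cat == reference) return(NA_real_)
      if (n == 0) {
        warn(paste0("empty category ", cat, "; Fisher test skipped"))
        return(NA_real_)
      }
      m <- member[[cat]]
      out_n <- sum(outliers & m, na.rm = TRUE)
      fisher.test(matrix(c(out_n, n - out_n, ref_out, ref_non), nrow = 2))$p.value
    })
  }
  structure(list(table = tab, reference = reference), class = "ht_enrichment")
}

#' @export
print.ht_enrichment <- function(x, ...) {
  cat("LV-outlier enrichment by ancestry category (reference:",
      x$reference, ")\n")
  print(as.data.frame(x$table), row.names = FALSE)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ht_enrichment <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.ht_enrichment <- function(x, ...) {
  tibble(n_categories = sum(x$table$n_snps > 0), reference = x$reference)
}

#' Enrichment robustness to the assumed ancestry weighting
#'
#' Recomputes the control-set selection and the enrichment table for a
#' range of Upper Nile ancestry weights.
#'
#' @param cat_tbl Output of [classify_categories()].
#' @param outliers Logical vector or [flag_outliers()] tibble.
#' @param nile_weights Upper Nile weights to sweep (default 0.10-0.30 by
#'   0.05).
#' @param window Weighted-MAF window passed to [select_control_set()].
#' @param reference Reference category for the Fisher tests.
#' @return A tibble of per-weight enrichment tables with a `w_nile` column.
#' @export
weight_robustness <- function(cat_tbl, outliers,
                              nile_weights = seq(0.10, 0.30, by = 0.05),
                              window = c(0.14, 0.18), reference = "5") {
  stopifnot(all(nile_weights > 0), all(nile_weights < 1))
  purrr::map(nile_weights, function(w) {
    ct <- select_control_set(cat_tbl, w_congo = 1 - w, w_nile = w,
                             window = window)
    tidy(enrichment(ct, outliers, reference = reference)) |>
      mutate(w_nile = w, .before = 1)
  }) |> bind_rows()
}

#' Do control species pairs fix LV-outlier alleles more often?
#'
#' For each pair of control species (taxa outside the radiation), restricts
#' to category-4 sites (divergently fixed between the parental lineages)
#' with at least `min_genotypes` called individuals in both species, asks
#' whether each site is differentially fixed between the two control
#' species, and Fisher-tests (two-sided) the 2x2 table of LV-outlier status
#' against differential fixation. A uniform/non-significant result says
#' the outlier enrichment at category-4 sites is not explained by an
#' inherently higher fixation probability of those loci.
#'
#' @param geno Genotype tibble.
#' @param popmap Population map covering the control species.
#' @param pairs List of length-2 character vectors of control group names.
#' @param cat4_sites Tibble with `scaffold`, `pos` of category-4 sites.
#' @param outliers Tibble from [flag_outliers()] (`scaffold`, `pos`,
#'   `lv_outlier`).
#' @param min_genotypes Minimum called individuals per species (default 3).
#' @return A tibble per pair: `species_a`, `species_b`, `n_sites`,
#'   `n_diff_fixed`, `p_value` (p = 1 with a warning when a table margin is
#'   degenerate).
#' @export
control_fixation_test <- function(geno, popmap, pairs, cat4_sites, outliers,
                                  min_genotypes = 3) {
  sites <- cat4_sites |>
    select("scaffold", "pos") |>
    left_join(select(outliers, "scaffold", "pos", "lv_outlier"),
              by = c("scaffold", "pos"))
  gsub_ <- semi_join(geno, sites, by = c("scaffold", "pos"))
  key <- paste(gsub_$scaffold, gsub_$pos)
  sites <- sites[match(key, paste(sites$scaffold, sites$pos)), ]
  res <- purrr::map(pairs, function(pr) {
    sa <- popmap$sample[popmap$group == pr[1]]
    sb <- popmap$sample[popmap$group == pr[2]]
    ma <- as.matrix(gsub_[sa]); mb <- as.matrix(gsub_[sb])
    na_ <- rowSums(!is.na(ma)); nb_ <- rowSums(!is.na(mb))
    ok <- na_ >= min_genotypes & nb_ >= min_genotypes
    if (!any(ok)) {
      warn(paste0("no qualifying sites for pair ", pr[1], "/", pr[2]))
      return(NULL)
    }
    pa <- rowSums(ma, na.rm = TRUE) / (2 * pmax(na_, 1))
    pb <- rowSums(mb, na.rm = TRUE) / (2 * pmax(nb_, 1))
    diff_fixed <- ok & ((pa == 0 & pb == 1) | (pa == 1 & pb == 0))
    out <- sites$lv_outlier & ok
    tab <- matrix(c(sum(out & diff_fixed, na.rm = TRUE),
                    sum(out & !diff_fixed, na.rm = TRUE),
                    sum(!out & diff_fixed & ok, na.rm = TRUE),
                    sum(!out & !diff_fixed & ok, na.rm = TRUE)), nrow = 2)
    p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      warn(paste0("degenerate 2x2 table for pair ", pr[1], "/", pr[2],
                  "; p = 1 by convention"))
      1
    } else fisher.test(tab)$p.value
    tibble(species_a = pr[1], species_b = pr[2], n_sites = sum(ok),
           n_diff_fixed = sum(diff_fixed, na.rm = TRUE), p_value = p)
  })
  bind_rows(res)
}
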