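# textbook WC84 components for one biallelic SNP, plain-loop arithmetic
wc84_oracle <- function(n_i, p_i, h_i) {
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  pbar <- sum(n_i * p_i) / sum(n_i)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / sum(n_i)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

test_that("per-SNP FST matches hand-computed WC84 components", {
  # two species of 5 diploids; site 1 fixed difference, site 2 intermediate
  sp1 <- cbind(c(0L, 1L), c(0L, 1L), c(0L, 0L), c(0L, 1L), c(0L, 0L))
  sp2 <- cbind(c(2L, 2L), c(2L, 1L), c(2L, 2L), c(2L, 1L), c(2L, 2L))
  g <- geno_tbl(cbind(sp1, sp2), sample_names = paste0("s", 1:10))
  pm <- popmap_tbl(A = paste0("s", 1:5), B = paste0("s", 6:10))
  fst <- global_fst(g, pm)
  expect_equal(fst$fst[1], 1) # divergently fixed
  for (i in 1:2) {
    n_i <- c(5, 5)
    p_i <- c(mean(sp1[i, ]) / 2, mean(sp2[i, ]) / 2)
    h_i <- c(mean(sp1[i, ] == 1), mean(sp2[i, ] == 1))
    expect_equal(fst$fst[i], wc84_oracle(n_i, p_i, h_i))
  }
})

test_that("identical allele frequencies across species give FST near zero", {
  set.seed(10)
  m <- matrix(rbinom(200 * 12, 2, 0.5), nrow = 200)
  g <- geno_tbl(m, sample_names = paste0("s", 1:12))
  pm <- popmap_tbl(A = paste0("s", 1:4), B = paste0("s", 5:8),
                   C = paste0("s", 9:12))
  fst <- global_fst(g, pm)
  expect_lt(abs(mean(fst$fst, na.rm = TRUE)), 0.02)
  # negative estimates are retained, not clamped
  expect_true(any(fst$fst < 0, na.rm = TRUE))
})

test_that("monomorphic sites get NA FST", {
  g <- geno_tbl(matrix(0L, 2, 8), sample_names = paste0("s", 1:8))
  pm <- popmap_tbl(A = paste0("s", 1:4), B = paste0("s", 5:8))
  expect_true(all(is.na(global_fst(g, pm)$fst)))
})

test_that("an extreme SNP is flagged and degenerate thresholds behave", {
  set.seed(11)
  m <- matrix(rbinom(400 * 12, 2, runif(400, 0.2, 0.8)), nrow = 400)
  m[1, 1:6] <- 0L; m[1, 7:12] <- 2L # one fixed difference
  g <- geno_tbl(m, sample_names = paste0("s", 1:12))
  pm <- popmap_tbl(A = paste0("s", 1:6), B = paste0("s", 7:12))
  fst <- global_fst(g, pm)
  fl <- flag_outliers(fst, n_ind = 6, n_pops = 2, n_null = 500, seed = 3)
  expect_true(fl$lv_outlier[1])
  flq <- flag_outliers(fst, n_ind = 6, n_pops = 2, method = "quantile",
                       p_threshold = 1)
  expect_true(all(flq$lv_outlier[!is.na(flq$fst)]))
})

test_that("the island-model null is calibrated: ~5% flagged under neutrality", {
  # neutral island-model data generated independently of the package
  withr::with_seed(202, {
    n <- 4000; r <- 6; nd <- 8; f <- 0.1
    p0 <- runif(n, 0.1, 0.9)
    dos <- matrix(0L, n, r * nd)
    for (k in seq_len(r)) {
      pk <- rbeta(n, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
      for (j in seq_len(nd)) {
        dos[, (k - 1) * nd + j] <- rbinom(n, 2, pk)
      }
    }
  })
  g <- geno_tbl(dos, sample_names = paste0("s", seq_len(6 * 8)))
  pm <- dplyr::bind_rows(lapply(1:6, function(k) {
    tibble::tibble(sample = paste0("s", (k - 1) * 8 + 1:8),
                   group = paste0("sp", k))
  }))
  fst <- global_fst(g, pm)
  fl <- flag_outliers(fst, n_ind = 8, n_pops = 6, n_null = 1000, seed = 5)
  rate <- mean(fl$lv_outlier[!is.na(fl$fst)])
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

make_cat_freqs <- function(p_lv1, p_lv2, p_congo, p_nile, n_par = 5) {
  n <- length(p_congo)
  dplyr::bind_rows(
    tibble::tibble(scaffold = "chr1", pos = seq_len(n), group = "lv1",
                   freq = p_lv1, n_ind = 10L, n_alleles = 20L),
    tibble::tibble(scaffold = "chr1", pos = seq_len(n), group = "lv2",
                   freq = p_lv2, n_ind = 10L, n_alleles = 20L),
    tibble::tibble(scaffold = "chr1", pos = seq_len(n), group = "congo",
                   freq = p_congo, n_ind = n_par, n_alleles = 2L * n_par),
    tibble::tibble(scaffold = "chr1", pos = seq_len(n), group = "nile",
                   freq = p_nile, n_ind = n_par, n_alleles = 2L * n_par)
  )
}

test_that("ancestry categories follow the presence/absence rules", {
  fr <- make_cat_freqs(
    p_lv1 = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
    p_lv2 = c(0.4, 0.4, 0.4, 0.4, 0.4, 0.0),
    p_congo = c(0, 0.3, 0, 0, 1, 0),
    p_nile = c(1, 1, 0.4, 0, 0, 0.5)
  )
  ct <- classify_categories(fr, c("lv1", "lv2"), "congo", "nile")
  expect_equal(as.character(ct$category),
               c("4",  # congo fixed ref, nile fixed alt
                 "2",  # both LV alleles within congo
                 "3",  # congo fixed, nile polymorphic
                 "1",  # alt allele absent from both parents
                 "4",  # mirrored fixation
                 "3"))
})

test_that("LV-monomorphic and under-covered parental sites are excluded", {
  fr <- make_cat_freqs(p_lv1 = c(0, 0.5), p_lv2 = c(0, 0.5),
                       p_congo = c(0.5, 0.5), p_nile = c(0.5, 0.5),
                       n_par = 2) # below min individuals
  ct <- classify_categories(fr, c("lv1", "lv2"), "congo", "nile",
                            min_parental_individuals = 3)
  expect_equal(nrow(ct), 1) # monomorphic site dropped entirely
  expect_true(is.na(ct$category))
})

test_that("categories 1-4 partition classified SNPs on simulated data", {
  sim <- sim_hybrid_swarm(sim_config(seed = 31, n_sites = 3000, n_species = 2,
                                     n_control_pairs = 0))
  fr <- allele_freqs(sim$geno, sim$popmap)
  ct <- classify_categories(fr, c("lv_sp1", "lv_sp2"), "congolese",
                            "upper_nile")
  expect_true(all(table(ct$category, useNA = "no") >= 0))
  expect_false(any(duplicated(ct[c("scaffold", "pos")])))
  expect_true(all(!is.na(ct$category) | ct$n_congo < 3 | ct$n_nile < 3))
})

test_that("category recovery is high with large parental samples", {
  sim <- sim_hybrid_swarm(sim_config(seed = 9, n_sites = 4000, n_diploids = 20,
                                     n_species = 2, n_control_pairs = 0))
  fr <- allele_freqs(sim$geno, sim$popmap)
  ct <- classify_categories(fr, c("lv_sp1", "lv_sp2"), "congolese",
                            "upper_nile")
  m <- dplyr::inner_join(ct, sim$truth$sites[c("pos", "true_category")],
                         by = "pos")
  m <- m[!is.na(m$category), ]
  expect_gte(mean(as.character(m$category) == as.character(m$true_category)),
             0.95)
})

test_that("the weighted control set reproduces the worked example", {
  fr <- make_cat_freqs(p_lv1 = c(0.5, 0.5, 0.5), p_lv2 = c(0.4, 0.4, 0.4),
                       p_congo = c(0.1, 0, 0.5), p_nile = c(0.5, 1, 0.5))
  ct <- select_control_set(classify_categories(fr, c("lv1", "lv2"),
                                               "congo", "nile"))
  # 0.1 * 0.84 + 0.5 * 0.16 = 0.164, inside the 14-18% window
  expect_equal(ct$weighted_maf[1], 0.164)
  expect_true(ct$control[1])
  # divergently fixed site: weighted maf 0.16 but category 4 -> excluded
  expect_equal(ct$weighted_maf[2], 0.16)
  expect_false(ct$control[2])
  # weighted maf 0.5 is outside the window
  expect_false(ct$control[3])
  expect_error(select_control_set(ct, w_congo = 0.8, w_nile = 0.1),
               "must equal 1")
})

test_that("Fisher enrichment p-values match the enumeration oracle", {
  ct <- tibble::tibble(
    scaffold = "chr1", pos = 1:20,
    category = factor(rep(c("4", NA), each = 10), levels = as.character(1:4)),
    control = rep(c(FALSE, TRUE), each = 10)
  )
  # (10,0;0,10): all category-4 SNPs outliers, no control outliers
  outliers <- rep(c(TRUE, FALSE), each = 10)
  enr <- suppressWarnings(enrichment(ct, outliers)) # only categories 4 and 5 populated
  p4 <- tidy(enr)$p_vs_reference[tidy(enr)$category == "4"]
  expect_equal(p4, fisher_enum_oracle(10, 0, 0, 10))

  # (1,1;1,1): no association -> p = 1
  ct2 <- ct[c(1, 2, 11, 12), ]
  enr2 <- suppressWarnings(enrichment(ct2, c(TRUE, FALSE, TRUE, FALSE)))
  expect_equal(tidy(enr2)$p_vs_reference[tidy(enr2)$category == "4"], 1)

  # equal proportions at a larger size stay non-significant
  ct3 <- tibble::tibble(scaffold = "chr1", pos = 1:100,
                        category = factor(rep(c("4", NA), each = 50),
                                          levels = as.character(1:4)),
                        control = rep(c(FALSE, TRUE), each = 50))
  out3 <- rep(rep(c(TRUE, FALSE), c(10, 40)), 2)
  enr3 <- suppressWarnings(enrichment(ct3, out3))
  expect_gte(tidy(enr3)$p_vs_reference[tidy(enr3)$category == "4"], 0.99)
})

test_that("fisher.test agrees with the enumeration oracle on a hand-built table", {
  expect_equal(stats::fisher.test(matrix(c(3, 7, 2, 8), 2))$p.value,
               fisher_enum_oracle(3, 7, 2, 8))
})

test_that("the 0.16 weighting in the robustness sweep reproduces the default", {
  sim <- sim_hybrid_swarm(sim_config(seed = 41, n_sites = 4000, n_species = 2,
                                     n_control_pairs = 0))
  fr <- allele_freqs(sim$geno, sim$popmap)
  ct <- classify_categories(fr, c("lv_sp1", "lv_sp2"), "congolese",
                            "upper_nile")
  fst <- global_fst(sim$geno, sim$popmap, species = c("lv_sp1", "lv_sp2"))
  fl <- flag_outliers(fst, n_ind = 10, n_pops = 2, n_null = 300, seed = 2)
  sweep <- weight_robustness(ct, fl, nile_weights = c(0.10, 0.16, 0.30))
  default <- tidy(enrichment(select_control_set(ct), fl))
  w16 <- dplyr::filter(sweep, w_nile == 0.16) |> dplyr::select(-w_nile)
  expect_equal(as.data.frame(w16), as.data.frame(default))
  # different weights change the control-set membership
  n5 <- sweep$n_snps[sweep$category == "5"]
  expect_true(length(unique(n5)) > 1)
})

test_that("control pairs with no fixed differences give p = 1 with a warning", {
  # two control species sharing identical intermediate frequencies
  set.seed(6)
  m <- matrix(rbinom(20 * 8, 2, 0.5), nrow = 20)
  m[, 1] <- 1L # keep every site polymorphic in species A
  g <- geno_tbl(m, sample_names = paste0("s", 1:8))
  pm <- popmap_tbl(ca = paste0("s", 1:4), cb = paste0("s", 5:8))
  cat4 <- tibble::tibble(scaffold = "chr1", pos = 1:20)
  outl <- tibble::tibble(scaffold = "chr1", pos = 1:20,
                         lv_outlier = rep(c(TRUE, FALSE), 10))
  expect_warning(
    res <- control_fixation_test(g, pm, list(c("ca", "cb")), cat4, outl),
    "degenerate"
  )
  expect_equal(res$p_value, 1)
  expect_equal(res$n_diff_fixed, 0)
})

test_that("ancestry-independent control fixation is not outlier-enriched", {
  sim <- sim_hybrid_swarm(sim_config(seed = 51, n_sites = 8000, n_species = 2,
                                     n_control_pairs = 2, frac_bdm = 0.05))
  fr <- allele_freqs(sim$geno, sim$popmap)
  ct <- classify_categories(fr, c("lv_sp1", "lv_sp2"), "congolese",
                            "upper_nile")
  fst <- global_fst(sim$geno, sim$popmap, species = c("lv_sp1", "lv_sp2"))
  fl <- flag_outliers(fst, n_ind = 10, n_pops = 2, n_null = 500, seed = 7)
  cat4 <- dplyr::filter(ct, category == "4")
  res <- suppressWarnings(control_fixation_test(
    sim$geno, sim$popmap,
    list(c("ctrl1a", "ctrl1b"), c("ctrl2a", "ctrl2b")), cat4, fl))
  expect_true(all(res$p_value > 0.001))
})
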