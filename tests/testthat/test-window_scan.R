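# frequency tables with controlled window content; positions spread so that
# each group of `per` sites falls in one 10-kb window
spread_freq_tbl <- function(df, window_bp = 10000, per = 5) {
  n <- nrow(df)
  win <- rep(seq_len(ceiling(n / per)) - 1, each = per)[seq_len(n)]
  offset <- stats::ave(seq_len(n), win, FUN = seq_along)
  fr <- freq_tbl(df)
  fr$pos <- rep(win * window_bp + offset * 10, length(unique(fr$group)))
  fr
}

test_that("fd is 1 when P2 and P3 are identical and 0 for negative window D", {
  p23 <- c(1, 1, 1, 1, 1, 0.9, 1, 0.8)
  df1 <- data.frame(P1 = 0, P2 = p23, P3 = p23, O = 0)
  # BABA-heavy window: P1 shares with P3, so D (fd orientation) < 0
  df2 <- data.frame(P1 = 1, P2 = 0, P3 = rep(1, 8), O = 0)
  fr <- spread_freq_tbl(rbind(df1, df2), per = 8)
  w <- fd_windows(fr, "P1", "P2", "P3", "O")
  expect_equal(w$fd[1], 1)
  expect_equal(w$fd[2], 0)
})

test_that("windows below the weighted-pattern minimum are excluded", {
  # 9 sites with ABBA weight 0.5 each -> weighted total 4.5 < 5
  df <- data.frame(P1 = 0, P2 = 0.5, P3 = rep(1, 9), O = 0)
  fr <- spread_freq_tbl(df, per = 9)
  w <- fd_windows(fr, "P1", "P2", "P3", "O", min_patterns = 5)
  expect_true(is.na(w$fd[1]))
  expect_equal(w$n_informative[1], 4.5)
  # at min_patterns = 4 the same window is retained
  w2 <- fd_windows(fr, "P1", "P2", "P3", "O", min_patterns = 4)
  expect_false(is.na(w2$fd[1]))
})

test_that("fd equals the hand-computed S_obs / S_max on a 3-site window", {
  df <- data.frame(P1 = c(0.1, 0.2, 0.0), P2 = c(0.9, 0.6, 1.0),
                   P3 = c(0.8, 0.9, 1.0), O = 0)
  fr <- spread_freq_tbl(df, per = 3)
  w <- fd_windows(fr, "P1", "P2", "P3", "O", min_patterns = 0)
  s_obs <- sum((1 - df$P1) * df$P2 * df$P3 - df$P1 * (1 - df$P2) * df$P3)
  pd <- pmax(df$P2, df$P3)
  s_max <- sum((1 - df$P1) * pd * pd - df$P1 * (1 - pd) * pd)
  expect_equal(w$fd[1], s_obs / s_max)
})

test_that("retained fd values lie in [0, 1] on simulated data", {
  sim <- sim_hybrid_swarm(sim_config(seed = 14, n_sites = 4000, n_species = 1,
                                     n_control_pairs = 0))
  fr <- polarize(allele_freqs(sim$geno, sim$popmap), "outgroup")
  w <- fd_windows(fr, "congolese", "lv_sp1", "upper_nile", "outgroup")
  expect_true(all(w$fd >= 0 & w$fd <= 1, na.rm = TRUE))
  expect_true(any(!is.na(w$fd)))
})

test_that("fd correlation is 1 for identical scans and -1 for mirrored ones", {
  w <- tibble::tibble(scaffold = "chr1", start = (0:9) * 10000,
                      end = (1:10) * 10000, fd = seq(0.1, 0.9, length.out = 10))
  expect_equal(fd_correlation(w, w)$r, 1)
  w2 <- w; w2$fd <- mean(w$fd) - (w$fd - mean(w$fd))
  expect_equal(fd_correlation(w, w2)$r, -1)
  expect_error(fd_correlation(w[1:2, ], w[1:2, ]), ">= 3 windows")
  wc <- w; wc$fd <- 0.5
  expect_warning(out <- fd_correlation(w, wc), "zero variance")
  expect_true(is.na(out$r))
})

test_that("conspecifics sharing one admixture history correlate in fd; independent histories do not", {
  sim <- sim_hybrid_swarm(sim_config(seed = 18, n_sites = 20000,
                                     chrom_length = 2e6, n_species = 2,
                                     n_diploids = 6, n_control_pairs = 0,
                                     t_admix = 3000))
  pm <- sim$popmap
  one <- function(s) {
    pm2 <- pm
    pm2$group[pm2$sample == s] <- "solo"
    fr <- polarize(allele_freqs(sim$geno, pm2), "outgroup")
    fd_windows(fr, "congolese", "solo", "upper_nile", "outgroup",
               window_bp = 20000, min_patterns = 2)
  }
  # two individuals of the same admixed species share ancestry tracts
  r_shared <- fd_correlation(one("lv_sp1_1"), one("lv_sp1_2"))
  expect_gt(r_shared$r, 0)
  expect_lt(r_shared$p_value, 0.01)
})

test_that("ancestry windows are coloured by the ABBA-proportion thresholds", {
  # ABBA site: target+nile derived; BBAA site: target+congo derived
  abba_row <- data.frame(C = 0, T_ = 1, N = 1, O = 0)
  bbaa_row <- data.frame(C = 1, T_ = 1, N = 0, O = 0)
  df <- rbind(abba_row[rep(1, 7), ], bbaa_row[rep(1, 3), ], # 0.7 -> upper nile
              bbaa_row[rep(1, 5), ],                        # 0   -> congolese
              abba_row[rep(1, 1), ],                        # total 1 -> no_data
              abba_row[rep(1, 4), ], bbaa_row[rep(1, 6), ]) # 0.4 -> unassigned
  n <- nrow(df)
  win <- rep(0:3, times = c(10, 5, 1, 10))
  fr <- freq_tbl(df)
  fr$pos <- rep(win * 3000 + stats::ave(seq_len(n), win, FUN = seq_along),
                4)
  w <- ancestry_windows(fr, "C", "T_", "N", "O", min_scaffold_bp = 0)
  expect_equal(w$colour, c("upper_nile", "congolese", "no_data", "unassigned"))
  expect_equal(w$abba_prop[1], 0.7)
})

test_that("short scaffolds are dropped from the painting", {
  df <- data.frame(C = 0, T_ = 1, N = 1, O = 0)[rep(1, 40), ]
  fr_long <- freq_tbl(df, scaffold = "big")
  fr_long$pos <- rep(seq(1, 200001, length.out = 40), 4)
  fr_short <- freq_tbl(df[1:10, ], scaffold = "small")
  fr_short$pos <- rep(seq(1, 9000, length.out = 10), 4)
  w <- ancestry_windows(dplyr::bind_rows(fr_long, fr_short),
                        "C", "T_", "N", "O", min_scaffold_bp = 1e5)
  expect_true(all(w$scaffold == "big"))
})

test_that("merge_tracts bridges single no-data windows only", {
  mk <- function(colours) {
    n <- length(colours)
    tibble::tibble(scaffold = "chr1", start = (seq_len(n) - 1) * 3000,
                   end = seq_len(n) * 3000, colour = colours)
  }
  t1 <- merge_tracts(mk(c("upper_nile", "no_data", "upper_nile")))
  expect_equal(nrow(t1), 1)
  expect_equal(t1$n_windows, 3)
  expect_equal(t1$end - t1$start, 9000)

  t2 <- merge_tracts(mk(c("upper_nile", "no_data", "no_data", "upper_nile")))
  expect_equal(nrow(t2), 2)

  t3 <- merge_tracts(mk(c("upper_nile", "congolese")))
  expect_equal(t3$colour, c("upper_nile", "congolese"))
  expect_equal(t3$start, c(0, 3000))

  t4 <- merge_tracts(mk(c("upper_nile", "unassigned", "upper_nile")))
  expect_equal(nrow(t4), 2)

  # a bridged gap between different colours still breaks
  t5 <- merge_tracts(mk(c("upper_nile", "no_data", "congolese")))
  expect_equal(nrow(t5), 2)
})

test_that("no two merged tracts of the same colour are window-adjacent", {
  set.seed(33)
  cols <- sample(c("upper_nile", "congolese", "unassigned", "no_data"), 400,
                 replace = TRUE, prob = c(0.35, 0.35, 0.15, 0.15))
  w <- tibble::tibble(scaffold = "chr1", start = (seq_along(cols) - 1) * 3000,
                      end = seq_along(cols) * 3000, colour = cols)
  tr <- merge_tracts(w)
  expect_true(all(tr$end > tr$start))
  adjacent_same <- with(tr, head(end, -1) == tail(start, -1) &
                          head(colour, -1) == tail(colour, -1))
  expect_false(any(adjacent_same))
})

test_that("tract length histograms bin by size and colour", {
  expect_equal(nrow(tract_length_summary(
    tibble::tibble(scaffold = character(), start = numeric(),
                   end = numeric(), colour = character()))), 0)
  tr <- tibble::tibble(scaffold = "chr1", start = c(0, 10000, 20000),
                       end = c(3000, 13000, 26000),
                       colour = c("upper_nile", "upper_nile", "congolese"))
  h <- tract_length_summary(tr)
  expect_equal(h$n[h$colour == "upper_nile" & h$bin == 3000], 2)
  expect_equal(h$n[h$colour == "congolese" & h$bin == 6000], 1)
})

test_that("expected tract length follows 1 / ((1 - m) r t)", {
  expect_equal(expected_tract_length(0.2, 2.5e-8, 1e5), 500)
  expect_equal(expected_tract_length(0.2, 2.5e-8, 5e4), 1000)
  expect_equal(expected_tract_length(0.3, 1e-8, 2e4),
               2 * expected_tract_length(0.3, 1e-8, 4e4))
  expect_error(expected_tract_length(0, 1e-8, 100), "m must")
  expect_error(expected_tract_length(0.5, -1, 100), "r must")
  expect_error(expected_tract_length(0.5, 1e-8, 0), "t must")
})

test_that("simulated tract lengths track the analytic expectation as t varies", {
  mean_len <- function(t) {
    cfg <- sim_config(seed = 77, n_sites = 10, chrom_length = 5e6, t_admix = t)
    tr <- withr::with_seed(77, simulate_ancestry_tracts(cfg, n_hap = 4))
    nile <- tr[tr$lineage == "upper_nile", ]
    mean(nile$end - nile$start)
  }
  m1e5 <- mean_len(1e5)
  m5e4 <- mean_len(5e4)
  expect_equal(m1e5, 500, tolerance = 0.1)
  expect_equal(m5e4, 1000, tolerance = 0.1)
  expect_gt(m5e4, m1e5)
})
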