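#' Per-site ABBA and BABA weights from derived allele frequencies
#'
#' Each segregating site is weighted by its fit to the ABBA or BABA pattern:
#' `abba_w = (1 - p1) * p2 * p3 * (1 - p4)` and
#' `baba_w = p1 * (1 - p2) * p3 * (1 - p4)`, where `p1..p4` are derived
#' allele frequencies in populations P1, P2, P3 and the outgroup. A site
#' with frequencies (0, 0.5, 1, 0) counts as half an ABBA site.
#'
#' @param p1,p2,p3,p4 Numeric vectors of derived allele frequencies in
#'   \[0, 1\]; `p4` is the outgroup.
#' @return A tibble with per-site columns `abba_w` and `baba_w` (`NA` where
#'   any input frequency is missing).
#' @export
abba_baba_weights <- function(p1, p2, p3, p4) {
  stopifnot(length(p1) == length(p2), length(p1) == length(p3),
            length(p1) == length(p4))
  rng <- range(c(p1, p2, p3, p4), na.rm = TRUE)
  if (length(p1) && (rng[1] < 0 || rng[2] > 1)) abort("frequencies must lie in [0, 1]")
  tibble(abba_w = (1 - p1) * p2 * p3 * (1 - p4),
         baba_w = p1 * (1 - p2) * p3 * (1 - p4))
}

#' Block jackknife for a ratio-of-sums statistic
#'
#' Given per-block numerator and denominator sums, computes the pooled
#' ratio, its delete-one-block jackknife standard error (blocks weighted by
#' size, following the delete-m_j jackknife of Busing et al. 1999, the
#' scheme used for genomic D and f4 statistics), and the z score.
#'
#' @param num Per-block numerator sums.
#' @param den Per-block denominator sums.
#' @param weights Per-block sizes (e.g. number of sites); equal by default.
#' @return A list with `estimate`, `se`, `z` and `n_blocks`.
#' @export
block_jackknife <- function(num, den, weights = NULL) {
  g <- length(num)
  if (g < 2) abort("block jackknife needs >= 2 blocks; use a smaller block_size")
  stopifnot(length(den) == g)
  if (is.null(weights)) weights <- rep(1, g)
  n <- sum(weights)
  est <- sum(num) / sum(den)
  loo <- vapply(seq_len(g), function(j) (sum(num) - num[j]) / (sum(den) - den[j]),
                numeric(1))
  h <- n / weights
  theta_j <- g * est - sum((1 - weights / n) * loo)
  ps <- h * est - (h - 1) * loo
  v <- sum((ps - theta_j)^2 / (h - 1)) / g
  se <- sqrt(v)
  z <- if (se > 0) est / se else if (est == 0) 0 else Inf * sign(est)
  list(estimate = est, se = se, z = z, n_blocks = g)
}

# contiguous blocks of `block_size` sites within each scaffold
site_blocks <- function(scaffold, block_size) {
  idx <- stats::ave(seq_along(scaffold), scaffold, FUN = seq_along)
  paste0(scaffold, ":", ceiling(idx / block_size))
}

#' Patterson's D statistic with block jackknife significance
#'
#' Computes the frequency-weighted ABBA-BABA test for the quartet
#' (((P1, P2), P3), O). The numerator is `sum(baba_w - abba_w)`, so positive
#' D indicates excess derived-allele sharing between P1 and P3 and negative
#' D sharing between P2 and P3. Note this orientation is the mirror of
#' Durand et al./Martin et al., who put the P2-P3 excess on the positive
#' side. Significance uses a delete-one block jackknife over contiguous
#' runs of sites with |z| >= 3 as the significance threshold.
#'
#' @param freqs Long frequency tibble (ideally polarized; see [polarize()]).
#' @param p1,p2,p3,outgroup Group names for the quartet.
#' @param block_size Number of consecutive sites per jackknife block.
#' @return An object of class `ht_dstat` with elements `d`, `se`, `z`,
#'   `significant`, `abba_sum`, `baba_sum`, `n_sites`, `n_blocks` and the
#'   group roles. `tidy()` returns it as a one-row tibble.
#' @export
d_statistic <- function(freqs, p1, p2, p3, outgroup, block_size = 500) {
  stopifnot(block_size >= 1)
  w <- freqs_wide(freqs, c(p1, p2, p3, outgroup))
  w <- w[complete.cases(w[c("p1", "p2", "p3", "p4")]), ]
  if (nrow(w) == 0) abort("no sites with complete frequencies for all four groups")
  # both allele-label orientations, so D does not depend on which allele is
  # called alternate; the mirrored terms vanish when the outgroup is fixed
  # for the ancestral allele
  ww <- abba_baba_weights(w$p1, w$p2, w$p3, w$p4)
  mirror <- abba_baba_weights(1 - w$p1, 1 - w$p2, 1 - w$p3, 1 - w$p4)
  ww$abba_w <- ww$abba_w + mirror$abba_w
  ww$baba_w <- ww$baba_w + mirror$baba_w
  if (sum(ww$abba_w) + sum(ww$baba_w) == 0) {
    abort("undefined D: no ABBA or BABA weight at any site")
  }
  blk <- site_blocks(w$scaffold, block_size)
  num <- tapply(ww$baba_w - ww$abba_w, blk, sum)
  den <- tapply(ww$baba_w + ww$abba_w, blk, sum)
  wt <- tapply(rep(1, nrow(w)), blk, sum)
  jk <- block_jackknife(as.numeric(num), as.numeric(den), as.numeric(wt))
  structure(list(
    d = jk$estimate, se = jk$se, z = jk$z, significant = abs(jk$z) >= 3,
    abba_sum = sum(ww$abba_w), baba_sum = sum(ww$baba_w),
    n_sites = nrow(w), n_blocks = jk$n_blocks,
    p1 = p1, p2 = p2, p3 = p3, outgroup = outgroup
  ), class = "ht_dstat")
}

#' @export
print.ht_dstat <- function(x, ...) {
  cat(sprintf("Patterson's D: (((%s, %s), %s), %s)\n", x$p1, x$p2, x$p3, x$outgroup))
  cat(sprintf("  D = %.4f  SE = %.4f  z = %.2f%s\n", x$d, x$se, x$z,
              if (x$significant) "  (|z| >= 3)" else ""))
  cat(sprintf("  ABBA = %.1f  BABA = %.1f  sites = %d  blocks = %d\n",
              x$abba_sum, x$baba_sum, x$n_sites, x$n_blocks))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ht_dstat <- function(x, ...) {
  tibble(p1 = x$p1, p2 = x$p2, p3 = x$p3, outgroup = x$outgroup,
         d = x$d, se = x$se, z = x$z, significant = x$significant,
         abba = x$abba_sum, baba = x$baba_sum, n_sites = x$n_sites)
}

#' @exportS3Method generics::glance
glance.ht_dstat <- function(x, ...) tidy(x)

#' The f4 statistic
#'
#' Mean over sites of `(pA - pB) * (pC - pD)`, using sites where all four
#' group frequencies are present.
#'
#' @param freqs Long frequency tibble.
#' @param a,b,c,d Group names.
#' @return The f4 value (a single number).
#' @export
f4 <- function(freqs, a, b, c, d) {
  w <- freqs_wide(freqs, c(a, b, c, d))
  w <- w[complete.cases(w[c("p1", "p2", "p3", "p4")]), ]
  if (nrow(w) == 0) abort("no sites with complete frequencies for all four groups")
  mean((w$p1 - w$p2) * (w$p3 - w$p4))
}

#' F4-ratio estimate of an admixture proportion
#'
#' For the genealogy (((A, B) C) O) and a test population X admixed between
#' the B and C lineages, estimates the proportion of X's ancestry derived
#' from the B lineage as
#' `alpha = f4(A, O; X, C) / f4(A, O; B, C)`,
#' with a standard error from a block jackknife of the ratio of sums.
#'
#' @param freqs Long frequency tibble.
#' @param a,b,c,outgroup,x Group names: A (unadmixed relative of B), B and C
#'   (the two source lineages), the outgroup, and the putative hybrid X.
#' @param block_size Sites per jackknife block.
#' @return An object of class `ht_f4ratio` with `alpha`, `se`, `numerator_f4`,
#'   `denominator_f4`, `n_sites`, `n_blocks` and roles; `tidy()` gives a
#'   one-row tibble.
#' @export
f4_ratio <- function(freqs, a, b, c, outgroup, x, block_size = 500) {
  w <- freqs_wide(freqs, c(a, b, c, outgroup, x))
  w <- w[complete.cases(w[c("p1", "p2", "p3", "p4", "p5")]), ]
  if (nrow(w) == 0) abort("no sites with complete frequencies for all five groups")
  num <- (w$p1 - w$p4) * (w$p5 - w$p3)
  den <- (w$p1 - w$p4) * (w$p2 - w$p3)
  if (abs(sum(den)) < 1e-12) abort("undefined F4 ratio: denominator f4 is ~0")
  blk <- site_blocks(w$scaffold, block_size)
  jk <- block_jackknife(as.numeric(tapply(num, blk, sum)),
                        as.numeric(tapply(den, blk, sum)),
                        as.numeric(tapply(rep(1, nrow(w)), blk, sum)))
  structure(list(
    alpha = jk$estimate, se = jk$se,
    numerator_f4 = mean(num), denominator_f4 = mean(den),
    n_sites = nrow(w), n_blocks = jk$n_blocks,
    a = a, b = b, c = c, outgroup = outgroup, x = x
  ), class = "ht_f4ratio")
}

#' @export
print.ht_f4ratio <- function(x, ...) {
  cat(sprintf("F4 ratio: (((%s, %s) %s) %s) + %s\n", x$a, x$b, x$c, x$outgroup, x$x))
  cat(sprintf("  alpha (ancestry from %s lineage) = %.4f  SE = %.4f  sites = %d\n",
              x$b, x$alpha, x$se, x$n_sites))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ht_f4ratio <- function(x, ...) {
  tibble(a = x$a, b = x$b, c = x$c, outgroup = x$outgroup,
         alpha = x$alpha, se = x$se, numerator_f4 = x$numerator_f4,
         denominator_f4 = x$denominator_f4, n_sites = x$n_sites,
         x = x$x)
}

#' @exportS3Method generics::glance
glance.ht_f4ratio <- function(x, ...) tidy(x)

#' Sweep candidate A populations for the F4 ratio
#'
#' The choice of the unadmixed reference A affects the jackknife precision
#' of the F4 ratio; this utility fits the ratio for each candidate and
#' returns all fits ranked by standard error so the most precise
#' combination can be selected rather than hard-coded.
#'
#' @param freqs Long frequency tibble.
#' @param a_candidates Character vector of candidate A group names.
#' @inheritParams f4_ratio
#' @return A tibble of tidied fits, one row per candidate, sorted by `se`.
#' @export
f4_ratio_sweep <- function(freqs, a_candidates, b, c, outgroup, x,
                           block_size = 500) {
  purrr::map(a_candidates, function(a) {
    tidy(f4_ratio(freqs, a, b, c, outgroup, x, block_size = block_size))
  }) |>
    bind_rows() |>
    arrange(.data$se)
}
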