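#' Configuration for the hybrid-swarm simulator
#'
#' Defaults encode the study conditions the package is exercised under: two
#' parental lineages separated by substantial drift (F = 0.2 each,
#' standing in for a ~1.6-5.8 My divergence), an admixture pulse with an
#' Upper Nile (minor parent) proportion of 0.2 some 100,000 generations
#' ago, a recombination rate of 2.5e-8 per bp per generation (so expected
#' minor-parent tracts of 500 bp), post-admixture drift into daughter
#' species, and a small fraction of divergently fixed parental loci given
#' exaggerated sorting (BDM-like candidates).
#'
#' @param seed Integer seed; fully determines [sim_hybrid_swarm()] output.
#' @param n_sites Number of biallelic SNPs.
#' @param chrom_length Chromosome length in bp (default 200 bp per site).
#' @param r Recombination rate per bp per generation.
#' @param t_admix Generations since the admixture pulse.
#' @param alpha Upper Nile (minor parent) ancestry proportion in (0, 1).
#' @param f_congo,f_nile Balding-Nichols drift of each parental lineage
#'   from the ancestral frequency.
#' @param f_species Post-admixture drift per daughter species (applied to
#'   the parental frequencies each species draws its alleles from).
#' @param f_control Drift per branch of the control-species pairs.
#' @param n_species Number of daughter (radiation) species.
#' @param n_diploids Diploid individuals per group.
#' @param n_founders Founder haplotype mosaics per daughter species; each
#'   sampled haplotype copies the ancestry mosaic of one founder, so
#'   conspecific individuals share tract structure (a shared admixture
#'   history) while different species have independent mosaics.
#' @param n_control_pairs Number of control species pairs.
#' @param loss_threshold Parental lineage frequencies closer than this to
#'   0 or 1 are set to exact loss/fixation, emulating the absence of
#'   alleles rarer than ~1/(2N) in a finite parental deme; gives the
#'   parental lineages a realistic spectrum of genuinely fixed and shared
#'   sites (ancestry categories 1-4 all occur).
#' @param frac_bdm Fraction of sites forced to divergent parental fixation
#'   (pC, pN in \{0, 1\} on opposite sides).
#' @param bdm_drift Strength of exaggerated per-species sorting at those
#'   sites (Balding-Nichols F on the species' minor-parent allele
#'   frequency); 0 disables it, leaving divergently fixed sites to sort
#'   neutrally through the tract process.
#' @param missing_rate Per-genotype missingness probability.
#' @param species_model How daughter-species genotypes arise. `"tracts"`
#'   (default): haplotypes are ancestry mosaics copied from species
#'   founders, with alleles drawn from per-species drifted parental
#'   frequencies conditional on local ancestry - use for window-scan and
#'   tract analyses. `"drift"`: each species' allele frequency at every
#'   site is one Balding-Nichols draw around the swarm mean
#'   `alpha * pN + (1 - alpha) * pC` with drift `f_species`, i.e. a single
#'   neutral drift process acting on frequency alone (no ancestry
#'   linkage) - the null model matched to unlinked RAD-like SNPs used in
#'   the allele-sorting analyses.
#' @return A `ht_sim_config` list.
#' @export
sim_config <- function(seed = 1, n_sites = 10000, chrom_length = NULL,
                       r = 2.5e-8, t_admix = 1e5, alpha = 0.2,
                       f_congo = 0.2, f_nile = 0.2, f_species = 0.05,
                       f_control = 0.2, n_species = 3, n_diploids = 10,
                       n_founders = 4, n_control_pairs = 3,
                       loss_threshold = 0.01, frac_bdm = 0.02,
                       bdm_drift = 0.8, missing_rate = 0,
                       species_model = c("tracts", "drift")) {
  species_model <- match.arg(species_model)
  if (is.null(chrom_length)) chrom_length <- 200L * n_sites
  stopifnot(alpha >= 0, alpha < 1, r > 0, t_admix > 0,
            f_congo > 0, f_congo < 1, f_nile > 0, f_nile < 1,
            f_species > 0, f_species < 1,
            frac_bdm >= 0, frac_bdm < 1, bdm_drift >= 0, bdm_drift < 1,
            missing_rate >= 0, missing_rate < 1, n_sites >= 1,
            chrom_length >= n_sites)
  structure(list(seed = seed, n_sites = n_sites, chrom_length = chrom_length,
                 r = r, t_admix = t_admix, alpha = alpha, f_congo = f_congo,
                 f_nile = f_nile, f_species = f_species,
                 f_control = f_control, n_species = n_species,
                 n_diploids = n_diploids, n_founders = n_founders,
                 n_control_pairs = n_control_pairs,
                 loss_threshold = loss_threshold,
                 frac_bdm = frac_bdm, bdm_drift = bdm_drift,
                 missing_rate = missing_rate, species_model = species_model),
            class = "ht_sim_config")
}

# Balding-Nichols draw; fixed frequencies stay fixed (drift cannot
# resurrect a lost allele).
rbn <- function(p, f) {
  out <- p
  i <- which(p > 0 & p < 1)
  if (length(i)) {
    out[i] <- rbeta(length(i), p[i] * (1 - f) / f, (1 - p[i]) * (1 - f) / f)
  }
  out
}

#' Draw per-site parental allele frequencies
#'
#' Ancestral frequencies are uniform on (0.05, 0.95); each parental lineage
#' drifts from them under a Balding-Nichols beta with its F parameter. A
#' `frac_bdm` subset of sites is then forced to divergent fixation
#' (pC = 0, pN = 1 or the mirror image, at random).
#'
#' Uses the current RNG state; [sim_hybrid_swarm()] seeds it from the
#' config.
#'
#' @param config A [sim_config()].
#' @return A tibble per site: `site`, `pos`, `p_anc`, `p_congo`, `p_nile`,
#'   `bdm` (logical).
#' @export
draw_parental_freqs <- function(config) {
  n <- config$n_sites
  pos <- sort(sample.int(config$chrom_length, n))
  p_anc <- runif(n, 0.05, 0.95)
  lose <- function(p) {
    th <- config$loss_threshold %||% 0
    p[p < th] <- 0
    p[p > 1 - th] <- 1
    p
  }
  p_congo <- lose(rbn(p_anc, config$f_congo))
  p_nile <- lose(rbn(p_anc, config$f_nile))
  bdm <- rep(FALSE, n)
  n_bdm <- round(config$frac_bdm * n)
  if (n_bdm > 0) {
    idx <- sample.int(n, n_bdm)
    bdm[idx] <- TRUE
    flip <- runif(n_bdm) < 0.5
    p_congo[idx] <- ifelse(flip, 0, 1)
    p_nile[idx] <- ifelse(flip, 1, 0)
  }
  tibble(site = seq_len(n), pos = pos, p_anc = p_anc,
         p_congo = p_congo, p_nile = p_nile, bdm = bdm)
}

#' Simulate recombination-driven ancestry tracts along a chromosome
#'
#' Ancestry along each haplotype follows a stationary two-state Markov
#' process: Upper Nile tracts are exponential with mean
#' `1 / ((1 - alpha) * r * t_admix)` and Congolese tracts with mean
#' `1 / (alpha * r * t_admix)`, so the stationary Upper Nile fraction is
#' `alpha`. Tracts tile `[0, chrom_length)` (BED convention).
#'
#' @param config A [sim_config()].
#' @param n_hap Number of haplotypes to simulate.
#' @return A tibble: `hap`, `start`, `end`, `lineage`
#'   ("congolese"/"upper_nile").
#' @export
simulate_ancestry_tracts <- function(config, n_hap = 1) {
  len <- config$chrom_length
  if (config$alpha == 0) {
    return(bind_rows(purrr::map(seq_len(n_hap), function(h) {
      tibble(hap = h, start = 0, end = len, lineage = "congolese")
    })))
  }
  mean_nile <- 1 / ((1 - config$alpha) * config$r * config$t_admix)
  mean_congo <- 1 / (config$alpha * config$r * config$t_admix)
  purrr::map(seq_len(n_hap), function(h) {
    first_nile <- runif(1) < config$alpha # TRUE = upper nile
    lens <- numeric(0)
    batch <- ceiling(2.4 * len / (mean_nile + mean_congo)) + 20
    repeat {
      k <- length(lens)
      is_nile <- xor(rep_len(c(TRUE, FALSE), k + batch), !first_nile)[(k + 1):(k + batch)]
      lens <- c(lens, rexp(batch, rate = 1 / ifelse(is_nile, mean_nile, mean_congo)))
      if (sum(lens) >= len) break
    }
    ends <- pmin(cumsum(lens), len)
    keep <- seq_len(match(TRUE, ends >= len))
    starts <- c(0, ends[-length(ends)])[keep]
    is_nile <- xor(rep_len(c(TRUE, FALSE), length(lens)), !first_nile)[keep]
    tibble(hap = h, start = starts, end = ends[keep],
           lineage = if_else(is_nile, "upper_nile", "congolese"))
  }) |> bind_rows()
}

# ancestry (TRUE = upper nile) of one haplotype at given positions
ancestry_at <- function(tracts_one, pos) {
  i <- findInterval(pos - 1, tracts_one$start)
  tracts_one$lineage[i] == "upper_nile"
}

random_bases <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref_i <- sample.int(4, n, replace = TRUE)
  # shift by 1..3 positions (mod 4) so alt is always a different base
  alt_i <- (ref_i - 1 + sample.int(3, n, replace = TRUE)) %% 4 + 1
  list(ref = bases[ref_i], alt = bases[alt_i])
}

# dosages for n_diploids individuals whose two haplotypes each draw the
# alternate allele with per-site probability p (or per-haplotype matrix)
draw_group <- function(p, n_diploids) {
  n <- length(p)
  m <- matrix(0L, nrow = n, ncol = n_diploids)
  for (j in seq_len(n_diploids)) {
    m[, j] <- (runif(n) < p) + (runif(n) < p)
  }
  m
}

#' Generate the full hybrid-swarm genotype panel with known truth
#'
#' Builds every group the analyses need from one seeded draw: the two
#' parental lineages (`congolese`, `upper_nile`), an Eastern-like sister of
#' the Upper Nile lineage (`eastern`), an unadmixed Congolese-side sister
#' of the swarm (`sister`), `n_species` admixed daughter species
#' (`lv_sp1..`) whose haplotypes are mosaics of exponential ancestry
#' tracts with per-species drifted parental frequencies (differential
#' sorting), control species pairs (`ctrl1a`/`ctrl1b`, ...) unrelated to
#' the admixture, and an outgroup fixed for the ancestral allele at every
#' site (so the reference allele is ancestral and polarization is exact).
#' At BDM-flagged sites with `bdm_drift > 0`, each species' minor-parent
#' allele frequency is drawn with exaggerated drift, emulating rapid
#' differential sorting of divergently fixed parental variants.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; when given, writes `sim.vcf`,
#'   `popmap.tsv`, `truth_sites.tsv`, `truth_tracts.tsv` and `config.json`.
#' @return A list: `geno` (genotype tibble), `popmap`, and `truth` (list
#'   with `alpha`, the `sites` parental-frequency/category table, `tracts`
#'   (founder ancestry mosaics per species), `founder_assignment` (which
#'   founder each sampled haplotype copies) and the `config`).
#' @export
sim_hybrid_swarm <- function(config, dir = NULL) {
  set.seed(config$seed)
  fr <- draw_parental_freqs(config)
  nd <- config$n_diploids
  n <- config$n_sites
  groups <- list()
  groups$congolese <- draw_group(fr$p_congo, nd)
  groups$upper_nile <- draw_group(fr$p_nile, nd)
  groups$eastern <- draw_group(rbn(fr$p_nile, 0.1), nd)
  groups$sister <- draw_group(rbn(fr$p_congo, config$f_species), nd)
  groups$outgroup <- matrix(0L, nrow = n, ncol = nd)

  tract_list <- list()
  assign_list <- list()
  for (s in seq_len(config$n_species)) {
    if (config$species_model == "drift") {
      # one neutral drift process on the species' allele frequency alone
      p_swarm <- config$alpha * fr$p_nile + (1 - config$alpha) * fr$p_congo
      p_s <- rbn(p_swarm, config$f_species)
      if (config$bdm_drift > 0 && any(fr$bdm)) {
        u_s <- rbn(rep(config$alpha, sum(fr$bdm)), config$bdm_drift)
        p_s[fr$bdm] <- ifelse(fr$p_nile[fr$bdm] == 1, u_s, 1 - u_s)
      }
      groups[[paste0("lv_sp", s)]] <- draw_group(p_s, nd)
      next
    }
    pc_s <- rbn(fr$p_congo, config$f_species)
    pn_s <- rbn(fr$p_nile, config$f_species)
    if (config$bdm_drift > 0 && any(fr$bdm)) {
      u_s <- rbn(rep(config$alpha, sum(fr$bdm)), config$bdm_drift)
      pn_s[fr$bdm] <- ifelse(fr$p_nile[fr$bdm] == 1, 1, 0)
      pc_s[fr$bdm] <- ifelse(fr$p_nile[fr$bdm] == 1, 0, 1)
    }
    # founder haplotype mosaics; sampled haplotypes copy a founder's tracts
    tr <- simulate_ancestry_tracts(config, n_hap = config$n_founders)
    tr$species <- paste0("lv_sp", s)
    tract_list[[s]] <- tr
    nile_mat <- vapply(seq_len(config$n_founders), function(fd) {
      ancestry_at(tr[tr$hap == fd, ], fr$pos)
    }, logical(n))
    assign_f <- sample.int(config$n_founders, 2 * nd, replace = TRUE)
    assign_list[[s]] <- tibble(species = paste0("lv_sp", s),
                               hap = seq_len(2 * nd), founder = assign_f)
    m <- matrix(0L, nrow = n, ncol = nd)
    for (j in seq_len(nd)) {
      h <- matrix(0L, nrow = n, ncol = 2)
      for (k in 1:2) {
        nile <- nile_mat[, assign_f[2 * (j - 1) + k]]
        p_hap <- ifelse(nile, pn_s, pc_s)
        if (config$bdm_drift > 0 && any(fr$bdm)) {
          # exaggerated sorting overrides the tract process at BDM sites
          p_bdm <- ifelse(fr$p_nile[fr$bdm] == 1, u_s, 1 - u_s)
          p_hap[fr$bdm] <- p_bdm
        }
        h[, k] <- as.integer(runif(n) < p_hap)
      }
      m[, j] <- h[, 1] + h[, 2]
    }
    groups[[paste0("lv_sp", s)]] <- m
  }
  for (k in seq_len(config$n_control_pairs)) {
    p_pair <- rbn(fr$p_anc, config$f_control)
    groups[[paste0("ctrl", k, "a")]] <- draw_group(rbn(p_pair, config$f_control), nd)
    groups[[paste0("ctrl", k, "b")]] <- draw_group(rbn(p_pair, config$f_control), nd)
  }

  bases <- random_bases(n)
  geno <- tibble(scaffold = "chr1", pos = fr$pos, ref = bases$ref,
                 alt = bases$alt)
  popmap <- purrr::imap(groups, function(m, g) {
    tibble(sample = paste0(g, "_", seq_len(ncol(m))), group = g)
  }) |> bind_rows()
  for (g in names(groups)) {
    m <- groups[[g]]
    if (config$missing_rate > 0) {
      m[matrix(runif(length(m)) < config$missing_rate, nrow = n)] <- NA_integer_
    }
    for (j in seq_len(ncol(m))) geno[[paste0(g, "_", j)]] <- m[, j]
  }

  truth_sites <- fr |>
    mutate(true_category = true_category_from_freqs(.data$p_congo, .data$p_nile))
  truth <- list(alpha = config$alpha, sites = truth_sites,
                tracts = bind_rows(tract_list),
                founder_assignment = bind_rows(assign_list), config = config)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_vcf(geno, file.path(dir, "sim.vcf"))
    readr::write_tsv(popmap, file.path(dir, "popmap.tsv"), col_names = FALSE)
    readr::write_tsv(truth_sites, file.path(dir, "truth_sites.tsv"))
    readr::write_tsv(truth$tracts, file.path(dir, "truth_tracts.tsv"))
    readr::write_tsv(truth$founder_assignment,
                     file.path(dir, "truth_founders.tsv"))
    jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(geno = geno, popmap = popmap, truth = truth)
}

#' True ancestry category from parental population frequencies
#'
#' The category each site would receive from [classify_categories()] if the
#' parental population frequencies were observed without sampling noise
#' (and the site segregates in the radiation).
#'
#' @param p_congo,p_nile Parental population allele frequencies.
#' @return Factor with levels "1".."4".
#' @export
true_category_from_freqs <- function(p_congo, p_nile) {
  congo_poly <- p_congo > 0 & p_congo < 1
  nile_poly <- p_nile > 0 & p_nile < 1
  cat <- dplyr::case_when(
    (p_congo == 0 & p_nile == 0) | (p_congo == 1 & p_nile == 1) ~ "1",
    congo_poly ~ "2",
    nile_poly ~ "3",
    TRUE ~ "4"
  )
  factor(cat, levels = c("1", "2", "3", "4"))
}

#' Simulate a four-population quartet with optional gene flow
#'
#' Frequency-level simulator for D-statistic calibration: an ingroup
#' ancestor with uniform derived frequencies drifts into the (P1, P2) and
#' P3 lineages under Balding-Nichols branches; optional gene flow mixes a
#' fraction `m` of P3's frequencies into P1. Sampled group frequencies for
#' `n_diploids` individuals per group are returned as a long frequency
#' tibble (outgroup fixed ancestral), ready for [d_statistic()].
#'
#' @param n_sites Number of sites.
#' @param f_internal Drift of each deep branch (default 0.3).
#' @param f_terminal Drift of each terminal branch (default 0.05).
#' @param m Gene-flow fraction from P3 into P1 (0 = none).
#' @param n_diploids Individuals per group (default 10).
#' @param n_scaffolds Sites are split evenly over this many scaffolds.
#' @param seed Integer seed.
#' @return A long frequency tibble with groups "P1", "P2", "P3", "O".
#' @export
sim_quartet <- function(n_sites, f_internal = 0.3, f_terminal = 0.05, m = 0,
                        n_diploids = 10, n_scaffolds = 1, seed = 1) {
  withr::with_seed(seed, {
    p0 <- runif(n_sites, 0.05, 0.95)
    p12 <- rbn(p0, f_internal)
    p3 <- rbn(rbn(p0, f_internal), f_terminal)
    p1 <- rbn(p12, f_terminal)
    p2 <- rbn(p12, f_terminal)
    if (m > 0) p1 <- (1 - m) * p1 + m * p3
    samp <- function(p) rbinom(n_sites, 2 * n_diploids, p) / (2 * n_diploids)
    scaffold <- paste0("chr", rep(seq_len(n_scaffolds), length.out = n_sites,
                                  each = ceiling(n_sites / n_scaffolds)))
    pos <- stats::ave(seq_len(n_sites), scaffold, FUN = seq_along)
    base <- tibble(scaffold = scaffold, pos = as.integer(pos),
                   n_ind = n_diploids, n_alleles = 2L * n_diploids)
    bind_rows(
      base |> mutate(group = "P1", freq = samp(p1)),
      base |> mutate(group = "P2", freq = samp(p2)),
      base |> mutate(group = "P3", freq = samp(p3)),
      base |> mutate(group = "O", freq = 0)
    )
  })
}

#' Simulate a five-taxon quintet with one-way introgression
#'
#' Haploid single-individual sequences over ((P1, P2), (P3a, P3b)), O with
#' the outgroup fixed ancestral. The deep split carries drift `f_internal`
#' per branch and each terminal `f_terminal`; one-way gene flow of
#' fraction `m` is applied in the requested direction before a single
#' haploid allele per taxon and site is drawn.
#'
#' @param n_sites Number of sites.
#' @param f_internal,f_terminal Branch drift (defaults 0.3, 0.05).
#' @param m Donor fraction (default 0.2).
#' @param direction One of "none", "P3a_to_P1", "P1_to_P3a", "P1_to_P3b".
#' @param seed Integer seed.
#' @return A list of integer haploid vectors `h1`, `h2`, `h3a`, `h3b`,
#'   `ho` (ho all ancestral).
#' @export
sim_quintet <- function(n_sites, f_internal = 0.3, f_terminal = 0.05,
                        m = 0.2,
                        direction = c("none", "P3a_to_P1", "P1_to_P3a",
                                      "P1_to_P3b"),
                        seed = 1) {
  direction <- match.arg(direction)
  withr::with_seed(seed, {
    p0 <- runif(n_sites, 0.05, 0.95)
    p12 <- rbn(p0, f_internal); p34 <- rbn(p0, f_internal)
    p1 <- rbn(p12, f_terminal); p2 <- rbn(p12, f_terminal)
    p3a <- rbn(p34, f_terminal); p3b <- rbn(p34, f_terminal)
    if (direction == "P3a_to_P1") p1 <- (1 - m) * p1 + m * p3a
    if (direction == "P1_to_P3a") p3a <- (1 - m) * p3a + m * p1
    if (direction == "P1_to_P3b") p3b <- (1 - m) * p3b + m * p1
    h <- function(p) as.integer(runif(n_sites) < p)
    list(h1 = h(p1), h2 = h(p2), h3a = h(p3a), h3b = h(p3b),
         ho = integer(n_sites))
  })
}
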