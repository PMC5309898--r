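#' Read a population map
#'
#' A population map is a two-column tab-separated file assigning each sample
#' to a group (e.g. a species or lineage). A header line `sample<TAB>group`
#' is allowed but not required.
#'
#' @param path Path to a two-column TSV file.
#' @return A tibble with columns `sample` and `group`.
#' @export
read_popmap <- function(path) {
  pm <- readr::read_tsv(path, col_names = c("sample", "group"),
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  pm <- dplyr::filter(pm, !(.data$sample == "sample" & .data$group == "group"))
  if (anyDuplicated(pm$sample)) {
    abort("duplicated sample identifiers in population map")
  }
  pm
}

geno_meta_cols <- c("scaffold", "pos", "ref", "alt")

#' Sample columns of a genotype table
#'
#' @param geno A genotype tibble as returned by [read_vcf()].
#' @return Character vector of sample column names.
#' @export
geno_samples <- function(geno) {
  setdiff(names(geno), geno_meta_cols)
}

#' Read biallelic SNP genotypes from a VCF file
#'
#' Reads a VCF (v4.x), keeps only biallelic SNP records (indels and
#' multiallelic sites are dropped), and converts diploid genotype calls to
#' alternate-allele dosages in \{0, 1, 2\} (`NA` = missing). When the VCF
#' carries a per-genotype `FORMAT/DP` field and `min_depth` is given,
#' genotypes below that depth are set missing; by default no depth filter is
#' applied, on the assumption that depth filtering happened during variant
#' calling.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param popmap Optional population map tibble (see [read_popmap()]). When
#'   given, only the mapped samples are retained and an error names any
#'   mapped sample absent from the VCF header.
#' @param min_depth Optional integer; genotypes with `FORMAT/DP` below this
#'   are set missing. Ignored when the VCF has no DP field.
#' @return A tibble with columns `scaffold`, `pos` (1-based), `ref`, `alt`
#'   and one integer dosage column per sample, sorted by scaffold and
#'   position.
#' @export
read_vcf <- function(path, popmap = NULL, min_depth = NULL) {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n_rec <- nrow(fix)
  vcf_samples <- colnames(vcf@gt)[-1]
  if (!is.null(popmap)) {
    missing_samples <- setdiff(popmap$sample, vcf_samples)
    if (length(missing_samples) > 0) {
      abort(paste0("popmap sample(s) absent from VCF header: ",
                   paste(missing_samples, collapse = ", ")))
    }
    vcf_samples <- popmap$sample
  }
  empty <- tibble(scaffold = character(), pos = integer(),
                  ref = character(), alt = character())
  for (s in vcf_samples) empty[[s]] <- integer()
  if (n_rec == 0) return(empty)

  snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  if (!any(snp)) return(empty)

  gt <- vcfR::extract.gt(vcf, element = "GT")[snp, vcf_samples, drop = FALSE]
  dos <- dosage_from_gt(gt)
  if (!is.null(min_depth) && any(grepl("DP", vcf@gt[, "FORMAT"], fixed = TRUE))) {
    dp <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)[snp, vcf_samples, drop = FALSE])
    dos[!is.na(dp) & dp < min_depth] <- NA_integer_
  }
  out <- tibble(scaffold = fix$CHROM[snp],
                pos = as.integer(fix$POS[snp]),
                ref = fix$REF[snp], alt = fix$ALT[snp])
  for (j in seq_along(vcf_samples)) out[[vcf_samples[j]]] <- unname(dos[, j])
  arrange(out, .data$scaffold, .data$pos)
}

# "0/1", "0|1", "1/1", "./." etc. -> alt-allele dosage
dosage_from_gt <- function(gt) {
  alleles1 <- substr(gt, 1, 1)
  alleles2 <- substr(gt, 3, 3)
  d <- (alleles1 == "1") + (alleles2 == "1")
  d[alleles1 == "." | alleles2 == "." | is.na(gt)] <- NA_integer_
  matrix(as.integer(d), nrow = nrow(gt), dimnames = dimnames(gt))
}

#' Write a genotype table to VCF
#'
#' Writes a minimal VCF v4.2 with GT-only genotypes; the exact inverse of
#' [read_vcf()] for tables produced by this package.
#'
#' @param geno Genotype tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  samples <- geno_samples(geno)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- vapply(samples, function(s) {
    d <- geno[[s]]
    out <- rep("./.", length(d))
    ok <- !is.na(d)
    out[ok] <- gt_code[as.character(d[ok])]
    out
  }, character(nrow(geno)))
  if (nrow(geno) == 1) gt <- matrix(gt, nrow = 1)
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(geno$scaffold, geno$pos, ".", geno$ref, geno$alt, ".", ".",
                ".", "GT",
                if (nrow(geno)) apply(gt, 1, paste, collapse = "\t") else character(),
                sep = "\t")
  writeLines(c(header, if (nrow(geno)) body), path)
  invisible(path)
}

#' Filter SNP sites on frequency, missingness and per-group coverage
#'
#' Retains sites that simultaneously satisfy a minor-allele-frequency
#' minimum (computed across all samples in the table), a maximum proportion
#' of missing genotypes, and optional per-group minimum numbers of called
#' individuals. Site order is preserved; the filter is idempotent.
#'
#' @param geno Genotype tibble.
#' @param maf_min Minimum minor allele frequency in \[0, 1\] (default 0).
#' @param max_missing Maximum tolerated proportion of missing genotype calls
#'   in \[0, 1\] (default 1).
#' @param groups_min_called Optional named vector/list mapping group name to
#'   the minimum number of called (non-missing) individuals required in that
#'   group; requires `popmap`.
#' @param popmap Population map tibble, needed for `groups_min_called`.
#' @return The filtered genotype tibble (warns when no site survives).
#' @export
filter_sites <- function(geno, maf_min = 0, max_missing = 1,
                         groups_min_called = NULL, popmap = NULL) {
  stopifnot(maf_min >= 0, maf_min <= 1, max_missing >= 0, max_missing <= 1)
  samples <- geno_samples(geno)
  m <- as.matrix(geno[samples])
  called <- rowSums(!is.na(m))
  miss_prop <- 1 - called / length(samples)
  p <- rowSums(m, na.rm = TRUE) / (2 * called)
  maf <- pmin(p, 1 - p)
  keep <- miss_prop <= max_missing & !is.na(maf) & maf >= maf_min
  if (!is.null(groups_min_called)) {
    if (is.null(popmap)) abort("groups_min_called requires a popmap")
    unknown <- setdiff(names(groups_min_called), unique(popmap$group))
    if (length(unknown)) abort(paste0("unknown group(s): ", paste(unknown, collapse = ", ")))
    for (g in names(groups_min_called)) {
      gs <- popmap$sample[popmap$group == g]
      keep <- keep & rowSums(!is.na(m[, gs, drop = FALSE])) >= groups_min_called[[g]]
    }
  }
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) warn("all sites removed by filter_sites()")
  geno[keep, , drop = FALSE]
}

#' Per-group alternate-allele frequencies
#'
#' @param geno Genotype tibble.
#' @param popmap Population map tibble; every group must have at least one
#'   sample present in `geno`.
#' @return A long tibble with one row per site x group: `scaffold`, `pos`,
#'   `group`, `freq` (alternate-allele frequency, `NA` when no calls),
#'   `n_ind` (called individuals) and `n_alleles` (called alleles).
#' @export
allele_freqs <- function(geno, popmap) {
  samples <- geno_samples(geno)
  pm <- dplyr::filter(popmap, .data$sample %in% samples)
  if (nrow(pm) == 0) abort("no popmap samples present in genotype table")
  m <- as.matrix(geno[pm$sample])
  groups <- unique(pm$group)
  per_group <- purrr::map(groups, function(g) {
    gm <- m[, pm$sample[pm$group == g], drop = FALSE]
    n_ind <- rowSums(!is.na(gm))
    freq <- rowSums(gm, na.rm = TRUE) / (2 * n_ind)
    freq[n_ind == 0] <- NA_real_
    tibble(scaffold = geno$scaffold, pos = geno$pos, group = g,
           freq = freq, n_ind = n_ind, n_alleles = 2L * n_ind)
  })
  bind_rows(per_group)
}

#' Polarize allele frequencies against an outgroup
#'
#' Re-expresses frequencies as derived-allele frequencies, taking the
#' outgroup major allele as ancestral. Sites where the outgroup is missing
#' or exactly 50/50 polymorphic are flagged unpolarizable (frequencies are
#' left on the alternate-allele scale there; polarized analyses should drop
#' them via the `polarizable` flag).
#'
#' @param freqs Long frequency tibble from [allele_freqs()].
#' @param outgroup Name of the outgroup group.
#' @return `freqs` with `freq` on the derived-allele scale plus logical
#'   columns `derived_is_alt` and `polarizable`.
#' @export
polarize <- function(freqs, outgroup) {
  if (!outgroup %in% freqs$group) abort(paste0("outgroup group not present: ", outgroup))
  og <- freqs |>
    dplyr::filter(.data$group == outgroup) |>
    select("scaffold", "pos", out_freq = "freq")
  out <- freqs |>
    left_join(og, by = c("scaffold", "pos")) |>
    mutate(
      polarizable = !is.na(.data$out_freq) & .data$out_freq != 0.5,
      derived_is_alt = if_else(.data$polarizable, .data$out_freq < 0.5, NA),
      freq = dplyr::case_when(
        !.data$polarizable ~ .data$freq,
        .data$derived_is_alt ~ .data$freq,
        TRUE ~ 1 - .data$freq
      )
    ) |>
    select(-"out_freq")
  out
}

# wide per-site frequency table for a set of groups; freq_<i> columns follow
# the order of `groups`. Drops unpolarizable sites if the flag is present.
freqs_wide <- function(freqs, groups) {
  fr <- dplyr::filter(freqs, .data$group %in% groups)
  if ("polarizable" %in% names(fr)) {
    bad <- fr |> dplyr::filter(!.data$polarizable) |> distinct(.data$scaffold, .data$pos)
    fr <- fr |> dplyr::anti_join(bad, by = c("scaffold", "pos"))
  }
  fr |>
    mutate(group = paste0("p", match(.data$group, groups))) |>
    select("scaffold", "pos", "group", "freq") |>
    tidyr::pivot_wider(names_from = "group", values_from = "freq") |>
    arrange(.data$scaffold, .data$pos)
}
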