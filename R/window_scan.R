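# assign sites to non-overlapping windows; coordinates are 0-based
# half-open internally (VCF positions are 1-based inclusive on input).
# Terminal partial windows keep their true span (scaffold extent taken as
# the last observed site position).
window_index <- function(pos, window_bp) (pos - 1L) %/% window_bp

#' fd admixture scan in non-overlapping genomic windows
#'
#' Computes Martin et al.'s fd statistic per window for the quartet
#' (((P1, P2), P3), O), where P2 is the putative recipient of gene flow
#' from P3 (note P1/P2 are switched relative to [d_statistic()], following
#' the fd convention). Per site, the observed ABBA-BABA excess is
#' `abba_w - baba_w`; the maximum is computed with the donor set, per site,
#' to whichever of P2 and P3 has the higher derived frequency, and
#' `fd = S_obs / S_max`. Windows with a weighted ABBA+BABA total below
#' `min_patterns` get `NA`; windows whose D is negative get `fd = 0` (only
#' positive fd is a correctly standardized admixture fraction). Retained
#' fd values are clamped to \[0, 1\].
#'
#' @param freqs Long derived-frequency tibble (see [polarize()]).
#' @param p1,p2,p3,outgroup Group names; P2 is the recipient under test.
#' @param window_bp Window size in bp (default 10000).
#' @param min_patterns Minimum weighted ABBA+BABA total per window
#'   (default 5).
#' @return A window tibble: `scaffold`, `start`, `end` (0-based half-open),
#'   `n_sites`, `n_informative` (weighted pattern total), `d` (window D,
#'   fd orientation: positive = P2-P3 sharing) and `fd`.
#' @export
fd_windows <- function(freqs, p1, p2, p3, outgroup, window_bp = 10000,
                       min_patterns = 5) {
  stopifnot(window_bp > 0)
  w <- freqs_wide(freqs, c(p1, p2, p3, outgroup))
  w <- w[complete.cases(w[c("p1", "p2", "p3", "p4")]), ]
  ww <- abba_baba_weights(w$p1, w$p2, w$p3, w$p4)
  pd <- pmax(w$p2, w$p3)
  wmax <- abba_baba_weights(w$p1, pd, pd, w$p4)
  per_site <- w |>
    mutate(win = window_index(.data$pos, window_bp),
           s_obs = ww$abba_w - ww$baba_w,
           s_max = wmax$abba_w - wmax$baba_w,
           informative = ww$abba_w + ww$baba_w)
  out <- per_site |>
    group_by(.data$scaffold, .data$win) |>
    summarise(n_sites = dplyr::n(),
              n_informative = sum(.data$informative),
              s_obs = sum(.data$s_obs), s_max = sum(.data$s_max),
              max_pos = max(.data$pos), .groups = "drop") |>
    group_by(.data$scaffold) |>
    mutate(scaffold_extent = max(.data$max_pos)) |>
    ungroup() |>
    mutate(start = .data$win * window_bp,
           end = pmin((.data$win + 1) * window_bp, .data$scaffold_extent),
           d = .data$s_obs / dplyr::na_if(.data$n_informative, 0),
           fd = dplyr::case_when(
             .data$n_informative < min_patterns ~ NA_real_,
             .data$d < 0 ~ 0,
             .data$s_max <= 0 ~ NA_real_,
             TRUE ~ pmin(.data$s_obs / .data$s_max, 1)
           ))
  if (any(out$n_informative >= min_patterns & out$s_max <= 0 & out$d >= 0,
          na.rm = TRUE)) {
    warn("window(s) with zero maximal ABBA-BABA excess; fd set missing there")
  }
  out |>
    select("scaffold", "start", "end", "n_sites", "n_informative", "d", "fd") |>
    arrange(.data$scaffold, .data$start)
}

#' Pearson correlation of fd between two window scans
#'
#' Correlates fd over the windows (matched on scaffold and start) where
#' both scans have a value; used to ask whether two individuals share the
#' same genomic admixture mosaic.
#'
#' @param w1,w2 Window tibbles from [fd_windows()].
#' @return A one-row tibble with `r`, `p_value` and `n_windows`.
#' @export
fd_correlation <- function(w1, w2) {
  m <- inner_join(select(w1, "scaffold", "start", fd1 = "fd"),
                  select(w2, "scaffold", "start", fd2 = "fd"),
                  by = c("scaffold", "start")) |>
    dplyr::filter(!is.na(.data$fd1), !is.na(.data$fd2))
  if (nrow(m) < 3) abort("need >= 3 windows with fd present in both scans")
  if (sd(m$fd1) == 0 || sd(m$fd2) == 0) {
    warn("zero variance in fd; correlation undefined")
    return(tibble(r = NA_real_, p_value = NA_real_, n_windows = nrow(m)))
  }
  ct <- stats::cor.test(m$fd1, m$fd2, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n_windows = nrow(m))
}

#' Paint genomic windows by parental ancestry
#'
#' Compares, in non-overlapping windows, the weighted frequency of ABBA
#' sites (the target lineage shares the derived allele with the Upper
#' Nile-side parent while the Congolese-side parent is ancestral) with BBAA
#' sites (target shares the derived allele with the Congolese-side parent
#' while the Upper Nile-side parent is ancestral). Windows with ABBA
#' proportion `>= hi` are painted as minor-parent (`upper_nile`) ancestry,
#' `<= lo` as major-parent (`congolese`) ancestry, in between
#' `unassigned`; windows whose weighted ABBA+BBAA total does not exceed
#' `min_total` are `no_data`. Scaffolds whose span of data windows is below
#' `min_scaffold_bp` are dropped entirely.
#'
#' @param freqs Long derived-frequency tibble.
#' @param congolese,target,upper_nile,outgroup Group names: the
#'   Congolese-side parent, the admixed target, the Upper Nile-side parent
#'   and the outgroup.
#' @param window_bp Window size in bp (default 3000).
#' @param min_total Weighted pattern total a window must exceed (default 1).
#' @param hi,lo ABBA-proportion thresholds for the two ancestry colours
#'   (defaults 0.7 and 0.3).
#' @param min_scaffold_bp Minimum data span per scaffold (default 1e5).
#' @return A window tibble with `scaffold`, `start`, `end`, `abba`, `bbaa`,
#'   `abba_prop` and `colour` in \{upper_nile, congolese, unassigned,
#'   no_data\}.
#' @export
ancestry_windows <- function(freqs, congolese, target, upper_nile, outgroup,
                             window_bp = 3000, min_total = 1, hi = 0.7,
                             lo = 0.3, min_scaffold_bp = 1e5) {
  stopifnot(window_bp > 0, lo >= 0, hi <= 1, lo < hi)
  w <- freqs_wide(freqs, c(congolese, target, upper_nile, outgroup))
  w <- w[complete.cases(w[c("p1", "p2", "p3", "p4")]), ]
  # p1 = congolese, p2 = target, p3 = upper nile, p4 = outgroup
  per_site <- w |>
    mutate(win = window_index(.data$pos, window_bp),
           abba_w = (1 - .data$p1) * .data$p2 * .data$p3 * (1 - .data$p4),
           bbaa_w = .data$p1 * .data$p2 * (1 - .data$p3) * (1 - .data$p4))
  out <- per_site |>
    group_by(.data$scaffold, .data$win) |>
    summarise(abba = sum(.data$abba_w), bbaa = sum(.data$bbaa_w),
              max_pos = max(.data$pos), .groups = "drop") |>
    group_by(.data$scaffold) |>
    mutate(scaffold_extent = max(.data$max_pos)) |>
    ungroup() |>
    mutate(start = .data$win * window_bp,
           end = pmin((.data$win + 1) * window_bp, .data$scaffold_extent),
           total = .data$abba + .data$bbaa,
           abba_prop = if_else(.data$total > min_total,
                               .data$abba / .data$total, NA_real_),
           colour = dplyr::case_when(
             .data$total <= min_total ~ "no_data",
             .data$abba_prop >= hi ~ "upper_nile",
             .data$abba_prop <= lo ~ "congolese",
             TRUE ~ "unassigned"
           ))
  span <- out |>
    dplyr::filter(.data$colour != "no_data") |>
    group_by(.data$scaffold) |>
    summarise(span = max(.data$end) - min(.data$start), .groups = "drop") |>
    dplyr::filter(.data$span >= min_scaffold_bp)
  out |>
    semi_join(span, by = "scaffold") |>
    select("scaffold", "start", "end", "abba", "bbaa", "abba_prop", "colour") |>
    arrange(.data$scaffold, .data$start)
}

#' Merge coloured windows into ancestry tracts
#'
#' An ancestry tract is a maximal run of consecutive windows of the same
#' colour on a scaffold. A single interior `no_data` window does not break
#' a run (it is bridged when flanked by the same colour); two or more
#' consecutive `no_data` windows do, and `unassigned` windows always do.
#'
#' @param windows Window tibble from [ancestry_windows()], sorted by
#'   scaffold and start.
#' @return A tract tibble in BED convention: `scaffold`, `start`, `end`,
#'   `colour` (upper_nile or congolese), `n_windows` (windows spanned,
#'   bridged gaps included).
#' @export
merge_tracts <- function(windows) {
  windows <- arrange(windows, .data$scaffold, .data$start)
  per_scaffold <- split(windows, windows$scaffold)
  tracts <- purrr::map(per_scaffold, function(wd) {
    col <- wd$colour
    n <- length(col)
    if (n >= 3) {
      bridge <- which(col[-c(1, n)] == "no_data" &
                        col[seq_len(n - 2)] == col[3:n] &
                        col[seq_len(n - 2)] %in% c("upper_nile", "congolese")) + 1L
      col[bridge] <- col[bridge - 1L]
    }
    r <- rle(col)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values %in% c("upper_nile", "congolese")
    tibble(scaffold = wd$scaffold[1],
           start = wd$start[starts[keep]],
           end = wd$end[ends[keep]],
           colour = r$values[keep],
           n_windows = r$lengths[keep])
  })
  bind_rows(tracts) |> arrange(.data$scaffold, .data$start)
}

#' Histogram of ancestry tract lengths
#'
#' @param tracts Tract tibble from [merge_tracts()] (or a truth-tract table
#'   with the same columns).
#' @param breaks Bin breaks in bp; tract lengths fall into
#'   left-open/right-closed bins. Default: 3-kb bins up to the longest
#'   tract.
#' @return A tibble with `colour`, `bin` (upper bound label in bp) and `n`.
#' @export
tract_length_summary <- function(tracts, breaks = NULL) {
  if (nrow(tracts) == 0) {
    return(tibble(colour = character(), bin = numeric(), n = integer()))
  }
  len <- tracts$end - tracts$start
  if (is.null(breaks)) {
    breaks <- seq(0, 3000 * ceiling(max(len) / 3000), by = 3000)
  }
  tibble(colour = tracts$colour,
         bin = breaks[-1][findInterval(len, breaks, left.open = TRUE,
                                       rightmost.closed = TRUE)]) |>
    count(.data$colour, .data$bin, name = "n")
}

#' Expected mean admixture tract length
#'
#' Under recombination-driven breakup, the expected mean length of tracts
#' of the minor ancestry is `1 / ((1 - m) * r * t)`, with `m` the minor
#' ancestry proportion, `r` the per-bp per-generation recombination rate
#' and `t` generations since admixture. At m = 0.2, r = 2.5e-8 and
#' t = 50,000-100,000 this gives 1 kb down to 500 bp.
#'
#' @param m Minor ancestry proportion in (0, 1).
#' @param r Recombination rate per bp per generation (> 0).
#' @param t Generations since admixture (> 0).
#' @return Expected mean tract length in bp.
#' @export
expected_tract_length <- function(m, r, t) {
  if (!is.numeric(m) || any(m <= 0) || any(m >= 1)) abort("m must lie in (0, 1)")
  if (!is.numeric(r) || any(r <= 0)) abort("r must be > 0")
  if (!is.numeric(t) || any(t <= 0)) abort("t must be > 0")
  1 / ((1 - m) * r * t)
}
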