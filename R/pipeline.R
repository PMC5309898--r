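#' Default pipeline configuration
#'
#' The analysis defaults baked into the pipeline: |z| >= 3 jackknife
#' significance, 500-site jackknife blocks, 100 bootstrap replicates for
#' the five-population test, 10-kb fd windows requiring five weighted
#' patterns, 3-kb ancestry windows with 0.7/0.3 colour thresholds and a
#' weighted pattern total exceeding one, ancestry weights 0.84/0.16 with a
#' 14-18% control window, and P < 0.05 FST outliers. Every value can be
#' overridden in the config passed to [run_pipeline()].
#'
#' @return A named list of parameter defaults.
#' @export
pipeline_defaults <- function() {
  list(
    seed = 1,
    block_size = 500,
    n_boot = 100,
    z_threshold = 3,
    fd_window_bp = 10000,
    fd_min_patterns = 5,
    ancestry_window_bp = 3000,
    ancestry_min_total = 1,
    ancestry_hi = 0.7,
    ancestry_lo = 0.3,
    min_scaffold_bp = 1e5,
    w_congo = 0.84,
    w_nile = 0.16,
    control_window = c(0.14, 0.18),
    p_threshold = 0.05,
    maf_min = 0.01,
    max_missing = 0.2
  )
}

stage_order <- c("simulate", "filter", "dstat", "f4ratio", "fivepop",
                 "fd_scan", "blocks", "sort_alleles")

#' Run the full hybrid-ancestry pipeline from one configuration
#'
#' Executes the requested stages in dependency order (simulate -> filter ->
#' D/F4 -> five-population test -> fd scan -> ancestry blocks -> allele
#' sorting), writing per-stage TSV/BED outputs and a JSON report to the
#' output directory. All randomness derives from one root seed with fixed
#' per-stage substreams, so a rerun with the same config reproduces every
#' statistic exactly and single stages are individually reproducible.
#'
#' @param config A named list, or path to a YAML/JSON file with one. Keys:
#'   `stages` (character vector; default all), `out_dir`, `params`
#'   (overrides for [pipeline_defaults()]), `sim` (arguments to
#'   [sim_config()]) or `vcf` + `popmap` paths, and `roles` (group-name
#'   assignments: p1, p2, p3, p3a_sample..., outgroup, lv_groups,
#'   congolese, upper_nile, control_pairs, a_candidates, b, c, x).
#' @return A `ht_report` list: package version, config hash, per-stage
#'   outputs, summaries and wall-clock seconds. Also written as
#'   `report.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  params <- modifyList(pipeline_defaults(), config$params %||% list())
  stages <- config$stages %||% stage_order
  unknown <- setdiff(stages, stage_order)
  if (length(unknown)) abort(paste0("unknown stage(s): ", paste(unknown, collapse = ", ")))
  stages <- stage_order[stage_order %in% stages]
  out_dir <- config$out_dir %||% tempfile("hybridtrace_run_")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- params$seed
  stage_seeds <- withr::with_seed(seed,
    setNames(sample.int(1e6, length(stage_order)), stage_order))

  roles <- modifyList(list(
    p1 = "lv_sp1", p2 = "congolese", p3 = "upper_nile", outgroup = "outgroup",
    lv_groups = NULL, congolese = "congolese", upper_nile = "upper_nile",
    a_candidates = "eastern", b = "upper_nile", c = "congolese", x = "lv_sp1",
    control_pairs = NULL
  ), config$roles %||% list())

  report <- list(package = "hybridtrace",
                 version = as.character(utils::packageVersion("hybridtrace")),
                 config_hash = rlang::hash(config), seed = seed,
                 out_dir = out_dir, stages = list())
  state <- list()
  for (st in stages) {
    t0 <- proc.time()[["elapsed"]]
    res <- run_stage(st, state, config, params, roles, stage_seeds[[st]], out_dir)
    state <- res$state
    report$stages[[st]] <- c(res$report,
                             list(seconds = round(proc.time()[["elapsed"]] - t0, 3)))
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  structure(report, class = "ht_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

need_geno <- function(state, config) {
  if (!is.null(state$geno)) return(state)
  if (is.null(config$vcf)) {
    abort("stage needs genotypes: provide a simulate stage or vcf/popmap paths")
  }
  state$popmap <- read_popmap(config$popmap)
  state$geno <- read_vcf(config$vcf, state$popmap, min_depth = config$min_depth)
  state
}

need_freqs <- function(state, roles) {
  if (is.null(state$freqs)) {
    state$freqs <- polarize(allele_freqs(state$geno, state$popmap),
                            roles$outgroup)
  }
  state
}

run_stage <- function(st, state, config, params, roles, stage_seed, out_dir) {
  out <- function(name) file.path(out_dir, name)
  switch(st,
    simulate = {
      sim_args <- config$sim %||% list()
      sim_args$seed <- sim_args$seed %||% stage_seed
      cfg <- do.call(sim_config, sim_args)
      sim <- sim_hybrid_swarm(cfg, dir = out_dir)
      state$geno <- sim$geno; state$popmap <- sim$popmap; state$truth <- sim$truth
      list(state = state,
           report = list(outputs = c(out("sim.vcf"), out("popmap.tsv"),
                                     out("truth_sites.tsv"),
                                     out("truth_tracts.tsv")),
                         summary = list(n_sites = nrow(sim$geno),
                                        n_samples = nrow(sim$popmap),
                                        alpha = sim$truth$alpha)))
    },
    filter = {
      state <- need_geno(state, config)
      n0 <- nrow(state$geno)
      state$geno <- filter_sites(state$geno, maf_min = params$maf_min,
                                 max_missing = params$max_missing)
      state$freqs <- NULL
      readr::write_tsv(state$geno[, c("scaffold", "pos", "ref", "alt")],
                       out("filtered_sites.tsv"))
      list(state = state,
           report = list(outputs = out("filtered_sites.tsv"),
                         summary = list(n_before = n0, n_after = nrow(state$geno),
                                        maf_min = params$maf_min,
                                        max_missing = params$max_missing)))
    },
    dstat = {
      state <- need_geno(state, config); state <- need_freqs(state, roles)
      d <- d_statistic(state$freqs, roles$p1, roles$p2, roles$p3,
                       roles$outgroup, block_size = params$block_size)
      readr::write_tsv(tidy(d), out("dstat.tsv"))
      list(state = state,
           report = list(outputs = out("dstat.tsv"),
                         summary = list(d = d$d, se = d$se, z = d$z,
                                        significant = d$significant,
                                        block_size = params$block_size,
                                        z_threshold = params$z_threshold)))
    },
    f4ratio = {
      state <- need_geno(state, config); state <- need_freqs(state, roles)
      sw <- f4_ratio_sweep(state$freqs, roles$a_candidates, roles$b, roles$c,
                           roles$outgroup, roles$x,
                           block_size = params$block_size)
      readr::write_tsv(sw, out("f4ratio.tsv"))
      best <- sw[1, ]
      list(state = state,
           report = list(outputs = out("f4ratio.tsv"),
                         summary = list(alpha = best$alpha, se = best$se,
                                        a = best$a, x = best$x)))
    },
    fivepop = {
      state <- need_geno(state, config)
      pm <- state$popmap
      pick <- function(g, k = 1) head(pm$sample[pm$group == g], k)
      p1s <- config$roles$p1_samples %||% pick(roles$p1, 3)
      p3a <- config$roles$p3a_sample %||% pick(roles$p3)[1]
      p3b <- config$roles$p3b_sample %||% pick(roles$p3, 2)[2]
      panel <- run_fivepop_panel(state$geno, p1s,
                                 config$roles$p2_sample %||% pick(roles$p2)[1],
                                 p3a, p3b,
                                 config$roles$outgroup_sample %||% pick(roles$outgroup)[1],
                                 n_boot = params$n_boot, seed = stage_seed,
                                 z_threshold = params$z_threshold)
      tab <- purrr::imap(panel$results, ~ tidy(.x) |> mutate(p1_sample = .y)) |>
        bind_rows()
      readr::write_tsv(tab, out("fivepop.tsv"))
      calls <- vapply(panel$results, function(r) r$direction_call, character(1))
      list(state = state,
           report = list(outputs = out("fivepop.tsv"),
                         summary = list(mean_d = as.list(
                                          setNames(panel$mean$mean_d, panel$mean$stat)),
                                        direction_calls = unname(calls),
                                        n_boot = params$n_boot)))
    },
    fd_scan = {
      state <- need_geno(state, config); state <- need_freqs(state, roles)
      # fd orientation: recipient is P2, so the radiation target goes second
      wt <- fd_windows(state$freqs, roles$p2, roles$p1, roles$p3, roles$outgroup,
                       window_bp = params$fd_window_bp,
                       min_patterns = params$fd_min_patterns)
      readr::write_tsv(wt, out("fd_windows.tsv"))
      state$fd_windows <- wt
      list(state = state,
           report = list(outputs = out("fd_windows.tsv"),
                         summary = list(n_windows = nrow(wt),
                                        mean_fd = mean(wt$fd, na.rm = TRUE),
                                        window_bp = params$fd_window_bp,
                                        min_patterns = params$fd_min_patterns)))
    },
    blocks = {
      state <- need_geno(state, config); state <- need_freqs(state, roles)
      aw <- ancestry_windows(state$freqs, roles$congolese, roles$x,
                             roles$upper_nile, roles$outgroup,
                             window_bp = params$ancestry_window_bp,
                             min_total = params$ancestry_min_total,
                             hi = params$ancestry_hi, lo = params$ancestry_lo,
                             min_scaffold_bp = params$min_scaffold_bp)
      tracts <- merge_tracts(aw)
      readr::write_tsv(aw, out("ancestry_windows.tsv"))
      bed <- tracts |>
        mutate(name = .data$colour, score = .data$n_windows) |>
        select("scaffold", "start", "end", "name", "score")
      readr::write_tsv(bed, out("ancestry_tracts.bed"), col_names = FALSE)
      hist <- tract_length_summary(tracts)
      readr::write_tsv(hist, out("tract_histogram.tsv"))
      list(state = state,
           report = list(outputs = c(out("ancestry_windows.tsv"),
                                     out("ancestry_tracts.bed"),
                                     out("tract_histogram.tsv")),
                         summary = list(n_windows = nrow(aw),
                                        n_tracts = nrow(tracts),
                                        window_bp = params$ancestry_window_bp,
                                        hi = params$ancestry_hi,
                                        lo = params$ancestry_lo)))
    },
    sort_alleles = {
      state <- need_geno(state, config)
      lv_groups <- roles$lv_groups %||%
        grep("^lv_sp", unique(state$popmap$group), value = TRUE)
      freqs <- allele_freqs(state$geno, state$popmap)
      fst <- global_fst(state$geno, state$popmap, species = lv_groups)
      nd <- round(mean(table(state$popmap$group[state$popmap$group %in% lv_groups])))
      fst <- flag_outliers(fst, n_ind = nd, n_pops = length(lv_groups),
                           p_threshold = params$p_threshold, seed = stage_seed)
      cats <- classify_categories(freqs, lv_groups, roles$congolese,
                                  roles$upper_nile)
      cats <- select_control_set(cats, w_congo = params$w_congo,
                                 w_nile = params$w_nile,
                                 window = params$control_window)
      enr <- enrichment(cats, fst)
      per_snp <- cats |>
        left_join(select(fst, "scaffold", "pos", "fst", "p_fst", "lv_outlier"),
                  by = c("scaffold", "pos"))
      readr::write_tsv(per_snp, out("snp_categories.tsv"))
      readr::write_tsv(tidy(enr), out("enrichment.tsv"))
      res <- list(outputs = c(out("snp_categories.tsv"), out("enrichment.tsv")),
                  summary = list(n_classified = sum(!is.na(cats$category)),
                                 n_outliers = sum(fst$lv_outlier, na.rm = TRUE),
                                 w_congo = params$w_congo, w_nile = params$w_nile,
                                 control_window = params$control_window,
                                 p_threshold = params$p_threshold,
                                 p_cat4_vs_control = enr$table$p_vs_reference[
                                   enr$table$category == "4"]))
      if (!is.null(roles$control_pairs)) {
        cft <- control_fixation_test(state$geno, state$popmap,
                                     roles$control_pairs,
                                     dplyr::filter(cats, .data$category == "4"),
                                     fst)
        readr::write_tsv(cft, out("control_fixation.tsv"))
        res$outputs <- c(res$outputs, out("control_fixation.tsv"))
        res$summary$control_fixation_p <- cft$p_value
      }
      list(state = state, report = res)
    },
    abort(paste0("unimplemented stage: ", st))
  )
}

#' @export
print.ht_report <- function(x, ...) {
  cat("hybridtrace pipeline report (", x$version, ")\n", sep = "")
  cat("config hash:", x$config_hash, " seed:", x$seed, "\n")
  for (st in names(x$stages)) {
    cat(sprintf("  %-12s %6.2fs  %s\n", st, x$stages[[st]]$seconds,
                paste(basename(unlist(x$stages[[st]]$outputs)), collapse = ", ")))
  }
  invisible(x)
}
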