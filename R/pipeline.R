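# End-to-end orchestration: inputs -> per-pen networks -> trait table ->
# univariate and bivariate animal models -> posterior summary tables.

#' Run the complete analysis pipeline
#'
#' Reads (or accepts in-memory) the four standard inputs, computes the six
#' square-root-transformed network traits, fits one univariate chain per
#' network trait, bivariate chains for every network-trait pair and for
#' every network x performance pair, and writes the summary tables, the
#' Spearman phenotypic correlation matrix, per-model chain files and a run
#' manifest to `out_dir`. The manifest records the seed and MCMC settings,
#' so a rerun with the same manifest reproduces every chain bit for bit.
#'
#' @param fights,animals,pedigree,performance Paths to the input CSVs, or
#'   the corresponding objects (fight records, metadata, `pedigree`,
#'   performance table).
#' @param out_dir Output directory.
#' @param config A `gibbs_config`; its seed drives all chains.
#' @param sna Which network traits to analyse (transformed column names).
#' @param perf Which performance traits to cross against them.
#' @param sna_pairs,perf_pairs Fit the within-SNA / SNA-by-performance
#'   bivariate models (default TRUE; disable for quick runs).
#' @param weight_mode,clustering_mode Passed to [compute_sna_traits()].
#' @return Invisibly, a list with the summary tables and the chain set.
#' @export
run_pipeline <- function(fights, animals, pedigree, performance = NULL,
                         out_dir, config = gibbs_config_test(seed = 1L),
                         sna = paste0("t_", sna_trait_names()),
                         perf = perf_trait_names(),
                         sna_pairs = TRUE, perf_pairs = TRUE,
                         weight_mode = "cost", clustering_mode = "binary") {
  t0 <- Sys.time()
  if (is.character(animals)) animals <- read_animal_metadata(animals)
  if (is.character(pedigree)) pedigree <- read_pedigree(pedigree)
  if (is.character(fights))
    fights <- read_fight_records(fights, pen_rosters(animals))
  if (is.character(performance)) performance <- read_performance(performance)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  msg <- function(...) message(sprintf(...))
  msg("stage traits: %d fight records, %d animals, %d pens",
      nrow(fights), nrow(animals), length(unique(animals$pen_id)))
  traits <- compute_sna_traits(fights, animals,
                               weight_mode = weight_mode,
                               clustering_mode = clustering_mode)
  write_csv_plain(traits, file.path(out_dir, "sna_traits.csv"))

  data <- merge(animals, traits[c("animal", setdiff(names(traits),
                                                    c("animal", "pen_id")))],
                by = "animal", sort = FALSE)
  use_perf <- character(0)
  if (!is.null(performance)) {
    data <- merge(data, performance, by = "animal", all.x = TRUE, sort = FALSE)
    use_perf <- intersect(perf, names(performance))
  }

  msg("stage kinship: pedigree of %d animals", nrow(pedigree))
  ainv <- ainverse(pedigree)

  msg("stage mcmc: %d univariate + %d bivariate models",
      length(sna),
      (if (sna_pairs) choose(length(sna), 2) else 0L) +
        (if (perf_pairs) length(sna) * length(use_perf) else 0L))
  chains <- run_all_models(
    data, sna, pedigree, ainv,
    partner_traits = if (perf_pairs) use_perf else character(0),
    pairs = sna_pairs, config = config)

  chain_dir <- file.path(out_dir, "chains")
  dir.create(chain_dir, showWarnings = FALSE)
  for (nm in names(chains))
    write_chain(chains[[nm]], file.path(chain_dir, paste0(gsub(":", "_", nm),
                                                          ".csv")))

  uni <- names(chains)[lengths(lapply(chains, `[[`, "traits")) == 1L]
  h2 <- do.call(rbind, lapply(uni, function(nm) summarize_univariate(chains[[nm]])))
  biv <- setdiff(names(chains), uni)
  rg <- do.call(rbind, lapply(biv, function(nm) summarize_bivariate(chains[[nm]])))
  rg_sna <- if (is.null(rg)) NULL else rg[rg$trait_b %in% sna, , drop = FALSE]
  rg_perf <- if (is.null(rg)) NULL else rg[rg$trait_b %in% use_perf, , drop = FALSE]

  rp <- spearman_matrix(data, c(sna, use_perf))
  summaries <- list(h2 = h2, rg_sna = rg_sna, rg_sna_perf = rg_perf, rp = rp)
  write_results_tables(summaries, out_dir)

  manifest <- c(
    sprintf("seed: %s", config$seed),
    sprintf("n_iter: %d", config$n_iter),
    sprintf("burn_in: %d", config$burn_in),
    sprintf("thin: %d", config$thin),
    sprintf("sna_traits: %s", paste(sna, collapse = ",")),
    sprintf("perf_traits: %s", paste(use_perf, collapse = ",")),
    sprintf("weight_mode: %s", weight_mode),
    sprintf("clustering_mode: %s", clustering_mode),
    sprintf("n_records: %d", nrow(data)),
    sprintf("n_pedigree: %d", nrow(pedigree))
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  msg("pipeline done in %.1f s", as.numeric(difftime(Sys.time(), t0, "secs")))
  invisible(list(summaries = summaries, chains = chains, traits = traits))
}

#' Render a human-readable report of a pipeline run
#'
#' Markdown summary of the output tables in `dir`. Correlations whose HPD95
#' interval excludes zero are marked in bold, mirroring the reporting
#' convention for genetic correlation tables.
#'
#' @param dir A pipeline output directory.
#' @return Character vector of markdown lines (also printed).
#' @export
report <- function(dir) {
  lines <- c("# Network-trait genetic analysis", "")
  h2p <- file.path(dir, "h2_table.csv")
  fmt <- function(x) formatC(x, digits = 2, format = "f")
  if (file.exists(h2p)) {
    h2 <- utils::read.csv(h2p)
    lines <- c(lines, "## Heritability and pen effects", "",
               "| trait | h2 (HPD95) | c2 (HPD95) | Vp |", "|---|---|---|---|")
    for (i in seq_len(nrow(h2))) {
      lines <- c(lines, sprintf(
        "| %s | %s (%s, %s) | %s (%s, %s) | %s |",
        h2$trait[i], fmt(h2$h2_mean[i]), fmt(h2$h2_lo[i]), fmt(h2$h2_hi[i]),
        fmt(h2$c2_mean[i]), fmt(h2$c2_lo[i]), fmt(h2$c2_hi[i]),
        fmt(h2$Vp_mean[i])))
    }
    lines <- c(lines, "")
  }
  for (nm in c("rg_sna", "rg_sna_perf")) {
    p <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(p)) next
    rg <- utils::read.csv(p)
    title <- if (nm == "rg_sna") "## Genetic correlations among network traits"
             else "## Genetic correlations with performance traits"
    lines <- c(lines, title, "",
               "| pair | rg (HPD95) |", "|---|---|")
    for (i in seq_len(nrow(rg))) {
      val <- sprintf("%s (%s, %s)", fmt(rg$rg_mean[i]), fmt(rg$rg_lo[i]),
                     fmt(rg$rg_hi[i]))
      if (isTRUE(rg$significant[i])) val <- paste0("**", val, "**")
      lines <- c(lines, sprintf("| %s : %s | %s |", rg$trait_a[i],
                                rg$trait_b[i], val))
    }
    lines <- c(lines,
               "Bold: HPD95 interval excludes zero.", "")
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
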