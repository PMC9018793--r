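# End-to-end orchestration on synthetic data: simulate a study, count,
# test, call DMRs, annotate, compare, detect modules, classify pathology,
# and leave every stage output plus a reproducibility manifest in one run
# directory.

#' Default pipeline configuration
#'
#' A small but complete synthetic study: one chromosome, 1-kb windows, two
#' exposure lineages of 6 animals tested against 6 controls, planted DMRs
#' per exposure (partially shared), two latent module blocks, and a
#' pathology arm. Thresholds follow the study defaults: seed p 1e-6 with a
#' sparse-comparison override of 1e-4, extension p 0.1 within 1000 bp,
#' relaxed overlap p 0.05, gene distance 10 kb, soft power 4, minimum
#' module size 30, merge height 0.25.
#'
#' @param seed master RNG seed; all stage seeds derive from it.
#' @return a nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    genome = list(n_chroms = 1L, chrom_length = 2e6, cpg_rate = 0.01),
    window_size = 1000L,
    n_per_group = 6L,
    baseline = c(intercept = 10, per_cpg = 2),
    dispersion = 0.1,
    planted = list(n_dmrs = 5L, dmr_windows = 4L, log2fc = 2,
                   shared_fraction = 0.5),
    module_blocks = list(n_blocks = 2L, block_windows = 50L,
                         loading = 0.35),
    n_genes = 150L,
    thresholds = list(seed_p = 1e-6, sparse_seed_p = 1e-4, extend_p = 0.1,
                      max_gap_bp = 1000, relaxed_p = 0.05,
                      gene_distance = 10000, min_row_sum = 10),
    wgcna = list(n_top = 500L, power = 4, min_module_size = 30,
                 merge_cut_height = 0.25),
    pathology = list(n_control = 12L, n_case = 12L, control_rate = 2,
                     case_shift = 4, n_observers = 3L)
  )
}

# Build the synthetic study described by a config: genome, grid, genes,
# design with two exposures whose planted DMRs partially overlap.
build_study <- function(config) {
  g <- generate_genome(config$genome$n_chroms, config$genome$chrom_length,
                       config$genome$cpg_rate,
                       seed = sub_seed(config$seed, "genome"))
  grid <- make_windows(g, config$window_size)
  genes <- generate_gene_models(g, config$n_genes,
                                seed = sub_seed(config$seed, "genes"))
  n <- config$n_per_group
  ids <- c(sprintf("ctrl_%02d", seq_len(n)),
           sprintf("expA_%02d", seq_len(n)),
           sprintf("expB_%02d", seq_len(n)))
  samples <- data.frame(
    sample_id = ids,
    exposure = rep(c("control", "exposure_a", "exposure_b"), each = n),
    stringsAsFactors = FALSE)
  samples$is_exposure_a <- as.integer(samples$exposure == "exposure_a")
  samples$is_exposure_b <- as.integer(samples$exposure == "exposure_b")
  comparisons <- list(
    exposure_a = list(a = ids[samples$exposure == "exposure_a"],
                      b = ids[samples$exposure == "control"]),
    exposure_b = list(a = ids[samples$exposure == "exposure_b"],
                      b = ids[samples$exposure == "control"]))

  pl <- config$planted
  nw <- nrow(grid)
  # planted regions sit in the first ~60% of the grid; module blocks at the
  # end, so the two planted structures never overlap
  gap <- floor(0.6 * nw / (2L * pl$n_dmrs + 1L))
  startw <- gap * seq_len(2L * pl$n_dmrs)
  n_shared <- round(pl$shared_fraction * pl$n_dmrs)
  a_idx <- seq_len(pl$n_dmrs)
  b_idx <- c(seq_len(n_shared),                       # shared with A
             pl$n_dmrs + seq_len(pl$n_dmrs - n_shared))
  mk <- function(idx, cmp) data.frame(
    comparison = cmp, first_window = startw[idx],
    last_window = startw[idx] + pl$dmr_windows - 1L, log2fc = pl$log2fc)
  planted <- rbind(mk(a_idx, "exposure_a"), mk(b_idx, "exposure_b"))

  mb <- config$module_blocks
  block_start <- nw - mb$n_blocks * (mb$block_windows + 10L)
  blocks <- lapply(seq_len(mb$n_blocks), function(k) {
    w0 <- block_start + (k - 1L) * (mb$block_windows + 10L)
    list(windows = w0:(w0 + mb$block_windows - 1L), loading = mb$loading,
         trait = paste0("latent_block_", k))
  })

  design <- study_design(
    samples = samples, comparisons = comparisons,
    library_size_targets = NULL, planted_dmrs = planted,
    dispersion = config$dispersion, baseline = config$baseline,
    module_blocks = blocks, seed = sub_seed(config$seed, "design"))
  list(genome = g, grid = grid, genes = genes, design = design,
       planted = planted)
}

#' Run the full synthetic pipeline
#'
#' Simulates the study defined by `config`, then runs every analysis
#' stage, writing stage outputs (TSV/CSV/BED/JSON) and a manifest with the
#' package version, configuration, its hash, and the seed into `out_dir`.
#' Outputs are deterministic for a fixed configuration.
#'
#' @param config configuration list (see [default_config()]).
#' @param out_dir run directory (created; must not pre-exist unless
#'   `force`).
#' @param force overwrite an existing run directory.
#' @return invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config = default_config(), out_dir, force = FALSE) {
  if (dir.exists(out_dir) &&
      length(list.files(out_dir)) && !force) {
    stop("run directory exists and is non-empty; use force = TRUE")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  study <- build_study(config)
  write_genome(study$genome, out_dir)
  write_gene_models(study$genes, file.path(out_dir, "genes.gff3"))

  counts <- simulate_counts(study$design, study$grid)
  write_counts(counts, study$grid, file.path(out_dir, "counts.tsv"))
  write.csv(study$design$samples, file.path(out_dir, "samples.csv"),
            row.names = FALSE)

  thr <- config$thresholds
  filtered <- filter_low_coverage(counts, thr$min_row_sum)
  stats_list <- list()
  dmr_list <- list()
  assoc_list <- list()
  for (cmp in names(study$design$comparisons)) {
    gp <- study$design$comparisons[[cmp]]
    st <- test_all_windows(filtered, gp$a, gp$b, dispersion = "grid_cml",
                           grid = study$grid)
    write_window_stats(st, file.path(out_dir,
                                     paste0("stats_", cmp, ".tsv")))
    dm <- call_dmrs(st, seed_p = thr$sparse_seed_p, extend_p = thr$extend_p,
                    max_gap_bp = thr$max_gap_bp, genome = study$genome)
    write_dmrs(dm, file.path(out_dir, paste0("dmrs_", cmp, ".tsv")),
               comparison = cmp)
    write_dmr_bed(dm, file.path(out_dir, paste0("dmrs_", cmp, ".bed")))
    assoc <- associate_genes(dm, study$genes,
                             max_distance = thr$gene_distance)
    write.table(assoc, file.path(out_dir, paste0("genes_", cmp, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    stats_list[[cmp]] <- st
    dmr_list[[cmp]] <- dm
    assoc_list[[cmp]] <- assoc
  }

  venn <- venn_overlap(dmr_list)
  jsonlite::write_json(venn, file.path(out_dir, "venn.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  ext <- extended_overlap_matrix(dmr_list, stats_list,
                                 relaxed_p = thr$relaxed_p)
  write.csv(ext$percent, file.path(out_dir, "extended_overlap_pct.csv"))
  clusters <- cluster_scan(dmr_list[[1]], study$genome)
  write.table(clusters, file.path(out_dir, "clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # methylation modules on the top windows by mean RPKM
  rk <- rpkm(counts, study$grid)
  top <- select_top_windows(rk, config$wgcna$n_top)
  mods <- detect_methylation_modules(
    rk[top, , drop = FALSE], power = config$wgcna$power,
    min_module_size = config$wgcna$min_module_size,
    merge_cut_height = config$wgcna$merge_cut_height)
  write.table(data.frame(window = top, module = mods$labels),
              file.path(out_dir, "modules.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  traits <- attr(counts, "traits")
  traits_num <- traits[, vapply(traits, is.numeric, TRUE), drop = FALSE]
  mtc <- NULL
  if (!is.null(mods$eigengenes) && ncol(traits_num)) {
    mtc <- module_trait_correlation(mods$eigengenes, traits_num)
    write.csv(mtc$r, file.path(out_dir, "module_trait_r.csv"))
    write.csv(mtc$p, file.path(out_dir, "module_trait_p.csv"))
  }

  pa <- config$pathology
  records <- simulate_pathology(pa$n_control, pa$n_case, pa$control_rate,
                                pa$case_shift, pa$n_observers,
                                seed = sub_seed(config$seed, "pathology"))
  write.csv(records, file.path(out_dir, "pathology_records.csv"),
            row.names = FALSE)
  thresholds <- compute_disease_thresholds(records)
  cls <- classify_animals(records, thresholds, m = pa$n_observers)
  write.csv(cls$calls, file.path(out_dir, "disease_calls.csv"),
            row.names = FALSE)
  freq <- disease_frequency_report(cls$calls)
  write.csv(freq, file.path(out_dir, "disease_frequency.csv"),
            row.names = FALSE)

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  cfg_file <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_file)
  manifest <- list(
    package = "epidmr",
    version = as.character(utils::packageVersion("epidmr")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    outputs = sort(setdiff(list.files(out_dir), "manifest.json")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(study = study, counts = counts, stats = stats_list,
                 dmrs = dmr_list, associations = assoc_list, venn = venn,
                 extended = ext, clusters = clusters, modules = mods,
                 module_traits = mtc, pathology = list(
                   records = records, thresholds = thresholds,
                   calls = cls, frequency = freq)))
}
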