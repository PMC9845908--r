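# End-to-end driver reproducing the analysis order on synthetic or user
# data: filter -> normalize -> DE per tissue; network -> module-trait ->
# cross-tissue correspondence; miRNA curation -> miRNA DE -> consensus
# targets and RBH orthologs.

#' Default pipeline configuration
#'
#' Every stage threshold carries its standard default (CPM filter
#' min_count 10 / min_total 15; TMM trims 0.30/0.05; voom-style span 0.5;
#' soft power 4; minimum module size 30; deep split 2; merge cut height
#' 0.25; 10,000 bootstrap iterations; miRNA read floor 5 and randfold
#' alpha 0.05; homolog identity 0.90 with at most 2 non-seed mismatches;
#' consensus p < 0.01; RBH e-value 1e-5). The simulation block sets the
#' synthetic-data scale used by the driver; the paired 22 + 22 sample
#' design and planted module structure come from [design_spec()] and
#' [module_spec()] defaults.
#'
#' @param seed master seed for every random draw in the run.
#' @param n_genes simulated gene count for the driver (default 2000, which
#'   keeps the network stage tractable on one CPU).
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1, n_genes = 2000) {
  list(
    seed = seed,
    simulate = list(n_genes = n_genes, n_mirna_loci = 75,
                    libsize_log_mean = c(oocyte = log(2e6), egg = log(2e6))),
    drop_samples = character(0),
    filter = list(min_count = 10, min_total = 15),
    tmm = list(logratio_trim = 0.30, abs_trim = 0.05),
    voom = list(span = 0.5),
    de = list(alphas = c(0.05, 0.1)),
    network = list(beta = 4, betas_scanned = 1:10, min_module_size = 30,
                   deep_split = 2, merge_cut_height = 0.25),
    overlap = list(n_iter = 10000, include_unassigned = FALSE),
    mirna = list(min_reads = 5, randfold_alpha = 0.05, identity = 0.90,
                 max_mismatches = 2, seed_start = 2, seed_end = 7),
    targets = list(p_max = 0.01, score_min = 140, energy_max = -20),
    rbh = list(evalue_max = 1e-5, n_a = 200, n_b = 180,
               ortholog_fraction = 0.6)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of [default_config()].
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_config_yaml <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user)
}

stage_log <- function(log, stage, ...) {
  entry <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             list(...))
  c(log, list(entry))
}

mrna_tissue_analysis <- function(counts, md, cfg) {
  grp <- paste0(md$season, ifelse(md$condition == "poor", "Poor", "Control"))
  kept <- filter_by_expression(counts, grp, cfg$filter$min_count,
                               cfg$filter$min_total)
  fc <- counts[kept, , drop = FALSE]
  nf <- tmm_factors(fc, cfg$tmm$logratio_trim, cfg$tmm$abs_trim)
  lc <- log_cpm(fc, nf)
  design <- group_design(md)
  w <- precision_weights(lc, design, span = cfg$voom$span)
  fit <- fit_moderated(lc, design, weights = w)
  list(kept = kept, logcpm = lc, factors = nf, fit = fit,
       summary = de_summary(fit, cfg$de$alphas))
}

#' Run the full analysis pipeline on simulated data
#'
#' Simulates the paired two-tissue design, then runs each analysis branch
#' in order, writing all tables, summaries and a run log into `out_dir`.
#' Re-running with the same configuration and seed reproduces the numeric
#' outputs byte for byte (the run log carries wall-clock timestamps and is
#' the one file excluded from that guarantee). Tissues are always analyzed
#' separately; the driver never pools oocyte and egg samples in one
#' design.
#'
#' @param config configuration list from [default_config()] or
#'   [read_config_yaml()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  log <- list()

  ## ---- simulate ----------------------------------------------------------
  design <- design_spec(n_genes = config$simulate$n_genes,
                        n_mirna_loci = config$simulate$n_mirna_loci)
  noise <- noise_spec(libsize_log_mean = config$simulate$libsize_log_mean,
                      seed = config$seed)
  sim <- generate_counts(design, module_spec(), noise)
  write_counts_tsv(sim$counts, file.path(out_dir, "counts.tsv"))
  write_metadata_tsv(sim$metadata, file.path(out_dir, "metadata.tsv"))
  write_json_summary(list(config_hash = hash,
                          oocyte_modules = as.list(sim$truth$oocyte_modules),
                          egg_modules = as.list(sim$truth$egg_modules)),
                     file.path(out_dir, "truth_modules.json"))
  log <- stage_log(log, "simulate", n_genes = design$n_genes,
                   n_samples = ncol(sim$counts))

  drop <- config$drop_samples
  keep_samples <- setdiff(colnames(sim$counts), drop)
  counts <- sim$counts[, keep_samples, drop = FALSE]
  md <- sim$metadata[keep_samples, , drop = FALSE]

  ## ---- mRNA filter/normalize/DE per tissue -------------------------------
  de_res <- list()
  for (tis in c("oocyte", "egg")) {
    sel <- md$tissue == tis
    res <- mrna_tissue_analysis(counts[, sel, drop = FALSE], md[sel, ], config)
    de_res[[tis]] <- res
    utils::write.table(res$fit$table,
                       file.path(out_dir, sprintf("de_mrna_%s.tsv", tis)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$summary,
                       file.path(out_dir, sprintf("de_mrna_summary_%s.tsv", tis)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log <- stage_log(log, paste0("de_mrna_", tis),
                     n_features_in = nrow(counts),
                     n_features_kept = length(res$kept))
  }

  ## ---- coexpression networks per tissue ----------------------------------
  nets <- list()
  for (tis in c("oocyte", "egg")) {
    sel <- md$tissue == tis
    lc <- de_res[[tis]]$logcpm
    traits <- data.frame(
      cage = as.numeric(md$cage[sel] == md$cage[sel][1]),
      season = as.numeric(md$season[sel] == "late"),
      condition = as.numeric(md$condition[sel] == "poor"))
    scan <- scale_free_scan(lc, betas = config$network$betas_scanned)
    net <- network_analysis(lc, traits, beta = config$network$beta,
                            min_module_size = config$network$min_module_size,
                            deep_split = config$network$deep_split,
                            merge_cut_height = config$network$merge_cut_height)
    nets[[tis]] <- net
    utils::write.table(scan, file.path(out_dir, sprintf("scale_free_%s.tsv", tis)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_partition_tsv(net$partition,
                        file.path(out_dir, sprintf("modules_%s.tsv", tis)))
    if (!is.null(net$module_trait))
      utils::write.table(net$module_trait,
                         file.path(out_dir, sprintf("module_trait_%s.tsv", tis)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    log <- stage_log(log, paste0("network_", tis),
                     n_modules = max(net$partition),
                     n_unassigned = sum(net$partition == 0),
                     n_outliers = length(net$outliers))
  }

  ## ---- cross-tissue module correspondence --------------------------------
  egg_relabeled <- match_labels(nets$egg$partition, nets$oocyte$partition)
  mt <- nets$oocyte$module_trait
  interest <- if (!is.null(mt)) {
    labs <- unique(mt$module[mt$significant & mt$trait %in% c("season", "condition")])
    as.integer(sub("^ME", "", labs))
  } else integer(0)
  ov <- overlap_table(nets$oocyte$partition, egg_relabeled,
                      modules_of_interest = interest,
                      n_iter = config$overlap$n_iter,
                      seed = substream_seed(config$seed, "overlap"),
                      include_unassigned = config$overlap$include_unassigned)
  utils::write.table(ov$table, file.path(out_dir, "module_overlap.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_json_summary(list(config_hash = hash, universe_size = ov$universe_size,
                          modules_of_interest = interest,
                          flow = ov$flow,
                          bootstrap = lapply(ov$bootstrap, function(b)
                            list(observed = b$observed,
                                 empirical_p = b$empirical_p,
                                 p_label = b$p_label, n_iter = b$n_iter))),
                     file.path(out_dir, "module_overlap_summary.json"))
  log <- stage_log(log, "module_correspondence",
                   n_modules_of_interest = length(interest))

  ## ---- miRNA curation and DE ---------------------------------------------
  mir <- generate_mirna_records(n_loci = config$simulate$n_mirna_loci,
                                sample_ids = md$sample_id, sample_meta = md,
                                seed = substream_seed(config$seed, "mirna_records"))
  passing <- filter_precursor_pairs(mir$records, config$mirna$min_reads,
                                    config$mirna$randfold_alpha)
  composite <- compile_novel_precursors(
    passing$precursor_seq[passing$novel], mir$known_precursors)
  loci <- merge_loci(passing)
  write_gff3_precursors(loci, file.path(out_dir, "mirna_loci.gff3"))
  write_fasta_rna(mir$mature_fasta, file.path(out_dir, "mirna_mature.fasta"))
  mir_counts <- mirna_count_table(loci, passing)
  write_counts_tsv(mir_counts, file.path(out_dir, "mirna_counts.tsv"))
  log <- stage_log(log, "mirna_curation",
                   n_records_in = nrow(mir$records),
                   n_records_passing = nrow(passing),
                   n_loci = length(unique(loci$locus_id)),
                   n_composite_precursors = length(composite))

  mir_de <- list()
  for (tis in c("oocyte", "egg")) {
    sel <- md$tissue == tis
    res <- mrna_tissue_analysis(mir_counts[, md$sample_id[sel], drop = FALSE],
                                md[sel, ], config)
    mir_de[[tis]] <- res
    utils::write.table(res$fit$table,
                       file.path(out_dir, sprintf("de_mirna_%s.tsv", tis)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log <- stage_log(log, paste0("de_mirna_", tis),
                     n_features_in = nrow(mir_counts),
                     n_features_kept = length(res$kept))
  }

  ## ---- consensus targets and overlap with DE genes -----------------------
  tt <- generate_target_tables(rownames(mir_counts), rownames(counts),
                               seed = substream_seed(config$seed, "targets"))
  cons <- consensus_targets(tt$preds_a, tt$preds_b, config$targets$p_max,
                            config$targets$score_min, config$targets$energy_max)
  utils::write.table(cons, file.path(out_dir, "consensus_targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  oo_tab <- de_res$oocyte$fit$table
  de_season <- oo_tab$feature[oo_tab$contrast == "season" &
                                oo_tab$adj_p_value < 0.1]
  universe <- de_res$oocyte$kept
  target_genes <- intersect(unique(cons$gene_id), universe)
  tg_overlap <- set_overlap_test(target_genes,
                                 intersect(de_season, universe), universe)
  write_json_summary(list(config_hash = hash,
                          n_consensus_pairs = nrow(cons),
                          n_target_genes_in_universe = length(target_genes),
                          n_de_season = length(intersect(de_season, universe)),
                          overlap = tg_overlap),
                     file.path(out_dir, "target_de_overlap.json"))
  log <- stage_log(log, "targets", n_consensus = nrow(cons))

  ## ---- RBH orthologs ------------------------------------------------------
  hits <- generate_hit_tables(config$rbh$n_a, config$rbh$n_b,
                              config$rbh$ortholog_fraction,
                              seed = substream_seed(config$seed, "rbh"))
  pairs <- rbh_orthologs(hits$hits_ab, hits$hits_ba, config$rbh$evalue_max)
  utils::write.table(pairs, file.path(out_dir, "rbh_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log <- stage_log(log, "rbh", n_pairs = nrow(pairs))

  write_json_summary(list(config_hash = hash, config = config, stages = log),
                     file.path(out_dir, "run_log.json"))

  invisible(list(sim = sim, de = de_res, networks = nets,
                 egg_relabeled = egg_relabeled, overlap = ov,
                 mirna = list(records = mir, loci = loci,
                              counts = mir_counts, de = mir_de),
                 targets = list(tables = tt, consensus = cons,
                                overlap = tg_overlap),
                 rbh = list(hits = hits, pairs = pairs),
                 config_hash = hash))
}
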