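# Synthetic-data generators emulating the paired oocyte/egg two-tissue
# design, with ground truth for every downstream stage.
#
# The count model is negative binomial with gene-wise log-normal baseline
# means and a common dispersion; coexpression modules are planted through a
# latent-factor (eigengene) model with Gaussian loadings acting additively
# on the log2 mean; differential expression is planted as log2 fold changes
# on the group means; library sizes are log-normal per tissue with a shared
# female-level random intercept linking each oocyte to its paired egg.

#' Experimental design specification
#'
#' Defaults reproduce the study layout: 22 females, each contributing one
#' maturing oocyte and one 24-h egg, split over the four season-by-condition
#' cells with sizes 6 (earlyControl), 4 (earlyPoor), 6 (lateControl) and
#' 6 (latePoor), nesting in two cages.
#'
#' @param n_genes number of genes (default 12770).
#' @param n_mirna_loci number of distinct miRNA loci (default 75).
#' @param group_sizes named integer vector over the four cells; overrides
#'   `samples_per_group`.
#' @param samples_per_group balanced per-cell size (used when `group_sizes`
#'   is NULL and a balanced design is wanted).
#' @param cages cage labels (default two).
#' @return List of class `"design_spec"`.
#' @export
design_spec <- function(n_genes = 12770, n_mirna_loci = 75,
                        group_sizes = NULL, samples_per_group = NULL,
                        cages = c("cageA", "cageB")) {
  if (is.null(group_sizes)) {
    group_sizes <- if (is.null(samples_per_group))
      c(earlyControl = 6, earlyPoor = 4, lateControl = 6, latePoor = 6)
    else stats::setNames(rep(samples_per_group, 4), GROUP_LEVELS)
  }
  stopifnot(n_genes >= 1, n_mirna_loci >= 1, all(group_sizes >= 1),
            identical(sort(names(group_sizes)), sort(GROUP_LEVELS)))
  structure(list(n_genes = n_genes, n_mirna_loci = n_mirna_loci,
                 group_sizes = group_sizes[GROUP_LEVELS], cages = cages,
                 paired = TRUE),
            class = "design_spec")
}

#' Planted module structure specification
#'
#' Defaults plant five oocyte modules of sizes 80, 70, 60, 50 and 40.
#' Modules 1-3 are season-coupled (eigengene correlation 0.6 with the
#' season coding) and converge in the egg network: fractions 0.519, 0.451
#' and 0.652 of their genes are re-assigned together into egg module 1,
#' while modules 4 and 5 carry 80% of their genes into egg modules of
#' their own.
#'
#' @param module_sizes integer vector of module sizes.
#' @param trait_coupled_modules indices of season-coupled modules.
#' @param trait_r planted eigengene-season correlation (default 0.6).
#' @param loading_mean,loading_sd Gaussian distribution of the loading
#'   magnitudes of member genes on the module eigengene (log2 scale;
#'   defaults 1 and 0.3). With `signed_loadings` each gene's sign is
#'   drawn at random, so modules contain both positively and negatively
#'   responding genes, as an unsigned coexpression network presumes.
#' @param signed_loadings balanced random loading signs (default TRUE).
#' @param cross_tissue_map data.frame with columns oocyte_module,
#'   egg_module, fraction.
#' @return List of class `"module_spec"`.
#' @export
module_spec <- function(module_sizes = c(80, 70, 60, 50, 40),
                        trait_coupled_modules = 1:3, trait_r = 0.6,
                        loading_mean = 1, loading_sd = 0.3,
                        signed_loadings = TRUE,
                        cross_tissue_map = data.frame(
                          oocyte_module = 1:5,
                          egg_module = c(1, 1, 1, 2, 3),
                          fraction = c(0.519, 0.451, 0.652, 0.8, 0.8))) {
  stopifnot(abs(trait_r) <= 1, all(module_sizes >= 1))
  structure(list(module_sizes = module_sizes,
                 trait_coupled_modules = trait_coupled_modules,
                 trait_r = trait_r, loading_mean = loading_mean,
                 loading_sd = loading_sd, signed_loadings = signed_loadings,
                 cross_tissue_map = cross_tissue_map),
            class = "module_spec")
}

#' Count-noise specification
#'
#' @param nb_dispersion common negative-binomial dispersion (default 0.1).
#' @param libsize_log_mean named per-tissue log library-size means
#'   (defaults log(2e7) for both tissues).
#' @param libsize_log_sd log library-size standard deviation (default 0.15).
#' @param female_sd female-level random intercept on log library size
#'   shared by the paired oocyte and egg samples (default 0.1).
#' @param baseline_log2_sd spread of gene baseline log2 means (default 1.5).
#' @param silent_fraction fraction of the unstructured (non-module, non-DE)
#'   genes that are essentially unexpressed in both tissues (baseline
#'   shifted down by `silent_log2_shift`), emulating the annotated genes a
#'   tissue does not transcribe so that the expression filter has
#'   realistic work to do (default 0.3).
#' @param silent_log2_shift log2 downshift applied to silent genes
#'   (default -8).
#' @param de_effects list of planted effects, each a list with fields
#'   `tissue`, `contrast` ("season"/"condition"/"interaction"), `n_genes`
#'   and `log2_fc`; the default plants 30 up- and 20 down-regulated
#'   season genes in the oocyte at |log2 FC| = 2.
#' @param seed master seed.
#' @return List of class `"noise_spec"`.
#' @export
noise_spec <- function(nb_dispersion = 0.1,
                       libsize_log_mean = c(oocyte = log(2e7), egg = log(2e7)),
                       libsize_log_sd = 0.15, female_sd = 0.1,
                       baseline_log2_sd = 1.5,
                       silent_fraction = 0.3, silent_log2_shift = -8,
                       de_effects = list(
                         list(tissue = "oocyte", contrast = "season",
                              n_genes = 30, log2_fc = 2),
                         list(tissue = "oocyte", contrast = "season",
                              n_genes = 20, log2_fc = -2)),
                       seed = 1) {
  stopifnot(nb_dispersion > 0,
            all(vapply(de_effects, function(e) is.finite(e$log2_fc), logical(1))))
  structure(list(nb_dispersion = nb_dispersion,
                 libsize_log_mean = libsize_log_mean,
                 libsize_log_sd = libsize_log_sd, female_sd = female_sd,
                 baseline_log2_sd = baseline_log2_sd,
                 silent_fraction = silent_fraction,
                 silent_log2_shift = silent_log2_shift,
                 de_effects = de_effects, seed = seed),
            class = "noise_spec")
}

# Contrast covariate per sample on the 0/1 scale used to plant effects:
# the planted log2_fc is the exact difference of group log2 means implied
# by the contrast.
contrast_coding <- function(metadata, contrast) {
  switch(contrast,
         season = as.numeric(metadata$season == "late"),
         condition = as.numeric(metadata$condition == "poor"),
         interaction = as.numeric(metadata$season == "late" &
                                    metadata$condition == "poor"),
         stop("unknown contrast: ", contrast))
}

# Latent module factor with exact sample correlation r against the season
# coding (residual orthogonalized and standardized).
module_factor <- function(season01, r) {
  n <- length(season01)
  s <- as.numeric(scale(season01))
  e <- stats::rnorm(n)
  e <- e - s * sum(e * s) / sum(s * s)
  e <- as.numeric(scale(e))
  f <- r * s + sqrt(1 - r^2) * e
  as.numeric(scale(f))
}

#' Generate the paired two-tissue count matrix with ground truth
#'
#' @param design [design_spec()] object.
#' @param modules [module_spec()] object.
#' @param noise [noise_spec()] object.
#' @return List with `counts` (genes x 2*females integer matrix),
#'   `metadata` (sample_id, tissue, season, condition, cage, female) and
#'   `truth` (module partitions per tissue, planted factors, DE gene sets
#'   with signs, library sizes).
#' @export
generate_counts <- function(design = design_spec(), modules = module_spec(),
                            noise = noise_spec()) {
  stopifnot(inherits(design, "design_spec"), inherits(modules, "module_spec"),
            inherits(noise, "noise_spec"))
  G <- design$n_genes
  if (sum(modules$module_sizes) > G)
    stop("module sizes exceed the number of genes")
  set.seed(substream_seed(noise$seed, "counts"))

  # --- samples -------------------------------------------------------------
  n_f <- sum(design$group_sizes)
  female <- sprintf("F%02d", seq_len(n_f))
  grp <- rep(names(design$group_sizes), design$group_sizes)
  season <- ifelse(grepl("^early", grp), "early", "late")
  condition <- ifelse(grepl("Poor$", grp), "poor", "control")
  cage <- character(n_f)
  for (g in unique(grp)) { # cages balanced within each cell
    idx <- which(grp == g)
    cage[idx] <- rep_len(design$cages, length(idx))
  }
  meta_f <- data.frame(female = female, season = season,
                       condition = condition, cage = cage,
                       stringsAsFactors = FALSE)
  metadata <- rbind(
    data.frame(sample_id = paste0(female, "_oocyte"), tissue = "oocyte", meta_f),
    data.frame(sample_id = paste0(female, "_egg"), tissue = "egg", meta_f))
  rownames(metadata) <- metadata$sample_id

  # --- gene baselines and module membership --------------------------------
  genes <- sprintf("gene_%05d", seq_len(G))
  base_log2 <- stats::rnorm(G, mean = 4, sd = noise$baseline_log2_sd)
  oo_part <- stats::setNames(integer(G), genes)
  pool <- sample.int(G)
  used <- 0
  for (m in seq_along(modules$module_sizes)) {
    idx <- pool[(used + 1):(used + modules$module_sizes[m])]
    oo_part[idx] <- m
    used <- used + modules$module_sizes[m]
  }
  background <- pool[(used + 1):G]

  # egg partition via the cross-tissue map: the stated fraction of each
  # oocyte module moves together into its egg module, the rest dissolve
  egg_part <- stats::setNames(integer(G), genes)
  ctm <- modules$cross_tissue_map
  for (i in seq_len(nrow(ctm))) {
    mem <- which(oo_part == ctm$oocyte_module[i])
    n_move <- round(ctm$fraction[i] * length(mem))
    if (n_move > 0) {
      moved <- sample(mem, n_move)
      egg_part[moved] <- ctm$egg_module[i]
    }
  }

  loadings <- stats::rnorm(G, modules$loading_mean, modules$loading_sd)
  if (isTRUE(modules$signed_loadings))
    loadings <- loadings * sample(c(-1, 1), G, replace = TRUE)

  # --- planted DE ----------------------------------------------------------
  de_pool <- background
  de_truth <- list()
  de_delta <- list(oocyte = matrix(0, G, n_f), egg = matrix(0, G, n_f))
  for (ei in seq_along(noise$de_effects)) {
    e <- noise$de_effects[[ei]]
    if (e$n_genes > length(de_pool)) stop("not enough background genes for DE effects")
    sel <- de_pool[seq_len(e$n_genes)]
    de_pool <- setdiff(de_pool, sel)
    x <- contrast_coding(meta_f, e$contrast)
    de_delta[[e$tissue]][sel, ] <- de_delta[[e$tissue]][sel, ] +
      e$log2_fc * matrix(x, length(sel), n_f, byrow = TRUE)
    de_truth[[ei]] <- list(tissue = e$tissue, contrast = e$contrast,
                           genes = genes[sel], log2_fc = e$log2_fc)
  }

  # --- silent genes (never module members or planted DE) -------------------
  n_silent <- round(noise$silent_fraction * length(de_pool))
  silent <- de_pool[seq_len(n_silent)]
  base_log2[silent] <- base_log2[silent] + noise$silent_log2_shift

  # --- library sizes (paired female intercept) -----------------------------
  fem_int <- stats::rnorm(n_f, 0, noise$female_sd)
  lib <- list()
  for (tis in c("oocyte", "egg")) {
    lib[[tis]] <- exp(stats::rnorm(n_f, noise$libsize_log_mean[[tis]] + fem_int,
                                   noise$libsize_log_sd))
  }

  # --- per-tissue latent factors and counts --------------------------------
  season01 <- as.numeric(meta_f$season == "late")
  parts <- list(oocyte = oo_part, egg = egg_part)
  factors <- list()
  counts <- matrix(0L, G, 2 * n_f,
                   dimnames = list(genes, metadata$sample_id))
  for (tis in c("oocyte", "egg")) {
    part <- parts[[tis]]
    n_mod <- max(part)
    fmat <- matrix(0, n_f, max(n_mod, 1))
    for (m in seq_len(n_mod)) {
      r <- if (tis == "oocyte" && m %in% modules$trait_coupled_modules)
        modules$trait_r else 0
      fmat[, m] <- module_factor(season01, r)
    }
    factors[[tis]] <- fmat
    log2mu <- matrix(base_log2, G, n_f)
    for (m in seq_len(n_mod)) {
      mem <- which(part == m)
      log2mu[mem, ] <- log2mu[mem, ] +
        outer(loadings[mem], fmat[, m])
    }
    log2mu <- log2mu + de_delta[[tis]]
    rel <- 2^log2mu
    prop <- sweep(rel, 2, colSums(rel), "/")
    mu <- sweep(prop, 2, lib[[tis]], "*")
    cnt <- matrix(stats::rnbinom(G * n_f, mu = mu, size = 1 / noise$nb_dispersion),
                  G, n_f)
    counts[, metadata$tissue == tis] <- cnt
  }
  storage.mode(counts) <- "integer"

  list(counts = counts, metadata = metadata,
       truth = list(oocyte_modules = oo_part, egg_modules = egg_part,
                    loadings = stats::setNames(loadings, genes),
                    silent_genes = genes[silent],
                    factors = factors, de_effects = de_truth,
                    lib_sizes = lib, female_intercept = fem_int))
}

#' Generate candidate precursor-mature miRNA records with ground truth
#'
#' Emits long-format per-sample records for a set of true loci plus
#' controlled complications: loci sharing an identical mature sequence at
#' disjoint genomic locations (which must stay separate), multi-precursor
#' loci whose overlapping precursors share a mature sequence (which must
#' merge), and precursors failing the quality filters (rRNA/tRNA flag, low
#' star reads, or non-significant folding).
#'
#' @param n_loci number of distinct final loci (default 75).
#' @param duplicate_mature_fraction fraction of loci sharing a mature
#'   sequence with a disjoint partner (default 0.04, i.e. 3 of 75).
#' @param n_multi_precursor loci built from two overlapping precursors
#'   (default 5).
#' @param n_failing additional precursors that must be filtered out
#'   (default 15).
#' @param sample_ids sample identifiers (default the 22 oocyte + 22 egg
#'   layout's sample names, supplied by the caller in practice).
#' @param sample_meta optional data.frame with sample_id, tissue and season
#'   columns; when given, season-responsive mature expression is planted in
#'   oocyte samples per `mirna_de`.
#' @param mirna_de planted oocyte season effects: list with n_up, n_down
#'   and log2_fc (defaults 2 up- and 11 down-regulated loci in the late
#'   season at |log2 FC| = 1.5, the scale of seasonal shifts seen in
#'   maternal miRNA data).
#' @param seed integer seed.
#' @return List with `records` (data.frame), `mature_fasta` (named vector),
#'   `known_precursors` (named vector) and `truth` (locus merge map,
#'   expected locus count, pass/fail per precursor).
#' @export
generate_mirna_records <- function(n_loci = 75, duplicate_mature_fraction = 0.04,
                                   n_multi_precursor = 5, n_failing = 15,
                                   sample_ids = sprintf("S%02d", 1:8),
                                   sample_meta = NULL,
                                   mirna_de = list(n_up = 2, n_down = 11,
                                                   log2_fc = 1.5),
                                   seed = 1) {
  stopifnot(n_loci >= 1, duplicate_mature_fraction >= 0,
            duplicate_mature_fraction <= 1)
  set.seed(substream_seed(seed, "mirna"))
  n_dup <- round(duplicate_mature_fraction * n_loci)
  if (n_dup + n_multi_precursor > n_loci)
    stop("more complications than loci")
  rand_seq <- function(n, len) vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = ""),
    character(1))

  # mature sequences: duplicated pairs share one sequence
  n_unique <- n_loci - n_dup
  mature <- rand_seq(n_unique, 22)
  mature_of_locus <- c(mature, mature[seq_len(n_dup)])

  chrom_of <- sprintf("scaffold_%d", 1 + (seq_len(n_loci) %% 6))
  strand_of <- rep(c("+", "-"), length.out = n_loci)
  start_of <- 1000 * seq_len(n_loci) + 1
  # duplicated-mature partners sit on the same chromosome/strand but far away
  if (n_dup > 0) {
    dup_idx <- n_unique + seq_len(n_dup)
    chrom_of[dup_idx] <- chrom_of[seq_len(n_dup)]
    strand_of[dup_idx] <- strand_of[seq_len(n_dup)]
    start_of[dup_idx] <- start_of[seq_len(n_dup)] + 500000
  }

  prec <- data.frame(precursor_id = character(0), chrom = character(0),
                     start = integer(0), end = integer(0), strand = character(0),
                     mature_seq = character(0), locus = integer(0),
                     should_pass = logical(0), novel = logical(0),
                     stringsAsFactors = FALSE)
  pid <- 0
  add_prec <- function(df, chrom, start, end, strand, mat, locus, pass, novel) {
    pid <<- pid + 1
    rbind(df, data.frame(precursor_id = sprintf("prec_%03d", pid),
                         chrom = chrom, start = start, end = end,
                         strand = strand, mature_seq = mat, locus = locus,
                         should_pass = pass, novel = novel,
                         stringsAsFactors = FALSE))
  }
  multi <- sample(seq_len(n_loci), n_multi_precursor)
  for (l in seq_len(n_loci)) {
    novel <- l %% 3 == 0 # a third of loci are novel discoveries
    prec <- add_prec(prec, chrom_of[l], start_of[l], start_of[l] + 79,
                     strand_of[l], mature_of_locus[l], l, TRUE, novel)
    if (l %in% multi) # overlapping partner precursor, same mature: must merge
      prec <- add_prec(prec, chrom_of[l], start_of[l] + 40, start_of[l] + 119,
                       strand_of[l], mature_of_locus[l], l, TRUE, novel)
  }
  # failing precursors at fresh locations
  fail_mode <- rep_len(c("rrna", "star", "randfold"), n_failing)
  for (i in seq_len(n_failing)) {
    prec <- add_prec(prec, "scaffold_9", 1000 * i + 1, 1000 * i + 80,
                     "+", rand_seq(1, 22), NA, FALSE, TRUE)
  }

  n_prec <- nrow(prec)
  # planted season response (oocyte samples only, when metadata is given)
  de_up <- de_down <- integer(0)
  if (!is.null(sample_meta) && (mirna_de$n_up + mirna_de$n_down) > 0) {
    if (mirna_de$n_up + mirna_de$n_down > n_loci)
      stop("more planted miRNA effects than loci")
    de_loci <- sample(seq_len(n_loci), mirna_de$n_up + mirna_de$n_down)
    de_up <- de_loci[seq_len(mirna_de$n_up)]
    de_down <- setdiff(de_loci, de_up)
  }
  sm <- if (is.null(sample_meta)) NULL else
    sample_meta[match(sample_ids, sample_meta$sample_id), ]
  records <- do.call(rbind, lapply(seq_along(sample_ids), function(si) {
    s <- sample_ids[si]
    df <- prec[, c("precursor_id", "chrom", "start", "end", "strand",
                   "mature_seq")]
    df$sample_id <- s
    df$precursor_seq <- NA_character_
    mu <- rep(200, n_prec)
    if (!is.null(sm) && sm$tissue[si] == "oocyte" && sm$season[si] == "late") {
      mu[prec$locus %in% de_up] <- 200 * 2^mirna_de$log2_fc
      mu[prec$locus %in% de_down] <- 200 * 2^(-mirna_de$log2_fc)
    }
    df$mature_count <- 5L + stats::rnbinom(n_prec, mu = mu, size = 5)
    df$star_count <- 5L + stats::rnbinom(n_prec, mu = 20, size = 2)
    df$randfold_p <- stats::runif(n_prec, 0, 0.049)
    df$rrna_trna <- FALSE
    df$novel <- prec$novel
    df
  }))
  # deterministic precursor sequences (shared across samples)
  prec_seq <- rand_seq(n_prec, 70)
  records$precursor_seq <- prec_seq[match(records$precursor_id, prec$precursor_id)]
  # break the failing precursors per their failure mode, in every sample
  fail_ids <- prec$precursor_id[!prec$should_pass]
  for (i in seq_along(fail_ids)) {
    rows <- records$precursor_id == fail_ids[i]
    mode <- fail_mode[i]
    if (mode == "rrna") records$rrna_trna[rows] <- TRUE
    if (mode == "star") records$star_count[rows] <- sample(0:4, sum(rows), TRUE)
    if (mode == "randfold") records$randfold_p[rows] <- stats::runif(sum(rows), 0.05, 1)
  }
  rownames(records) <- NULL

  mature_fasta <- stats::setNames(mature_of_locus,
                                  sprintf("mat_locus_%03d", seq_len(n_loci)))
  known <- prec_seq[match(prec$precursor_id[!prec$novel & prec$should_pass],
                          prec$precursor_id)]
  known <- stats::setNames(known, paste0("known_", seq_along(known)))

  list(records = records,
       mature_fasta = mature_fasta,
       known_precursors = known,
       truth = list(
         n_loci = n_loci,
         merge_map = stats::setNames(prec$locus, prec$precursor_id),
         passing_precursors = prec$precursor_id[prec$should_pass],
         failing_precursors = prec$precursor_id[!prec$should_pass],
         n_duplicate_mature = n_dup,
         n_multi_precursor = n_multi_precursor,
         de_up_loci = de_up, de_down_loci = de_down))
}

#' Generate directional similarity-hit tables with planted orthologs
#'
#' True ortholog pairs are mutual best hits with e-values far below the
#' cutoff; decoy hits (including cross-hits from orthologous queries to
#' wrong subjects) carry strictly worse e-values.
#'
#' @param n_a,n_b gene counts in the two sets.
#' @param ortholog_fraction fraction of `min(n_a, n_b)` genes with a true
#'   ortholog (default 0.6).
#' @param n_decoys_per_query decoy hits added per query (default 2).
#' @param seed integer seed.
#' @return List with `hits_ab`, `hits_ba` (query, subject, evalue,
#'   bitscore) and `truth` (data.frame gene_a, gene_b).
#' @export
generate_hit_tables <- function(n_a, n_b, ortholog_fraction = 0.6,
                                n_decoys_per_query = 2, seed = 1) {
  stopifnot(ortholog_fraction >= 0, ortholog_fraction <= 1)
  set.seed(substream_seed(seed, "hits"))
  genes_a <- sprintf("geneA_%04d", seq_len(n_a))
  genes_b <- sprintf("geneB_%04d", seq_len(n_b))
  n_orth <- round(ortholog_fraction * min(n_a, n_b))
  orth_a <- sample(genes_a, n_orth)
  orth_b <- sample(genes_b, n_orth)
  truth <- data.frame(gene_a = orth_a, gene_b = orth_b,
                      stringsAsFactors = FALSE)
  mk_hits <- function(queries, subjects, true_map) {
    rows <- list()
    for (q in queries) {
      if (!is.na(true_map[q])) {
        rows[[length(rows) + 1]] <- data.frame(
          query = q, subject = unname(true_map[q]),
          evalue = 10^stats::runif(1, -60, -20),
          bitscore = stats::runif(1, 200, 500), stringsAsFactors = FALSE)
      }
      nd <- n_decoys_per_query
      if (nd > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          query = q, subject = sample(subjects, nd),
          evalue = 10^stats::runif(nd, -3, 1),
          bitscore = stats::runif(nd, 30, 60), stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }
  map_ab <- stats::setNames(rep(NA_character_, n_a), genes_a)
  map_ab[orth_a] <- orth_b
  map_ba <- stats::setNames(rep(NA_character_, n_b), genes_b)
  map_ba[orth_b] <- orth_a
  list(hits_ab = mk_hits(genes_a, genes_b, map_ab),
       hits_ba = mk_hits(genes_b, genes_a, map_ba),
       truth = truth)
}

#' Generate two miRNA-target predictor tables with planted consensus pairs
#'
#' Plants a set of true (miRNA, gene) target pairs reported by both
#' predictors with qualifying thresholds, plus pairs unique to each
#' predictor and pairs present in both but failing the hybridization
#' p-value cutoff.
#'
#' @param mirna_ids,gene_ids identifier pools.
#' @param n_true consensus pairs to plant.
#' @param n_only_a,n_only_b,n_weak_p non-consensus complications.
#' @param seed integer seed.
#' @return List with `preds_a`, `preds_b` and `truth` (the consensus
#'   pairs).
#' @export
generate_target_tables <- function(mirna_ids, gene_ids, n_true = 40,
                                   n_only_a = 15, n_only_b = 15,
                                   n_weak_p = 10, seed = 1) {
  set.seed(substream_seed(seed, "targets"))
  n_all <- n_true + n_only_a + n_only_b + n_weak_p
  pairs <- unique(data.frame(
    mirna_id = sample(mirna_ids, n_all * 2, replace = TRUE),
    gene_id = sample(gene_ids, n_all * 2, replace = TRUE),
    stringsAsFactors = FALSE))
  if (nrow(pairs) < n_all) stop("identifier pools too small for requested pairs")
  pairs <- pairs[seq_len(n_all), ]
  role <- rep(c("true", "only_a", "only_b", "weak_p"),
              c(n_true, n_only_a, n_only_b, n_weak_p))
  a_rows <- role %in% c("true", "only_a", "weak_p")
  b_rows <- role %in% c("true", "only_b", "weak_p")
  preds_a <- data.frame(pairs[a_rows, ],
                        score = stats::runif(sum(a_rows), 145, 190),
                        energy = stats::runif(sum(a_rows), -35, -21),
                        stringsAsFactors = FALSE)
  p_b <- stats::runif(sum(b_rows), 0, 0.009)
  weak <- role[b_rows] == "weak_p"
  p_b[weak] <- stats::runif(sum(weak), 0.02, 0.5)
  preds_b <- data.frame(pairs[b_rows, ],
                        energy = stats::runif(sum(b_rows), -35, -21),
                        p = p_b, stringsAsFactors = FALSE)
  rownames(preds_a) <- rownames(preds_b) <- NULL
  list(preds_a = preds_a, preds_b = preds_b,
       truth = pairs[role == "true", ])
}
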