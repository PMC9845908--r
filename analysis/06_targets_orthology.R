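#!/usr/bin/env Rscript
# Step 6 — consensus miRNA targets and reciprocal-best-hit orthologs.
#
# Target pairs must be predicted by both programs (the alignment-based
# table at score >= 140 and energy <= -20; the hybridization-based table at
# energy <= -20 with p < 0.01). The consensus set is intersected with the
# season-responsive genes from step 2 under a hypergeometric test with
# representation factor. Orthologs are called as reciprocal best hits at
# e-value <= 1e-5 and checked against the planted truth.

suppressPackageStartupMessages(library(matprov))

SEED <- 1
counts <- read_counts_tsv("results/data/counts.tsv")
mir_counts <- read_counts_tsv("results/mirna/mirna_counts.tsv")
de <- utils::read.table("results/de/de_oocyte.tsv", sep = "\t", header = TRUE)
out <- "results/targets"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tt <- generate_target_tables(rownames(mir_counts), rownames(counts),
                             seed = substream_seed(SEED, "targets"))
cons <- consensus_targets(tt$preds_a, tt$preds_b)
utils::write.table(cons, file.path(out, "consensus_targets.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("consensus targets: %d pairs (%d planted)\n",
            nrow(cons), nrow(tt$truth)))

universe <- unique(de$feature)
de_season <- de$feature[de$contrast == "season" & de$adj_p_value < 0.1]
tg <- intersect(unique(cons$gene_id), universe)
ovl <- set_overlap_test(tg, intersect(de_season, universe), universe)
write_json_summary(
  list(n_targets_in_universe = length(tg),
       n_de_season = length(intersect(de_season, universe)),
       overlap = ovl),
  file.path(out, "target_de_overlap.json"))
cat(sprintf("target/DE-set overlap: k = %d, RF = %.2f, p = %.3g, coverage = %.1f%%\n",
            ovl$k, ovl$representation_factor, ovl$p_value,
            100 * ovl$coverage_a_in_b))

hits_ab <- read_hits_tsv("results/data/hits_ab.tsv")
hits_ba <- read_hits_tsv("results/data/hits_ba.tsv")
truth <- utils::read.table("results/data/truth_orthologs.tsv", sep = "\t",
                           header = TRUE)
pairs <- rbh_orthologs(hits_ab, hits_ba, evalue_max = 1e-5)
utils::write.table(pairs, file.path(out, "rbh_pairs.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
hit_rate <- mean(paste(truth$gene_a, truth$gene_b) %in%
                   paste(pairs$gene_a, pairs$gene_b))
cat(sprintf("RBH orthologs: %d pairs called; %.0f%% of %d planted pairs recovered\n",
            nrow(pairs), 100 * hit_rate, nrow(truth)))
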