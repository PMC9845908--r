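#!/usr/bin/env Rscript
# Step 4 — cross-tissue module correspondence.
#
# Egg module labels are matched and relabeled against the oocyte reference,
# the full oocyte-by-egg overlap table is computed over the shared universe
# of assigned genes (hypergeometric p and representation factor per cell),
# and the modules significantly associated with season or condition are
# additionally tested with the size-aware bootstrap null (10,000 draws).

suppressPackageStartupMessages(library(matprov))

SEED <- 1
parts <- list(oocyte = read_partition_tsv("results/network/modules_oocyte.tsv"),
              egg = read_partition_tsv("results/network/modules_egg.tsv"))
mt <- utils::read.table("results/network/module_trait_oocyte.tsv",
                        sep = "\t", header = TRUE)
out <- "results/overlap"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

egg_relabeled <- match_labels(parts$egg, parts$oocyte)
interest <- unique(as.integer(sub("^ME", "", mt$module[mt$significant &
                     mt$trait %in% c("season", "condition")])))
cat("Oocyte modules of interest (season/condition-linked):",
    if (length(interest)) paste(interest, collapse = ", ") else "none", "\n")

ov <- overlap_table(parts$oocyte, egg_relabeled,
                    modules_of_interest = interest,
                    n_iter = 10000, seed = substream_seed(SEED, "overlap"))
utils::write.table(ov$table, file.path(out, "overlap_table.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_json_summary(
  list(universe_size = ov$universe_size,
       modules_of_interest = interest,
       flow = ov$flow,
       bootstrap = lapply(ov$bootstrap, function(b)
         list(observed_proportion = b$observed, empirical_p = b$empirical_p,
              p_label = b$p_label, n_iter = b$n_iter))),
  file.path(out, "overlap_summary.json"))

top <- ov$table[ov$table$k > 0, ]
top <- top[order(top$p_value), ][1:min(5, sum(ov$table$k > 0)), ]
cat("Strongest module correspondences (source -> target):\n")
for (i in seq_len(nrow(top)))
  cat(sprintf("  mod%d -> mod%d: %.1f%% of genes, p = %.3g, RF = %.2f\n",
              top$source_module[i], top$target_module[i],
              100 * top$fraction[i], top$p_value[i],
              top$representation_factor[i]))
for (nm in names(ov$bootstrap))
  cat(sprintf("  bootstrap null, module %s: observed %.3f, p %s\n",
              nm, ov$bootstrap[[nm]]$observed, ov$bootstrap[[nm]]$p_label))
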