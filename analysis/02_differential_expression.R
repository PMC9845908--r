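#!/usr/bin/env Rscript
# Step 2 — per-tissue moderated differential expression.
#
# Oocyte and egg samples are analyzed separately (never pooled): filter by
# expression, TMM-normalize, estimate precision weights from the
# mean-variance trend, fit the non-intercept group model, and test the
# condition, season and interaction contrasts with empirical-Bayes
# moderation. DE counts are tallied at BH-adjusted p < 0.05 and < 0.1.

suppressPackageStartupMessages(library(matprov))

counts <- read_counts_tsv("results/data/counts.tsv")
md <- read_metadata_tsv("results/data/metadata.tsv")
out <- "results/de"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (tis in c("oocyte", "egg")) {
  sel <- md$tissue == tis
  cnt <- counts[, md$sample_id[sel]]
  mdt <- md[sel, ]
  grp <- paste0(mdt$season, ifelse(mdt$condition == "poor", "Poor", "Control"))
  kept <- filter_by_expression(cnt, grp)
  cat(sprintf("%s: %d of %d genes (%.1f%%) pass the expression filter\n",
              tis, length(kept), nrow(cnt), 100 * length(kept) / nrow(cnt)))
  cnt <- cnt[kept, ]
  nf <- tmm_factors(cnt)
  lc <- log_cpm(cnt, nf)
  design <- group_design(mdt)
  w <- precision_weights(lc, design)
  fit <- fit_moderated(lc, design, weights = w)
  utils::write.table(fit$table, file.path(out, sprintf("de_%s.tsv", tis)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  s <- de_summary(fit)
  utils::write.table(s, file.path(out, sprintf("de_summary_%s.tsv", tis)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s DE counts (up/down) at BH < 0.05 (and < 0.1):\n", tis))
  for (cn in unique(s$contrast)) {
    r05 <- s[s$contrast == cn & s$alpha == 0.05, ]
    r10 <- s[s$contrast == cn & s$alpha == 0.1, ]
    cat(sprintf("  %-12s %d/%d (%d/%d)\n", cn, r05$up, r05$down, r10$up, r10$down))
  }
}
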