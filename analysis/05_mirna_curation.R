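#!/usr/bin/env Rscript
# Step 5 — miRNA locus curation and miRNA differential expression.
#
# Candidate precursor-mature records are filtered (no rRNA/tRNA, >= 5 reads
# on mature and star strands, folding p < 0.05), surviving novel precursor
# sequences are compiled into the composite reference, precursors with
# identical mature sequences at overlapping locations are merged into loci
# (disjoint locations stay separate), homologs are called with the
# seed-aware >90%-identity rule against a mutated decoy database, and the
# per-locus count table feeds the same DE machinery as the mRNA branch.

suppressPackageStartupMessages(library(matprov))

SEED <- 1
records <- utils::read.table("results/data/mirna_records.tsv", sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
known <- read_fasta_rna("results/data/known_precursors.fasta")
mature <- read_fasta_rna("results/data/mirna_mature.fasta")
md <- read_metadata_tsv("results/data/metadata.tsv")
out <- "results/mirna"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

passing <- filter_precursor_pairs(records)
cat(sprintf("%d of %d records pass curation (%d distinct precursors)\n",
            nrow(passing), nrow(records), length(unique(passing$precursor_id))))
composite <- compile_novel_precursors(passing$precursor_seq[passing$novel], known)
cat(sprintf("composite precursor reference: %d known + %d novel = %d\n",
            length(known), length(composite) - length(known), length(composite)))

loci <- merge_loci(passing)
cat(sprintf("%d distinct miRNA loci after merging (%d member precursors)\n",
            length(unique(loci$locus_id)), nrow(loci)))
write_gff3_precursors(loci, file.path(out, "mirna_loci.gff3"))

# homology: mutate half the matures lightly outside the seed (homologs),
# leave the rest as random decoys
set.seed(substream_seed(SEED, "homolog_db"))
db <- vapply(seq_along(mature), function(i) {
  s <- mature[[i]]
  if (i %% 2 == 0) {
    pos <- sample(setdiff(8:nchar(s), integer(0)), 2)
    for (p in pos) substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "U"),
                                                    substr(s, p, p)), 1)
    s
  } else paste(sample(c("A", "C", "G", "U"), nchar(s), TRUE), collapse = "")
}, character(1))
names(db) <- sprintf("db-mir-%03d", seq_along(db))
hom <- match_homologs(mature, db)
utils::write.table(hom, file.path(out, "homologs.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("%d of %d mature sequences have accepted homologs\n",
            sum(hom$accepted), nrow(hom)))

tab <- mirna_count_table(loci, passing)
write_counts_tsv(tab, file.path(out, "mirna_counts.tsv"))

for (tis in c("oocyte", "egg")) {
  mdt <- md[md$tissue == tis, ]
  cnt <- tab[, mdt$sample_id]
  grp <- paste0(mdt$season, ifelse(mdt$condition == "poor", "Poor", "Control"))
  kept <- filter_by_expression(cnt, grp)
  cat(sprintf("%s: %d of %d miRNA loci pass the expression filter\n",
              tis, length(kept), nrow(cnt)))
  lc <- log_cpm(cnt[kept, ], tmm_factors(cnt[kept, ]))
  design <- group_design(mdt)
  fit <- fit_moderated(lc, design, weights = precision_weights(lc, design))
  utils::write.table(fit$table, file.path(out, sprintf("de_mirna_%s.tsv", tis)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  s <- de_summary(fit)
  r05 <- s[s$contrast == "season" & s$alpha == 0.05, ]
  cat(sprintf("%s: season-responsive miRNAs at BH < 0.05: %d up, %d down\n",
              tis, r05$up, r05$down))
}
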