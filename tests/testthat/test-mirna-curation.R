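# miRNA curation: read-floor/randfold filtering, novel precursor
# compilation, locus merging, homolog matching and the locus count table.

record_row <- function(id, start, end, mature, sample = "S1", chrom = "c1",
                       strand = "+", mcount = 50, scount = 20, p = 0.01,
                       rrna = FALSE, novel = FALSE) {
  data.frame(sample_id = sample, precursor_id = id, chrom = chrom,
             start = start, end = end, strand = strand,
             precursor_seq = strrep("ACGU", 20), mature_seq = mature,
             mature_count = mcount, star_count = scount, randfold_p = p,
             rrna_trna = rrna, novel = novel, stringsAsFactors = FALSE)
}

test_that("precursor filtering applies all three rules with strict boundaries", {
  recs <- rbind(
    record_row("p01", 1, 80, "A"),                        # pass
    record_row("p02", 1, 80, "A", mcount = 4, scount = 100), # below mature floor
    record_row("p03", 1, 80, "A", scount = 4),            # below star floor
    record_row("p04", 1, 80, "A", p = 0.05),              # boundary: rejected
    record_row("p05", 1, 80, "A", p = 0.049999),          # just under: pass
    record_row("p06", 1, 80, "A", rrna = TRUE),           # rRNA/tRNA
    record_row("p07", 1, 80, "A", mcount = 5, scount = 5),# floors inclusive
    record_row("p08", 1, 80, "A", mcount = 0, scount = 0),
    record_row("p09", 1, 80, "A", p = 0),
    record_row("p10", 1, 80, "A", rrna = TRUE, mcount = 4),
    record_row("p11", 1, 80, "A", scount = 5, p = 0.02),
    record_row("p12", 1, 80, "A", mcount = 1000, p = 0.9))
  got <- filter_precursor_pairs(recs)
  # independent per-record rule evaluation
  want <- recs[!recs$rrna_trna & recs$mature_count >= 5 &
                 recs$star_count >= 5 & recs$randfold_p < 0.05, ]
  expect_identical(got, want)
  expect_setequal(got$precursor_id, c("p01", "p05", "p07", "p09", "p11"))
})

test_that("novel precursor compilation deduplicates against the known list", {
  known <- c(k1 = "AAAA", k2 = "CCCC")
  expect_identical(compile_novel_precursors(character(0), known), known)
  # a novel sequence seen in three samples appears once
  expect_equal(sum(compile_novel_precursors(rep("GGGG", 3), known) == "GGGG"), 1)
  # 5 novel, 2 duplicating known entries: composite = known + 3
  novel <- c("AAAA", "CCCC", "GGGG", "UUUU", "AACC")
  comp <- compile_novel_precursors(novel, known)
  expect_length(comp, 5)
  expect_identical(unname(comp[1:2]), unname(known))
})

test_that("locus merging takes connected components per mature sequence", {
  # overlapping intervals, same mature: one locus
  r1 <- rbind(record_row("a", 100, 179, "AAGG"),
              record_row("b", 150, 229, "AAGG"))
  expect_equal(length(unique(merge_loci(r1)$locus_id)), 1)
  # disjoint intervals, same mature: two loci
  r2 <- rbind(record_row("a", 100, 179, "AAGG"),
              record_row("b", 500, 579, "AAGG"))
  expect_equal(length(unique(merge_loci(r2)$locus_id)), 2)
  # different strands never merge
  r3 <- rbind(record_row("a", 100, 179, "AAGG"),
              record_row("b", 150, 229, "AAGG", strand = "-"))
  expect_equal(length(unique(merge_loci(r3)$locus_id)), 2)
  # chain A-B-C with A and C disjoint merges transitively
  r4 <- rbind(record_row("a", 100, 179, "AAGG"),
              record_row("b", 150, 249, "AAGG"),
              record_row("c", 230, 309, "AAGG"))
  m4 <- merge_loci(r4)
  expect_equal(length(unique(m4$locus_id)), 1)
  expect_equal(nrow(m4), 3)
  # order-invariance and idempotence
  m4r <- merge_loci(r4[c(3, 1, 2), ])
  expect_equal(split(m4$precursor_id, m4$locus_id),
               split(m4r$precursor_id, m4r$locus_id))
})

test_that("locus merging matches brute-force components on random intervals", {
  set.seed(13)
  for (rep in 1:5) {
    n <- 15
    starts <- sample(1:500, n)
    recs <- do.call(rbind, lapply(seq_len(n), function(i)
      record_row(sprintf("p%02d", i), starts[i], starts[i] + 60, "ACGU")))
    m <- merge_loci(recs)
    comp_oracle <- oracle_interval_components(recs$start, recs$end)
    got <- as.integer(factor(m$locus_id[match(recs$precursor_id, m$precursor_id)]))
    expect_equal(ari(got, comp_oracle), 1)
  }
})

test_that("homolog matching enforces identity, mismatch count and seed rules", {
  q <- paste(rep("A", 22), collapse = "")
  # identical 22-mers: accepted at 100%
  hit <- match_homologs(c(q1 = q), c(db1 = q))
  expect_true(hit$accepted)
  expect_equal(hit$identity, 1)
  # mismatches at positions 2 and 5 (seed region): rejected
  s2 <- q; substr(s2, 2, 2) <- "C"; substr(s2, 5, 5) <- "G"
  hit2 <- match_homologs(c(q1 = q), c(db1 = s2))
  expect_false(hit2$accepted)
  expect_true(hit2$seed_mismatch)
  expect_equal(hit2$n_mismatches, 2)
  # mismatches at 10 and 20: identity 20/22 > 90%, no seed hits: accepted
  s3 <- q; substr(s3, 10, 10) <- "C"; substr(s3, 20, 20) <- "G"
  hit3 <- match_homologs(c(q1 = q), c(db1 = s3))
  expect_true(hit3$accepted)
  expect_equal(hit3$identity, 20 / 22, tolerance = 1e-12)
  expect_identical(hit3$mismatch_positions, "10,20")
  # three mismatches outside the seed: rejected on the count rule
  s4 <- s3; substr(s4, 15, 15) <- "C"
  expect_false(match_homologs(c(q1 = q), c(db1 = s4))$accepted)
  # alphabet violations rejected
  expect_error(match_homologs(c(q1 = "ACGT"), c(d = q)), "RNA alphabet")
})

test_that("homolog identity is symmetric and sliding picks the best offset", {
  set.seed(21)
  a <- paste(sample(c("A", "C", "G", "U"), 22, TRUE), collapse = "")
  b <- paste(sample(c("A", "C", "G", "U"), 22, TRUE), collapse = "")
  ab <- match_homologs(c(q = a), c(s = b))
  ba <- match_homologs(c(q = b), c(s = a))
  expect_equal(ab$identity, ba$identity, tolerance = 1e-12)
  # query embedded in a longer subject matches perfectly at the right offset
  long <- paste0("GGGG", a, "CCCC")
  emb <- match_homologs(c(q = a), c(s = long))
  expect_equal(emb$identity, 1)
  expect_true(emb$accepted)
})

test_that("locus count table sums member precursors and matches group sums", {
  recs <- rbind(record_row("a", 100, 179, "AAGG", sample = "S1", mcount = 3),
                record_row("b", 150, 229, "AAGG", sample = "S1", mcount = 4),
                record_row("a", 100, 179, "AAGG", sample = "S2", mcount = 7),
                record_row("b", 150, 229, "AAGG", sample = "S2", mcount = 0),
                record_row("c", 900, 979, "CCGG", sample = "S1", mcount = 11))
  loci <- merge_loci(recs)
  tab <- mirna_count_table(loci, recs)
  merged_id <- loci$locus_id[loci$precursor_id == "a"]
  expect_equal(unname(tab[merged_id, "S1"]), 7)
  expect_equal(unname(tab[merged_id, "S2"]), 7)
  single_id <- loci$locus_id[loci$precursor_id == "c"]
  expect_equal(unname(tab[single_id, "S2"]), 0)
  # conservation: totals survive merging
  expect_equal(sum(tab), sum(recs$mature_count))
})

test_that("curation pipeline reproduces the generator's declared truth", {
  g <- generate_mirna_records(n_loci = 40, n_multi_precursor = 6,
                              n_failing = 12, sample_ids = sprintf("S%02d", 1:6),
                              seed = 17)
  passing <- filter_precursor_pairs(g$records)
  expect_setequal(unique(passing$precursor_id), g$truth$passing_precursors)
  expect_false(any(g$truth$failing_precursors %in% passing$precursor_id))
  loci <- merge_loci(passing)
  expect_equal(length(unique(loci$locus_id)), g$truth$n_loci)
  # the merge map matches the declared truth exactly (as a partition)
  truth_map <- g$truth$merge_map[loci$precursor_id]
  expect_equal(ari(as.integer(factor(loci$locus_id)),
                   as.integer(factor(truth_map))), 1)
  # counts conserved through merging
  tab <- mirna_count_table(loci, passing)
  expect_equal(sum(tab), sum(passing$mature_count))
})
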