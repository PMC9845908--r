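# Post-discovery miRNA locus curation: quality filtering, two-pass novel
# precursor compilation, identical-mature merge rules, seed-aware homolog
# matching, and the per-locus count table.
#
# Records are long-format data.frames, one row per (sample, precursor),
# with columns: sample_id, precursor_id, chrom, start, end, strand (GFF3
# style 1-based closed intervals), precursor_seq, mature_seq, mature_count,
# star_count, randfold_p, rrna_trna, novel.

MIRNA_RECORD_COLS <- c("sample_id", "precursor_id", "chrom", "start", "end",
                       "strand", "mature_seq", "mature_count", "star_count",
                       "randfold_p", "rrna_trna", "novel")

check_mirna_records <- function(records) {
  missing <- setdiff(MIRNA_RECORD_COLS, names(records))
  if (length(missing) > 0)
    stop("records missing columns: ", paste(missing, collapse = ", "))
  if (any(records$start > records$end)) stop("invalid precursor intervals")
  if (any(records$mature_count < 0) || any(records$star_count < 0))
    stop("negative read counts")
  if (any(records$randfold_p < 0 | records$randfold_p > 1))
    stop("randfold p outside [0, 1]")
  invisible(records)
}

#' Filter precursor-mature read pairs
#'
#' A record passes when it is not flagged as rRNA/tRNA, has at least
#' `min_reads` reads on both the mature and star strands of the hairpin,
#' and a hairpin-folding randomization p strictly below `randfold_alpha`.
#' Order-preserving.
#'
#' @param records miRNA record data.frame (see module header).
#' @param min_reads read floor for mature and star strands (default 5).
#' @param randfold_alpha folding-significance cutoff, strict (default 0.05).
#' @return The passing subset of `records`.
#' @export
filter_precursor_pairs <- function(records, min_reads = 5, randfold_alpha = 0.05) {
  check_mirna_records(records)
  keep <- !records$rrna_trna &
    records$mature_count >= min_reads &
    records$star_count >= min_reads &
    records$randfold_p < randfold_alpha
  records[keep, , drop = FALSE]
}

#' Compile the composite precursor reference
#'
#' Second-pass discovery input: the union of known precursor sequences and
#' the deduplicated novel precursor sequences that survived filtering in
#' any sample. Novel sequences identical to a known precursor collapse to
#' the known entry. Ordering is deterministic: known sequences first (input
#' order), then novel sequences lexicographically.
#'
#' @param novel_seqs character vector of passing novel precursor sequences
#'   (repeats across samples allowed).
#' @param known_seqs character vector of known precursor sequences.
#' @return Character vector, the composite precursor reference.
#' @export
compile_novel_precursors <- function(novel_seqs, known_seqs) {
  if (any(!nzchar(c(novel_seqs, known_seqs)))) stop("empty sequences not allowed")
  novel <- sort(setdiff(unique(novel_seqs), known_seqs))
  c(known_seqs, novel)
}

#' Merge precursors into miRNA loci
#'
#' Precursors with identical mature sequences whose genomic intervals
#' overlap (same chromosome and strand, at least 1 bp shared) are merged
#' into one locus, taking connected components of the overlap graph so
#' that chains merge transitively. Identical mature sequences at
#' non-overlapping locations remain separate loci. The result is
#' independent of record order.
#'
#' @param records miRNA record data.frame; rows from multiple samples of
#'   the same precursor are allowed and counted once per precursor.
#' @return data.frame with one row per (locus, member precursor):
#'   locus_id, mature_seq, precursor_id, chrom, start, end, strand.
#' @export
merge_loci <- function(records) {
  check_mirna_records(records)
  prec <- unique(records[, c("precursor_id", "chrom", "start", "end",
                             "strand", "mature_seq")])
  if (anyDuplicated(prec$precursor_id))
    stop("precursor with inconsistent interval or mature sequence")
  prec <- prec[order(prec$mature_seq, prec$chrom, prec$strand,
                     prec$start, prec$end, prec$precursor_id), ]
  prec$locus_id <- NA_character_
  counter <- 0L
  for (key in unique(paste(prec$mature_seq, prec$chrom, prec$strand))) {
    idx <- which(paste(prec$mature_seq, prec$chrom, prec$strand) == key)
    gr <- IRanges::IRanges(start = prec$start[idx], end = prec$end[idx])
    # connected components of the 1-D overlap graph = chains after sorting,
    # which IRanges::reduce computes directly
    red <- IRanges::reduce(gr, min.gapwidth = 0L)
    comp <- S4Vectors::subjectHits(IRanges::findOverlaps(gr, red))
    for (cc in sort(unique(comp))) {
      counter <- counter + 1L
      prec$locus_id[idx[comp == cc]] <- sprintf("locus_%04d", counter)
    }
  }
  rownames(prec) <- NULL
  prec[, c("locus_id", "mature_seq", "precursor_id", "chrom", "start",
           "end", "strand")]
}

#' Seed-aware miRNA homolog matching
#'
#' Gapless end-to-end comparison of a query mature sequence against each
#' database sequence; unequal lengths are handled by sliding the shorter
#' sequence along the longer and keeping the best-identity offset.
#' Identity is matches over query length; query positions without a match
#' (substitutions and overhang) count as mismatches, indexed 1-based from
#' the query 5' end. A hit is accepted when identity exceeds
#' `min_identity`, at most `max_mismatches` positions mismatch, and no
#' mismatch falls in the seed region (positions `seed_start`..`seed_end`).
#' The best-scoring database subject is reported per query (ties broken by
#' subject name).
#'
#' @param queries named character vector of mature sequences (RNA
#'   alphabet ACGU).
#' @param database named character vector of database mature sequences.
#' @param min_identity identity floor, strict (default 0.90).
#' @param max_mismatches mismatch ceiling (default 2).
#' @param seed_start,seed_end seed region bounds, 1-based inclusive
#'   (defaults 2 and 7).
#' @return data.frame with one row per query: query, subject, identity,
#'   n_mismatches, mismatch_positions (comma-separated), seed_mismatch,
#'   accepted.
#' @export
match_homologs <- function(queries, database, min_identity = 0.90,
                           max_mismatches = 2, seed_start = 2, seed_end = 7) {
  check_rna <- function(x) {
    if (any(grepl("[^ACGU]", x))) stop("sequences must use the RNA alphabet ACGU")
  }
  check_rna(queries); check_rna(database)
  if (any(nchar(queries) < 8)) stop("queries must be at least 8 nt")
  if (is.null(names(queries))) names(queries) <- paste0("query_", seq_along(queries))
  if (is.null(names(database))) names(database) <- paste0("db_", seq_along(database))
  score_pair <- function(q, s) {
    lq <- nchar(q); ls <- nchar(s)
    qv <- strsplit(q, "")[[1]]
    sv <- strsplit(s, "")[[1]]
    best <- NULL
    if (lq <= ls) {
      for (off in 0:(ls - lq)) {
        mm <- which(qv != sv[(off + 1):(off + lq)])
        if (is.null(best) || length(mm) < length(best)) best <- mm
      }
    } else {
      for (off in 0:(lq - ls)) {
        inside <- (off + 1):(off + ls)
        mm <- sort(c(setdiff(seq_len(lq), inside),
                     inside[qv[inside] != sv]))
        if (is.null(best) || length(mm) < length(best)) best <- mm
      }
    }
    list(mismatches = best, identity = (lq - length(best)) / lq)
  }
  out <- lapply(names(queries), function(qn) {
    hits <- lapply(names(database), function(sn)
      score_pair(queries[[qn]], database[[sn]]))
    ident <- vapply(hits, `[[`, numeric(1), "identity")
    best_i <- order(-ident, names(database))[1]
    h <- hits[[best_i]]
    seed_hit <- any(h$mismatches >= seed_start & h$mismatches <= seed_end)
    data.frame(query = qn, subject = names(database)[best_i],
               identity = h$identity, n_mismatches = length(h$mismatches),
               mismatch_positions = paste(h$mismatches, collapse = ","),
               seed_mismatch = seed_hit,
               accepted = h$identity > min_identity &
                 length(h$mismatches) <= max_mismatches & !seed_hit,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-locus, per-sample miRNA count table
#'
#' Sums mature-strand read counts over the member precursors of each
#' merged locus, yielding the count matrix consumed by the normalization
#' and differential-expression stages.
#'
#' @param loci locus table from [merge_loci()].
#' @param records miRNA record data.frame.
#' @return Integer locus x sample count matrix.
#' @export
mirna_count_table <- function(loci, records) {
  check_mirna_records(records)
  if (!all(loci$precursor_id %in% records$precursor_id))
    stop("locus references a precursor absent from the records")
  samples <- sort(unique(records$sample_id))
  locus_ids <- unique(loci$locus_id)
  prec2locus <- stats::setNames(loci$locus_id, loci$precursor_id)
  rec <- records[records$precursor_id %in% names(prec2locus), , drop = FALSE]
  # warn (not error) when one sample's reads map to multiple precursors of
  # a locus; expected to be absent in well-behaved data
  dup <- duplicated(rec[, c("sample_id", "precursor_id")])
  if (any(dup)) warning("duplicate (sample, precursor) rows summed")
  m <- matrix(0L, nrow = length(locus_ids), ncol = length(samples),
              dimnames = list(locus_ids, samples))
  agg <- stats::aggregate(mature_count ~ sample_id + precursor_id, data = rec, FUN = sum)
  for (i in seq_len(nrow(agg))) {
    l <- prec2locus[[agg$precursor_id[i]]]
    m[l, agg$sample_id[i]] <- m[l, agg$sample_id[i]] + as.integer(agg$mature_count[i])
  }
  m
}
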