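# Consensus miRNA-target calling and reciprocal-best-hit orthology.

#' Consensus miRNA-target pairs from two predictors
#'
#' Keeps a (miRNA, gene) pair only when it is reported by the
#' alignment-based predictor (table A, already thresholded at score >= 140
#' and energy <= -20) and by the hybridization-based predictor (table B,
#' energy <= -20) with `p < p_max`. Pairs are deduplicated.
#'
#' Argument order matters: table A must carry `score`, table B must carry
#' `p`; swapped tables are rejected rather than silently accepted.
#'
#' @param preds_a data.frame with columns mirna_id, gene_id, score, energy.
#' @param preds_b data.frame with columns mirna_id, gene_id, energy, p.
#' @param p_max strict p threshold on predictor B (default 0.01).
#' @param score_min,energy_max predictor A thresholds re-applied
#'   defensively (defaults 140 and -20).
#' @return data.frame of consensus pairs (mirna_id, gene_id), deduplicated
#'   and sorted.
#' @export
consensus_targets <- function(preds_a, preds_b, p_max = 0.01,
                              score_min = 140, energy_max = -20) {
  if (!all(c("mirna_id", "gene_id", "score", "energy") %in% names(preds_a)))
    stop("table A must carry mirna_id, gene_id, score, energy")
  if (!all(c("mirna_id", "gene_id", "energy", "p") %in% names(preds_b)))
    stop("table B must carry mirna_id, gene_id, energy, p")
  a <- preds_a[preds_a$score >= score_min & preds_a$energy <= energy_max, ]
  b <- preds_b[preds_b$energy <= energy_max & preds_b$p < p_max, ]
  key_a <- unique(paste(a$mirna_id, a$gene_id, sep = "\t"))
  key_b <- unique(paste(b$mirna_id, b$gene_id, sep = "\t"))
  keys <- sort(intersect(key_a, key_b))
  parts <- strsplit(keys, "\t", fixed = TRUE)
  data.frame(mirna_id = vapply(parts, `[`, character(1), 1),
             gene_id = vapply(parts, `[`, character(1), 2),
             stringsAsFactors = FALSE)
}

# Best hit per query: lowest e-value, ties by highest bitscore, then
# lexicographic subject.
best_hits <- function(hits) {
  ord <- order(hits$query, hits$evalue, -hits$bitscore, hits$subject)
  h <- hits[ord, ]
  h[!duplicated(h$query), ]
}

#' Reciprocal-best-hit ortholog pairs
#'
#' A pair (a, b) is called orthologous when b is a's best hit in the
#' forward table, a is b's best hit in the reverse table, and both
#' e-values are at or below `evalue_max`. "Best" means lowest e-value,
#' with ties broken by higher bitscore and then lexicographic subject
#' identifier, making the call deterministic. The result is one-to-one by
#' construction.
#'
#' @param hits_ab forward hit table: query, subject, evalue, bitscore.
#' @param hits_ba reverse hit table, same columns.
#' @param evalue_max e-value cutoff (default 1e-5).
#' @return data.frame with columns gene_a, gene_b, evalue_ab, evalue_ba.
#' @export
rbh_orthologs <- function(hits_ab, hits_ba, evalue_max = 1e-5) {
  need <- c("query", "subject", "evalue", "bitscore")
  if (!all(need %in% names(hits_ab)) || !all(need %in% names(hits_ba)))
    stop("hit tables need columns query, subject, evalue, bitscore")
  fa <- best_hits(hits_ab)
  fb <- best_hits(hits_ba)
  back <- stats::setNames(fb$subject, fb$query)
  back_e <- stats::setNames(fb$evalue, fb$query)
  keep <- !is.na(back[fa$subject]) & back[fa$subject] == fa$query &
    fa$evalue <= evalue_max & back_e[fa$subject] <= evalue_max
  keep[is.na(keep)] <- FALSE
  out <- data.frame(gene_a = fa$query[keep], gene_b = fa$subject[keep],
                    evalue_ab = fa$evalue[keep],
                    evalue_ba = unname(back_e[fa$subject[keep]]),
                    stringsAsFactors = FALSE)
  out[order(out$gene_a), , drop = FALSE]
}

#' Gene-set overlap test
#'
#' Hypergeometric upper-tail test and representation factor for the
#' overlap of two gene sets in a common universe, plus the coverage
#' fraction of `set_a` found in `set_b`.
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe the common gene universe.
#' @return List with the [hypergeometric_overlap()] fields plus
#'   `coverage_a_in_b`.
#' @export
set_overlap_test <- function(set_a, set_b, universe) {
  if (length(universe) == 0) stop("empty universe")
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("sets must be subsets of the universe")
  k <- length(intersect(set_a, set_b))
  res <- hypergeometric_overlap(k, length(set_a), length(set_b), length(universe))
  res$coverage_a_in_b <- if (length(set_a) == 0) NA_real_ else k / length(set_a)
  res
}
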