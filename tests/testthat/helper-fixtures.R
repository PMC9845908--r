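# Shared fixtures and small independent oracles used across test files.

# Small-scale generator settings: 500 genes and ~5e5 reads keep network
# construction fast while preserving the 22 + 22 paired design.
small_sim <- function(seed, n_genes = 500, modules = module_spec(),
                      de_effects = list(), ...) {
  generate_counts(
    design_spec(n_genes = n_genes),
    modules,
    noise_spec(libsize_log_mean = c(oocyte = log(5e5), egg = log(5e5)),
               de_effects = de_effects, seed = seed, ...))
}

tissue_counts <- function(sim, tissue) {
  sel <- sim$metadata$tissue == tissue
  list(counts = sim$counts[, sel, drop = FALSE],
       metadata = sim$metadata[sel, , drop = FALSE])
}

group_labels <- function(md) {
  paste0(md$season, ifelse(md$condition == "poor", "Poor", "Control"))
}

# Independent TMM oracle: direct evaluation of the doubly trimmed,
# inverse-variance weighted mean of M-values, written from the estimator's
# definition (kept separate from the package implementation).
oracle_tmm_pair <- function(obs, ref, n_obs, n_ref,
                            logratio_trim = 0.30, abs_trim = 0.05) {
  pos <- obs > 0 & ref > 0
  obs <- obs[pos]; ref <- ref[pos]
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  w <- 1 / ((n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref))
  n <- length(M)
  keepM <- rank(M) >= floor(n * logratio_trim) + 1 &
    rank(M) <= n - floor(n * logratio_trim)
  keepA <- rank(A) >= floor(n * abs_trim) + 1 &
    rank(A) <= n - floor(n * abs_trim)
  keep <- keepM & keepA
  2^(sum(M[keep] * w[keep]) / sum(w[keep]))
}

# Brute-force connected components of the interval overlap graph
# (quadratic scan; oracle for merge_loci).
oracle_interval_components <- function(start, end) {
  n <- length(start)
  adj <- outer(seq_len(n), seq_len(n), function(i, j)
    start[i] <= end[j] & start[j] <= end[i])
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# Quadratic mutual-best scan (oracle for rbh_orthologs).
oracle_rbh <- function(hits_ab, hits_ba, evalue_max) {
  best_of <- function(h, q) {
    rows <- h[h$query == q, ]
    rows <- rows[order(rows$evalue, -rows$bitscore, rows$subject), ]
    rows[1, ]
  }
  out <- list()
  for (q in unique(hits_ab$query)) {
    b <- best_of(hits_ab, q)
    if (b$evalue > evalue_max) next
    if (!b$subject %in% hits_ba$query) next
    r <- best_of(hits_ba, b$subject)
    if (r$subject == q && r$evalue <= evalue_max)
      out[[length(out) + 1]] <- data.frame(gene_a = q, gene_b = b$subject)
  }
  if (length(out) == 0) return(data.frame(gene_a = character(0),
                                          gene_b = character(0)))
  do.call(rbind, out)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
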