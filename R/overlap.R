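# Cross-tissue module correspondence: label matching, hypergeometric
# overlap tests, representation factors, and the size-aware bootstrap null.

#' Hypergeometric overlap test and representation factor
#'
#' Upper-tail probability `P(X >= k)` for the overlap of two gene sets of
#' sizes `n_source` and `n_target` drawn from a universe of `N` genes,
#' together with the representation factor `k * N / (n_source * n_target)`
#' (observed overlap over the overlap expected under independence).
#'
#' @param k observed overlap.
#' @param n_source,n_target set sizes.
#' @param N universe size.
#' @return List with `p_value`, `representation_factor`, and the inputs.
#' @export
hypergeometric_overlap <- function(k, n_source, n_target, N) {
  if (k > min(n_source, n_target) || n_source > N || n_target > N || k < 0)
    stop("inconsistent overlap counts")
  p <- stats::phyper(k - 1, n_target, N - n_target, n_source, lower.tail = FALSE)
  rf <- k * N / (n_source * n_target)
  list(k = k, n_source = n_source, n_target = n_target, N = N,
       p_value = p, representation_factor = rf)
}

#' Relabel a module partition against a reference partition
#'
#' Greedy matching: over the shared gene universe, repeatedly pick the
#' (source module, reference module) pair with the smallest hypergeometric
#' overlap p-value, give the source module the reference module's label,
#' and remove both from the pool; ties are broken by larger overlap and
#' then by smaller reference label. Unmatched source modules receive fresh
#' labels beyond the reference range. Label 0 (unassigned) is never
#' matched.
#'
#' @param source named integer partition to relabel.
#' @param reference named integer partition providing the target labels.
#' @return The source partition with relabeled modules.
#' @export
match_labels <- function(source, reference) {
  shared <- intersect(names(source), names(reference))
  if (length(shared) == 0) stop("partitions share no genes")
  src <- source[shared]; ref <- reference[shared]
  src_mods <- sort(unique(src[src != 0]))
  ref_mods <- sort(unique(ref[ref != 0]))
  N <- length(shared)
  if (length(src_mods) == 0 || length(ref_mods) == 0) return(source)
  stats_df <- expand.grid(s = src_mods, r = ref_mods)
  stats_df$k <- mapply(function(s, r) sum(src == s & ref == r), stats_df$s, stats_df$r)
  stats_df$p <- mapply(function(s, r, k)
    hypergeometric_overlap(k, sum(src == s), sum(ref == r), N)$p_value,
    stats_df$s, stats_df$r, stats_df$k)
  map <- integer(0)
  pool <- stats_df
  while (nrow(pool) > 0) {
    ord <- order(pool$p, -pool$k, pool$r)
    best <- pool[ord[1], ]
    map[as.character(best$s)] <- best$r
    pool <- pool[pool$s != best$s & pool$r != best$r, , drop = FALSE]
  }
  unmatched <- setdiff(src_mods, as.integer(names(map)))
  if (length(unmatched) > 0)
    map[as.character(unmatched)] <- max(ref_mods) + seq_along(unmatched)
  out <- source
  nz <- source != 0
  out[nz] <- map[as.character(source[nz])]
  out
}

#' Size-aware bootstrap null for module overlap
#'
#' Draws `n_iter` random gene sets of the module's size, without
#' replacement, from the universe of assigned genes, records the proportion
#' of each draw landing in the target module, and reports the empirical
#' probability that a random set has a strictly greater target proportion
#' than observed. Zero exceedances are reported as an upper bound
#' `p < 1/n_iter`.
#'
#' @param module_genes genes of the module under test (character), or a
#'   single integer module size (then `observed_prop` must be given).
#' @param target_genes genes of the target module (subset of `universe`).
#' @param universe gene universe to sample from.
#' @param n_iter bootstrap iterations (default 10000).
#' @param seed integer seed for the sampling stream.
#' @param observed_prop observed proportion; computed from `module_genes`
#'   when those are identifiers.
#' @return List of class `"bootstrap_null"`: `observed`, `empirical_p`,
#'   `p_label`, `null_props`, `n_iter`, `seed`, `module_size`.
#' @export
bootstrap_module_overlap <- function(module_genes, target_genes, universe,
                                     n_iter = 10000, seed = 1,
                                     observed_prop = NULL) {
  if (length(universe) == 0) stop("empty universe")
  if (!all(target_genes %in% universe)) stop("target must lie in the universe")
  if (is.character(module_genes)) {
    m <- length(module_genes)
    if (is.null(observed_prop))
      observed_prop <- mean(module_genes %in% target_genes)
  } else {
    m <- as.integer(module_genes)
    if (is.null(observed_prop)) stop("observed_prop required with a bare module size")
  }
  if (m > length(universe)) stop("module size exceeds universe size")
  if (observed_prop < 0 || observed_prop > 1) stop("observed proportion not in [0, 1]")
  is_target <- universe %in% target_genes
  set.seed(seed)
  null_props <- vapply(seq_len(n_iter), function(i)
    mean(is_target[sample.int(length(universe), m)]), numeric(1))
  exceed <- sum(null_props > observed_prop)
  p <- exceed / n_iter
  structure(list(observed = observed_prop, empirical_p = p,
                 p_label = if (exceed == 0) sprintf("< %g", 1 / n_iter) else
                   format(p, digits = 4),
                 null_props = null_props, n_iter = n_iter, seed = seed,
                 module_size = m),
            class = "bootstrap_null")
}

#' Cross-tabulate two module partitions with overlap statistics
#'
#' Full source-by-target module cross-tabulation over the shared universe
#' of genes assigned (label != 0) in both partitions (set
#' `include_unassigned = TRUE` to keep label 0 in the universe). For every
#' module pair the overlap count, overlap fraction (of the source module),
#' hypergeometric p and representation factor are reported; for source
#' modules named in `modules_of_interest` a bootstrap empirical p against
#' the designated (or best-overlapping) target module is added. A flow
#' summary bins the overlap fractions into the bands <1%, 1-10%, 10-20%,
#' ..., 60-70%, >70%.
#'
#' @param source named integer partition (e.g. oocyte modules).
#' @param target named integer partition (e.g. relabeled egg modules).
#' @param modules_of_interest integer labels of source modules to test with
#'   the bootstrap null (default none).
#' @param n_iter,seed bootstrap settings.
#' @param include_unassigned include label-0 genes in the universe
#'   (default FALSE).
#' @return List with `table` (one row per module pair), `flow` (binned
#'   fraction summary), `universe_size`, and `bootstrap` (named list of
#'   `"bootstrap_null"` objects).
#' @export
overlap_table <- function(source, target, modules_of_interest = integer(0),
                          n_iter = 10000, seed = 1,
                          include_unassigned = FALSE) {
  shared <- intersect(names(source), names(target))
  if (length(shared) == 0) stop("partitions share no genes")
  src <- source[shared]; tgt <- target[shared]
  if (!include_unassigned) {
    keep <- src != 0 & tgt != 0
    src <- src[keep]; tgt <- tgt[keep]
  }
  universe <- names(src)
  N <- length(universe)
  src_mods <- sort(unique(src[src != 0]))
  tgt_mods <- sort(unique(tgt[tgt != 0]))
  tab <- expand.grid(source_module = src_mods, target_module = tgt_mods)
  res <- mapply(function(s, r) {
    k <- sum(src == s & tgt == r)
    hy <- hypergeometric_overlap(k, sum(src == s), sum(tgt == r), N)
    c(k = k, n_source = hy$n_source, n_target = hy$n_target,
      fraction = k / hy$n_source, p_value = hy$p_value,
      representation_factor = hy$representation_factor)
  }, tab$source_module, tab$target_module)
  tab <- cbind(tab, t(res))
  tab$N <- N
  tab$bootstrap_p <- NA_real_
  boots <- list()
  for (s in modules_of_interest) {
    if (!any(src == s)) {
      warning("module of interest ", s, " has no genes in the shared universe")
      next
    }
    rows <- tab[tab$source_module == s, ]
    best <- rows[which.min(rows$p_value), ]
    bn <- bootstrap_module_overlap(
      universe[src == s], universe[tgt == best$target_module], universe,
      n_iter = n_iter, seed = substream_seed(seed, paste0("boot", s)))
    boots[[as.character(s)]] <- bn
    tab$bootstrap_p[tab$source_module == s &
                      tab$target_module == best$target_module] <- bn$empirical_p
  }
  bands <- c(0, 0.01, seq(0.1, 0.7, by = 0.1), 1)
  band_lab <- c("<1%", "1-10%", "10-20%", "20-30%", "30-40%", "40-50%",
                "50-60%", "60-70%", ">70%")
  nonzero <- tab[tab$k > 0, , drop = FALSE]
  flow <- data.frame(band = band_lab,
                     n_pairs = as.integer(table(cut(nonzero$fraction,
                                                    breaks = bands,
                                                    labels = band_lab,
                                                    include.lowest = TRUE,
                                                    right = FALSE))))
  list(table = tab, flow = flow, universe_size = N, bootstrap = boots)
}
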