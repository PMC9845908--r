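# Weighted gene-coexpression network construction, module detection and
# module-trait correlation.
#
# Expression matrices are genes x samples throughout. Correlations are
# Pearson on pairwise-complete observations; the network is unsigned
# (adjacency = |cor|^beta).

#' Remove genes with excessive missingness or zero variance
#'
#' @param expr genes x samples matrix, possibly with NAs.
#' @param max_missing_frac maximum tolerated fraction of missing values per
#'   gene (default 0.5).
#' @return List with `expr` (the retained submatrix), `kept`, `dropped`
#'   (identifier vectors) and `n_dropped`.
#' @export
good_genes_filter <- function(expr, max_missing_frac = 0.5) {
  stopifnot(is.matrix(expr))
  miss <- rowMeans(is.na(expr))
  v <- apply(expr, 1, stats::var, na.rm = TRUE)
  bad <- miss > max_missing_frac | !is.finite(v) | v == 0
  if (all(bad)) stop("all genes dropped by quality filter")
  list(expr = expr[!bad, , drop = FALSE],
       kept = rownames(expr)[!bad],
       dropped = rownames(expr)[bad],
       n_dropped = sum(bad))
}

#' Flag outlying samples by hierarchical clustering
#'
#' Average-linkage clustering on Euclidean sample distances; a sample is
#' flagged when it enters the dendrogram as a singleton at a merge height
#' strictly above the given quantile of all merge heights.
#'
#' @param expr genes x samples matrix.
#' @param cut_height_quantile quantile of merge heights defining "joins too
#'   high" (default 0.99).
#' @return Character vector of flagged sample identifiers (possibly empty).
#' @export
detect_sample_outliers <- function(expr, cut_height_quantile = 0.99) {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 3) stop("at least 3 samples required")
  hc <- stats::hclust(stats::dist(t(expr)), method = "average")
  thr <- stats::quantile(hc$height, cut_height_quantile, names = FALSE)
  n <- ncol(expr)
  # height at which each sample first joins the tree; a sample is a
  # singleton branch up to exactly that merge
  leaf_merge_height <- numeric(n)
  for (i in seq_len(nrow(hc$merge))) {
    for (m in hc$merge[i, ]) if (m < 0) leaf_merge_height[-m] <- hc$height[i]
  }
  flagged <- leaf_merge_height > thr
  colnames(expr)[flagged]
}

#' Unsigned soft-threshold adjacency
#'
#' @param expr genes x samples matrix.
#' @param beta soft-thresholding power (>= 1).
#' @return Symmetric genes x genes adjacency `|cor|^beta` with unit diagonal.
#' @export
adjacency_matrix <- function(expr, beta = 4) {
  stopifnot(beta >= 1)
  a <- abs(stats::cor(t(expr), use = "pairwise.complete.obs"))^beta
  a[is.na(a)] <- 0
  diag(a) <- 1
  a
}

#' Scan soft-thresholding powers for approximate scale-free fit
#'
#' For each candidate power the unsigned adjacency is formed, per-gene
#' connectivity `k_i = sum_j a_ij` (diagonal excluded) computed, and the
#' scale-free fit index obtained as the R-squared of the regression of
#' log10 binned frequency of k on log10 bin-center k (10 bins), sign-flipped
#' when the slope is positive. Mean connectivity is also reported.
#'
#' @param expr genes x samples matrix.
#' @param betas candidate powers (default 1:10).
#' @param n_bins connectivity histogram bins (default 10).
#' @return data.frame with columns beta, r_squared (signed), slope,
#'   mean_connectivity.
#' @export
scale_free_scan <- function(expr, betas = 1:10, n_bins = 10) {
  stopifnot(is.matrix(expr), nrow(expr) >= 3)
  cors <- abs(stats::cor(t(expr), use = "pairwise.complete.obs"))
  cors[is.na(cors)] <- 0
  diag(cors) <- 0
  out <- lapply(betas, function(b) {
    a <- cors^b
    k <- rowSums(a)
    if (stats::sd(k) == 0 && mean(k) == 0) stop("degenerate connectivity vector")
    fit <- scale_free_fit_index(k, n_bins)
    data.frame(beta = b, r_squared = fit$r_squared, slope = fit$slope,
               mean_connectivity = mean(k))
  })
  do.call(rbind, out)
}

# Scale-free fit index from a connectivity vector: bin k, regress
# log10(freq) on log10(bin center), flip the sign of R^2 if slope > 0.
scale_free_fit_index <- function(k, n_bins = 10) {
  if (stats::sd(k) == 0) return(list(r_squared = NA_real_, slope = NA_real_))
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  centers <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0 & centers > 0
  x <- log10(centers[keep]); y <- log10(freq[keep])
  if (length(x) < 2) return(list(r_squared = NA_real_, slope = NA_real_))
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  list(r_squared = if (isTRUE(slope > 0)) -r2 else r2, slope = slope)
}

#' Topological overlap similarity
#'
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with connectivities `k` excluding the diagonal, and `TOM_ii = 1`. Values
#' lie in `[0, 1]`; `1 - TOM` is the clustering dissimilarity.
#'
#' @param adjacency symmetric matrix in `[0, 1]` with unit diagonal.
#' @return Symmetric TOM matrix.
#' @export
tom_similarity <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(adjacency < 0 | adjacency > 1)) stop("adjacency out of [0, 1]")
  a <- adjacency
  diag(a) <- 0
  k <- rowSums(a)
  shared <- a %*% a            # (A^2)_ij = sum_u a_iu a_uj, u != i,j since diag 0
  num <- shared + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect coexpression modules by cutting the TOM dendrogram
#'
#' Deterministic variable-height branch cut. Average-linkage clustering of
#' `1 - TOM` is cut at a fraction of the dendrogram height range controlled
#' by `deep_split` (deeper splits cut lower, producing more and finer
#' branches); branches reaching `min_module_size` become candidate modules.
#' Membership is then refined by topological-overlap connectivity: each
#' gene's mean TOM to every candidate module is computed, and the gene is
#' assigned to its best module only when that connectivity stands out from
#' the background overlap level (median off-diagonal TOM) by at least
#' `assign_factor`; otherwise it is left unassigned. Two refinement passes
#' are run so that module cores purge loosely chained background genes.
#' Candidate branches made of uncorrelated genes dissolve below
#' `min_module_size` during refinement and are discarded. Labels are
#' ordered by decreasing module size; label 0 marks unassigned genes.
#'
#' @param tom TOM matrix from [tom_similarity()].
#' @param min_module_size minimum genes per module (default 30).
#' @param deep_split split aggressiveness, integer 0-4 (default 2).
#' @param cut_fraction optional explicit fraction of the dendrogram height
#'   range at which to cut; default `0.95 - 0.1 * deep_split`.
#' @param assign_factor multiple of the background overlap a gene's mean
#'   TOM to a module must exceed for assignment (default 3).
#' @return Named integer vector of module labels (0 = unassigned).
#' @export
cut_modules <- function(tom, min_module_size = 30, deep_split = 2,
                        cut_fraction = NULL, assign_factor = 3) {
  stopifnot(is.matrix(tom))
  n <- nrow(tom)
  if (n < min_module_size) {
    warning("fewer genes than the minimum module size: all genes unassigned")
    return(stats::setNames(integer(n), rownames(tom)))
  }
  if (!deep_split %in% 0:4) stop("deep_split must be an integer in 0..4")
  if (is.null(cut_fraction)) cut_fraction <- 0.95 - 0.1 * deep_split
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  h_cut <- min(hc$height) + cut_fraction * (max(hc$height) - min(hc$height))
  cl <- stats::cutree(hc, h = h_cut)
  background <- max(stats::median(tom[upper.tri(tom)]), 1e-12)
  threshold <- assign_factor * background
  sizes <- table(cl)
  cand <- as.integer(names(sizes))[as.integer(sizes) >= min_module_size]
  if (length(cand) == 0) return(stats::setNames(integer(n), rownames(tom)))
  members <- lapply(cand, function(g) which(cl == g))
  tom0 <- tom; diag(tom0) <- 0
  for (pass in 1:2) {
    conn <- vapply(members, function(idx)
      rowSums(tom0[, idx, drop = FALSE]) / pmax(length(idx) - 1, 1),
      numeric(n)) # gene x candidate mean TOM (own contribution excluded via diag 0)
    # per-module floor: half the median connectivity of the module's own
    # members, so genes must be about as connected as the module core;
    # the background floor additionally dissolves incoherent branches
    core <- vapply(seq_along(members), function(j)
      stats::median(conn[members[[j]], j]), numeric(1))
    floor_j <- pmax(core / 2, threshold)
    best <- max.col(conn, ties.method = "first")
    best_val <- conn[cbind(seq_len(n), best)]
    assigned <- ifelse(best_val >= floor_j[best], best, 0L)
    members <- lapply(seq_along(cand), function(j) which(assigned == j))
    keep <- vapply(members, length, integer(1)) >= min_module_size
    if (!any(keep)) return(stats::setNames(integer(n), rownames(tom)))
    members <- members[keep]
    cand <- cand[keep]
    assigned <- match(assigned, which(keep))
    assigned[is.na(assigned)] <- 0L
  }
  labels <- integer(n)
  for (j in seq_along(members)) labels[members[[j]]] <- j
  relabel_by_size(stats::setNames(labels, rownames(tom)))
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' per-gene standardized expression submatrix, scaled to unit variance and
#' sign-oriented so that its mean correlation with member genes is positive.
#'
#' @param expr genes x samples matrix.
#' @param partition named integer labels as from [cut_modules()]; label 0 is
#'   ignored.
#' @return Samples x modules matrix; column names `"ME<label>"`.
#' @export
module_eigengene <- function(expr, partition) {
  stopifnot(is.matrix(expr))
  partition <- partition[rownames(expr)]
  mods <- sort(unique(partition[partition != 0]))
  if (length(mods) == 0) stop("no modules in partition")
  me <- vapply(mods, function(m) {
    sub <- expr[partition == m, , drop = FALSE]
    if (nrow(sub) == 0) stop("empty module ", m)
    z <- t(scale(t(sub)))
    z[is.na(z)] <- 0
    sv <- svd(z, nu = 0, nv = 1)
    e <- sv$v[, 1]
    e <- e / stats::sd(e)
    if (mean(stats::cor(e, t(sub)), na.rm = TRUE) < 0) e <- -e
    e
  }, numeric(ncol(expr)))
  rownames(me) <- colnames(expr)
  colnames(me) <- paste0("ME", mods)
  me
}

#' Merge modules with similar eigengenes
#'
#' Repeatedly merges the pair of modules whose eigengene correlation is
#' highest while the corresponding dissimilarity `1 - cor` is below
#' `cut_height`, recomputing eigengenes after each merge, until no pair of
#' module eigengenes correlates above `1 - cut_height`. Labels are
#' re-ordered by decreasing module size.
#'
#' @param expr genes x samples matrix.
#' @param partition named integer module labels.
#' @param cut_height eigengene dissimilarity below which modules merge
#'   (default 0.25, i.e. correlation > 0.75).
#' @return Named integer vector of merged module labels.
#' @export
merge_similar_modules <- function(expr, partition, cut_height = 0.25) {
  stopifnot(cut_height > 0, cut_height < 1)
  part <- partition
  repeat {
    mods <- sort(unique(part[part != 0]))
    if (length(mods) < 2) break
    me <- module_eigengene(expr, part)
    cc <- stats::cor(me)
    diag(cc) <- -Inf
    top <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (1 - max(cc) >= cut_height) break
    a <- mods[top[1]]; b <- mods[top[2]]
    part[part == max(a, b)] <- min(a, b)
  }
  relabel_by_size(part)
}

# Relabel nonzero module labels as 1..K by decreasing size (ties by first
# occurrence); label 0 is preserved.
relabel_by_size <- function(partition) {
  nz <- partition[partition != 0]
  if (length(nz) == 0) return(partition)
  sizes <- table(nz)
  first <- vapply(names(sizes), function(g)
    min(which(partition == as.integer(g))), numeric(1))
  ord <- order(-as.integer(sizes), first)
  map <- stats::setNames(seq_along(ord), names(sizes)[ord])
  out <- partition
  out[partition != 0] <- map[as.character(partition[partition != 0])]
  out
}

#' Correlate module eigengenes with sample traits
#'
#' Pearson correlation of each eigengene with each 0/1-coded trait;
#' p-values from the t transform `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom, two-sided. A constant trait yields missing
#' statistics with a warning.
#'
#' @param eigengenes samples x modules matrix from [module_eigengene()].
#' @param traits data.frame of numeric 0/1 trait codings, one row per
#'   sample in the order of `eigengenes` rows.
#' @param alpha significance threshold for the flag column (default 0.05).
#' @return data.frame with columns module, trait, r, p_value, significant.
#' @export
module_trait_correlation <- function(eigengenes, traits, alpha = 0.05) {
  stopifnot(is.matrix(eigengenes), nrow(eigengenes) >= 3)
  n <- nrow(eigengenes)
  out <- expand.grid(module = colnames(eigengenes), trait = names(traits),
                     stringsAsFactors = FALSE)
  stats_list <- mapply(function(m, tr) {
    x <- eigengenes[, m]
    y <- traits[[tr]]
    if (stats::sd(y) == 0) {
      warning("constant trait '", tr, "': correlation undefined")
      return(c(NA_real_, NA_real_))
    }
    r <- stats::cor(x, y)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    c(r, p)
  }, out$module, out$trait)
  out$r <- stats_list[1, ]
  out$p_value <- stats_list[2, ]
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out
}

#' Per-tissue network analysis
#'
#' Convenience wrapper running the full per-tissue network stage: gene
#' quality filter, sample-outlier removal, adjacency and TOM at the chosen
#' power, module detection, eigengene merging, and module-trait
#' correlation.
#'
#' @param expr genes x samples matrix (e.g. log-CPM).
#' @param traits data.frame of 0/1 traits (rows matching samples).
#' @param beta soft power (default 4).
#' @param min_module_size,deep_split,merge_cut_height see [cut_modules()]
#'   and [merge_similar_modules()].
#' @param drop_outliers whether to remove flagged outlier samples
#'   (default TRUE).
#' @return List with `partition`, `eigengenes`, `module_trait`,
#'   `outliers`, `dropped_genes` and the `samples` retained.
#' @export
network_analysis <- function(expr, traits, beta = 4, min_module_size = 30,
                             deep_split = 2, merge_cut_height = 0.25,
                             drop_outliers = TRUE) {
  gg <- good_genes_filter(expr)
  expr <- gg$expr
  outliers <- detect_sample_outliers(expr)
  if (drop_outliers && length(outliers) > 0) {
    keep <- !(colnames(expr) %in% outliers)
    expr <- expr[, keep, drop = FALSE]
    traits <- traits[keep, , drop = FALSE]
  }
  adj <- adjacency_matrix(expr, beta = beta)
  tom <- tom_similarity(adj)
  part <- cut_modules(tom, min_module_size = min_module_size,
                      deep_split = deep_split)
  if (any(part != 0)) {
    part <- merge_similar_modules(expr, part, cut_height = merge_cut_height)
    me <- module_eigengene(expr, part)
    mt <- module_trait_correlation(me, traits)
  } else {
    me <- NULL
    mt <- NULL
  }
  list(partition = part, eigengenes = me, module_trait = mt,
       outliers = outliers, dropped_genes = gg$dropped,
       samples = colnames(expr))
}
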