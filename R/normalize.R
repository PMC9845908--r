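# Expression-level filtering and TMM library-size normalization.

#' Filter features by expression level
#'
#' Keeps a feature when (a) its counts-per-million reach a cutoff in at least
#' `k` samples, where `k` is the size of the smallest experimental group and
#' the CPM cutoff corresponds to `min_count` reads in the median-sized
#' library, and (b) its total count over all samples reaches `min_total`.
#' This is the standard pre-filter applied before between-sample
#' normalization and linear modelling of RNA-seq counts.
#'
#' @param counts integer feature x sample count matrix with dimnames.
#' @param group per-sample group labels (length `ncol(counts)`).
#' @param min_count minimum count in the median library defining the CPM
#'   cutoff; default 10.
#' @param min_total minimum total count across all samples; default 15.
#' @return Character vector of retained feature identifiers, in input order.
#' @export
filter_by_expression <- function(counts, group, min_count = 10, min_total = 15) {
  check_counts(counts)
  if (length(group) != ncol(counts)) stop("one group label per sample required")
  group <- as.factor(group)
  if (any(table(group) == 0L)) stop("empty groups are not allowed")
  lib <- library_sizes(counts)
  k <- min(table(group))
  cpm_cutoff <- min_count / stats::median(lib) * 1e6
  cpm <- t(t(counts) / lib * 1e6)
  keep <- rowSums(cpm >= cpm_cutoff) >= k & rowSums(counts) >= min_total
  rownames(counts)[keep]
}

# Upper-quartile CPM per sample; used to pick the TMM reference sample.
upper_quartile_cpm <- function(counts, lib) {
  apply(counts, 2, function(x) stats::quantile(x, probs = 0.75)) / lib * 1e6
}

# Doubly trimmed, precision-weighted mean of M-values for one sample against
# the reference. Trimming keeps the central (1 - 2*logratio_trim) of M and
# (1 - 2*abs_trim) of A, by ranks; weights are inverse asymptotic binomial
# variances summed over the two samples.
tmm_pair_factor <- function(obs, ref, n_obs, n_ref, logratio_trim, abs_trim) {
  pos <- obs > 0 & ref > 0
  if (!any(pos)) stop("no co-expressed features between sample and reference")
  obs <- obs[pos]; ref <- ref[pos]
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
  loA <- floor(n * abs_trim) + 1;      hiA <- n + 1 - loA
  rL <- rank(logR); rA <- rank(absE)
  keep <- rL >= loL & rL <= hiL & rA >= loA & rA <= hiA
  f <- sum(logR[keep] / v[keep]) / sum(1 / v[keep])
  2^f
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Computes per-sample scale factors by the TMM estimator: for each sample
#' versus a reference, per-feature log-ratios (M) and mean log-abundances (A)
#' are formed over features positive in both libraries, the extremes of both
#' are trimmed, and the surviving M-values are averaged with
#' inverse-variance (asymptotic binomial) weights. The reference is the
#' sample whose upper-quartile CPM is closest to the mean upper-quartile
#' (ties broken by input order). Factors are rescaled to geometric mean 1.
#'
#' @param counts integer feature x sample count matrix.
#' @param logratio_trim fraction trimmed from each tail of the M-values
#'   (default 0.30).
#' @param abs_trim fraction trimmed from each tail of the A-values
#'   (default 0.05).
#' @return A list of class `"norm_factors"` with `factors` (named, geometric
#'   mean 1), `reference` (sample identifier) and `lib_size`.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.30, abs_trim = 0.05) {
  check_counts(counts)
  if (ncol(counts) < 2L) stop("TMM requires at least two samples")
  lib <- library_sizes(counts)
  uq <- upper_quartile_cpm(counts, lib)
  ref_idx <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref_idx) return(1)
    tmm_pair_factor(counts[, j], counts[, ref_idx], lib[j], lib[ref_idx],
                    logratio_trim, abs_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  structure(list(factors = f, reference = colnames(counts)[ref_idx],
                 lib_size = lib),
            class = "norm_factors")
}

#' Log2 counts per million
#'
#' `log2((count + prior) / (library_size * factor + 2 * prior) * 1e6)`,
#' the moderated log-CPM transform applied after TMM normalization.
#'
#' @param counts integer feature x sample count matrix.
#' @param factors `"norm_factors"` object from [tmm_factors()], or `NULL` for
#'   unit factors.
#' @param prior prior count added to numerator (default 0.5).
#' @return Real matrix with the dimensions and dimnames of `counts`.
#' @export
log_cpm <- function(counts, factors = NULL, prior = 0.5) {
  check_counts(counts)
  lib <- library_sizes(counts)
  f <- if (is.null(factors)) rep(1, ncol(counts)) else factors$factors[colnames(counts)]
  if (any(!is.finite(f)) || any(f <= 0)) stop("normalization factors must be positive")
  eff <- lib * f
  if (any(eff <= 0)) stop("non-positive effective library size")
  t(log2(t(counts + prior) / (eff + 2 * prior) * 1e6))
}
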