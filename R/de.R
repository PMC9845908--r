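# Moderated differential expression under the non-intercept group model.

GROUP_LEVELS <- c("earlyControl", "earlyPoor", "lateControl", "latePoor")

#' Build the non-intercept group design matrix
#'
#' One indicator column per season-by-condition cell (`~ 0 + group`), so each
#' coefficient is a group mean and contrasts of interest are formed directly
#' on group means.
#'
#' @param metadata data.frame with `season` ("early"/"late") and `condition`
#'   ("control"/"poor") columns, one row per sample.
#' @return Samples x 4 indicator matrix with columns
#'   `earlyControl`, `earlyPoor`, `lateControl`, `latePoor`.
#' @export
group_design <- function(metadata) {
  stopifnot(all(c("season", "condition") %in% names(metadata)))
  grp <- paste0(metadata$season, ifelse(metadata$condition == "poor", "Poor", "Control"))
  grp <- factor(grp, levels = GROUP_LEVELS)
  if (anyNA(grp)) stop("season must be early/late and condition control/poor")
  design <- stats::model.matrix(~ 0 + grp)
  colnames(design) <- levels(grp)
  rownames(design) <- rownames(metadata)
  design
}

#' Contrasts over group means
#'
#' The three contrasts of interest: `condition` (poor minus control mean,
#' averaged over seasons), `season` (late minus early mean, averaged over
#' conditions) and `interaction` (the condition effect in the late season
#' minus the condition effect in the early season). Each contrast's
#' coefficients sum to zero.
#'
#' @return 4 x 3 numeric matrix (groups x contrasts).
#' @export
group_contrasts <- function() {
  cm <- cbind(
    condition   = c(earlyControl = -0.5, earlyPoor = 0.5, lateControl = -0.5, latePoor = 0.5),
    season      = c(earlyControl = -0.5, earlyPoor = -0.5, lateControl = 0.5, latePoor = 0.5),
    interaction = c(earlyControl = 1, earlyPoor = -1, lateControl = -1, latePoor = 1)
  )
  cm[GROUP_LEVELS, , drop = FALSE]
}

#' Precision weights from the mean-variance trend
#'
#' Fits the per-feature linear model, regresses the square root of the
#' residual standard deviation on mean log-CPM with a locally weighted
#' scatterplot smoother, and assigns each observation the predicted trend
#' value at its fitted log-CPM raised to the power -4 (i.e. an
#' inverse-variance weight on the log scale). With fewer than 10 features
#' the trend cannot be estimated and equal weights are returned with a
#' warning.
#'
#' @param logcpm real feature x sample matrix of log2-CPM values.
#' @param design design matrix from [group_design()].
#' @param span smoother span (default 0.5).
#' @return Positive weight matrix with the dimensions of `logcpm`.
#' @export
precision_weights <- function(logcpm, design, span = 0.5) {
  stopifnot(is.matrix(logcpm), nrow(design) == ncol(logcpm))
  df_resid <- ncol(logcpm) - qr(design)$rank
  if (df_resid < 2) stop("at least 2 residual degrees of freedom required")
  if (nrow(logcpm) < 10) {
    warning("fewer than 10 features: falling back to equal precision weights")
    return(matrix(1, nrow(logcpm), ncol(logcpm), dimnames = dimnames(logcpm)))
  }
  fit <- stats::lm.fit(design, t(logcpm))
  res <- t(fit$residuals)                       # features x samples
  sd_resid <- sqrt(rowSums(res^2) / df_resid)
  sqrt_sd <- sqrt(sd_resid)
  mean_log <- rowMeans(logcpm)
  lo <- stats::lowess(mean_log, sqrt_sd, f = span)
  fitted <- t(design %*% fit$coefficients)      # features x samples
  pred <- stats::approx(lo$x, lo$y, xout = as.vector(fitted), rule = 2,
                        ties = mean)$y
  pred <- pmax(pred, 1e-6)
  w <- matrix(pred^-4, nrow(logcpm), ncol(logcpm), dimnames = dimnames(logcpm))
  w
}

#' Moderated linear-model differential expression
#'
#' Per-feature weighted least squares on the non-intercept group design,
#' contrast estimation, and empirical-Bayes variance moderation: the prior
#' (d0, s0^2) is estimated by moment matching on the log residual variances,
#' posterior variances are `(d0*s0^2 + d*s^2) / (d0 + d)`, and moderated
#' t-statistics are referred to a t distribution on `d0 + d` degrees of
#' freedom. P-values are adjusted per contrast by Benjamini-Hochberg.
#'
#' @param logcpm real feature x sample matrix.
#' @param design design matrix (full column rank).
#' @param contrasts groups x contrasts matrix, e.g. [group_contrasts()].
#' @param weights optional positive observation weights (same shape as
#'   `logcpm`).
#' @param moderation optional list with elements `d0` and `s0_2` overriding
#'   the estimated prior; `d0 = 0` gives ordinary (unmoderated) t-statistics
#'   and `d0 = Inf` full shrinkage to `s0_2`.
#' @return A list of class `"de_fit"`: `table` (long data.frame with columns
#'   feature, contrast, log_fc, ave_expr, t, p_value, adj_p_value) and
#'   `moderation` (the prior actually used).
#' @export
fit_moderated <- function(logcpm, design, contrasts = group_contrasts(),
                          weights = NULL, moderation = NULL) {
  stopifnot(is.matrix(logcpm), is.matrix(contrasts))
  if (qr(design)$rank < ncol(design)) stop("design matrix is singular")
  if (ncol(logcpm) - ncol(design) < 1) stop("zero residual degrees of freedom")
  if (!is.null(weights) && any(weights <= 0)) stop("weights must be positive")
  fit <- limma::lmFit(logcpm, design, weights = weights)
  cf <- limma::contrasts.fit(fit, contrasts)
  if (is.null(moderation)) {
    eb <- limma::eBayes(cf)
    d0 <- eb$df.prior
    s0_2 <- eb$s2.prior
    tt <- eb$t
    pp <- eb$p.value
  } else {
    d0 <- moderation$d0
    s0_2 <- moderation$s0_2
    d <- cf$df.residual
    s2 <- cf$sigma^2
    post <- if (is.infinite(d0)) rep(s0_2, length(s2)) else (d0 * s0_2 + d * s2) / (d0 + d)
    tt <- cf$coefficients / (cf$stdev.unscaled * sqrt(post))
    pp <- 2 * stats::pt(-abs(tt), df = d0 + d)
  }
  tab <- do.call(rbind, lapply(colnames(contrasts), function(cn) {
    data.frame(feature = rownames(logcpm), contrast = cn,
               log_fc = cf$coefficients[, cn], ave_expr = fit$Amean,
               t = tt[, cn], p_value = pp[, cn],
               adj_p_value = bh_adjust(pp[, cn]),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  structure(list(table = tab,
                 moderation = list(d0 = unname(d0[1]), s0_2 = unname(s0_2[1])),
                 contrasts = contrasts),
            class = "de_fit")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control; a validating wrapper around
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Count differentially expressed features per contrast
#'
#' Tallies up- and down-regulated features (by sign of the contrast log2
#' fold change) at each significance threshold applied to the BH-adjusted
#' p-values, the layout used for headline DE counts.
#'
#' @param fit `"de_fit"` object.
#' @param alphas adjusted-p thresholds (default `c(0.05, 0.1)`).
#' @return data.frame with columns contrast, alpha, up, down.
#' @export
de_summary <- function(fit, alphas = c(0.05, 0.1)) {
  stopifnot(inherits(fit, "de_fit"))
  tab <- fit$table
  out <- expand.grid(contrast = unique(tab$contrast), alpha = alphas,
                     stringsAsFactors = FALSE)
  out$up <- mapply(function(cn, a)
    sum(tab$contrast == cn & tab$adj_p_value < a & tab$log_fc > 0),
    out$contrast, out$alpha)
  out$down <- mapply(function(cn, a)
    sum(tab$contrast == cn & tab$adj_p_value < a & tab$log_fc < 0),
    out$contrast, out$alpha)
  out
}
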