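# Design/contrast construction, precision weights, moderated fitting,
# BH adjustment and DE summaries.

toy_logcpm <- function(n_feat = 50, n_per_group = 5, seed = 1, sd = 1) {
  set.seed(seed)
  md <- data.frame(season = rep(c("early", "late"), each = 2 * n_per_group),
                   condition = rep(rep(c("control", "poor"), each = n_per_group), 2))
  rownames(md) <- sprintf("s%02d", seq_len(nrow(md)))
  lc <- matrix(rnorm(n_feat * nrow(md), 5, sd), n_feat, nrow(md),
               dimnames = list(sprintf("f%03d", 1:n_feat), rownames(md)))
  list(logcpm = lc, metadata = md, design = group_design(md))
}

test_that("group design and contrasts have the stated structure", {
  t <- toy_logcpm()
  expect_true(all(rowSums(t$design) == 1))
  expect_equal(qr(t$design)$rank, 4)
  cm <- group_contrasts()
  expect_equal(unname(colSums(cm)), c(0, 0, 0))
  # season contrast is the late-minus-early mean difference
  expect_equal(unname(cm[, "season"]), c(-0.5, -0.5, 0.5, 0.5))
})

test_that("precision weights are equal for a flat trend, positive otherwise", {
  t <- toy_logcpm(sd = 1)
  # exactly flat mean-variance trend: every feature is a shifted copy of
  # the same profile, so residual sd is identical across features
  base <- rnorm(ncol(t$logcpm))
  flat <- outer(rep(1, 60), base) + seq_len(60)
  dimnames(flat) <- list(sprintf("f%02d", 1:60), colnames(t$logcpm))
  w <- precision_weights(flat, t$design)
  expect_lt(diff(range(w)) / mean(w), 1e-6)
  w2 <- precision_weights(t$logcpm, t$design)
  expect_true(all(w2 > 0) && all(is.finite(w2)))
})

test_that("precision weights track a decreasing mean-variance trend", {
  set.seed(8)
  n <- 50
  md <- toy_logcpm()$metadata
  mu <- seq(2, 12, length.out = n)
  sdv <- 1.5 / sqrt(mu)           # decreasing sd with abundance
  lc <- t(vapply(seq_len(n), function(i) rnorm(nrow(md), mu[i], sdv[i]),
                 numeric(nrow(md))))
  dimnames(lc) <- list(sprintf("f%02d", 1:n), rownames(md))
  design <- group_design(md)
  w <- precision_weights(lc, design)
  # independent trend evaluation at probe points: weights should increase
  # with abundance, matching a standalone lowess of sqrt(sd) on mean
  fit <- lm.fit(design, t(lc))
  sd_res <- sqrt(colSums(fit$residuals^2) / (nrow(md) - 4))
  lo <- lowess(rowMeans(lc), sqrt(sd_res), f = 0.5)
  probes <- quantile(rowMeans(lc), c(0.1, 0.3, 0.5, 0.7, 0.9))
  pred <- approx(lo$x, lo$y, xout = probes, rule = 2, ties = mean)$y
  expect_true(all(diff(pred^-4) > 0))
  ord <- order(rowMeans(lc))
  expect_gt(mean(w[ord[41:50], ]), mean(w[ord[1:10], ]))
})

test_that("precision weights correlate with the reference voom weights", {
  skip_if_not_installed("limma")
  sim <- small_sim(61, n_genes = 400)
  tc <- tissue_counts(sim, "oocyte")
  kept <- filter_by_expression(tc$counts, group_labels(tc$metadata))
  cnt <- tc$counts[kept, ]
  nf <- tmm_factors(cnt)
  lc <- log_cpm(cnt, nf)
  design <- group_design(tc$metadata)
  w <- precision_weights(lc, design)
  v <- limma::voom(cnt, design, lib.size = colSums(cnt) * nf$factors)
  expect_gt(cor(as.vector(w), as.vector(v$weights), method = "spearman"), 0.85)
})

test_that("moderated t reduces to ordinary t as the prior df vanishes", {
  t <- toy_logcpm(n_feat = 40)
  fit0 <- fit_moderated(t$logcpm, t$design,
                        moderation = list(d0 = 0, s0_2 = 1))
  # ordinary t computed independently from the group means
  d <- ncol(t$logcpm) - 4
  cm <- group_contrasts()[, "season"]
  grp <- factor(colnames(t$design)[max.col(t$design)], levels = colnames(t$design))
  ord_t <- apply(t$logcpm, 1, function(y) {
    m <- tapply(y, grp, mean)
    nn <- table(grp)
    s2 <- sum((y - ave(y, grp))^2) / d
    est <- sum(cm * m)
    est / sqrt(s2 * sum(cm^2 / as.numeric(nn)))
  })
  got <- fit0$table
  expect_equal(got$t[got$contrast == "season"], unname(ord_t), tolerance = 1e-8)
})

test_that("identical residual variances are left unshrunk", {
  t <- toy_logcpm(n_feat = 30)
  fitv <- fit_moderated(t$logcpm, t$design,
                        moderation = list(d0 = Inf, s0_2 = 0.25))
  # with full shrinkage every posterior variance equals s0^2: the t equals
  # estimate / (0.5 * unscaled se); verify through the d0 = 0 route
  fit0 <- fit_moderated(t$logcpm, t$design,
                        moderation = list(d0 = 0, s0_2 = 0.25))
  ratio <- fitv$table$t / fit0$table$t
  # ratio = s / s0 per feature, equal across contrasts of a feature
  m <- matrix(ratio, ncol = 3)
  expect_equal(m[, 1], m[, 2], tolerance = 1e-10)
})

test_that("BH adjustment reproduces the step-up procedure", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.02, 0.02)), c(0.02, 0.02))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("type-I error is calibrated on the null simulation", {
  sim <- generate_counts(
    design_spec(n_genes = 2000, samples_per_group = 5),
    module_spec(module_sizes = integer(0)),
    noise_spec(libsize_log_mean = c(oocyte = log(2e6), egg = log(2e6)),
               de_effects = list(), seed = 1))
  tc <- tissue_counts(sim, "oocyte")
  kept <- filter_by_expression(tc$counts, group_labels(tc$metadata))
  lc <- log_cpm(tc$counts[kept, ], tmm_factors(tc$counts[kept, ]))
  design <- group_design(tc$metadata)
  fit <- fit_moderated(lc, design, weights = precision_weights(lc, design))
  for (cn in c("condition", "season", "interaction")) {
    frac <- mean(fit$table$p_value[fit$table$contrast == cn] < 0.05)
    expect_gt(frac, 0.035)
    expect_lt(frac, 0.065)
  }
})

test_that("planted DE genes are recovered and counts nest across alphas", {
  sim <- generate_counts(
    design_spec(n_genes = 2000),
    module_spec(module_sizes = integer(0)),
    noise_spec(libsize_log_mean = c(oocyte = log(2e6), egg = log(2e6)), seed = 2))
  tc <- tissue_counts(sim, "oocyte")
  kept <- filter_by_expression(tc$counts, group_labels(tc$metadata))
  lc <- log_cpm(tc$counts[kept, ], tmm_factors(tc$counts[kept, ]))
  design <- group_design(tc$metadata)
  fit <- fit_moderated(lc, design, weights = precision_weights(lc, design))
  s <- de_summary(fit)
  season05 <- s[s$contrast == "season" & s$alpha == 0.05, ]
  expect_gte(season05$up, 24); expect_lte(season05$up, 36)
  expect_gte(season05$down, 16); expect_lte(season05$down, 24)
  # nestedness: counts at 0.05 never exceed counts at 0.1
  for (cn in unique(s$contrast)) {
    expect_lte(s$up[s$contrast == cn & s$alpha == 0.05],
               s$up[s$contrast == cn & s$alpha == 0.1])
    expect_lte(s$down[s$contrast == cn & s$alpha == 0.05],
               s$down[s$contrast == cn & s$alpha == 0.1])
  }
})

test_that("stronger planted effects give larger moderated t in expectation", {
  mean_abs_t <- function(lfc, seed) {
    sim <- generate_counts(
      design_spec(n_genes = 400),
      module_spec(module_sizes = integer(0)),
      noise_spec(libsize_log_mean = c(oocyte = log(5e5), egg = log(5e5)),
                 de_effects = list(list(tissue = "oocyte", contrast = "season",
                                        n_genes = 40, log2_fc = lfc)),
                 seed = seed))
    tc <- tissue_counts(sim, "oocyte")
    lc <- log_cpm(tc$counts, tmm_factors(tc$counts))
    design <- group_design(tc$metadata)
    fit <- fit_moderated(lc, design)
    de_genes <- sim$truth$de_effects[[1]]$genes
    mean(abs(fit$table$t[fit$table$contrast == "season" &
                           fit$table$feature %in% de_genes]))
  }
  weak <- mean(vapply(1:5, function(s) mean_abs_t(0.5, s), numeric(1)))
  strong <- mean(vapply(1:5, function(s) mean_abs_t(2, s), numeric(1)))
  expect_gt(strong, weak)
})
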