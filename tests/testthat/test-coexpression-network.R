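# Network construction: gene/sample quality filters, scale-free scan,
# topological overlap, module detection, eigengenes, merging and
# module-trait statistics.

toy_expr <- function(n_genes = 30, n_samples = 12, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
         dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples))))
}

# Planted-block expression: each block driven by its own latent factor.
block_expr <- function(sizes, n_bg = 0, n_samples = 22, noise = 0.3, seed = 1) {
  set.seed(seed)
  rows <- list(); labels <- integer(0)
  for (b in seq_along(sizes)) {
    f <- rnorm(n_samples)
    rows[[b]] <- outer(rep(1, sizes[b]), f) +
      matrix(rnorm(sizes[b] * n_samples, 0, noise), sizes[b])
    labels <- c(labels, rep(b, sizes[b]))
  }
  if (n_bg > 0) {
    rows[[length(rows) + 1]] <- matrix(rnorm(n_bg * n_samples), n_bg)
    labels <- c(labels, rep(0L, n_bg))
  }
  expr <- do.call(rbind, rows)
  dimnames(expr) <- list(sprintf("g%03d", seq_len(nrow(expr))),
                         sprintf("s%02d", seq_len(n_samples)))
  list(expr = expr, labels = setNames(labels, rownames(expr)))
}

test_that("gene quality filter drops exactly the bad genes", {
  expr <- toy_expr(10, 10)
  expr[1, ] <- 7            # constant
  expr[2, ] <- 0            # constant at zero
  expr[3, ] <- -1.5         # constant
  expr[4, c(1:5)] <- NA     # 50% missing: at threshold 0.4 must go
  expr[5, c(1:5)] <- NA
  res <- good_genes_filter(expr, max_missing_frac = 0.4)
  expect_setequal(res$dropped, c("g01", "g02", "g03", "g04", "g05"))
  expect_equal(res$n_dropped, 5)
  expect_true("g06" %in% res$kept)
})

test_that("sample outlier detection flags extreme singletons only", {
  expr <- toy_expr(50, 10)
  # identical samples: nothing flagged
  same <- matrix(1:50, 50, 10, dimnames = dimnames(expr))
  expect_length(detect_sample_outliers(same), 0)
  # one sample shifted by 100 sd: flagged
  shifted <- expr
  shifted[, 4] <- shifted[, 4] + 100
  expect_identical(detect_sample_outliers(shifted), "s04")
  expect_error(detect_sample_outliers(expr[, 1:2]), "3 samples")
})

test_that("planted outliers are flagged across seeds", {
  hits <- vapply(1:20, function(s) {
    sim <- small_sim(s, n_genes = 200,
                     modules = module_spec(module_sizes = integer(0)))
    tc <- tissue_counts(sim, "oocyte")
    lc <- log_cpm(tc$counts, NULL)
    victim <- (s %% ncol(lc)) + 1
    lc[, victim] <- lc[, victim] + 30
    identical(detect_sample_outliers(lc), colnames(lc)[victim])
  }, logical(1))
  expect_true(all(hits))
})

test_that("scale-free scan matches the adjacency definition", {
  # complete graph of perfectly correlated genes: k_i = n - 1
  n <- 20
  base <- rnorm(15)
  perfect <- outer(seq_len(n), base, function(i, b) i + 2 * b)
  dimnames(perfect) <- list(sprintf("g%02d", 1:n), sprintf("s%02d", 1:15))
  scan <- scale_free_scan(perfect, betas = c(2, 6))
  expect_equal(scan$mean_connectivity, c(n - 1, n - 1), tolerance = 1e-8)
  # mean connectivity is non-increasing in beta on any matrix
  expr <- toy_expr(60, 15)
  s2 <- scale_free_scan(expr, betas = c(2, 6))
  expect_lte(s2$mean_connectivity[2], s2$mean_connectivity[1])
  # full re-evaluation from the definition on a 100-gene synthetic
  d <- block_expr(c(30, 30), n_bg = 40, seed = 5)
  scan3 <- scale_free_scan(d$expr, betas = 1:10)
  cors <- abs(cor(t(d$expr))); diag(cors) <- 0
  for (i in c(1, 4, 10)) {
    k <- rowSums(cors^scan3$beta[i])
    expect_equal(scan3$mean_connectivity[i], mean(k), tolerance = 1e-10)
    br <- seq(min(k), max(k), length.out = 11)
    bin <- cut(k, br, include.lowest = TRUE)
    freq <- tapply(k, bin, length); cen <- tapply(k, bin, mean)
    ok <- !is.na(freq) & cen > 0
    fit <- lm(log10(freq[ok]) ~ log10(cen[ok]))
    r2 <- summary(fit)$r.squared * ifelse(coef(fit)[2] > 0, -1, 1)
    expect_equal(scan3$r_squared[i], unname(r2), tolerance = 1e-10)
  }
  # beta = 1 adjacency equals |cor| exactly
  expect_equal(adjacency_matrix(d$expr, 1) - diag(nrow(d$expr)) * 0,
               {a <- abs(cor(t(d$expr))); diag(a) <- 1; a}, tolerance = 1e-12)
})

test_that("topological overlap follows the closed form", {
  # 2-gene network: TOM12 reduces to a12
  for (x in c(0.2, 0.5, 0.9)) {
    adj <- matrix(c(1, x, x, 1), 2)
    expect_equal(tom_similarity(adj)[1, 2], x, tolerance = 1e-12)
  }
  # identity adjacency: TOM is the identity
  expect_equal(tom_similarity(diag(4)), diag(4))
  # 4x4 toy vs scalar hand evaluation
  a <- matrix(0, 4, 4)
  a[1, 2] <- a[2, 1] <- 0.8
  a[1, 3] <- a[3, 1] <- 0.4
  a[2, 3] <- a[3, 2] <- 0.6
  a[3, 4] <- a[4, 3] <- 0.3
  a[1, 4] <- a[4, 1] <- 0.1
  a[2, 4] <- a[4, 2] <- 0.2
  diag(a) <- 1
  tom <- tom_similarity(a)
  k <- rowSums(a) - 1
  for (i in 1:3) for (j in (i + 1):4) {
    u <- setdiff(1:4, c(i, j))
    want <- (sum(a[i, u] * a[u, j]) + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    expect_equal(tom[i, j], want, tolerance = 1e-12)
  }
  expect_true(all(tom >= 0 & tom <= 1))
  expect_error(tom_similarity(matrix(c(1, 2, 2, 1), 2)), "0, 1")
})

test_that("module cut recovers separated blocks and honors the size floor", {
  d <- block_expr(c(40, 40), noise = 0.2, seed = 2)
  tom <- tom_similarity(adjacency_matrix(d$expr, 4))
  part <- cut_modules(tom, min_module_size = 30)
  expect_equal(ari(part, d$labels), 1)
  # a 10-gene block with min size 30 stays unassigned
  d2 <- block_expr(c(10), n_bg = 60, noise = 0.2, seed = 3)
  tom2 <- tom_similarity(adjacency_matrix(d2$expr, 4))
  part2 <- cut_modules(tom2, min_module_size = 30)
  expect_true(all(part2[d2$labels == 1] == 0))
})

test_that("planted five-module synthetic is recovered across seeds", {
  ok <- vapply(1:10, function(s) {
    sim <- small_sim(s)
    tc <- tissue_counts(sim, "oocyte")
    lc <- log_cpm(tc$counts, tmm_factors(tc$counts))
    tom <- tom_similarity(adjacency_matrix(lc, 4))
    part <- merge_similar_modules(lc, cut_modules(tom))
    ari(part, sim$truth$oocyte_modules) >= 0.8
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("eigengenes match an independent factorization", {
  d <- block_expr(c(20), n_samples = 15, seed = 4)
  part <- setNames(rep(1L, 20), rownames(d$expr))
  me <- module_eigengene(d$expr, part)
  z <- t(scale(t(d$expr)))
  sv <- svd(z)
  expect_gte(abs(cor(me[, 1], sv$v[, 1])), 1 - 1e-8)
  expect_equal(sd(me[, 1]), 1, tolerance = 1e-10)
  # orientation: mean correlation with members is positive
  expect_gt(mean(cor(me[, 1], t(d$expr))), 0)
  # single-gene module: eigengene is the z-scored profile
  p1 <- setNames(c(1L, rep(0L, 19)), rownames(d$expr))
  me1 <- module_eigengene(d$expr, p1)
  expect_equal(unname(me1[, 1]), unname(as.numeric(scale(d$expr[1, ]))),
               tolerance = 1e-10)
  # perfectly correlated module: eigengene correlates 1 with each member
  perf <- outer(rep(1, 5), rnorm(15)) * c(1, 2, 3, 4, 5)
  dimnames(perf) <- list(paste0("p", 1:5), sprintf("s%02d", 1:15))
  mep <- module_eigengene(perf, setNames(rep(1L, 5), rownames(perf)))
  expect_equal(unname(abs(cor(mep[, 1], t(perf)))[1, ]), rep(1, 5),
               tolerance = 1e-8)
})

test_that("eigengene-similar modules merge to a fixed point", {
  set.seed(6)
  n_samples <- 30
  f <- rnorm(n_samples)
  # two modules driven by the same factor: must merge
  expr <- rbind(outer(rep(1, 20), f) + matrix(rnorm(20 * n_samples, 0, 0.2), 20),
                outer(rep(1, 20), f) + matrix(rnorm(20 * n_samples, 0, 0.2), 20))
  dimnames(expr) <- list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:n_samples))
  part <- setNames(rep(c(1L, 2L), each = 20), rownames(expr))
  merged <- merge_similar_modules(expr, part)
  expect_equal(max(merged), 1)
  # orthogonal modules stay apart
  g <- rnorm(n_samples)
  expr2 <- rbind(outer(rep(1, 20), f) + matrix(rnorm(20 * n_samples, 0, 0.2), 20),
                 outer(rep(1, 20), g) + matrix(rnorm(20 * n_samples, 0, 0.2), 20))
  dimnames(expr2) <- dimnames(expr)
  merged2 <- merge_similar_modules(expr2, part)
  expect_equal(max(merged2), 2)
  # chained similarity merges transitively; post-condition audited
  h <- 0.8 * f + sqrt(1 - 0.64) * rnorm(n_samples)
  i <- 0.8 * h + sqrt(1 - 0.64) * rnorm(n_samples)
  expr3 <- rbind(outer(rep(1, 15), f) + matrix(rnorm(15 * n_samples, 0, 0.1), 15),
                 outer(rep(1, 15), h) + matrix(rnorm(15 * n_samples, 0, 0.1), 15),
                 outer(rep(1, 15), i) + matrix(rnorm(15 * n_samples, 0, 0.1), 15))
  dimnames(expr3) <- list(sprintf("g%02d", 1:45), sprintf("s%02d", 1:n_samples))
  part3 <- setNames(rep(1:3, each = 15), rownames(expr3))
  merged3 <- merge_similar_modules(expr3, part3, cut_height = 0.25)
  if (max(merged3) > 1) {
    me <- module_eigengene(expr3, merged3)
    cc <- cor(me); diag(cc) <- 0
    expect_lt(max(cc), 0.75)
  } else succeed()
})

test_that("module-trait correlation matches the t transform", {
  me <- cbind(ME1 = c(1, 2, 3, 4, 5, 6))
  rownames(me) <- sprintf("s%d", 1:6)
  # hand-picked trait with r = -0.5 against 1..6
  y <- c(4, 6, 2, 5, 1, 3)
  r <- cor(me[, 1], y)
  mt <- module_trait_correlation(me, data.frame(tr = y))
  tstat <- r * sqrt(4 / (1 - r^2))
  expect_equal(mt$r, r, tolerance = 1e-12)
  expect_equal(mt$p_value, 2 * pt(abs(tstat), 4, lower.tail = FALSE),
               tolerance = 1e-10)
  # eigengene equal to the trait coding: r = 1
  season <- rep(c(0, 1), each = 11)
  me2 <- cbind(ME1 = season); rownames(me2) <- sprintf("s%02d", 1:22)
  mt2 <- module_trait_correlation(me2, data.frame(season = season))
  expect_equal(mt2$r, 1)
  expect_lt(mt2$p_value, 1e-12)
  # constant trait: missing with warning
  expect_warning(mt3 <- module_trait_correlation(me2, data.frame(k = rep(1, 22))),
                 "constant")
  expect_true(is.na(mt3$r))
})

test_that("season-coupled modules are detected as significant across seeds", {
  hits <- vapply(1:10, function(s) {
    sim <- small_sim(s)
    tc <- tissue_counts(sim, "oocyte")
    lc <- log_cpm(tc$counts, tmm_factors(tc$counts))
    part <- merge_similar_modules(lc, cut_modules(tom_similarity(adjacency_matrix(lc, 4))))
    if (max(part) == 0) return(FALSE)
    me <- module_eigengene(lc, part)
    traits <- data.frame(season = as.numeric(tc$metadata$season == "late"))
    any(module_trait_correlation(me, traits)$significant)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("partition pipeline is permutation-equivariant", {
  d <- block_expr(c(35, 35), n_bg = 30, seed = 8)
  tom <- tom_similarity(adjacency_matrix(d$expr, 4))
  part <- cut_modules(tom)
  perm <- sample(nrow(d$expr))
  tom_p <- tom_similarity(adjacency_matrix(d$expr[perm, ], 4))
  part_p <- cut_modules(tom_p)
  expect_equal(ari(part_p[names(part)], part), 1)
})
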