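test_that("Brownian covariance matches definition and brute-force oracle", {
  two <- ape::read.tree(text = "(a:1,b:1):0;")
  # two tips, shared stem 2, tip branches 1
  two <- ape::read.tree(text = "((a:1,b:1):2);")
  C2 <- phylo_covariance(two)
  expect_equal(unname(diag(C2)), c(3, 3))
  expect_equal(C2["a", "b"], 2)

  star <- ape::read.tree(text = "(a:1,b:1,c:1);")
  expect_equal(unname(phylo_covariance(star)), diag(3))

  set.seed(3)
  for (rep in 1:5) {
    tr <- ape::rtree(8)
    expect_equal(phylo_covariance(tr, tip_order = tr$tip.label),
                 brute_phylo_cov(tr)[tr$tip.label, tr$tip.label],
                 tolerance = 1e-12)
  }

  expect_error(phylo_covariance(star, tip_order = c("a", "zz")), "zz")
})

test_that("PGLS with identity covariance reproduces OLS to machine precision", {
  set.seed(11)
  x <- rnorm(20); y <- 1 + 0.5 * x + rnorm(20)
  fit <- pgls_fit(y, x, diag(20))
  ols <- stats::lm(y ~ x)
  expect_equal(unname(fit$beta), unname(stats::coef(ols)), tolerance = 1e-10)
  expect_equal(unname(fit$residuals), unname(stats::residuals(ols)), tolerance = 1e-10)
})

test_that("PGLS residuals vanish for an exact linear relation and are V-orthogonal", {
  set.seed(12)
  tr <- ape::rtree(10)
  C <- phylo_covariance(tr)
  x <- rnorm(10)
  y <- 2 - 3 * x
  fit <- pgls_fit(y, x, C)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-10)

  y2 <- y + rnorm(10)
  fit2 <- pgls_fit(y2, x, C)
  X <- cbind(1, x)
  expect_lt(max(abs(t(X) %*% solve(C, fit2$residuals))), 1e-8)
})

test_that("PGLS agrees with an established GLS fit under Brownian correlation", {
  skip_if_not_installed("nlme")
  set.seed(13)
  tr <- ape::rcoal(15) # ultrametric, so the Brownian correlation is C/depth
  C <- phylo_covariance(tr, tip_order = tr$tip.label)
  x <- stats::setNames(rnorm(15), tr$tip.label)
  y <- stats::setNames(1 + 0.4 * x + as.numeric(t(chol(C)) %*% rnorm(15)) * 0.5,
                       tr$tip.label)
  fit <- pgls_fit(y, x, C)
  df <- data.frame(y = y, x = x, sp = tr$tip.label)
  gls_fit <- nlme::gls(y ~ x, data = df,
                       correlation = ape::corBrownian(1, tr, form = ~sp))
  expect_equal(unname(fit$beta), unname(stats::coef(gls_fit)), tolerance = 1e-6)
})

test_that("PGLS recovers the generating slope over replicates", {
  set.seed(14)
  tr <- ape::rtree(25)
  C <- phylo_covariance(tr, tip_order = tr$tip.label)
  L <- t(chol(C))
  slopes <- vapply(1:200, function(i) {
    x <- as.numeric(L %*% rnorm(25))
    y <- 0.6 * x + as.numeric(L %*% rnorm(25)) * 0.3
    pgls_fit(y, x, C)$beta[["slope"]]
  }, numeric(1))
  se <- stats::sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 0.6), 2 * se + 1e-3)
})

test_that("Box-Cox profile maximization finds known optima", {
  withr::with_seed(21, v <- exp(rnorm(200)))
  res <- boxcox_transform(v)
  expect_lt(abs(res$lambda), 0.15)                     # lognormal: lambda ~ 0

  # fixed-exponent branches: lambda 0 is log, lambda 1 preserves shape
  expect_equal(boxcox_transform(v, lambda_grid = 0)$transformed, log(v))
  expect_equal(boxcox_transform(v, lambda_grid = 1)$transformed, v - 1)
  # agreement with the established profile-likelihood implementation
  skip_if_not_installed("MASS")
  bc <- MASS::boxcox(vv ~ 1, data = data.frame(vv = v),
                     lambda = seq(-3, 3, 0.01), plotit = FALSE)
  expect_equal(res$lambda, bc$x[which.max(bc$y)], tolerance = 0.011)

  expect_error(boxcox_transform(rep(2, 10)), "constant")
})

test_that("negative inputs are shifted to positivity before Box-Cox", {
  withr::with_seed(22, r <- rnorm(50))
  res <- boxcox_transform(r)
  expect_equal(res$shift, -min(r) + 1)
  expect_true(all(is.finite(res$transformed)))
})

test_that("Wilks' lambda matches the established MANOVA on random data", {
  set.seed(31)
  for (rep in 1:10) {
    n_g <- sample(2:4, 1)
    g <- factor(rep(seq_len(n_g), each = sample(3:8, 1)))
    Y <- cbind(rnorm(length(g), mean = as.integer(g)),
               rnorm(length(g), mean = 0.5 * as.integer(g)))
    ours <- manova_wilks(Y, g)
    ref <- summary(stats::manova(Y ~ g), test = "Wilks")$stats
    expect_equal(ours$wilks_lambda, unname(ref[1, "Wilks"]), tolerance = 1e-8)
    expect_equal(ours$F_stat, unname(ref[1, "approx F"]), tolerance = 1e-8)
    expect_equal(ours$df1, unname(ref[1, "num Df"]))
    expect_equal(ours$df2, unname(ref[1, "den Df"]))
    # exact-F identity for two responses (three or more groups)
    if (nlevels(g) > 2) {
      rt <- sqrt(ours$wilks_lambda)
      nu_h <- nlevels(g) - 1; nu_e <- length(g) - nlevels(g)
      expect_equal(ours$F_stat, ((1 - rt) / rt) * ((nu_e - 1) / nu_h),
                   tolerance = 1e-12)
    }
  }
})

test_that("identical group means give Wilks' lambda 1 and F 0", {
  Y <- rbind(cbind(c(1, 2, 3), c(2, 4, 5)),
             cbind(c(1, 2, 3), c(2, 4, 5)))
  g <- rep(c("a", "b"), each = 3)
  res <- manova_wilks(Y, g)
  expect_equal(res$wilks_lambda, 1)
  expect_equal(res$F_stat, 0)
  expect_error(manova_wilks(Y[c(1, 2, 4, 5), ], c("a", "a", "b", "c")), "fewer than 2")
})

test_that("the published Wilks' lambda converts to its printed F and effect size", {
  res <- wilks_to_exact_f(0.169, n_groups = 5, df_error = 34)
  expect_equal(res$F_stat, 11.8, tolerance = 0.002)
  expect_equal(res$df1, 8)
  expect_equal(res$df2, 66)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$partial_eta_sq, 0.589, tolerance = 0.001)
})

test_that("pairwise MANOVA is null-calm on duplicated groups and BH-adjusted", {
  set.seed(32)
  Y <- matrix(rnorm(40), ncol = 2)
  g <- rep(c("a", "b"), each = 10)
  Y[g == "b", ] <- Y[g == "a", ] + matrix(rnorm(20, 0, 1e-8), ncol = 2)
  res <- pairwise_manova(Y, g)
  expect_gt(res$pairs$p_raw[1], 0.99)
  expect_true(all(res$pairs$p_adjusted >= res$pairs$p_raw, na.rm = TRUE))
})

test_that("one-way ANOVA reproduces hand-computed F and effect sizes", {
  res <- anova_oneway(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$F_stat, 13.5)
  expect_equal(res$partial_eta_sq, 0.771, tolerance = 0.001)

  same <- anova_oneway(rep(2, 6), rep(c("a", "b"), each = 3))
  expect_equal(same$F_stat, 0)
  expect_equal(same$partial_eta_sq, 0)

  # effect size from published F and dfs: F (4,34) = 10.75 -> 0.558
  expect_equal(10.75 * 4 / (10.75 * 4 + 34), 0.558, tolerance = 0.001)
  expect_equal(7.578 * 4 / (7.578 * 4 + 34), 0.471, tolerance = 0.001)

  sep <- anova_oneway(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  expect_true(is.infinite(sep$F_stat))
  expect_equal(sep$p_value, 0)
})

test_that("Kruskal-Wallis and Dunn match hand computations", {
  y <- c(1, 2, 3, 4, 5, 6); g <- rep(c("a", "b"), each = 3)
  expect_equal(kruskal_wallis(y, g)$H, 3.857143, tolerance = 1e-6)
  expect_equal(kruskal_wallis(rep(1, 6), g)$H, 0)

  dn <- dunn_pairwise(y, g)
  expect_equal(abs(dn$pairs$statistic), 1.963961, tolerance = 1e-6)

  same <- dunn_pairwise(rep(c(1, 2, 3), 2), g)
  expect_equal(same$pairs$statistic, 0)
  expect_equal(same$pairs$p_raw, 1)
})

test_that("Kruskal-Wallis H is invariant in distribution under label permutation", {
  withr::with_seed(33, {
    y <- rnorm(24); g <- rep(letters[1:3], each = 8)
    h_obs <- kruskal_wallis(y, g)$H
    h_perm <- vapply(1:500, function(i) kruskal_wallis(y, sample(g))$H, numeric(1))
    # observed H from exchangeable data is not extreme among permutations
    expect_gt(mean(h_perm >= h_obs), 0.01)
    p_perm <- vapply(h_perm, function(h) stats::pchisq(h, 2, lower.tail = FALSE),
                     numeric(1))
    expect_gt(suppressWarnings(stats::ks.test(p_perm, "punif"))$p.value, 1e-4)
  })
})

test_that("Dunn z matches a brute-force mean-rank computation on three groups", {
  withr::with_seed(34, {
    y <- round(rnorm(18), 1) # ties likely at 1 decimal
    g <- rep(c("a", "b", "c"), each = 6)
    dn <- dunn_pairwise(y, g)
    N <- length(y); r <- rank(y)
    ties <- table(y)
    tt <- sum(ties^3 - ties) / (12 * (N - 1))
    for (k in seq_len(nrow(dn$pairs))) {
      g1 <- dn$pairs$group1[k]; g2 <- dn$pairs$group2[k]
      z <- (mean(r[g == g1]) - mean(r[g == g2])) /
        sqrt((N * (N + 1) / 12 - tt) * (1 / 6 + 1 / 6))
      expect_equal(dn$pairs$statistic[k], z, tolerance = 1e-12)
    }
  })
})

test_that("BH adjustment matches the step-up oracle and is idempotent", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(35)
  for (rep in 1:10) {
    p <- runif(sample(3:12, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, brute_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_false(is.unsorted(adj[order(p)])) # monotone in raw p
  }
  # a fully tied step-up family re-adjusts to itself
  adj <- bh_fdr(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(bh_fdr(adj), adj)
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("pooled-SD pairwise contrasts match the standard post-hoc t tests", {
  withr::with_seed(36, {
    y <- rnorm(30, mean = rep(c(0, 0.5, 2), each = 10))
    g <- rep(c("a", "b", "c"), each = 10)
    ours <- pairwise_anova(y, g)
    ref <- stats::pairwise.t.test(y, g, p.adjust.method = "none", pool.sd = TRUE)
    expect_equal(ours$pairs$p_raw[ours$pairs$group1 == "a" & ours$pairs$group2 == "b"],
                 ref$p.value["b", "a"], tolerance = 1e-12)
    expect_equal(ours$pairs$p_raw[ours$pairs$group1 == "b" & ours$pairs$group2 == "c"],
                 ref$p.value["c", "b"], tolerance = 1e-12)
    expect_equal(ours$pairs$p_adjusted,
                 unname(bh_fdr(ours$pairs$p_raw)))
  })
})
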