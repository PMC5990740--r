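test_that("distinct group means give a decisive MANOVA and CER contrasts", {
  cfg <- comparative_config(brownian_sd = 0, residual_sd = 1e-4,
                            mass_brownian_sd = 0.5, seed = 8)
  tbl <- simulate_species_dataset(cfg)
  res <- run_group_comparison(tbl, cfg$tree)
  expect_lt(res$manova$p_value, 0.001)
  cer_pairs <- res$per_variable$cer$pairwise_anova$pairs
  key <- cer_pairs$group1 == "mammaliamorph" | cer_pairs$group2 == "mammaliamorph"
  np <- cer_pairs$group1 == "non_probainognathian" | cer_pairs$group2 == "non_probainognathian"
  expect_lt(cer_pairs$p_adjusted[key & np], 0.001)
})

test_that("the comparison returns every family of tests with sane structure", {
  cfg <- comparative_config(seed = 5)
  res <- run_group_comparison(simulate_species_dataset(cfg), cfg$tree)
  td <- tidy(res)
  expect_setequal(unique(td$family),
                  c("manova", "pairwise_manova", "anova", "pairwise_anova",
                    "kruskal_wallis", "dunn"))
  # 5 groups -> 10 unordered pairs per pairwise family
  expect_equal(sum(td$family == "pairwise_manova"), 10L)
  expect_equal(sum(td$family == "dunn" & td$variable == "cer"), 10L)
  expect_true(all(td$p_adjusted >= td$p_value - 1e-12, na.rm = TRUE))
  # pairwise matrices are symmetric with the diagonal omitted
  m <- res$pairwise_manova$p_matrix
  expect_true(all(is.na(diag(m))))
  expect_equal(m, t(m))
  g <- glance(res)
  expect_equal(g$n, 39L)
  expect_equal(g$df1, 8)
  expect_equal(g$df2, 66)
  # Box-Cox lambda maximizes the stored profile for each variable
  for (var in c("dsr", "cer")) {
    bc <- res$per_variable[[var]]$boxcox
    expect_equal(bc$lambda, bc$profile$lambda[which.max(bc$profile$log_likelihood)])
  }
})

test_that("exclusions and group reassignment are honoured", {
  cfg <- comparative_config(seed = 6)
  tbl <- simulate_species_dataset(cfg)
  drop_sp <- tbl$species[tbl$group == "diapsid"][1]
  move_sp <- tbl$species[tbl$group == "non_probainognathian"][1]
  res <- run_group_comparison(tbl, cfg$tree, exclude = drop_sp,
                              assign = stats::setNames("mammaliamorph", move_sp))
  expect_equal(nrow(res$data), 38L)
  expect_false(drop_sp %in% res$data$species)
  expect_equal(res$data$group[res$data$species == move_sp], "mammaliamorph")
  expect_equal(sum(res$data$group == "mammaliamorph"), 3L)
})

test_that("per-tooth tables aggregate to species means by default", {
  cfg <- comparative_config(seed = 7, n_teeth = 3L)
  tbl <- simulate_species_dataset(cfg)
  expect_equal(nrow(tbl), 39L * 3L)
  res <- run_group_comparison(tbl, cfg$tree)
  expect_equal(nrow(res$data), 39L)
  sp1 <- tbl$species[1]
  expect_equal(res$data$cer_um_d[res$data$species == sp1],
               mean(tbl$cer_um_d[tbl$species == sp1]))
  # tooth-level option keeps rows as data points
  res_t <- run_group_comparison(tbl, cfg$tree, unit = "tooth")
  expect_equal(nrow(res_t$data), 117L)
})

test_that("MANOVA p-values are calibrated under label permutation", {
  cfg <- comparative_config(seed = 9, brownian_sd = 0)
  tbl <- simulate_species_dataset(cfg)
  tree <- cfg$tree
  # permuting group labels destroys the effect; p should look uniform
  withr::with_seed(10, {
    pvals <- vapply(1:60, function(i) {
      t2 <- tbl
      t2$group <- sample(t2$group)
      sizes <- table(t2$group)
      while (any(sizes < 2)) { t2$group <- sample(t2$group); sizes <- table(t2$group) }
      run_group_comparison(t2, tree)$manova$p_value
    }, numeric(1))
  })
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("plot methods return ggplot objects", {
  cfg <- comparative_config(seed = 4)
  tbl <- simulate_species_dataset(cfg)
  expect_s3_class(plot_growth_rates(tbl), "ggplot")
  expect_s3_class(autoplot(run_group_comparison(tbl, cfg$tree)), "ggplot")
  expect_s3_class(autoplot(demo_section(n_days = 6)), "ggplot")
})
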