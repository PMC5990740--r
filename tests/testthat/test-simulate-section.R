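test_that("the activation front advances as the integral of the extension rate", {
  sec <- demo_section(cer = 20, n_days = 10)
  last <- sec$enamel_lines[[10]]
  expect_equal(intersect_with_edj(last, sec$edj)$arc, 200, tolerance = 1e-6)

  # piecewise schedule: arc covered by day T = integral of c, per front
  cfg <- section_config(cer = c(rep(90, 5), rep(10, 5)), n_days = 10)
  sec2 <- simulate_section(cfg)
  s_true <- cumsum(cfg$cer)
  for (t in c(2, 5, 7, 10)) {
    arc <- intersect_with_edj(sec2$enamel_lines[[t]], sec2$edj)$arc
    expect_lt(abs(arc - s_true[t]) / s_true[t], 0.001)
  }
})

test_that("every R-th daily front is an accentuated long-period line", {
  sec <- demo_section(n_days = 10)
  kinds <- vapply(sec$enamel_lines, function(l) l$kind, character(1))
  expect_equal(sum(kinds == "long_period"), 5L)
  expect_true(all(vapply(sec$enamel_lines[kinds == "long_period"],
                         function(l) l$accentuated, logical(1))))
  days <- vapply(sec$enamel_lines[kinds == "long_period"],
                 function(l) l$day_index, integer(1))
  expect_equal(days, c(2L, 4L, 6L, 8L, 10L))
})

test_that("daily line spacing along the EDJ normal equals the secretion rate", {
  sec <- demo_section(cer = 20, dsr = 1.5, n_days = 12, jitter_sd = 0)
  edj <- sec$edj
  for (s in c(20, 60, 100)) {
    origin <- as.numeric(point_at_arc(edj, s)[1, ])
    dir <- as.numeric(normal_at_arc(edj, s)[1, ])
    cross <- sort(unlist(lapply(sec$enamel_lines, function(l) {
      h <- enamelgrowth:::ray_crossings(origin, dir, 50, l$path)
      h$arc_a[h$arc_a > 1e-9][1]
    })))
    expect_equal(unname(diff(cross)), rep(1.5, length(cross) - 1), tolerance = 1e-9)
  }
})

test_that("enamel and dentine lines of the same day share an EDJ intersection", {
  sec <- demo_section(n_days = 8)
  for (t in c(2, 5, 8)) {
    ae <- intersect_with_edj(sec$enamel_lines[[t]], sec$edj)$arc
    ad <- intersect_with_edj(sec$dentine_lines[[t]], sec$edj)$arc
    expect_equal(ae, ad, tolerance = 1e-6)
  }
})

test_that("a schedule reaching the cervix stops there and reports the coverage day", {
  expect_message(
    sec <- simulate_section(section_config(cer = 20, n_days = 10, edj_length = 100)),
    "day 5"
  )
  expect_equal(length(sec$enamel_lines), 5L)
  expect_equal(attr(sec, "coverage_day"), 5L)
})

test_that("simulation is reproducible from its seed", {
  a <- simulate_section(section_config(jitter_sd = 0.2, seed = 99))
  b <- simulate_section(section_config(jitter_sd = 0.2, seed = 99))
  expect_identical(a$enamel_lines[[3]]$path, b$enamel_lines[[3]]$path)
})

test_that("species simulator hits group means exactly with all noise off", {
  cfg <- comparative_config(brownian_sd = 0, residual_sd = 0, mass_slope_b = 0,
                            mass_brownian_sd = 0)
  tbl <- simulate_species_dataset(cfg)
  means <- tapply(tbl$cer_um_d, tbl$group, mean)
  expect_equal(means[["non_probainognathian"]], 86.0, tolerance = 1e-12)
  expect_equal(means[["mammaliamorph"]], 10.1, tolerance = 1e-12)
  expect_equal(tapply(tbl$dsr_um_d, tbl$group, mean)[["hypsodont_mammal"]], 7.0)
  # every species at its group mean exactly
  expect_true(all(abs(tbl$cer_um_d - c(86, 10.1, 25, 12, 90)[
    match(tbl$group, c("non_probainognathian", "mammaliamorph", "diapsid",
                       "non_hypsodont_mammal", "hypsodont_mammal"))
  ]) < 1e-9))
})

test_that("star tree yields a diagonal trait covariance", {
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  C <- phylo_covariance(star)
  expect_equal(unname(C), diag(4))
})

test_that("tip covariance over replicates converges to brownian_sd^2 * C", {
  tree <- ape::read.tree(text = "((a:0.5,b:0.5):0.5,(c:0.7,d:0.7):0.3);")
  C <- phylo_covariance(tree)
  cfg0 <- comparative_config(
    tree = tree,
    group_assignment = stats::setNames(rep("non_probainognathian", 4), tree$tip.label),
    mass_slope_b = 0, residual_sd = 0, brownian_sd = 0.3, mass_brownian_sd = 0,
    pin_group_means = FALSE
  )
  reps <- vapply(1:500, function(i) {
    cfg <- cfg0; cfg$seed <- i
    log10(simulate_species_dataset(cfg)$cer_um_d)
  }, numeric(4))
  emp <- stats::cov(t(reps))
  expect_lt(norm(emp - 0.3^2 * C, "F") / norm(0.3^2 * C, "F"), 0.1)
})

test_that("unassigned tips are a configuration error listing them", {
  tree <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  expect_error(
    comparative_config(tree = tree,
                       group_assignment = c(a = "diapsid", b = "diapsid")),
    "c"
  )
})
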