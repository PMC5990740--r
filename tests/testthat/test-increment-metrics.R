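test_that("DSR recovers the secretion rate on clean synthetic enamel", {
  sec <- demo_section(cer = 20, dsr = 1.5, n_days = 12)
  est <- measure_dsr(sec)
  expect_false(est$flagged)
  expect_equal(est$mean_dsr, 1.5, tolerance = 0.005)
  expect_true(all(est$samples$n_gaps >= 1))
  expect_true(all(est$samples$spacing > 0))

  # doubled line density (sub-daily misread) halves the apparent DSR
  sub <- demo_section(cer = 20, dsr = 0.75, n_days = 12)
  expect_equal(measure_dsr(sub)$mean_dsr, 0.75, tolerance = 0.005)
})

test_that("DSR under jitter stays within a few percent over many gaps", {
  sec <- simulate_section(section_config(cer = 30, dsr = 3, n_days = 14,
                                         jitter_sd = 0.1, seed = 5))
  est <- suppressWarnings(measure_dsr(sec, window = 5))
  expect_gt(length(est$gaps), 200)
  expect_lt(abs(est$mean_dsr - 3) / 3, 0.02)
})

test_that("a section with fewer than two daily lines is flagged, not an error", {
  sec <- demo_section(n_days = 10)
  sec$enamel_lines <- sec$enamel_lines[1]
  est <- measure_dsr(sec)
  expect_true(est$flagged)
  expect_true(is.na(est$mean_dsr))
  expect_equal(nrow(est$samples), 0L)
})

test_that("prism_path mode agrees with prismless mode on thin straight enamel", {
  sec <- demo_section(cer = 20, dsr = 1.5, n_days = 12)
  a <- measure_dsr(sec, mode = "prismless")$mean_dsr
  b <- measure_dsr(sec, mode = "prism_path")$mean_dsr
  expect_equal(a, b, tolerance = 0.02)
})

test_that("cumulative-length CER reproduces constant and piecewise schedules", {
  sec <- demo_section(cer = 20, dsr = 1.5, n_days = 10)
  s2 <- cumulative_cer(sec, p = 2)
  expect_equal(s2$average_cer, 20, tolerance = 1e-6)
  expect_equal(s2$sum_x, 10)
  expect_equal(s2$sum_y, 200, tolerance = 1e-6)
  expect_equal(s2$segments$extension_rate,
               s2$segments$edj_advance_y / s2$segments$days_x)

  s1 <- cumulative_cer(sec, p = 1)
  expect_equal(s1$average_cer, 40, tolerance = 1e-6)

  # two plateaus: 90 then 10 um/day; average is the pooled ratio 50
  pw <- simulate_section(section_config(cer = c(rep(90, 5), rep(10, 5)),
                                        dsr = 1.5, n_days = 10))
  spw <- cumulative_cer(pw, p = 2)
  expect_equal(spw$average_cer, 50, tolerance = 1e-6) # Sum(y)/Sum(x) closed form
  plateau <- spw$segments$extension_rate
  expect_lt(abs(plateau[1] - 90) / 90, 0.05)
  expect_lt(abs(plateau[length(plateau)] - 10) / 10, 0.05)
})

test_that("the 1-day assumption exactly doubles the 2-day average CER", {
  for (seed in 1:5) {
    sec <- simulate_section(section_config(
      cer = 30, dsr = 2, n_days = 12, jitter_sd = 0.15, seed = seed
    ))
    a1 <- suppressWarnings(cumulative_cer(sec, p = 1))
    a2 <- suppressWarnings(cumulative_cer(sec, p = 2))
    expect_equal(a1$average_cer, 2 * a2$average_cer, tolerance = 1e-12)
    expect_equal(a1$sum_y, a2$sum_y)
    expect_equal(a2$sum_x, 2 * a1$sum_x)
  }
})

test_that("segment EDJ advances add up to the anchor-to-anchor arc distance", {
  sec <- demo_section(cer = 25, dsr = 2, n_days = 12)
  s <- cumulative_cer(sec, p = 2)
  expect_equal(sum(s$segments$edj_advance_y),
               s$segments$arc_end[nrow(s$segments)] - s$segments$arc_start[1])
})

test_that("CER and DSR estimators recover ground truth across the design grid", {
  for (cer in c(5, 50)) {
    for (dsr in c(1, 4)) {
      sec <- simulate_section(section_config(cer = cer, dsr = dsr, n_days = 16))
      expect_lt(abs(cumulative_cer(sec, 2)$average_cer - cer) / cer, 0.03)
      expect_lt(abs(measure_dsr(sec)$mean_dsr - dsr) / dsr, 0.03)
    }
  }
})

test_that("dentine extension rate matches the shared front schedule", {
  sec <- simulate_section(section_config(cer = 88, dsr = 1.5, n_days = 12))
  expect_lt(abs(dentine_extension_rate(sec)$rate - 88) / 88, 0.01)

  # exactly two daily lines one day apart with a 15 um EDJ gap
  sec2 <- simulate_section(section_config(cer = 15, dsr = 1.5, n_days = 6))
  sec2$dentine_lines <- sec2$dentine_lines[3:4]
  expect_equal(dentine_extension_rate(sec2)$rate, 15, tolerance = 1e-6)

  sec3 <- sec2
  sec3$dentine_lines <- sec3$dentine_lines[1]
  expect_error(dentine_extension_rate(sec3), "at least 2")
})

test_that("enamel CER at the true periodicity concords with the dentine rate", {
  sec <- simulate_section(section_config(cer = 40, dsr = 2, n_days = 12))
  dent <- dentine_extension_rate(sec)
  enam <- cumulative_cer(sec, p = 2, span = dent$span)$average_cer
  expect_lt(abs(enam - dent$rate) / dent$rate, 0.02)
})

test_that("tooth-level grand averages pool segments, not per-cusp means", {
  one <- cumulative_cer(demo_section(n_days = 10), p = 2)
  expect_equal(grand_average(list(one))$average_cer, one$average_cer)

  # hand computation: (200 + 100) / (10 + 10) = 15, not mean(20, 10) when
  # formation times differ the pooled and unweighted means diverge
  a <- one; a$sum_x <- 10; a$sum_y <- 200
  b <- one; b$sum_x <- 10; b$sum_y <- 100
  expect_equal(grand_average(list(a, b))$average_cer, 15)
  cda <- one; cda$sum_x <- 5; cda$sum_y <- 200   # 40 um/d over 5 d
  cdb <- one; cdb$sum_x <- 20; cdb$sum_y <- 100  # 5 um/d over 20 d
  pooled <- grand_average(list(cda, cdb))$average_cer
  expect_equal(pooled, 300 / 25)
  expect_false(isTRUE(all.equal(pooled, mean(c(40, 5)))))

  expect_error(grand_average(list()), "length")
})
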