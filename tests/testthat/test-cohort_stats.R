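test_that("ANCOVA recovers a deterministic group shift exactly", {
  set.seed(21)
  tab <- make_stats_table(n = 10, gen = function(g, w, base)
    base + 5 * (g == "T2D"))
  # zero-residual fixture: lm legitimately warns about the perfect fit
  r <- suppressWarnings(ancova_group_effect(tab, "m", "IPL", 8))
  expect_equal(r$estimate, 5, tolerance = 1e-10)
  expect_lt(r$p_value, 1e-12)
  expect_true(r$significant)
  expect_equal(r$test_name, "ancova")
  expect_equal(r$n_control, 10)
  expect_equal(r$n_t2d, 10)
})

test_that("ANCOVA errors on insufficient or degenerate data", {
  set.seed(22)
  tab <- make_stats_table(n = 2)
  expect_error(ancova_group_effect(tab, "m", "IPL", 8), "insufficient")

  tab2 <- make_stats_table(n = 5, gen = function(g, w, base) rep(1, length(g)))
  expect_error(ancova_group_effect(tab2, "m", "IPL", 8), "degenerate")
})

test_that("animals missing the baseline are dropped and counted", {
  set.seed(23)
  tab <- make_stats_table(n = 10)
  tab <- tab[!(tab$animal_id == "a01" & tab$week == 0), ]
  r <- ancova_group_effect(tab, "m", "IPL", 8)
  expect_equal(r$n_dropped, 1L)
  expect_equal(r$n_control + r$n_t2d, 19L)
})

test_that("without the covariate, ANCOVA reduces to the pooled t-test", {
  set.seed(24)
  tab <- make_stats_table(n = 12)
  r <- ancova_group_effect(tab, "m", "IPL", 8, baseline_week = NULL)
  at <- tab[tab$week == 8, ]
  tt <- t.test(value ~ group, data = at, var.equal = TRUE)
  expect_equal(r$p_value, tt$p.value, tolerance = 1e-12)
})

test_that("ANCOVA holds its nominal type-I error under the null", {
  set.seed(25)
  p <- replicate(500, {
    tab <- make_stats_table(n = 20, gen = function(g, w, base)
      base + rnorm(length(g), 0, 0.5))
    ancova_group_effect(tab, "m", "IPL", 8)$p_value
  })
  expect_gt(mean(p <= 0.05), 0.025)
  expect_lt(mean(p <= 0.05), 0.08)
})

test_that("null p-values are uniform when the baseline is strongly predictive", {
  set.seed(26)
  p <- replicate(400, {
    tab <- make_stats_table(n = 15, gen = function(g, w, base)
      base + rnorm(length(g), 0, 0.2))
    ancova_group_effect(tab, "m", "IPL", 8)$p_value
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("the normality gate routes to the expected test", {
  set.seed(27)
  x <- rnorm(30); y <- rnorm(30)
  stopifnot(shapiro.test(x)$p.value > 0.05, shapiro.test(y)$p.value > 0.05)
  expect_equal(gated_two_sample_test(x, y)$test_name, "t_test")

  set.seed(28)
  e <- rexp(30)
  stopifnot(shapiro.test(e)$p.value <= 0.05)
  expect_equal(gated_two_sample_test(rnorm(30), e)$test_name, "mann_whitney")
})

test_that("identical samples are never significant", {
  set.seed(29)
  x <- rnorm(15)
  r <- gated_two_sample_test(x, x)
  expect_gt(r$p_value, 0.99)
  expect_false(r$significant)
  expect_equal(r$estimate, 0)
})

test_that("constant samples route to Mann-Whitney with a warning", {
  set.seed(131)
  expect_warning(r <- gated_two_sample_test(rnorm(10), c(rep(2, 9), 3)),
                 "Shapiro-Wilk undefined")
  expect_equal(r$test_name, "mann_whitney")
  expect_true(is.finite(r$p_value))

  suppressWarnings(req <- gated_two_sample_test(rep(1, 10), rep(1, 12)))
  expect_equal(req$p_value, 1)
  expect_false(req$significant)
})

test_that("the gated test holds its nominal type-I error under the null", {
  set.seed(30)
  p <- replicate(800, gated_two_sample_test(rnorm(20), rnorm(20))$p_value)
  expect_gt(mean(p <= 0.05), 0.025)
  expect_lt(mean(p <= 0.05), 0.08)
})

test_that("five-number summaries match hand arithmetic", {
  s <- five_number_summary(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3)
  expect_equal(s$q25, 2)
  expect_equal(s$q75, 4)
  expect_equal(s$mean, 3)
  expect_equal(s$sem, sqrt(2.5) / sqrt(5))

  one <- five_number_summary(42)
  expect_equal(one$min, 42)
  expect_equal(one$max, 42)
  expect_equal(one$median, 42)
  expect_true(is.na(one$sem))

  expect_equal(five_number_summary(rep(7, 4))$sem, 0)
  expect_error(five_number_summary(numeric()), "empty cell")
})

test_that("cohort summaries respect quartile ordering invariants", {
  set.seed(31)
  tab <- make_stats_table(n = 8, weeks = c(0, 4, 8))
  s <- summarize_cohort(tab)
  expect_true(all(s$q25 <= s$median & s$median <= s$q75))
  expect_true(all(s$min <= s$q25 & s$q75 <= s$max))
  expect_equal(nrow(s), 2 * 3)  # groups x weeks, one layer/measure
})

test_that("run_full_comparison covers the grid and honours the FDR flag", {
  set.seed(32)
  tab <- rbind(
    make_stats_table(n = 8, weeks = c(0, 4, 8, 12),
                     gen = function(g, w, base)
                       base + 2 * (g == "T2D") * (w >= 8) +
                         rnorm(length(g), 0, 0.1)),
    make_stats_table(n = 8, weeks = c(0, 4, 8, 12), layer = "INL"))
  res <- run_full_comparison(tab)
  expect_equal(nrow(res), 2 * 3)  # 2 layers x 3 follow-up weeks
  ipl8 <- res[res$layer == "IPL" & res$week %in% c(8, 12), ]
  expect_true(all(ipl8$significant))

  resf <- run_full_comparison(tab, fdr = TRUE)
  expect_true(all(resf$p_adjusted >= resf$p_value))

  empty <- run_full_comparison(tab, endpoints = data.frame(
    measure = character(), test = character()))
  expect_equal(nrow(empty), 0L)
})

test_that("empirical power is monotone in the injected effect size", {
  set.seed(33)
  power <- sapply(c(0, 0.3, 0.6, 1.0), function(eff) {
    mean(replicate(300, {
      tab <- make_stats_table(n = 12, gen = function(g, w, base)
        base + eff * (g == "T2D") + rnorm(length(g), 0, 0.5))
      ancova_group_effect(tab, "m", "IPL", 8)$p_value <= 0.05
    }))
  })
  expect_true(all(diff(power) >= 0))
  expect_lt(power[1], 0.12)
  expect_gt(power[4], 0.9)
})
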