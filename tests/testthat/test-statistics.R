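# Group summaries, the one-sided Mann-Whitney battery, the KS subgroup
# check and the metric regression.

test_that("group_summary interpolates order statistics", {
  expect_equal(group_summary(c(1, 2, 3, 4, 5)),
               c(median = 3, q25 = 2, q75 = 4))
  expect_equal(group_summary(7), c(median = 7, q25 = 7, q75 = 7))
  expect_error(group_summary(numeric(0)), "empty")

  set.seed(51)
  x <- rnorm(10000)
  s <- group_summary(x)
  expect_lt(abs(s[["median"]]), 0.04)
  expect_lt(abs(s[["q25"]] + qnorm(0.75)), 0.04)
  expect_lt(abs(s[["q75"]] - qnorm(0.75)), 0.04)
})

test_that("mwu_one_sided agrees with exhaustive enumeration on small untied samples", {
  res <- mwu_one_sided(c(3, 4), c(1, 2), "greater")
  expect_equal(res$p, 1 / 6, tolerance = 1e-12)
  expect_equal(res$U, 4)

  set.seed(52)
  for (sizes in list(c(2, 2), c(2, 3), c(3, 3), c(2, 4), c(3, 4), c(4, 4))) {
    for (rep in 1:8) {
      pool <- sample(seq_len(20), sum(sizes)) + runif(sum(sizes), 0, 0.1)
      x <- pool[seq_len(sizes[1])]
      y <- pool[-seq_len(sizes[1])]
      for (alt in c("greater", "less")) {
        expect_equal(mwu_one_sided(x, y, alt)$p,
                     mwu_enumeration_p(x, y, alt), tolerance = 1e-10,
                     label = sprintf("n=(%d,%d) alt=%s", sizes[1], sizes[2], alt))
      }
    }
  }
})

test_that("mwu_one_sided gives no one-sided evidence for identical groups", {
  res <- mwu_one_sided(rep(2, 6), rep(2, 9), "greater")
  expect_gte(res$p, 0.5)
  expect_error(mwu_one_sided(numeric(0), 1:3), "non-empty")
})

test_that("mwu type-I error at alpha = 0.05 stays inside the binomial band", {
  set.seed(53)
  n_sim <- 2000
  rejections <- 0L
  for (i in seq_len(n_sim)) {
    x <- rnorm(16)
    y <- rnorm(60)
    if (mwu_one_sided(y, x, "greater")$p < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_sim
  band <- 2.807 * sqrt(0.05 * 0.95 / n_sim) # 99.5% binomial band
  expect_lt(rate, 0.05 + band)
  expect_gt(rate, 0.05 - band)
})

test_that("the KS subgroup check compares shapes after z-scoring", {
  x <- rnorm(200)
  p <- ks_subgroup_check(list(a = x, b = x))
  expect_equal(p["a", "a"], 1)
  expect_equal(dim(p), c(2, 2))
  expect_equal(p["a", "b"], p["b", "a"])

  # same shape at different location/scale: rejection rate stays near alpha
  set.seed(54)
  rej <- mean(replicate(200, {
    p2 <- ks_subgroup_check(list(s1 = rnorm(200, 5, 3), s2 = rnorm(200)))
    p2["s1", "s2"] < 0.05
  }))
  expect_lt(rej, 0.1)

  # heavy-tailed vs normal is detected after normalization
  set.seed(55)
  p3 <- ks_subgroup_check(list(norm = rnorm(500), heavy = rt(500, df = 1)))
  expect_lt(p3["norm", "heavy"], 0.05)

  expect_error(ks_subgroup_check(list(rep(1, 5), rnorm(5))), "zero-variance")
  expect_error(ks_subgroup_check(list(rnorm(5))), "length")
})

test_that("metric_regression returns OLS plus Pearson r", {
  x <- seq(0.6, 0.9, length.out = 20)
  y <- 5 - 4 * x
  fit <- metric_regression(y, x)
  expect_equal(fit$pearson_r, -1, tolerance = 1e-12)
  expect_equal(fit$slope, -4, tolerance = 1e-10)
  expect_equal(fit$intercept, 5, tolerance = 1e-10)

  set.seed(56)
  fit2 <- metric_regression(rnorm(10000), runif(10000))
  expect_lt(abs(fit2$pearson_r), 0.05)

  expect_error(metric_regression(1:5, rep(1, 5)), "zero variance")
  expect_error(metric_regression(1:2, 1:2), "at least 3")
})

test_that("significance stars follow the violin-figure thresholds", {
  expect_equal(significance_stars(c(0.004, 5e-6, 0.04, NA)),
               c("*", "**", "", ""))
})

test_that("hypothesis_battery reports all group x metric rows with one-sided tests", {
  presets <- cached_presets()
  co <- generate_cohort(presets, seed = 61)
  bat <- hypothesis_battery(co)
  expect_equal(nrow(bat), 15)
  expect_true(all(is.na(bat$p_value[bat$group == "CTL"])))
  expect_true(all(bat$q25 <= bat$median & bat$median <= bat$q75))
  # calibrated separation: every glioma/meningioma row significant
  strong <- bat[bat$group %in% c("LGG", "HGG", "MNG"), ]
  expect_true(all(strong$p_value < 0.05))

  tab <- battery_table(bat)
  expect_equal(ncol(tab), 7) # metric, statistic + 5 groups
  expect_equal(nrow(tab), 12) # 3 metrics x 4 statistic rows

  no_ctl <- co[co$group != "CTL", ]
  expect_error(hypothesis_battery(no_ctl), "CTL")
})

test_that("hypothesis_battery stays quiet under the null and handles n = 1 groups", {
  set.seed(62)
  lv <- c("CTL", "LGG", "HGG", "MNG", "MET")
  stars <- 0L
  for (i in 1:10) {
    null_cohort <- data.frame(
      group = factor(rep(lv, times = c(16, 71, 117, 64, 93)), levels = lv),
      tau_ns = rlnorm(361, 0.5, 0.3),
      redox_ratio = runif(361, 0.5, 0.9),
      r_flavin = rlnorm(361, 0, 0.2)
    )
    bat <- hypothesis_battery(null_cohort)
    stars <- stars + sum(bat$stars != "", na.rm = TRUE)
  }
  expect_lte(stars, 4) # 120 tests at the 0.005 star threshold

  tiny <- data.frame(group = factor(c(rep("CTL", 6), "LGG"),
                                    levels = c("CTL", "LGG")),
                     tau_ns = c(1.1, 1.2, 1.3, 1.4, 1.5, 1.6, 3.5),
                     redox_ratio = c(0.84, 0.83, 0.82, 0.85, 0.86, 0.84, 0.7),
                     r_flavin = c(0.9, 0.85, 0.88, 0.92, 0.87, 0.9, 1.3))
  bat <- hypothesis_battery(tiny)
  lgg_tau <- bat[bat$group == "LGG" & bat$metric == "tau_ns", ]
  expect_equal(lgg_tau$median, 3.5)
  expect_equal(lgg_tau$p_value, 1 / 7, tolerance = 1e-10) # exact, n1+n2 = 7
})
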