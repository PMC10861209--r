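test_that("two-group t test matches the closed form", {
  cmp0 <- compare_groups(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(cmp0$statistic, 0)
  expect_equal(cmp0$p_value, 1)

  # {1,2,3} vs {2,3,4}: pooled sd 1, se sqrt(2/3), t = -1.2247, df 4
  cmp <- compare_groups(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
  t_hand <- (2 - 3) / sqrt(1 * (1 / 3 + 1 / 3))
  expect_equal(cmp$statistic, t_hand, tolerance = 1e-9)
  expect_equal(cmp$statistic, -1.2247, tolerance = 1e-4)
  expect_equal(cmp$p_value, 2 * stats::pt(t_hand, df = 4), tolerance = 1e-9)
  expect_equal(cmp$p_value, 0.2879, tolerance = 1e-3)
})

test_that("ANOVA + Tukey flag only the shifted group", {
  set.seed(1)
  vals <- c(rnorm(8, 0, 0.5), rnorm(8, 0.2, 0.5), rnorm(8, 8, 0.5))
  grp <- rep(c("a", "b", "c"), each = 8)
  cmp <- compare_groups(vals, grp)
  expect_equal(cmp$test, "anova_tukey")
  expect_lt(cmp$p_value, 0.001)
  tk <- cmp$tukey
  involves_c <- grepl("c", tk$pair)
  expect_true(all(tk$p_adj[involves_c] < 0.001))
  expect_true(all(tk$p_adj[!involves_c] > 0.05))
})

test_that("two-group ANOVA F equals t squared", {
  set.seed(8)
  vals <- c(rnorm(6, 1), rnorm(6, 2))
  grp <- rep(c("a", "b"), each = 6)
  tt <- compare_groups(vals, grp)$statistic
  F_stat <- summary(stats::aov(vals ~ factor(grp)))[[1]]$`F value`[1]
  expect_equal(F_stat, tt^2, tolerance = 1e-9)
})

test_that("exact linear data give the exact fit with a zero-width band", {
  x <- 1:10; y <- 2 * x + 1
  fit <- suppressWarnings(regression_with_band(x, y))  # perfect-fit note
  expect_equal(unname(fit$fits[["all"]]["slope"]), 2, tolerance = 1e-9)
  expect_equal(unname(fit$fits[["all"]]["intercept"]), 1, tolerance = 1e-9)
  expect_lt(max(fit$band$upper - fit$band$lower), 1e-7)
})

test_that("confidence bands widen with the level and contain the fit", {
  set.seed(9)
  x <- runif(30, 0, 10); y <- 1.5 * x + rnorm(30)
  b90 <- regression_with_band(x, y, level = 0.90)$band
  b99 <- regression_with_band(x, y, level = 0.99)$band
  expect_true(all(b99$upper - b99$lower > b90$upper - b90$lower))
  expect_true(all(b90$fit >= b90$lower & b90$fit <= b90$upper))
  expect_error(regression_with_band(rep(1, 5), rnorm(5)), "constant")
})

test_that("old cells have a shallower force-area slope than young", {
  wins <- vapply(1:20, function(s) {
    set.seed(s)
    y <- simulate_static_force(cohort_defaults("young"), 50)
    o <- simulate_static_force(cohort_defaults("old"), 50)
    d <- rbind(y, o)
    fit <- regression_with_band(d$area_um2, d$force_nN, d$cohort)
    fit$fits[["young"]]["slope"] > fit$fits[["old"]]["slope"]
  }, logical(1))
  expect_true(all(wins))
})

test_that("min-max radar normalization behaves as specified", {
  r <- radar_summary(data.frame(m = c(2, 4, 6)), c("a", "b", "c"))
  expect_equal(unname(r$normalized[, 1]), c(0, 0.5, 1))
  # affine invariance
  r2 <- radar_summary(data.frame(m = 10 - 3 * c(2, 4, 6)), c("a", "b", "c"))
  expect_equal(abs(r2$normalized[, 1] - rev(r$normalized[, 1])),
               rep(0, 3), tolerance = 1e-12)
  expect_warning(
    rc <- radar_summary(data.frame(m = rep(3, 4)), rep(c("a", "b"), 2)),
    "constant")
  expect_true(all(rc$normalized == 0.5))
})

test_that("silencing the channel moves the old radar profile toward young", {
  set.seed(10)
  cfg <- tiny_config()
  rows <- list(); grp <- c()
  for (co in c("young", "old", "old_sipiezo1")) {
    p <- cohort_defaults(co)
    n <- 12
    stat <- simulate_static_force(p, n)
    met <- data.frame(
      area = stat$area_um2,
      force = stat$force_nN,
      peak_increase = rnorm(n, p$peak_increase, p$peak_increase_sd),
      osc_amplitude = rnorm(n, p$osc_amplitude, 0.05 * p$osc_amplitude),
      ca_recovery = vapply(seq_len(n), function(i)
        analyze_trace(simulate_calcium(p, cfg))$recovery, numeric(1)))
    rows[[co]] <- met
    grp <- c(grp, rep(co, n))
  }
  rs <- radar_summary(do.call(rbind, rows), grp)
  d <- function(a, b) sqrt(sum((rs$table[a, ] - rs$table[b, ])^2))
  expect_lt(d("old_sipiezo1", "young"), d("old", "young"))
})
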