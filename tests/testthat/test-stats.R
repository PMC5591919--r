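tidy_groups <- function(...) {
  vals <- list(...)
  tibble::tibble(value = unlist(vals),
                 group = rep(paste0("g", seq_along(vals)), lengths(vals)))
}

test_that("identical groups give F = 0, p = 1 and a null LSD comparison", {
  d <- tidy_groups(c(1, 2, 3), c(1, 2, 3))
  fit <- one_way_anova(d, value, group)
  expect_equal(fit$F, 0)
  expect_equal(fit$p, 1)
  cmp <- lsd_pairwise(fit)
  expect_equal(cmp$delta, 0)
  expect_false(cmp$significant)
})

test_that("hand-computed two-group decomposition is exact", {
  d <- tidy_groups(c(1, 2), c(3, 4))
  fit <- one_way_anova(d, value, group)
  expect_equal(fit$ss_between, 4)
  expect_equal(fit$ss_within, 1)
  expect_equal(fit$F, 8)
  expect_equal(fit$p, 0.10557, tolerance = 1e-4)
  cmp <- lsd_pairwise(fit)
  expect_equal(cmp$delta, -2)
  expect_equal(cmp$ci_high - cmp$delta, qt(0.975, 2) * sqrt(0.5 * (1 / 2 + 1 / 2)),
               tolerance = 1e-10) # 3.043
  expect_false(cmp$significant)
})

test_that("the decomposition matches aov() on random data", {
  set.seed(10)
  d <- tibble::tibble(value = rnorm(45), group = rep(c("a", "b", "c"), 15))
  fit <- one_way_anova(d, value, group)
  ref <- summary(stats::aov(value ~ group, data = d))[[1]]
  expect_equal(fit$F, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(fit$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  expect_equal(fit$ss_between, ref[["Sum Sq"]][1], tolerance = 1e-10)
  expect_equal(fit$ss_within, ref[["Sum Sq"]][2], tolerance = 1e-10)
})

test_that("the p value agrees with a permutation null on a small fixed dataset", {
  set.seed(3)
  x <- rnorm(8) + 0.8
  y <- rnorm(8)
  d <- tidy_groups(x, y)
  fit <- one_way_anova(d, value, group)
  v <- c(x, y)
  set.seed(99)
  fperm <- replicate(2e4, {
    i <- sample.int(16, 8)
    m1 <- mean(v[i]); m2 <- mean(v[-i])
    ssb <- 8 * (m1 - mean(v))^2 + 8 * (m2 - mean(v))^2
    ssw <- sum((v[i] - m1)^2) + sum((v[-i] - m2)^2)
    (ssb / 1) / (ssw / 14)
  })
  p_perm <- mean(fperm >= fit$F)
  expect_lt(abs(fit$p - p_perm), 0.015)
})

test_that("variance decomposition identity holds to 1e-9 relative", {
  set.seed(11)
  for (r in 1:20) {
    k <- sample(2:5, 1)
    d <- tibble::tibble(value = rnorm(10 * k, sd = runif(1, 0.1, 10)),
                        group = rep(paste0("g", 1:k), each = 10))
    fit <- one_way_anova(d, value, group)
    ss_tot <- sum((d$value - mean(d$value))^2)
    expect_lt(abs(fit$ss_between + fit$ss_within - ss_tot) / ss_tot, 1e-9)
  }
})

test_that("two-group LSD is the pooled-variance t test", {
  set.seed(21)
  for (r in 1:25) {
    d <- tidy_groups(rnorm(8, mean = runif(1, 0, 1)), rnorm(10))
    fit <- one_way_anova(d, value, group)
    cmp <- lsd_pairwise(fit)
    tt <- stats::t.test(value ~ group, data = d, var.equal = TRUE)
    expect_equal(cmp$p, tt$p.value, tolerance = 1e-10)
    expect_equal(cmp$significant, tt$p.value < 0.05)
    expect_equal(c(cmp$ci_low, cmp$ci_high), as.numeric(tt$conf.int),
                 tolerance = 1e-9)
  }
})

test_that("significance is exactly CI exclusion of zero", {
  set.seed(31)
  d <- tibble::tibble(value = rnorm(60, rep(c(0, 0.5, 1), 20)),
                      group = rep(c("a", "b", "c"), 20))
  cmp <- lsd_pairwise(one_way_anova(d, value, group))
  expect_equal(cmp$significant, !(cmp$ci_low <= 0 & cmp$ci_high >= 0))
  expect_equal(nrow(cmp), 3)
})

test_that("degenerate inputs are handled per contract", {
  expect_error(one_way_anova(tidy_groups(c(1, 2)), value, group), "2 groups")
  expect_error(one_way_anova(tidy_groups(c(1, 2), 3), value, group),
               "at least 2 observations")
  d <- tidy_groups(c(1, 1), c(2, 2))
  expect_warning(fit <- one_way_anova(d, value, group), "zero within-group")
  expect_equal(fit$p, 0)
  d2 <- tidy_groups(c(1, 1), c(1, 1))
  expect_warning(fit2 <- one_way_anova(d2, value, group), "zero within-group")
  expect_equal(fit2$p, 1)
})

test_that("type-I error of the omnibus test is calibrated at the study design", {
  set.seed(2024)
  rej <- mean(replicate(500, {
    d <- tibble::tibble(value = rnorm(80),
                        group = rep(c("CTRL", "ISO", "EMF", "ISO+EMF"), each = 20))
    one_way_anova(d, value, group)$p < 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.075) # wider band at 500 replicates; the 2000-replicate
                        # calibration lives in the acceptance suite
})

test_that("LSD confidence intervals cover a true two-group difference at ~95%", {
  set.seed(7)
  cover <- mean(replicate(2000, {
    d <- tidy_groups(rnorm(20, 1), rnorm(20))
    cmp <- lsd_pairwise(one_way_anova(d, value, group))
    delta_true <- if (cmp$group1 == "g1") 1 else -1
    cmp$ci_low <= delta_true && delta_true <= cmp$ci_high
  }))
  expect_gte(cover, 0.94)
  expect_lte(cover, 0.96)
})

test_that("significance patterns are summarized against control and ISO", {
  set.seed(5)
  d <- tibble::tibble(
    value = c(rnorm(20, 10), rnorm(20, 10.1), rnorm(20, 9.9), rnorm(20, 6)),
    group = rep(c("CTRL", "ISO", "EMF", "ISO+EMF"), each = 20)
  )
  pat <- significance_pattern(lsd_pairwise(one_way_anova(d, value, group)))
  expect_setequal(pat$contrast, c("ISO vs CTRL", "EMF vs CTRL",
                                  "ISO+EMF vs CTRL", "ISO+EMF vs ISO"))
  expect_true(pat$significant[pat$contrast == "ISO+EMF vs CTRL"])
  expect_equal(pat$direction[pat$contrast == "ISO+EMF vs CTRL"], "-")
  # all-equal groups: everything ns
  d2 <- tibble::tibble(value = rnorm(80), group = rep(c("CTRL", "ISO", "EMF", "ISO+EMF"), 20))
  pat2 <- significance_pattern(lsd_pairwise(one_way_anova(d2, value, group)))
  expect_true(nrow(pat2) == 4)
})

test_that("tidiers expose the fit the broom way", {
  d <- tidy_groups(rnorm(10), rnorm(10, 1))
  fit <- one_way_anova(d, value, group)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("delta", "ci_low", "ci_high", "p") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$df, 1)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
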