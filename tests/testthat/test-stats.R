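test_that("two-group tests behave at the extremes", {
  x <- c(1, 2, 3, 4)
  expect_equal(two_group_test(x, x, "mannwhitney")$p_value, 1)
  set.seed(1)
  a <- rnorm(50); b <- a + 10 * sd(a)
  expect_lt(two_group_test(a, b, "welch")$p_value, 1e-10)
  expect_lt(two_group_test(a, b, "student")$p_value, 1e-10)
  expect_error(two_group_test(rep(1, 5), rep(1, 5), "student"),
               "zero pooled variance")
  res <- two_group_test(a, b, "welch")
  expect_equal(res$estimate, mean(a) - mean(b))
  expect_identical(res$n1, 50L)
})

test_that("exact Mann-Whitney agrees with the reference implementation", {
  set.seed(2)
  for (i in 1:5) {
    x <- rnorm(4); y <- rnorm(4) + i / 3
    ours <- two_group_test(x, y, "mannwhitney")$p_value
    ref <- wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12, label = paste("rep", i))
  }
  # enumeration count sanity: 4 vs 4 has choose(8,4) = 70 assignments, so
  # every exact p is a multiple of 1/70
  x <- c(1.2, 3.4, 0.1, 2.2); y <- c(5.5, 1.9, 4.1, 3.3)
  p <- two_group_test(x, y, "mannwhitney")$p_value
  expect_equal(p * 70, round(p * 70), tolerance = 1e-9)
  # ties are handled (identical pooled values, symmetric): p = 1
  expect_equal(two_group_test(c(1, 1, 2), c(1, 2, 1), "mannwhitney")$p_value,
               1)
})

test_that("exact and approximate Mann-Whitney agree near the cutover", {
  set.seed(3)
  x <- rnorm(10); y <- rnorm(10) + 0.8
  p_exact <- two_group_test(x, y, "mannwhitney")$p_value  # pooled n = 20
  p_norm <- wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  expect_equal(p_exact, p_norm, tolerance = 0.2)
})

test_that("chi-square matches the hand-computed statistic on cohort counts", {
  # cesarean deliveries 77/121 preterm vs 36/134 term
  tab <- matrix(c(77, 36, 44, 98), 2)
  res <- chi_square(tab)
  expect_equal(res$statistic, 34.83912, tolerance = 1e-5)
  expect_lt(res$p_value, 1e-8)
  expect_equal(chi_square(matrix(c(20, 40, 10, 20), 2))$statistic, 0,
               tolerance = 1e-12)
  expect_lt(chi_square(tab, yates = TRUE)$statistic, res$statistic)
  expect_error(chi_square(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "marginal")
})

test_that("chi-square p matches a Monte Carlo permutation null", {
  tab <- matrix(c(12, 7, 6, 14), 2)
  res <- chi_square(tab)
  set.seed(4)
  sims <- r2dtable(20000, rowSums(tab), colSums(tab))
  stat <- function(m) {
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - e)^2 / e)
  }
  p_mc <- mean(vapply(sims, stat, 0) >= res$statistic - 1e-9)
  expect_equal(res$p_value, p_mc, tolerance = 0.35)
})

test_that("forced-entry OLS equals the normal-equation oracle", {
  set.seed(5)
  n <- 80
  X <- data.frame(a = rnorm(n), b = runif(n), c = rnorm(n, 2))
  y <- 1 + 0.5 * X$a - 2 * X$b + 0.3 * X$c + rnorm(n, 0, 0.5)
  fit <- forced_entry_ols(y, X)
  M <- cbind(1, as.matrix(X))
  beta_oracle <- solve(t(M) %*% M, t(M) %*% y)
  expect_equal(fit$coefficients$B, as.numeric(beta_oracle),
               tolerance = 1e-10)
  lm_fit <- summary(lm(y ~ a + b + c, data = X))
  expect_equal(fit$coefficients$se, unname(lm_fit$coefficients[, 2]),
               tolerance = 1e-10)
  expect_equal(fit$coefficients$p_value,
               unname(lm_fit$coefficients[, 4]), tolerance = 1e-10)
  # exact linear response
  fit2 <- forced_entry_ols(2 + 3 * X$a, X["a"])
  expect_equal(fit2$coefficients$B, c(2, 3), tolerance = 1e-9)
  expect_equal(fit2$r, cor(X$a, 2 + 3 * X$a), tolerance = 1e-12)
  X$dup <- 2 * X$a
  expect_error(forced_entry_ols(y, X), "dup")
})

test_that("GA stays a significant predictor of mass change alongside birthweight z", {
  cfg <- default_calibration()
  ch <- generate_cohort(cfg, seed = 6, n_preterm = 1000, n_term = 1000,
                        include_fetal = FALSE, include_contours = FALSE)
  s <- ch$subjects
  f <- ch$visits[ch$visits$stage == "followup", ]
  i <- match(s$subject_id, f$subject_id)
  fit <- forced_entry_ols(f$pct_lvmi[i],
                          data.frame(ga = s$ga_birth, bwz = s$birthweight_z))
  ga_row <- fit$coefficients[fit$coefficients$term == "ga", ]
  expect_lt(ga_row$p_value, 1e-6)
  expect_lt(ga_row$B, 0)
})

test_that("Pearson correlation handles exact and null cases", {
  x <- 1:20
  expect_equal(pearson_r(x, 2 * x)$estimate, 1, tolerance = 1e-12)
  set.seed(7)
  res <- pearson_r(rnorm(1e4), rnorm(1e4))
  expect_lt(abs(res$estimate), 0.03)
  expect_error(pearson_r(rep(1, 10), rnorm(10)), "zero variance")
  # p-value equals the hand-written t transform
  a <- rnorm(15); b <- a + rnorm(15)
  r <- cor(a, b)
  t_stat <- r * sqrt(13 / (1 - r^2))
  expect_equal(pearson_r(a, b)$p_value, 2 * pt(-abs(t_stat), 13),
               tolerance = 1e-12)
})

test_that("minimal detectable effect follows the closed form", {
  d <- mde_two_sample(134, 121, 0.05, 0.80)
  expect_equal(d, (qnorm(0.975) + qnorm(0.8)) * sqrt(1 / 134 + 1 / 121),
               tolerance = 1e-12)
  expect_equal(d, 0.351341, tolerance = 1e-5)
  expect_lte(d, 0.38)  # within the cohort's stated design bound
  # shrinks with n, noncentral-t variant is slightly more conservative
  expect_lt(mde_two_sample(500, 500), mde_two_sample(100, 100))
  expect_gt(mde_two_sample(134, 121, method = "noncentral_t"), d)
  expect_error(mde_two_sample(134, 121, alpha = 0), "alpha")
})

test_that("the MDE is confirmed by a power simulation oracle", {
  d <- mde_two_sample(134, 121, 0.05, 0.80)
  set.seed(8)
  rej <- mean(replicate(2000, {
    t.test(rnorm(134), rnorm(121, d))$p.value < 0.05
  }))
  expect_equal(rej, 0.80, tolerance = 0.035 / 0.8)
})

test_that("random-intercept fit equals OLS when intercept variance is zero", {
  set.seed(9)
  n <- 200
  sid <- rep(1:50, each = 4)
  x <- rnorm(n)
  y <- 2 + 0.7 * x + rnorm(n, 0, 0.3)
  re <- random_intercept_fit(y, x, sid)
  ols <- forced_entry_ols(y, data.frame(x = x))
  expect_equal(re$coefficients$B, ols$coefficients$B, tolerance = 0.02)
  expect_lt(re$sigma_b, 0.1)
  expect_warning(random_intercept_fit(y, x, seq_len(n)), "singletons")
})

test_that("random-intercept components and fixed effects are recovered", {
  set.seed(10)
  n_subj <- 200; k <- 3
  sid <- rep(seq_len(n_subj), each = k)
  u <- rnorm(n_subj, 0, 0.3)[sid]
  x <- rnorm(n_subj * k)
  y <- 1 + 0.5 * x + u + rnorm(n_subj * k, 0, 0.1)
  fit <- random_intercept_fit(y, x, sid)
  expect_equal(fit$sigma_b, 0.3, tolerance = 0.15)
  expect_equal(fit$sigma_w, 0.1, tolerance = 0.15)
  expect_equal(fit$coefficients$B[2], 0.5, tolerance = 0.05)
  lmer_fit <- lme4::lmer(y ~ x + (1 | sid),
                         data = data.frame(y = y, x = x, sid = sid))
  expect_equal(fit$coefficients$B, unname(lme4::fixef(lmer_fit)),
               tolerance = 0.01)
})

test_that("fixed-effect estimates are unbiased over repeated simulation", {
  set.seed(11)
  est <- replicate(200, {
    sid <- rep(1:40, each = 3)
    u <- rnorm(40, 0, 0.3)[sid]
    x <- rnorm(120)
    y <- 1 + 0.5 * x + u + rnorm(120, 0, 0.2)
    random_intercept_fit(y, x, sid)$coefficients$B[2]
  })
  expect_equal(mean(est), 0.5, tolerance = 3 * sd(est) / sqrt(200) / 0.5)
})

test_that("test p-values are uniform under their nulls", {
  set.seed(12)
  p_w <- replicate(400, two_group_test(rnorm(15), rnorm(15),
                                       "welch")$p_value)
  expect_gt(ks.test(p_w, "punif")$p.value, 0.01)
  p_mw <- replicate(400, two_group_test(rnorm(25), rnorm(25),
                                        "mannwhitney")$p_value)
  # rank statistic is discrete; compare mean/sd loosely to uniform
  expect_equal(mean(p_mw), 0.5, tolerance = 0.1)
  p_r <- replicate(400, pearson_r(rnorm(20), rnorm(20))$p_value)
  expect_gt(ks.test(p_r, "punif")$p.value, 0.01)
})
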