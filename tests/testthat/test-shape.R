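make_shape <- function(g, s, seed, n = 40) {
  generate_contour(g, s, 0.9, 0.3, n_points = n, noise_sd = 0.02,
                   seed = seed)$endo$points
}

test_that("Procrustes aligns rigid transforms to numerical identity", {
  A <- make_shape(0, 2.5, 1)
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  al <- generalized_procrustes(list(A, sweep(A %*% R, 2, c(3, -2))))
  expect_lt(sqrt(mean((al$shapes[1, , ] - al$shapes[2, , ])^2)), 1e-8)
  # proper rotations only, and centroids at the origin
  for (i in 1:2) {
    a <- al$rotations[i]
    expect_equal(det(matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)), 1,
                 tolerance = 1e-12)
    expect_equal(unname(colMeans(al$shapes[i, , ])), c(0, 0),
                 tolerance = 1e-12)
  }
})

test_that("per-shape alignment equals the closed-form SVD Kabsch oracle", {
  set.seed(4)
  shapes <- lapply(1:8, function(i) make_shape(runif(1, -1, 1),
                                               runif(1, 2, 3), i))
  al <- generalized_procrustes(shapes)
  m <- al$mean_shape
  for (i in seq_along(shapes)) {
    centered <- scale(shapes[[i]], scale = FALSE)
    R <- kabsch_svd(centered, m)
    expect_equal(sum((centered %*% R - m)^2),
                 sum((al$shapes[i, , ] - m)^2), tolerance = 1e-10)
  }
  expect_error(generalized_procrustes(list(make_shape(0, 2, 1))),
               "at least 2 shapes")
  expect_error(generalized_procrustes(list(make_shape(0, 2, 1),
                                           make_shape(0, 2, 2, n = 30))),
               "same point count")
})

test_that("a pure size family loads > 99% of variance on mode 1", {
  base <- generate_contour(0, 2.5, 0.9, 0.3, 40, 0, seed = 1)$endo$points
  set.seed(9)
  shapes <- lapply(runif(15, 0.7, 1.4), function(k) base * k)
  al <- generalized_procrustes(shapes)
  pdm <- fit_pdm(al)
  expect_gt(pdm$eigenvalues[1] / sum(pdm$eigenvalues), 0.99)
  sizes <- apply(al$shapes, 1, function(p) sqrt(sum(scale(p, scale = FALSE)^2)))
  sc <- project(pdm, al)
  expect_gt(cor(sc$raw[, 1], sizes), 0.99)
})

test_that("the eigendecomposition matches a dense SVD oracle", {
  set.seed(10)
  shapes <- lapply(1:12, function(i) make_shape(runif(1, -1, 1),
                                                runif(1, 2, 3), i + 50))
  al <- generalized_procrustes(shapes)
  pdm <- fit_pdm(al)
  X <- matrix(al$shapes, nrow = 12)
  Xc <- sweep(X, 2, colMeans(X))
  lam_oracle <- svd(Xc)$d^2 / (nrow(X) - 1)
  k <- length(pdm$eigenvalues)
  expect_equal(pdm$eigenvalues, lam_oracle[seq_len(k)], tolerance = 1e-9)
  expect_true(all(diff(pdm$eigenvalues) <= 1e-12))
  expect_equal(sum(pdm$eigenvalues), sum(apply(X, 2, var)),
               tolerance = 1e-9)
  # modes orthonormal
  expect_equal(crossprod(pdm$modes), diag(k), tolerance = 1e-9,
               ignore_attr = TRUE)
  # full-mode reconstruction reproduces every shape
  sc <- project(pdm, al)
  for (i in 1:12)
    expect_lt(max(abs(reconstruct(pdm, sc$standardized[i, ]) -
                        al$shapes[i, , ])), 1e-9)
})

test_that("projection is centered, unit-scaled, and residuals orthogonal", {
  set.seed(11)
  shapes <- lapply(1:10, function(i) make_shape(runif(1, -1, 1), 2.5, i))
  al <- generalized_procrustes(shapes)
  pdm <- fit_pdm(al)
  mean_mat <- matrix(pdm$mean, ncol = 2)
  expect_equal(unname(project(pdm, mean_mat)$raw[1, ]),
               rep(0, ncol(pdm$modes)), tolerance = 1e-9)
  synth <- pdm$mean + 3 * sqrt(pdm$eigenvalues[2]) * pdm$modes[, 2]
  sc <- project(pdm, matrix(synth, ncol = 2))$standardized[1, ]
  expect_equal(unname(sc[2]), 3, tolerance = 1e-9)
  expect_lt(max(abs(sc[-2])), 1e-9)
  # truncated reconstruction residual is orthogonal to retained modes
  x <- matrix(al$shapes[3, , ], ncol = 2)
  keep <- 2
  recon <- reconstruct(pdm, project(pdm, x)$standardized[1, seq_len(keep)])
  resid <- as.numeric(x) - as.numeric(recon)
  expect_lt(max(abs(t(pdm$modes[, seq_len(keep)]) %*% resid)), 1e-9)
  expect_error(project(pdm, matrix(0, 10, 2)), "mismatch")
})

test_that("reconstruction is linear and centered on the mean shape", {
  set.seed(12)
  shapes <- lapply(1:8, function(i) make_shape(0.2, 2.5, i))
  pdm <- fit_pdm(generalized_procrustes(shapes))
  expect_equal(reconstruct(pdm, numeric(0)),
               matrix(pdm$mean, ncol = 2), tolerance = 1e-12)
  plus <- reconstruct(pdm, c(0, 3))
  minus <- reconstruct(pdm, c(0, -3))
  expect_equal((plus + minus) / 2, matrix(pdm$mean, ncol = 2),
               tolerance = 1e-12)
})

test_that("per-mode tests detect injected shifts and match permutations", {
  set.seed(13)
  scores <- matrix(rnorm(100 * 4), 100, 4)
  labels <- rep(c("preterm", "term"), each = 50)
  scores[labels == "preterm", 2] <- scores[labels == "preterm", 2] + 2
  res <- per_mode_group_test(scores, labels)
  expect_lt(res$p_value[2], 1e-3)
  expect_gt(min(res$p_value[c(1, 3, 4)]), 0.001)
  # identical groups: all p = 1
  same <- rbind(scores[1:10, ], scores[1:10, ])
  res_same <- per_mode_group_test(same, rep(c("a", "b"), each = 10))
  expect_true(all(res_same$p_value > 0.999))
  expect_error(per_mode_group_test(matrix(1, 10, 2),
                                   rep(c("a", "b"), 5)), "zero variance")
  # permutation oracle on a small sample
  set.seed(14)
  x <- rnorm(10); y <- rnorm(10) + 1
  p_t <- per_mode_group_test(cbind(c(x, y)),
                             rep(c("a", "b"), each = 10))$p_value
  pooled <- c(x, y)
  stat_obs <- abs(mean(x) - mean(y))
  perm <- replicate(20000, {
    idx <- sample(20, 10)
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  })
  p_perm <- mean(perm >= stat_obs - 1e-12)
  expect_equal(p_t, p_perm, tolerance = 0.25)
})

test_that("LDA separates point masses and is null-calibrated", {
  X <- rbind(matrix(rep(c(0, 0), 5), ncol = 2, byrow = TRUE),
             matrix(rep(c(3, 3), 5), ncol = 2, byrow = TRUE))
  lab <- rep(c("preterm", "term"), each = 5)
  fit <- train_lda(X, lab, 1:2)
  expect_equal(fit$auc_resub, 1)
  set.seed(15)
  Xn <- matrix(rnorm(200 * 3), 200, 3)
  labn <- sample(rep(c("preterm", "term"), each = 100))
  fitn <- train_lda(Xn, labn, 1:3)
  expect_lt(abs(fitn$auc_resub - 0.5), 0.12)
  expect_lt(abs(loo_auc(Xn, labn, 1:3) - 0.5), 0.1)
  # one-dimensional subset reduces to the standardized mean difference
  x1 <- Xn[, 1, drop = FALSE]
  w <- train_lda(x1, labn, 1)$weights
  pre <- labn == "preterm"
  s2 <- ((sum(pre) - 1) * var(x1[pre, 1]) +
           (sum(!pre) - 1) * var(x1[!pre, 1])) / (length(labn) - 2)
  expect_equal(w, (mean(x1[pre, 1]) - mean(x1[!pre, 1])) / s2,
               tolerance = 1e-4)
  expect_error(train_lda(Xn, rep("preterm", 200), 1:2), "both classes")
})

test_that("LOO AUC never exceeds resubstitution AUC by more than noise", {
  set.seed(16)
  for (rep_i in 1:5) {
    X <- matrix(rnorm(120 * 4), 120, 4)
    lab <- rep(c("preterm", "term"), each = 60)
    X[lab == "preterm", ] <- X[lab == "preterm", ] + 0.3
    fit <- train_lda(X, lab, 1:4)
    expect_lte(loo_auc(X, lab, 1:4), fit$auc_resub + 0.02)
  }
})

test_that("mode-subset selection recovers an injected 2-6 signal", {
  set.seed(17)
  n <- c(121, 134)
  lab <- rep(c("preterm", "term"), n)
  scores <- matrix(rnorm(sum(n) * 8), sum(n), 8)
  # signal confined to modes 2-6, strongest in mode 6 so that every signal
  # mode contributes a distinguishable LOO-AUC increment
  shift <- c(0.4, 0.45, 0.5, 0.6, 1.0)
  scores[lab == "preterm", 2:6] <-
    sweep(scores[lab == "preterm", 2:6], 2, shift, "+")
  sel <- select_mode_subset(scores, lab, max_mode = 8)
  expect_identical(sel$subset, 2:6)
  expect_gt(sel$model$loo_auc, 0.75)
  expect_identical(nrow(sel$auc_curve), 7L)
  # the curve rises while signal modes accrue
  expect_gt(sel$auc_curve$loo_auc[5], sel$auc_curve$loo_auc[1])
})

test_that("globularity shift yields birth-only discrimination on small cohorts", {
  cfg <- small_config()
  ch <- generate_cohort(cfg, seed = 19, include_fetal = FALSE)
  res <- cohort_shape_scores(ch)
  pm_birth <- per_mode_group_test(res$birth$scores[, 1:6],
                                  res$birth$labels)
  expect_lt(min(pm_birth$p_value[2:6]), 1e-3)
  pm_fu <- per_mode_group_test(res$followup$scores[, 2:6, drop = FALSE],
                               res$followup$labels)
  expect_gt(min(pm_fu$p_value), 0.001)
})

test_that("null shape p-values are uniform across seeds", {
  cfg <- small_config(15, 15, 0)
  # same contour family for both groups: a true shape null
  cfg$shape_params$birth$term <- cfg$shape_params$birth$preterm
  pvals <- vapply(1:60, function(s) {
    ch <- generate_cohort(cfg, seed = 1000 + s, include_fetal = FALSE)
    ids <- names(ch$contours)[endsWith(names(ch$contours), "birth")]
    shp <- shapes_from_contours(ch$contours[ids], "endo")
    sid <- sub("_birth$", "", ids)
    lab <- ch$subjects$group[match(sid, ch$subjects$subject_id)]
    al <- generalized_procrustes(shp)
    sc <- project(fit_pdm(al), al)$standardized
    per_mode_group_test(sc[, 2, drop = FALSE], lab)$p_value
  }, 0)
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("globular shapes have higher annulus/mid-width ratio than conical", {
  glob <- generate_contour(1, 2.5, 0.9, 0.3, 51, 0, 1)$endo$points
  coni <- generate_contour(-1, 2.5, 0.9, 0.3, 51, 0, 1)$endo$points
  expect_gt(measure_shape_widths(glob)["mid_width"],
            measure_shape_widths(coni)["mid_width"])
  expect_equal(unname(measure_shape_widths(glob)["ratio"]), 1,
               tolerance = 0.05)
})
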