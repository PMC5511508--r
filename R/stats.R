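# Comparison and regression layer: two-group tests, chi-square association,
# forced-entry OLS, Pearson correlation, minimal detectable effect, and a
# moment-based random-intercept regression for repeated measures.

test_result <- function(statistic, p_value, estimate, n1, n2, method) {
  tibble::tibble(statistic = unname(statistic), p_value = unname(p_value),
                 estimate = unname(estimate), n1 = n1, n2 = n2,
                 method = method)
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments of
# the pooled ranks (ties handled via average ranks)
mw_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  dev_obs <- abs(u_obs - n1 * n2 / 2)
  combos <- utils::combn(n1 + n2, n1)
  u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(u_all - n1 * n2 / 2) >= dev_obs - 1e-9)
}

#' Two-group comparison test
#'
#' Student's t (pooled variance), Welch's t (default), or the Mann-Whitney
#' U test. Mann-Whitney uses exact enumeration of all group assignments for
#' pooled n of 20 or fewer, and the tie-corrected normal approximation
#' otherwise.
#'
#' @param x,y samples for the two groups (each n >= 2).
#' @param method `"welch"`, `"student"`, or `"mannwhitney"`.
#' @return one-row tibble: `statistic`, `p_value`, `estimate` (difference
#'   of means, or of medians for Mann-Whitney), `n1`, `n2`, `method`.
#' @export
two_group_test <- function(x, y, method = c("welch", "student",
                                            "mannwhitney")) {
  method <- match.arg(method)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (method == "student") {
    if (stats::var(c(x - mean(x), y - mean(y))) == 0)
      stop("zero pooled variance")
    tt <- stats::t.test(x, y, var.equal = TRUE)
    return(test_result(tt$statistic, tt$p.value, mean(x) - mean(y),
                       length(x), length(y), method))
  }
  if (method == "welch") {
    tt <- stats::t.test(x, y)
    return(test_result(tt$statistic, tt$p.value, mean(x) - mean(y),
                       length(x), length(y), method))
  }
  n1 <- length(x); n2 <- length(y)
  u <- sum(rank(c(x, y))[seq_len(n1)]) - n1 * (n1 + 1) / 2
  p <- if (n1 + n2 <= 20) {
    mw_exact_p(x, y)
  } else {
    stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  }
  test_result(u, p, stats::median(x) - stats::median(y), n1, n2, method)
}

#' Pearson chi-square test of association for a 2 x 2 table
#'
#' Without continuity correction by default (set `yates = TRUE` for the
#' corrected statistic).
#'
#' @param table 2 x 2 matrix of nonnegative integer counts.
#' @param yates apply Yates continuity correction.
#' @return one-row tibble with the chi-square statistic, p-value and the
#'   odds ratio as the estimate.
#' @export
chi_square <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0),
            all(abs(table - round(table)) < 1e-8))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in the 2x2 table")
  ct <- suppressWarnings(stats::chisq.test(table, correct = yates))
  or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  test_result(ct$statistic, ct$p.value, or,
              sum(table[1, ]), sum(table[2, ]),
              if (yates) "chi-square (Yates)" else "chi-square")
}

#' Forced-entry ordinary least squares
#'
#' All predictors entered simultaneously; unstandardized coefficients (B)
#' with standard errors, t statistics and two-sided p-values. A
#' rank-deficient design is an error naming the collinear columns.
#'
#' @param y response vector.
#' @param predictors data frame (or named matrix) of predictors.
#' @return list with `coefficients` (tibble: `term`, `B`, `se`, `t`,
#'   `p_value`), `n`, `sigma`, `r_squared`, and `r` (the bivariate Pearson
#'   correlation when there is a single predictor, else NA).
#' @export
forced_entry_ols <- function(y, predictors) {
  X <- as.data.frame(predictors)
  keep <- stats::complete.cases(X) & is.finite(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  n <- length(y); p <- ncol(X)
  if (n <= p + 1) stop("need n > p + 1 observations")
  M <- cbind(`(Intercept)` = 1, as.matrix(X))
  qr_m <- qr(M)
  if (qr_m$rank < ncol(M)) {
    bad <- colnames(M)[qr_m$pivot[(qr_m$rank + 1):ncol(M)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm.fit(M, y)
  res <- fit$residuals
  df <- n - ncol(M)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qr_m))
  se <- sqrt(sigma2 * diag(XtXinv))
  B <- fit$coefficients
  tval <- B / se
  pval <- 2 * stats::pt(-abs(tval), df)
  list(coefficients = tibble::tibble(term = colnames(M), B = unname(B),
                                     se = unname(se), t = unname(tval),
                                     p_value = unname(pval)),
       n = n, sigma = sqrt(sigma2),
       r_squared = 1 - sum(res^2) / sum((y - mean(y))^2),
       r = if (p == 1) stats::cor(X[[1]], y) else NA_real_)
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y numeric vectors (n >= 3 complete pairs).
#' @return one-row tibble: t statistic, p-value, `estimate` = r.
#' @export
pearson_r <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  stopifnot(length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson")
  test_result(ct$statistic, ct$p.value, ct$estimate,
              length(x), length(y), "pearson")
}

#' Minimal detectable standardized difference for a two-sample comparison
#'
#' Normal-approximation closed form
#' \deqn{d = (z_{1-\alpha/2} + z_{power}) \sqrt{1/n_1 + 1/n_2}}
#' (in SD units); a noncentral-t variant solving the exact two-sample t
#' power equation is available behind `method = "noncentral_t"`.
#'
#' @param n1,n2 group sizes (>= 2).
#' @param alpha two-sided significance level in (0, 1).
#' @param power target power in (0, 1).
#' @param method `"normal"` (default) or `"noncentral_t"`.
#' @return minimal detectable difference in SD units.
#' @export
mde_two_sample <- function(n1, n2, alpha = 0.05, power = 0.80,
                           method = c("normal", "noncentral_t")) {
  method <- match.arg(method)
  stopifnot(n1 >= 2, n2 >= 2, alpha > 0, alpha < 1, power > 0, power < 1)
  f <- sqrt(1 / n1 + 1 / n2)
  if (method == "normal")
    return((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) * f)
  df <- n1 + n2 - 2
  crit <- stats::qt(1 - alpha / 2, df)
  pw <- function(d) {
    ncp <- d / f
    1 - stats::pt(crit, df, ncp) + stats::pt(-crit, df, ncp) - power
  }
  stats::uniroot(pw, c(1e-6, 10), tol = 1e-10)$root
}

#' Random-intercept regression by moment decomposition
#'
#' Variance components from a between/within decomposition of the OLS
#' residuals (pooled within-subject variance; between variance by method of
#' moments, floored at zero), then fixed effects by quasi-demeaning
#' generalized least squares. With no repeated measures the fit falls back
#' to OLS with a warning.
#'
#' @param y response vector.
#' @param x single predictor vector (or data frame of predictors).
#' @param subject_ids subject identifier per observation.
#' @return list with `coefficients` (tibble: `term`, `B`, `se`, `t`,
#'   `p_value`), `sigma_b` and `sigma_w` (between/within SDs), `n`,
#'   `n_subjects`, `method`.
#' @export
random_intercept_fit <- function(y, x, subject_ids) {
  X <- as.data.frame(x)
  if (is.null(names(X)) || any(names(X) == "")) names(X) <- paste0("x", seq_along(X))
  M <- cbind(`(Intercept)` = 1, as.matrix(X))
  ni <- table(subject_ids)
  if (all(ni < 2)) {
    warning("all subjects are singletons; falling back to OLS")
    fit <- forced_entry_ols(y, X)
    return(list(coefficients = fit$coefficients, sigma_b = 0,
                sigma_w = fit$sigma, n = fit$n,
                n_subjects = length(ni), method = "ols-fallback"))
  }
  ols <- stats::lm.fit(M, y)
  vc <- re_variance_moments(ols$residuals, subject_ids)
  gls <- re_gls_fit(y, M, subject_ids, vc$sw2, vc$sb2)
  B <- gls$coefficients
  tval <- B / gls$se
  pval <- 2 * stats::pt(-abs(tval), gls$df)
  list(coefficients = tibble::tibble(term = colnames(M), B = unname(B),
                                     se = unname(gls$se), t = unname(tval),
                                     p_value = unname(pval)),
       sigma_b = sqrt(vc$sb2), sigma_w = sqrt(vc$sw2),
       n = length(y), n_subjects = length(ni), method = "moment-gls")
}
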