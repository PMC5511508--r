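# Fractional-polynomial machinery for growth standards on the log scale.
# Candidate powers follow the conventional set; power 0 denotes ln(age) and
# a repeated power p contributes x^p and x^p * ln(x).

fp_power_set <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

fp_term <- function(x, p) if (p == 0) log(x) else x^p

#' Fractional-polynomial basis for a set of powers
#'
#' @param x positive ages (weeks).
#' @param powers numeric vector of 1 or 2 powers from the candidate set;
#'   a repeated power uses the `x^p * ln(x)` convention.
#' @return design matrix without the intercept column.
#' @keywords internal
fp_basis <- function(x, powers) {
  stopifnot(all(x > 0))
  if (length(powers) == 1L) {
    out <- cbind(fp_term(x, powers))
  } else if (powers[1] == powers[2]) {
    out <- cbind(fp_term(x, powers[1]), fp_term(x, powers[1]) * log(x))
  } else {
    out <- cbind(fp_term(x, powers[1]), fp_term(x, powers[2]))
  }
  colnames(out) <- paste0("fp", seq_len(ncol(out)))
  out
}

fp_candidates <- function(degree) {
  if (degree == 1L) return(lapply(fp_power_set, function(p) p))
  out <- list()
  for (i in seq_along(fp_power_set))
    for (j in i:length(fp_power_set))
      out[[length(out) + 1L]] <- c(fp_power_set[i], fp_power_set[j])
  out
}

#' Fit a fractional-polynomial mean curve for ln(y) on age
#'
#' Exhaustively searches the candidate power set (8 degree-1 models, 36
#' degree-2 pairs with repetition), least-squares fitting ln(y) on the
#' transformed ages, and returns the lowest-deviance model. Ties are broken
#' toward the conventional linear powers, then the lexicographically
#' smallest pair.
#'
#' @param age positive ages in weeks (>= 10 points).
#' @param y positive outcome values.
#' @param degree 1 or 2 (default 2).
#' @return an object of class `fp_model` with elements `powers`,
#'   `coefficients` (intercept first), `deviance` (residual sum of squares
#'   of ln(y)), `degree` and `n`.
#' @export
fit_fp_mean <- function(age, y, degree = 2L) {
  stopifnot(length(age) == length(y), length(age) >= 10,
            all(age > 0), all(y > 0), degree %in% c(1L, 2L))
  ly <- log(y)
  cands <- fp_candidates(as.integer(degree))
  fits <- vector("list", length(cands))
  rss <- rep(Inf, length(cands))
  for (k in seq_along(cands)) {
    X <- cbind(1, fp_basis(age, cands[[k]]))
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X)) next  # degenerate transform for these ages
    fit <- qr.coef(qr_x, ly)
    res <- ly - X %*% fit
    rss[k] <- sum(res^2)
    fits[[k]] <- fit
  }
  if (!any(is.finite(rss)))
    stop("singular design for every candidate transform (constant age?)")
  best_rss <- min(rss)
  # tie set at numerical tolerance; prefer linear, then lexicographic order
  tie <- which(rss <= best_rss * (1 + 1e-10) + 1e-12)
  pref <- if (degree == 1L) 1 else c(1, 1)
  is_linear <- vapply(cands[tie], function(p) all(p == pref), TRUE)
  if (any(is_linear)) {
    pick <- tie[which(is_linear)[1]]
  } else {
    ord <- order(vapply(cands[tie], `[`, 0, 1),
                 vapply(cands[tie], function(p) p[length(p)], 0))
    pick <- tie[ord[1]]
  }
  structure(list(powers = cands[[pick]],
                 coefficients = as.numeric(fits[[pick]]),
                 deviance = rss[pick], degree = as.integer(degree),
                 n = length(age), all_rss = rss),
            class = "fp_model")
}

#' Evaluate a fractional-polynomial mean curve
#'
#' @param model an `fp_model`.
#' @param age positive ages (weeks).
#' @return fitted values of ln(y).
#' @export
fp_predict <- function(model, age) {
  stopifnot(inherits(model, "fp_model"))
  drop(cbind(1, fp_basis(age, model$powers)) %*% model$coefficients)
}

# moment (between/within) decomposition of residual variance for repeated
# measures; returns within and between variance components
re_variance_moments <- function(resid, subject) {
  ni <- table(subject)
  rep_ids <- names(ni)[ni >= 2]
  if (length(rep_ids) < 2)
    stop("need at least 2 subjects with repeated measures")
  rbar <- tapply(resid, subject, mean)
  within_ss <- sum(tapply(resid, subject, function(r) sum((r - mean(r))^2)))
  sw2 <- within_ss / sum(ni - 1)
  sb2 <- max(0, stats::var(as.numeric(rbar)) - sw2 * mean(1 / ni))
  list(sw2 = sw2, sb2 = sb2)
}

# quasi-demeaning GLS for a random-intercept model: partially centers y and
# the design at subject means with theta_i = 1 - sqrt(sw2/(sw2 + n_i sb2))
re_gls_fit <- function(y, X, subject, sw2, sb2) {
  ni <- table(subject)[as.character(subject)]
  theta <- 1 - sqrt(sw2 / (sw2 + as.numeric(ni) * sb2))
  center <- function(v) v - theta * ave(v, subject)
  ys <- center(y)
  Xs <- apply(X, 2, center)
  fit <- stats::lm.fit(Xs, ys)
  res <- fit$residuals
  df <- length(y) - fit$rank
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(Xs)))
  list(coefficients = fit$coefficients,
       se = sqrt(sigma2 * diag(XtXinv)), df = df)
}

#' Fit a growth-centile standard for a cardiac measure
#'
#' Builds a centile model for a positive outcome against postmenstrual age:
#' a fractional-polynomial mean curve for ln(y) ([fit_fp_mean]) plus a
#' log-scale SD model (constant by default, or a degree-1 fractional
#' polynomial of age behind `sd_model = "fp"`). With `repeated = TRUE` a
#' subject-level random intercept is estimated by a between/within moment
#' decomposition and the mean curve is refit by quasi-demeaning
#' (subject-mean-centered) generalized least squares; the marginal SD
#' (between + within) is used for centiles and z-scores.
#'
#' @param visits data frame with an age column, the outcome column and
#'   `subject_id`.
#' @param outcome name of the outcome column (positive values).
#' @param age_col name of the age column (default `"pma"`, weeks).
#' @param repeated account for repeated measures per subject.
#' @param sd_model `"constant"` or `"fp"` (age-varying log-scale SD).
#' @param degree fractional-polynomial degree for the mean curve.
#' @return an object of class `centile_model`: `mean_fn` (`fp_model`),
#'   `sd_fn`, `range` (age validity range), `outcome`, and the variance
#'   components when `repeated = TRUE`.
#' @export
fit_centile_model <- function(visits, outcome, age_col = "pma",
                              repeated = FALSE, sd_model = "constant",
                              degree = 2L) {
  df <- as.data.frame(visits)
  keep <- is.finite(df[[age_col]]) & is.finite(df[[outcome]]) &
    df[[outcome]] > 0
  df <- df[keep, ]
  age <- df[[age_col]]; y <- df[[outcome]]
  if (length(unique(age)) < 10)
    stop("visits must span at least 10 distinct ages")
  mean_fn <- fit_fp_mean(age, y, degree = degree)
  resid <- log(y) - fp_predict(mean_fn, age)
  components <- NULL
  if (repeated) {
    vc <- re_variance_moments(resid, df$subject_id)
    X <- cbind(1, fp_basis(age, mean_fn$powers))
    gls <- re_gls_fit(log(y), X, df$subject_id, vc$sw2, vc$sb2)
    mean_fn$coefficients <- as.numeric(gls$coefficients)
    resid <- log(y) - fp_predict(mean_fn, age)
    components <- vc
    sigma_const <- sqrt(vc$sb2 + vc$sw2)
  } else {
    sigma_const <- stats::sd(resid)
  }
  if (identical(sd_model, "fp")) {
    # degree-1 FP of age for the absolute residual, scaled to an SD
    sd_fit <- fit_fp_mean(age, pmax(abs(resid), 1e-8) * sqrt(pi / 2),
                          degree = 1L)
    sd_fn <- list(type = "fp", model = sd_fit, floor = 1e-6)
  } else {
    sd_fn <- list(type = "constant", sigma = sigma_const)
  }
  structure(list(mean_fn = mean_fn, sd_fn = sd_fn,
                 range = range(age), outcome = outcome,
                 components = components),
            class = "centile_model")
}

centile_mu <- function(model, age) fp_predict(model$mean_fn, age)

centile_sigma <- function(model, age) {
  if (model$sd_fn$type == "constant") {
    rep(model$sd_fn$sigma, length(age))
  } else {
    pmax(exp(fp_predict(model$sd_fn$model, age)), model$sd_fn$floor)
  }
}

check_range <- function(model, age, extrapolate) {
  if (!extrapolate &&
      any(age < model$range[1] - 1e-9 | age > model$range[2] + 1e-9))
    stop(sprintf("age outside model validity range [%.1f, %.1f]",
                 model$range[1], model$range[2]))
}

#' Evaluate a centile curve
#'
#' @param model a [centile_model][fit_centile_model].
#' @param age ages in weeks within the validity range.
#' @param p centile in (0, 100).
#' @param extrapolate allow ages outside the fitted range.
#' @return outcome values `exp(mu(age) + z_p * sigma(age))`.
#' @export
centile <- function(model, age, p, extrapolate = FALSE) {
  stopifnot(inherits(model, "centile_model"), p > 0, p < 100)
  check_range(model, age, extrapolate)
  exp(centile_mu(model, age) + stats::qnorm(p / 100) * centile_sigma(model, age))
}

#' Z-score of an observation against a centile standard
#'
#' @param model a [centile_model][fit_centile_model].
#' @param age ages in weeks within the validity range.
#' @param y positive observed outcome values.
#' @param extrapolate allow ages outside the fitted range.
#' @return standardized deviations `(ln y - mu(age)) / sigma(age)`.
#' @export
zscore <- function(model, age, y, extrapolate = FALSE) {
  stopifnot(inherits(model, "centile_model"), all(y > 0))
  check_range(model, age, extrapolate)
  (log(y) - centile_mu(model, age)) / centile_sigma(model, age)
}

#' Difference between two standards' centile curves at an age
#'
#' @param model_a,model_b [centile_model][fit_centile_model] objects.
#' @param age age in weeks within both validity ranges.
#' @param p centile in (0, 100).
#' @param extrapolate allow ages outside the fitted ranges.
#' @return `centile(model_a, age, p) - centile(model_b, age, p)` in outcome
#'   units.
#' @export
trajectory_difference <- function(model_a, model_b, age, p = 50,
                                  extrapolate = FALSE) {
  centile(model_a, age, p, extrapolate) - centile(model_b, age, p, extrapolate)
}

#' Serialize / restore a centile model as JSON
#'
#' @param model a `centile_model`.
#' @param path JSON file path.
#' @return `write_centile_model` returns `path` invisibly;
#'   `read_centile_model` the restored model.
#' @export
write_centile_model <- function(model, path) {
  obj <- list(outcome = model$outcome, range = model$range,
              mean_powers = model$mean_fn$powers,
              mean_coefficients = model$mean_fn$coefficients,
              mean_degree = model$mean_fn$degree,
              sd_type = model$sd_fn$type,
              sd_sigma = model$sd_fn$sigma,
              sd_powers = model$sd_fn$model$powers,
              sd_coefficients = model$sd_fn$model$coefficients,
              components = model$components)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_centile_model
#' @export
read_centile_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mean_fn <- structure(list(powers = obj$mean_powers,
                            coefficients = obj$mean_coefficients,
                            degree = obj$mean_degree, deviance = NA_real_),
                       class = "fp_model")
  sd_fn <- if (identical(obj$sd_type, "constant")) {
    list(type = "constant", sigma = obj$sd_sigma)
  } else {
    list(type = "fp",
         model = structure(list(powers = obj$sd_powers,
                                coefficients = obj$sd_coefficients,
                                degree = 1L), class = "fp_model"),
         floor = 1e-6)
  }
  structure(list(mean_fn = mean_fn, sd_fn = sd_fn, range = obj$range,
                 outcome = obj$outcome, components = obj$components),
            class = "centile_model")
}

#' Export centile curves on an age grid as CSV
#'
#' @param model a `centile_model`.
#' @param path CSV file path.
#' @param centiles centiles to tabulate (default 3, 50, 97).
#' @param n_grid number of grid points over the validity range.
#' @return `path`, invisibly.
#' @export
export_centile_curves <- function(model, path, centiles = c(3, 50, 97),
                                  n_grid = 101L) {
  age <- seq(model$range[1], model$range[2], length.out = n_grid)
  out <- data.frame(age = age)
  for (p in centiles)
    out[[paste0("c", p)]] <- centile(model, age, p)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
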