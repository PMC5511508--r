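# Point-distribution shape model of four-chamber ventricular borders:
# correspondence by arc-length resampling, generalized Procrustes alignment
# (scale retained by default so size emerges as mode 1), PCA eigenmodes,
# per-mode group tests, and an LDA morphological signature with
# leave-one-out AUC mode-subset selection.

shape_list <- function(shapes) {
  if (is.array(shapes) && length(dim(shapes)) == 3) {
    lapply(seq_len(dim(shapes)[1]), function(i) shapes[i, , ])
  } else if (is.list(shapes)) {
    lapply(shapes, contour_points)
  } else stop("shapes must be a list of point matrices or a 3D array")
}

#' Extract a shape array from generated contour pairs
#'
#' @param contours named list of `list(endo, epi)` pairs as produced by
#'   [generate_cohort] or [generate_contour].
#' @param border `"endo"` or `"epi"`.
#' @return list of n_points x 2 matrices, named as `contours`.
#' @export
shapes_from_contours <- function(contours, border = c("endo", "epi")) {
  border <- match.arg(border)
  lapply(contours, function(pair) contour_points(pair[[border]]))
}

centroid_size <- function(p) sqrt(sum(scale(p, scale = FALSE)^2))

# closed-form 2D least-squares rotation of shape A onto reference B
# (both centered); proper rotation only (det = +1)
rotation_to <- function(A, B) {
  num <- sum(A[, 2] * B[, 1] - A[, 1] * B[, 2])
  den <- sum(A[, 1] * B[, 1] + A[, 2] * B[, 2])
  theta <- atan2(num, den)
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Generalized Procrustes alignment of a set of shapes
#'
#' Iteratively translates each shape's centroid to the origin, rotates each
#' to the evolving mean by least squares (proper rotations only, never a
#' reflection), and — only when `retain_scale = FALSE` — scales each to
#' unit centroid size. Convergence when the mean shape moves less than
#' `tol` (Frobenius norm) or after `max_iter` iterations (error).
#'
#' Scale is retained by default so that overall ventricular size emerges as
#' the leading variation mode rather than being normalized away.
#'
#' @param shapes list of n_points x 2 matrices (equal point counts) or a
#'   3D array `n_shapes x n_points x 2`.
#' @param retain_scale keep each shape's size (default `TRUE`).
#' @param tol convergence tolerance on the mean shape.
#' @param max_iter maximum number of iterations.
#' @return an `aligned_shapes` object: `shapes` (3D array), `mean_shape`,
#'   `rotations` (per-shape angles, radians), `retain_scale`, `iterations`.
#' @export
generalized_procrustes <- function(shapes, retain_scale = TRUE,
                                   tol = 1e-8, max_iter = 100L) {
  sl <- shape_list(shapes)
  if (length(sl) < 2) stop("need at least 2 shapes")
  np <- unique(vapply(sl, nrow, 1L))
  if (length(np) != 1) stop("all shapes must have the same point count")
  centered <- lapply(sl, function(p) scale(p, scale = FALSE))
  if (!retain_scale)
    centered <- lapply(centered, function(p) p / centroid_size(p))
  angles <- numeric(length(centered))
  m <- centered[[1]]
  for (it in seq_len(max_iter)) {
    rotated <- vector("list", length(centered))
    for (i in seq_along(centered)) {
      R <- rotation_to(centered[[i]], m)
      rotated[[i]] <- centered[[i]] %*% R
      angles[i] <- atan2(R[2, 1], R[1, 1])
    }
    m_new <- Reduce(`+`, rotated) / length(rotated)
    if (!retain_scale) m_new <- m_new / centroid_size(m_new)
    delta <- sqrt(sum((m_new - m)^2))
    m <- m_new
    if (delta < tol) {
      arr <- array(0, c(length(rotated), np, 2))
      for (i in seq_along(rotated)) arr[i, , ] <- rotated[[i]]
      dimnames(arr) <- list(names(sl), NULL, c("x", "y"))
      return(structure(list(shapes = arr, mean_shape = m,
                            rotations = angles,
                            retain_scale = retain_scale, iterations = it),
                       class = "aligned_shapes"))
    }
  }
  stop(sprintf(
    "Procrustes did not converge in %d iterations (last change %.3e)",
    max_iter, delta))
}

flatten_shapes <- function(arr) {
  n <- dim(arr)[1]
  matrix(arr, nrow = n)  # columns: x_1..x_p, y_1..y_p
}

unflatten_shape <- function(v, np) matrix(v, nrow = np, ncol = 2)

#' Fit a point-distribution model to aligned shapes
#'
#' Eigendecomposition of the coordinate covariance about the mean shape.
#' Modes are sorted by decreasing eigenvalue; each eigenvalue is the
#' variance explained by its mode and their sum equals the total
#' aligned-shape variance. Mode signs are oriented so that the leading
#' mode's loading on overall scale is positive (its score correlates
#' positively with centroid size); remaining modes are oriented to a fixed
#' convention (largest-magnitude element positive).
#'
#' @param aligned an `aligned_shapes` object (>= 3 shapes).
#' @return a `shape_model`: `mean` (flattened), `modes` (columns, unit
#'   norm), `eigenvalues`, `n_points`, `retain_scale`.
#' @export
fit_pdm <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_shapes"))
  X <- flatten_shapes(aligned$shapes)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 shapes")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / (n - 1)
  eg <- eigen(C, symmetric = TRUE)
  k <- min(n - 1, ncol(X))
  modes <- eg$vectors[, seq_len(k), drop = FALSE]
  lambda <- pmax(eg$values[seq_len(k)], 0)
  np <- dim(aligned$shapes)[2]
  sizes <- apply(aligned$shapes, 1, centroid_size)
  scores <- Xc %*% modes
  for (j in seq_len(k)) {
    flip <- if (j == 1 && stats::sd(sizes) > 0) {
      stats::cor(scores[, 1], sizes) < 0
    } else {
      modes[which.max(abs(modes[, j])), j] < 0
    }
    if (isTRUE(flip)) modes[, j] <- -modes[, j]
  }
  structure(list(mean = mu, modes = modes, eigenvalues = lambda,
                 n_points = np, retain_scale = aligned$retain_scale),
            class = "shape_model")
}

#' Project shapes onto the modes of a point-distribution model
#'
#' @param model a `shape_model`.
#' @param shapes an `aligned_shapes` object, a single n_points x 2 matrix
#'   (already in the model frame), or a list/3D array of such matrices.
#' @return list with `raw` (n_shapes x n_modes score matrix) and
#'   `standardized` (raw scores divided by the per-mode SD `sqrt(lambda)`).
#' @export
project <- function(model, shapes) {
  stopifnot(inherits(model, "shape_model"))
  if (inherits(shapes, "aligned_shapes")) {
    X <- flatten_shapes(shapes$shapes)
  } else if (is.matrix(shapes) && ncol(shapes) == 2) {
    X <- matrix(as.numeric(shapes), nrow = 1)
  } else {
    X <- flatten_shapes(if (is.array(shapes)) shapes else {
      arr <- array(0, c(length(shapes), nrow(shapes[[1]]), 2))
      for (i in seq_along(shapes)) arr[i, , ] <- shapes[[i]]
      arr
    })
  }
  if (ncol(X) != length(model$mean))
    stop("point-count mismatch between shapes and model")
  raw <- sweep(X, 2, model$mean) %*% model$modes
  sdv <- sqrt(model$eigenvalues)
  std <- sweep(raw, 2, ifelse(sdv > 0, sdv, 1), "/")
  colnames(raw) <- colnames(std) <- paste0("mode", seq_len(ncol(raw)))
  list(raw = raw, standardized = std)
}

#' Reconstruct a shape from standardized mode scores
#'
#' `mean + sum_k score_k * sqrt(lambda_k) * mode_k`; used e.g. to render
#' shapes at +/- 3 SD along a discriminant axis.
#'
#' @param model a `shape_model`.
#' @param scores numeric vector of standardized scores (length at most the
#'   number of retained modes; missing trailing modes are taken as 0).
#' @return an n_points x 2 matrix.
#' @export
reconstruct <- function(model, scores) {
  stopifnot(inherits(model, "shape_model"),
            length(scores) <= ncol(model$modes))
  k <- length(scores)
  v <- model$mean
  if (k > 0)
    v <- v + model$modes[, seq_len(k), drop = FALSE] %*%
      (scores * sqrt(model$eigenvalues[seq_len(k)]))
  unflatten_shape(v, model$n_points)
}

#' Per-mode two-sample tests of shape scores
#'
#' Non-paired t-test of each mode's scores between the two groups; run it
#' on birth scores, follow-up scores, or their per-subject difference
#' ("growth") as the condition of interest.
#'
#' @param scores n_shapes x n_modes score matrix.
#' @param labels factor-like group labels (two levels, each with >= 2
#'   observations).
#' @param var_equal pooled-variance (Student) rather than Welch test.
#' @return tibble with `mode`, `statistic`, `p_value`, group means.
#' @export
per_mode_group_test <- function(scores, labels, var_equal = FALSE) {
  labels <- as.factor(labels)
  stopifnot(nlevels(labels) == 2, all(table(labels) >= 2))
  lv <- levels(labels)
  out <- lapply(seq_len(ncol(scores)), function(j) {
    a <- scores[labels == lv[1], j]
    b <- scores[labels == lv[2], j]
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      stop(sprintf("zero variance in mode %d", j))
    tt <- stats::t.test(a, b, var.equal = var_equal)
    tibble::tibble(mode = j, statistic = unname(tt$statistic),
                   p_value = tt$p.value,
                   mean_1 = mean(a), mean_2 = mean(b))
  })
  res <- do.call(rbind, out)
  names(res)[4:5] <- paste0("mean_", lv)
  res
}

#' Rank (Mann-Whitney) AUC of a score against binary labels
#'
#' @param score numeric discriminant scores.
#' @param positive logical vector, `TRUE` for the positive class.
#' @return AUC in \[0, 1\], ties averaged.
#' @export
auc_mw <- function(score, positive) {
  stopifnot(length(score) == length(positive), any(positive), any(!positive))
  r <- rank(score)
  n1 <- sum(positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * sum(!positive))
}

lda_direction <- function(X, positive, ridge_frac = 1e-6) {
  X1 <- X[positive, , drop = FALSE]
  X0 <- X[!positive, , drop = FALSE]
  n1 <- nrow(X1); n0 <- nrow(X0)
  S <- ((n1 - 1) * stats::cov(X1) + (n0 - 1) * stats::cov(X0)) / (n1 + n0 - 2)
  eps <- max(ridge_frac * sum(diag(S)) / ncol(X), 1e-12)
  w <- solve(S + diag(eps, ncol(X)), colMeans(X1) - colMeans(X0))
  as.numeric(w)
}

#' Train a linear discriminant over a subset of shape modes
#'
#' Fisher discriminant with a small ridge on the pooled covariance:
#' `w = (S_pooled + eps I)^-1 (mu_pos - mu_neg)`,
#' `eps = ridge_frac * trace(S)/dim`. The threshold is the midpoint of the
#' projected group means and the resubstitution AUC is the rank AUC of the
#' projected scores.
#'
#' @param scores n_shapes x n_modes score matrix (standardized scores by
#'   default convention, but any affine per-mode scaling gives the same
#'   AUC).
#' @param labels two-level group labels; `positive` names the class given
#'   positive discriminant scores.
#' @param mode_subset integer vector of mode columns to combine (>= 1).
#' @param positive label of the positive class (default `"preterm"`).
#' @param ridge_frac ridge fraction for the pooled covariance.
#' @return an `lda_model`: `mode_subset`, `weights`, `threshold`,
#'   `auc_resub`, `loo_auc` (NA until filled by [loo_auc]).
#' @export
train_lda <- function(scores, labels, mode_subset, positive = "preterm",
                      ridge_frac = 1e-6) {
  stopifnot(length(mode_subset) >= 1)
  pos <- as.character(labels) == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  X <- scores[, mode_subset, drop = FALSE]
  w <- lda_direction(X, pos, ridge_frac)
  proj <- drop(X %*% w)
  thr <- (mean(proj[pos]) + mean(proj[!pos])) / 2
  structure(list(mode_subset = mode_subset, weights = w, threshold = thr,
                 auc_resub = auc_mw(proj, pos), loo_auc = NA_real_,
                 positive = positive),
            class = "lda_model")
}

#' Leave-one-out cross-validated AUC of an LDA mode combination
#'
#' Each observation is scored by a discriminant trained on the remaining
#' n - 1; the AUC of the held-out scores is returned.
#'
#' @inheritParams train_lda
#' @return LOO-CV AUC in \[0, 1\].
#' @export
loo_auc <- function(scores, labels, mode_subset, positive = "preterm",
                    ridge_frac = 1e-6) {
  pos <- as.character(labels) == positive
  X <- scores[, mode_subset, drop = FALSE]
  n <- nrow(X)
  held <- numeric(n)
  for (i in seq_len(n)) {
    w <- lda_direction(X[-i, , drop = FALSE], pos[-i], ridge_frac)
    held[i] <- drop(X[i, , drop = FALSE] %*% w)
  }
  auc_mw(held, pos)
}

#' Select the optimal mode subset by leave-one-out AUC
#'
#' Mode 1 is excluded as the general size mode; nested subsets
#' `{2}, {2,3}, ..., {2..max_mode}` are evaluated by [loo_auc] and the
#' smallest subset whose LOO AUC is within `tol` of the maximum is
#' returned together with the full AUC-versus-subset curve.
#'
#' @inheritParams train_lda
#' @param max_mode largest mode index to consider (<= number of modes).
#' @param tol AUC tolerance for preferring a smaller subset.
#' @return list with `subset` (selected mode indices), `model` (the
#'   [train_lda] fit on the selection, `loo_auc` filled in) and
#'   `auc_curve` (tibble of `max_mode`, `loo_auc`).
#' @export
select_mode_subset <- function(scores, labels, max_mode,
                               positive = "preterm", tol = 0.005,
                               ridge_frac = 1e-6) {
  stopifnot(max_mode >= 2, max_mode <= ncol(scores))
  tops <- 2:max_mode
  aucs <- vapply(tops, function(k)
    loo_auc(scores, labels, 2:k, positive, ridge_frac), 0)
  best <- max(aucs)
  pick <- tops[which(aucs >= best - tol)[1]]
  subset <- 2:pick
  model <- train_lda(scores, labels, subset, positive, ridge_frac)
  model$loo_auc <- aucs[match(pick, tops)]
  list(subset = subset, model = model,
       auc_curve = tibble::tibble(max_mode = tops, loo_auc = aucs))
}

#' Annulus and mid-cavity widths of a shape
#'
#' Annulus width is the distance between the first and last points (the
#' annulus corners); mid-cavity width is the maximal distance between
#' arc-mirrored point pairs. Their ratio summarizes the "narrow annulus
#' relative to mid-ventricular width" aspect of a reconstructed shape.
#'
#' @param points n_points x 2 matrix.
#' @return named vector `c(annulus, mid_width, ratio)`.
#' @export
measure_shape_widths <- function(points) {
  p <- contour_points(points)
  n <- nrow(p)
  annulus <- sqrt(sum((p[1, ] - p[n, ])^2))
  pair_d <- vapply(seq_len(floor(n / 2)), function(i)
    sqrt(sum((p[i, ] - p[n + 1 - i, ])^2)), 0)
  c(annulus = annulus, mid_width = max(pair_d),
    ratio = annulus / max(pair_d))
}
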