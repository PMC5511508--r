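# shared fixtures and independent oracles (kept deliberately separate from
# the implementation paths they check)

# a scaled-down generator configuration for fast structural tests
small_config <- function(n_pre = 20L, n_term = 20L, n_fetal = 25L) {
  cfg <- default_calibration()
  cfg$n_preterm <- n_pre
  cfg$n_term <- n_term
  cfg$fetal$n_fetal_only <- n_fetal
  for (st in names(cfg$shape_params))
    for (g in names(cfg$shape_params[[st]]))
      cfg$shape_params[[st]][[g]]$n_points <- 40L
  cfg
}

# quadrature oracle: cavity area of the noise-free superellipse family cell
# above the annulus chord, integrating the width profile in y
quad_area <- function(globularity, size_scale, annulus_ratio) {
  m <- 2 + 0.4 * globularity
  ratio <- 1.55 - 0.35 * globularity
  q <- (1 - annulus_ratio^m)^(1 / m)
  L <- size_scale / (1 - q)
  W <- size_scale / (annulus_ratio * ratio)
  f <- function(y) W * (1 - ((y + q * L) / L)^m)^(1 / m)
  stats::integrate(f, 0, L * (1 - q), rel.tol = 1e-10)$value
}

# SVD-based Kabsch oracle: proper rotation matrix aligning centered A to B
kabsch_svd <- function(A, B) {
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, d)) %*% t(sv$v)
}

# arc length of the noise-free endocardial family curve by fine quadrature
dense_arc_length <- function(globularity, size_scale, annulus_ratio,
                             n = 20001L) {
  cp <- generate_contour(globularity, size_scale, annulus_ratio,
                         wall_thickness = 0.2, n_points = n,
                         noise_sd = 0, seed = 1)
  contour_arc_length(cp$endo)
}

# standardized mode-score matrix of a contour cohort (endocardial borders)
cohort_shape_scores <- function(cohort) {
  out <- list()
  for (stage in c("birth", "followup")) {
    ids <- names(cohort$contours)[endsWith(names(cohort$contours), stage)]
    shp <- shapes_from_contours(cohort$contours[ids], "endo")
    sid <- sub(paste0("_", stage, "$"), "", ids)
    lab <- cohort$subjects$group[match(sid, cohort$subjects$subject_id)]
    al <- generalized_procrustes(shp)
    pdm <- fit_pdm(al)
    out[[stage]] <- list(scores = project(pdm, al)$standardized,
                         labels = lab, pdm = pdm, aligned = al)
  }
  out
}

# hand-rolled centile model with known truth, for recovery tests
true_centile_model <- function(sigma = 0.15) {
  mean_fn <- structure(list(powers = c(0, 1),
                            coefficients = c(-17.955, 6.213, -0.08541),
                            degree = 2L, deviance = NA_real_),
                       class = "fp_model")
  structure(list(mean_fn = mean_fn,
                 sd_fn = list(type = "constant", sigma = sigma),
                 range = c(15, 53), outcome = "lv_mass",
                 components = NULL),
            class = "centile_model")
}

simulate_from_model <- function(model, n, seed) {
  set.seed(seed)
  age <- runif(n, model$range[1], model$range[2])
  mu <- cardiogrowth::fp_predict(model$mean_fn, age)
  sig <- if (model$sd_fn$type == "constant") model$sd_fn$sigma else
    stop("constant sd only")
  data.frame(pma = age, lv_mass = exp(mu + rnorm(n, 0, sig)),
             subject_id = seq_len(n))
}
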