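#' Construct a contour set
#'
#' An ordered open 2D curve (cm) tracing one ventricular border in the
#' four-chamber plane from one annulus corner, around the apex, to the other
#' corner, with landmark indices for the two corners and the apex.
#'
#' @param points n x 2 numeric matrix of (x, y) in cm.
#' @param border `"endocardial"` or `"epicardial"`.
#' @param landmarks named integer vector `c(corner_a, apex, corner_b)`.
#' @return an object of class `contour_set`.
#' @export
contour_set <- function(points, border = c("endocardial", "epicardial"),
                        landmarks = NULL) {
  border <- match.arg(border)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 20)
  n <- nrow(points)
  if (is.null(landmarks))
    landmarks <- c(corner_a = 1L, apex = as.integer(floor(n / 2) + 1L),
                   corner_b = n)
  structure(list(points = unname(points), border = border,
                 landmarks = landmarks),
            class = "contour_set")
}

contour_points <- function(x) {
  if (inherits(x, "contour_set")) x$points else as.matrix(x)
}

#' Total arc length of a contour (cm)
#' @param contour a [contour_set] or point matrix.
#' @return arc length in cm.
#' @export
contour_arc_length <- function(contour) {
  p <- contour_points(contour)
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Planimetered cavity area of a contour (cm^2)
#'
#' Shoelace area of the polygon formed by the border closed across the
#' annulus chord (last point back to first).
#'
#' @param contour a [contour_set] or point matrix.
#' @return area in cm^2.
#' @export
contour_area <- function(contour) {
  p <- contour_points(contour)
  x <- p[, 1]; y <- p[, 2]
  i2 <- c(seq_len(nrow(p))[-1], 1L)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

#' Long-axis length of a contour (cm)
#'
#' Distance from the apex landmark to the annulus midpoint (midpoint of the
#' two corner landmarks).
#'
#' @param contour a [contour_set].
#' @return length in cm.
#' @export
contour_long_axis <- function(contour) {
  stopifnot(inherits(contour, "contour_set"))
  p <- contour$points
  lm <- contour$landmarks
  mid <- (p[lm[["corner_a"]], ] + p[lm[["corner_b"]], ]) / 2
  sqrt(sum((p[lm[["apex"]], ] - mid)^2))
}

# open-polyline self-intersection test (non-adjacent segment pairs)
is_simple_curve <- function(points) {
  p <- contour_points(points)
  n <- nrow(p) - 1L
  seg_int <- function(a, b, c, d) {
    cr <- function(o, u, v)
      (u[1] - o[1]) * (v[2] - o[2]) - (u[2] - o[2]) * (v[1] - o[1])
    d1 <- cr(c, d, a); d2 <- cr(c, d, b); d3 <- cr(a, b, c); d4 <- cr(a, b, d)
    ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
  }
  for (i in seq_len(n - 2L)) {
    for (j in seq((i + 2L), n)) {
      if (seg_int(p[i, ], p[i + 1L, ], p[j, ], p[j + 1L, ])) return(FALSE)
    }
  }
  TRUE
}

# dense superellipse arc between the annulus corners, annulus midpoint at
# origin, apex on the +y axis
superellipse_arc <- function(m, ratio, annulus_ratio, size_scale, n_dense) {
  q <- (1 - annulus_ratio^m)^(1 / m)
  L <- size_scale / (1 - q)
  W <- size_scale / (annulus_ratio * ratio)
  t_a <- acos(annulus_ratio^(m / 2))
  t <- seq(t_a, pi - t_a, length.out = n_dense)
  x <- (W / 2) * sign(cos(t)) * abs(cos(t))^(2 / m)
  y <- L * abs(sin(t))^(2 / m) - q * L
  cbind(x = x, y = y)
}

# resample a polyline at equal arc-length spacing
arc_resample <- function(p, n_points) {
  s <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  if (s[length(s)] <= 0) stop("degenerate (zero-length) contour")
  si <- seq(0, s[length(s)], length.out = n_points)
  cbind(approx(s, p[, 1], xout = si)$y, approx(s, p[, 2], xout = si)$y)
}

#' Generate a matched endocardial/epicardial contour pair
#'
#' The endocardial border is an arc of the superellipse
#' \eqn{|x/(W/2)|^m + |y/L|^m = 1}, truncated at the annulus chord of width
#' `annulus_ratio * W`, with the exponent m and the length/width ratio
#' smooth monotone functions of `globularity`: +1 gives a "globular"
#' ventricle (length/width 1.2, m = 2.4), -1 a "conical" one (length/width
#' 1.9, m = 1.6). The epicardial border is the outward normal offset of the
#' endocardial arc by `wall_thickness`. i.i.d. Gaussian noise of SD
#' `noise_sd` is added to every point; a pair whose borders self-intersect
#' after noise is regenerated with a jittered seed (error after 10
#' attempts). The annulus midpoint is at the origin and the apex on the +y
#' axis; the realised apex-to-annulus length of the noise-free endocardial
#' border equals `size_scale`.
#'
#' @param globularity shape parameter in \[-1, 1\].
#' @param size_scale apex-to-annulus-midpoint length, cm (> 0).
#' @param annulus_ratio annulus width as a fraction of maximal width (0, 1).
#' @param wall_thickness outward offset, cm (> 0).
#' @param n_points points per border (>= 20).
#' @param noise_sd per-point noise SD, cm (>= 0).
#' @param seed integer seed; the pair is deterministic given all arguments.
#' @return list with `endo` and `epi` [contour_set] objects.
#' @export
generate_contour <- function(globularity, size_scale, annulus_ratio = 0.9,
                             wall_thickness = 0.3, n_points = 50L,
                             noise_sd = 0, seed = 1L) {
  stopifnot(n_points >= 20, size_scale > 0, wall_thickness > 0,
            annulus_ratio > 0, annulus_ratio < 1,
            globularity >= -1, globularity <= 1, noise_sd >= 0)
  m <- 2 + 0.4 * globularity
  ratio <- 1.55 - 0.35 * globularity
  # odd count puts a dense vertex exactly at the apex (t = pi/2)
  n_dense <- max(401L, 8L * n_points + 1L)
  dense <- superellipse_arc(m, ratio, annulus_ratio, size_scale, n_dense)
  # outward normals from the dense tangent (curve runs counterclockwise,
  # interior on the left, so outward = (dy, -dx) normalised)
  tang <- rbind(dense[2, ] - dense[1, ],
                (dense[3:n_dense, ] - dense[1:(n_dense - 2), ]) / 2,
                dense[n_dense, ] - dense[n_dense - 1, ])
  nl <- sqrt(rowSums(tang^2))
  normal <- cbind(tang[, 2] / nl, -tang[, 1] / nl)
  dense_epi <- dense + wall_thickness * normal
  endo_p <- arc_resample(dense, n_points)
  epi_p <- arc_resample(dense_epi, n_points)
  apex_idx <- function(p) {
    mid <- (p[1, ] + p[nrow(p), ]) / 2
    which.max(sqrt((p[, 1] - mid[1])^2 + (p[, 2] - mid[2])^2))
  }
  for (attempt in 0:9) {
    set.seed(as.integer((seed + attempt * 9973) %% .Machine$integer.max))
    e1 <- endo_p + matrix(rnorm(2 * n_points, 0, noise_sd), ncol = 2)
    e2 <- epi_p + matrix(rnorm(2 * n_points, 0, noise_sd), ncol = 2)
    # the noise-free family is simple by construction (convex arc + offset)
    if (noise_sd == 0 || (is_simple_curve(e1) && is_simple_curve(e2))) {
      lmk <- function(p) c(corner_a = 1L, apex = as.integer(apex_idx(p)),
                           corner_b = nrow(p))
      return(list(
        endo = contour_set(e1, "endocardial", lmk(e1)),
        epi = contour_set(e2, "epicardial", lmk(e2))))
    }
  }
  stop("could not generate a simple contour pair in 10 attempts")
}

#' Resample a contour to equal arc-length spacing
#'
#' Points are placed equally spaced in arc length from corner A to corner B;
#' landmarks are reset to the first point, the resampled point nearest the
#' original apex, and the last point.
#'
#' @param contour a [contour_set].
#' @param n_points number of output points (>= 20).
#' @return a resampled [contour_set] with the same border type.
#' @export
resample_contour <- function(contour, n_points) {
  stopifnot(inherits(contour, "contour_set"), n_points >= 20)
  p <- arc_resample(contour$points, n_points)
  apex_old <- contour$points[contour$landmarks[["apex"]], ]
  apex_new <- which.min((p[, 1] - apex_old[1])^2 + (p[, 2] - apex_old[2])^2)
  contour_set(p, contour$border,
              c(corner_a = 1L, apex = as.integer(apex_new),
                corner_b = as.integer(n_points)))
}

#' Write / read contours as plain-text CSV
#'
#' One row per point with columns `contour_id`, `border`, `point_index`,
#' `x_cm`, `y_cm`, `landmark` (`""`, `"corner_a"`, `"apex"` or
#' `"corner_b"`).
#'
#' @param contours named list of [contour_set] objects.
#' @param path CSV file path.
#' @return `write_contours_csv` returns `path` invisibly;
#'   `read_contours_csv` the named list of contours.
#' @export
write_contours_csv <- function(contours, path) {
  rows <- lapply(names(contours), function(id) {
    ct <- contours[[id]]
    n <- nrow(ct$points)
    lmk <- rep("", n)
    lmk[ct$landmarks] <- names(ct$landmarks)
    data.frame(contour_id = id, border = ct$border, point_index = seq_len(n),
               x_cm = ct$points[, 1], y_cm = ct$points[, 2], landmark = lmk)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contours_csv
#' @export
read_contours_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$landmark[is.na(df$landmark)] <- ""
  out <- lapply(split(df, df$contour_id), function(d) {
    d <- d[order(d$point_index), ]
    lmk <- vapply(c("corner_a", "apex", "corner_b"),
                  function(nm) which(d$landmark == nm)[1], 1L)
    contour_set(cbind(d$x_cm, d$y_cm), d$border[1], lmk)
  })
  out[unique(df$contour_id)]
}
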