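#' Body surface area by the weight-only Boyd formula
#'
#' \deqn{BSA = 0.0004688 \cdot W^{\,0.8168 - 0.0154\log_{10} W}}
#' with W in grams and BSA in m^2. This weight-only variant is the standard
#' choice for neonates, where supine length is unreliable; it reproduces the
#' emulated cohort's printed mean BSA values from its printed mean weights
#' (2053 g -> 0.16 m^2, 3315 g -> 0.23 m^2, 4960 g -> 0.30 m^2). Strictly
#' increasing in weight over the physiologic range.
#'
#' @param weight_g body weight in grams (vectorised, all > 0).
#' @return body surface area in m^2.
#' @export
boyd_bsa <- function(weight_g) {
  if (any(!is.finite(weight_g)) || any(weight_g <= 0))
    stop("weight must be positive and finite")
  0.0004688 * weight_g^(0.8168 - 0.0154 * log10(weight_g))
}

#' Left ventricular mass from linear wall measures
#'
#' Cube-formula mass from the diastolic septal thickness (IVSd), internal
#' diameter (LVIDd) and posterior wall thickness (PWd), all in cm:
#' \deqn{mass = 0.8 \cdot 1.04\,[(IVSd + LVIDd + PWd)^3 - LVIDd^3] + 0.6\ g.}
#'
#' @param ivsd,lvidd,pwd linear measures in cm (vectorised, all >= 0).
#' @return mass in grams.
#' @export
lv_mass_linear <- function(ivsd, lvidd, pwd) {
  if (any(c(ivsd, lvidd, pwd) < 0)) stop("linear measures must be nonnegative")
  0.8 * 1.04 * ((ivsd + lvidd + pwd)^3 - lvidd^3) + 0.6
}

#' Single-plane area-length chamber volume
#'
#' \deqn{V = 8A^2 / (3\pi L)} with A the planimetered cavity area (cm^2) and
#' L the long-axis length (cm); returns ml.
#'
#' @param area cavity area, cm^2 (>= 0).
#' @param length long-axis length, cm (> 0).
#' @return volume in ml.
#' @export
area_length_volume <- function(area, length) {
  if (any(area < 0)) stop("area must be nonnegative")
  if (any(length <= 0)) stop("length must be positive")
  8 * area^2 / (3 * pi * length)
}

#' Myocardial shell mass from an endocardial/epicardial border pair
#'
#' Applies the area-length volume to each border's own planimetered area,
#' using the shared long-axis length of the epicardial border (epicardial
#' apex to annulus midpoint), and converts the shell volume to mass with a
#' myocardial density of 1.05 g/ml.
#'
#' @param endo,epi matched [contour_set] borders in the same orientation.
#' @return mass in grams.
#' @export
shell_mass_from_contours <- function(endo, epi) {
  a_endo <- contour_area(endo)
  a_epi <- contour_area(epi)
  if (a_epi < a_endo)
    stop("epicardial area is smaller than endocardial area")
  len <- contour_long_axis(epi)
  1.05 * (area_length_volume(a_epi, len) - area_length_volume(a_endo, len))
}

#' Percent change of an indexed measure from birth to follow-up
#'
#' @param birth_index baseline value (> 0).
#' @param followup_index follow-up value.
#' @return percent change, 100 (followup - birth) / birth.
#' @export
percent_change <- function(birth_index, followup_index) {
  if (any(birth_index <= 0)) stop("baseline must be positive")
  100 * (followup_index - birth_index) / birth_index
}

safe_ratio <- function(num, den, what) {
  out <- num / den
  bad <- !is.na(den) & den == 0
  if (any(bad, na.rm = TRUE)) {
    warning(sprintf("division by zero in %s for %d visit(s); set to NA",
                    what, sum(bad)))
    out[bad] <- NA_real_
  }
  out
}

#' Derive the full set of indexed and functional measures for a cohort table
#'
#' Vectorised over the rows of a visit-level cohort table (one row per
#' visit, columns as written by [generate_cohort]). Adds: `bsa` (Boyd, from
#' `weight`), the BSA-indexed `lvmi`, `rvmi`, `lv_edvi`, `lv_esvi`,
#' `rv_edvi`, `ef` (%), `sv` (ml), `mass_edv_ratio`, `ea_ratio`,
#' `e_over_eprime`, `mass_per_hc` (g/cm) and the cube-formula
#' `lv_mass_linear`. Missing inputs propagate to missing outputs; a zero
#' denominator yields NA with a warning.
#'
#' @param visits visit-level data frame.
#' @return the input with derived columns appended.
#' @export
derive_measures <- function(visits) {
  v <- tibble::as_tibble(visits)
  n <- nrow(v)
  col <- function(nm) if (nm %in% names(v)) v[[nm]] else rep(NA_real_, n)
  weight <- col("weight")
  bsa <- rep(NA_real_, n)
  ok <- !is.na(weight) & weight > 0
  bsa[ok] <- boyd_bsa(weight[ok])
  v$bsa <- bsa
  v$lvmi <- safe_ratio(col("lv_mass"), bsa, "lvmi")
  v$rvmi <- safe_ratio(col("rv_mass"), bsa, "rvmi")
  v$lv_edvi <- safe_ratio(col("lv_edv"), bsa, "lv_edvi")
  v$lv_esvi <- safe_ratio(col("lv_esv"), bsa, "lv_esvi")
  v$rv_edvi <- safe_ratio(col("rv_edv"), bsa, "rv_edvi")
  v$sv <- col("lv_edv") - col("lv_esv")
  v$ef <- 100 * safe_ratio(v$sv, col("lv_edv"), "ef")
  v$mass_edv_ratio <- safe_ratio(col("lv_mass"), col("lv_edv"),
                                 "mass_edv_ratio")
  v$ea_ratio <- safe_ratio(col("mv_e"), col("mv_a"), "ea_ratio")
  v$e_over_eprime <- safe_ratio(col("mv_e"), col("lat_e_prime"),
                                "e_over_eprime")
  v$mass_per_hc <- safe_ratio(col("lv_mass"), col("hc"), "mass_per_hc")
  lm_in <- !is.na(col("ivsd")) & !is.na(col("lvidd")) & !is.na(col("pwd"))
  v$lv_mass_linear <- rep(NA_real_, n)
  v$lv_mass_linear[lm_in] <- lv_mass_linear(col("ivsd")[lm_in],
                                            col("lvidd")[lm_in],
                                            col("pwd")[lm_in])
  v
}

#' Derive measures for a single visit record
#'
#' Row-wise convenience wrapper around [derive_measures]: takes one visit as
#' a named list or one-row data frame and returns the derived quantities as
#' a named list.
#'
#' @param visit named list or one-row data frame of raw echo measures.
#' @return named list of derived measures.
#' @export
derive_all <- function(visit) {
  row <- tibble::as_tibble(lapply(as.list(visit), function(x) x[1]))
  out <- derive_measures(row)
  keep <- c("bsa", "lvmi", "rvmi", "lv_edvi", "lv_esvi", "rv_edvi", "ef",
            "sv", "mass_edv_ratio", "ea_ratio", "e_over_eprime",
            "mass_per_hc", "lv_mass_linear")
  as.list(out[1, keep])
}
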