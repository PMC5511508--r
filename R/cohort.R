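# truncated-normal echo sampling: two-sided at mean +/- 4 SD, floored at the
# physiologic minimum of the measure
sample_echo <- function(n, cell) {
  lo <- max(cell$floor, cell$mean - 4 * cell$sd)
  hi <- cell$mean + 4 * cell$sd
  if (cell$sd == 0) return(rep(cell$mean, n))
  rtruncnorm(n, cell$mean, cell$sd, lo, hi)
}

hc_at <- function(hc_model, pma, subject_factor = 1) {
  subject_factor * hc_model$hmax /
    (1 + exp(-hc_model$k * (pma - hc_model$t0)))
}

fetal_log_mass <- function(fm, pma) {
  unname(fm$lv["b0"] + fm$lv["b_log"] * log(pma) + fm$lv["b_lin"] * pma)
}

# one stage's worth of echo draws for a group, as a tibble of indexed and
# linear measures (indices are per-BSA; raw values are attached later)
draw_echo_stage <- function(n, cells) {
  out <- lapply(cells, function(cell) sample_echo(n, cell))
  tibble::as_tibble(out)
}

#' Generate a synthetic preterm/term cohort
#'
#' Samples subjects and longitudinal visits with the statistical structure
#' the downstream analyses assume: two birth groups with truncated-normal
#' gestational ages (disjoint at `config$ga_cut`), birth and 3-month echo
#' measures drawn from the configured group distributions, per-infant
#' percent mass-index change following the linear GA-effect model
#' (`followup index = birth index * (1 + pct/100)`), a logistic
#' head-circumference curve monotone in postmenstrual age, an optional
#' fetal scan history (1-5 visits per scanned fetus), and optional
#' parametric four-chamber contour pairs per postnatal visit.
#'
#' Output is deterministic for fixed `(config, seed)`; every stage draws
#' from its own named substream, so disabling contours or fetal visits does
#' not perturb the neonatal draws.
#'
#' @param config a [generator_config][default_calibration].
#' @param seed integer seed; defaults to `config$seed`.
#' @param n_preterm,n_term group sizes (default from `config`).
#' @param include_fetal add fetal-only subjects and fetal visit rows.
#' @param include_contours attach endocardial/epicardial contour pairs to
#'   postnatal visits.
#' @return list with `subjects` (one row per subject), `visits` (one row
#'   per assessment) and `contours` (named list of border pairs, possibly
#'   empty).
#' @export
generate_cohort <- function(config, seed = config$seed,
                            n_preterm = config$n_preterm,
                            n_term = config$n_term,
                            include_fetal = TRUE,
                            include_contours = TRUE) {
  validate_config(config)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  seed <- as.integer(seed)
  n_neo <- n_preterm + n_term
  group <- rep(c("preterm", "term"), c(n_preterm, n_term))
  id <- sprintf("S%05d", seq_len(n_neo))

  ## subjects ----------------------------------------------------------
  set.seed(sub_seed(seed, "subjects"))
  ga <- numeric(n_neo)
  gp <- config$ga_birth$preterm; gt <- config$ga_birth$term
  ga[group == "preterm"] <- rtruncnorm(n_preterm, gp["mean"], gp["sd"],
                                       gp["mean"] - 4 * gp["sd"],
                                       config$ga_cut)
  ga[group == "term"] <- rtruncnorm(n_term, gt["mean"], gt["sd"],
                                    config$ga_cut,
                                    gt["mean"] + 4 * gt["sd"])
  draw_group <- function(spec_list, floor = -Inf) {
    out <- numeric(n_neo)
    for (g in c("preterm", "term")) {
      p <- spec_list[[g]]
      k <- sum(group == g)
      out[group == g] <- rtruncnorm(k, p["mean"], p["sd"],
                                    max(floor, p["mean"] - 4 * p["sd"]),
                                    p["mean"] + 4 * p["sd"])
    }
    out
  }
  flag <- function(probs) rbinom(n_neo, 1L, unname(probs[group])) == 1L
  apgar <- integer(n_neo)
  for (g in c("preterm", "term")) {
    pr <- config$apgar5_probs[[g]]
    apgar[group == g] <- sample(as.integer(names(pr)), sum(group == g),
                                replace = TRUE, prob = pr)
  }
  subjects <- tibble::tibble(
    subject_id = id, cohort = "neonatal", group = group, ga_birth = ga,
    birthweight = draw_group(config$anthropometry$birthweight, floor = 300),
    birthweight_z = draw_group(config$anthropometry$birthweight_z),
    sex = ifelse(flag(config$covariate_probs$male), "male", "female"),
    steroids = flag(config$covariate_probs$steroids),
    cesarean = flag(config$covariate_probs$cesarean),
    hypertension = flag(config$covariate_probs$hypertension),
    multiple = flag(config$covariate_probs$multiple),
    apgar5 = apgar)

  ## percent mass-index change (GA-effect model) -----------------------
  set.seed(sub_seed(seed, "ga-effect"))
  eff <- config$ga_effect
  pct_lv <- eff$lv$alpha + eff$lv$beta * ga + rnorm(n_neo, 0, eff$lv$sigma_eps)
  pct_rv <- eff$rv$alpha + eff$rv$beta * ga + rnorm(n_neo, 0, eff$rv$sigma_eps)
  pct_lv <- pmax(pct_lv, config$pct_change_floor)
  pct_rv <- pmax(pct_rv, config$pct_change_floor)

  ## postnatal visits ---------------------------------------------------
  set.seed(sub_seed(seed, "visits"))
  hc_subj <- exp(rnorm(n_neo, 0, config$hc_model$subject_log_sd))
  age_birth <- round(draw_group(config$anthropometry$age_days_birth,
                                floor = 0))
  age_fu <- round(draw_group(config$anthropometry$age_days_followup,
                             floor = 30))
  pma_birth <- ga + age_birth / 7
  pma_fu <- ga + age_fu / 7
  wt_birth <- subjects$birthweight
  wt_fu <- pmax(draw_group(config$anthropometry$weight_followup,
                           floor = 1500), wt_birth + 200)

  eb <- config$echo$birth; ef_ <- config$echo$followup
  echo_b <- rbind(draw_echo_stage(n_preterm, eb$preterm),
                  draw_echo_stage(n_term, eb$term))
  echo_f <- rbind(draw_echo_stage(n_preterm, ef_$preterm),
                  draw_echo_stage(n_term, ef_$term))
  # end-systolic never exceeds end-diastolic volume
  echo_b$lv_esvi <- pmin(echo_b$lv_esvi, 0.95 * echo_b$lv_edvi)
  echo_f$lv_esvi <- pmin(echo_f$lv_esvi, 0.95 * echo_f$lv_edvi)
  # follow-up mass indices are the birth draw carried through the percent
  # change, not an independent draw
  lvmi_fu <- echo_b$lvmi * (1 + pct_lv / 100)
  rvmi_fu <- echo_b$rvmi * (1 + pct_rv / 100)

  visit_rows <- function(stage_name, pma, age_days, weight, echo, lvmi, rvmi) {
    bsa <- boyd_bsa(weight)
    fu <- stage_name == "followup"
    tibble::tibble(
      subject_id = id, stage = stage_name, pma = pma, age_days = age_days,
      weight = weight, hc = hc_at(config$hc_model, pma, hc_subj),
      lv_edv = echo$lv_edvi * bsa, lv_esv = echo$lv_esvi * bsa,
      lv_mass = lvmi * bsa, rv_edv = echo$rv_edvi * bsa,
      rv_mass = rvmi * bsa, ivsd = echo$ivsd, lvidd = echo$lvidd,
      pwd = echo$pwd, tapse = echo$tapse,
      mv_e = echo$e_over_eprime * echo$lat_e_prime,
      mv_a = echo$e_over_eprime * echo$lat_e_prime / echo$ea_ratio,
      lat_e_prime = echo$lat_e_prime,
      pct_lvmi = if (fu) pct_lv else NA_real_,
      pct_rvmi = if (fu) pct_rv else NA_real_,
      contour_id = NA_character_)
  }
  visits <- rbind(
    visit_rows("birth", pma_birth, age_birth, wt_birth, echo_b,
               echo_b$lvmi, echo_b$rvmi),
    visit_rows("followup", pma_fu, age_fu, wt_fu, echo_f, lvmi_fu, rvmi_fu))

  ## fetal visits -------------------------------------------------------
  if (include_fetal) {
    set.seed(sub_seed(seed, "fetal"))
    n_extra <- config$fetal$n_fetal_only
    extra_id <- sprintf("F%05d", seq_len(n_extra))
    extra_ga <- rtruncnorm(n_extra, gt["mean"], gt["sd"], config$ga_cut,
                           gt["mean"] + 4 * gt["sd"])
    subjects <- rbind(subjects, tibble::tibble(
      subject_id = extra_id, cohort = "fetal", group = "term",
      ga_birth = extra_ga, birthweight = NA_real_, birthweight_z = NA_real_,
      sex = sample(c("male", "female"), n_extra, replace = TRUE),
      steroids = FALSE, cesarean = NA, hypertension = FALSE,
      multiple = FALSE, apgar5 = NA_integer_))
    neo_scan <- runif(n_neo) < config$fetal$neonatal_fetal_fraction
    scan_id <- c(id[neo_scan], extra_id)
    scan_ga <- c(ga[neo_scan], extra_ga)
    scan_hc <- c(hc_subj[neo_scan], exp(rnorm(n_extra, 0,
                                              config$hc_model$subject_log_sd)))
    fm <- config$fetal_mass
    u <- rnorm(length(scan_id), 0, fm$subject_sd)
    k_visits <- sample(seq_along(config$fetal$visit_count_probs),
                       length(scan_id), replace = TRUE,
                       prob = config$fetal$visit_count_probs)
    frows <- vector("list", length(scan_id))
    for (i in seq_along(scan_id)) {
      hi <- min(config$fetal$age_range[2], scan_ga[i] - 0.5)
      pma <- sort(runif(k_visits[i], config$fetal$age_range[1], hi))
      lv <- exp(fetal_log_mass(fm, pma) + u[i] +
                  rnorm(k_visits[i], 0, fm$resid_sd))
      rv <- exp(log(lv) + fm$rv_log_offset +
                  rnorm(k_visits[i], 0, fm$resid_sd / 2))
      frows[[i]] <- tibble::tibble(
        subject_id = scan_id[i], stage = "fetal", pma = pma,
        age_days = NA_real_, weight = NA_real_,
        hc = hc_at(config$hc_model, pma, scan_hc[i]),
        lv_edv = NA_real_, lv_esv = NA_real_, lv_mass = lv,
        rv_edv = NA_real_, rv_mass = rv, ivsd = NA_real_,
        lvidd = NA_real_, pwd = NA_real_, tapse = NA_real_,
        mv_e = NA_real_, mv_a = NA_real_, lat_e_prime = NA_real_,
        pct_lvmi = NA_real_, pct_rvmi = NA_real_,
        contour_id = NA_character_)
    }
    visits <- rbind(visits, do.call(rbind, frows))
  }

  ## contours -----------------------------------------------------------
  contours <- list()
  if (include_contours) {
    set.seed(sub_seed(seed, "contours"))
    for (stage in c("birth", "followup")) {
      for (g in c("preterm", "term")) {
        fam <- config$shape_params[[stage]][[g]]
        idx <- which(group == g)
        glob <- pmin(pmax(rnorm(length(idx), fam$globularity,
                                fam$globularity_sd), -1), 1)
        size <- rtruncnorm(length(idx), fam$size_scale, fam$size_sd,
                           0.5, fam$size_scale + 4 * fam$size_sd)
        wall <- rtruncnorm(length(idx), fam$wall_thickness, fam$wall_sd,
                           0.05, fam$wall_thickness + 4 * fam$wall_sd)
        cseed <- sample.int(.Machine$integer.max, length(idx))
        for (j in seq_along(idx)) {
          cid <- paste0(id[idx[j]], "_", stage)
          contours[[cid]] <- generate_contour(
            glob[j], size[j], fam$annulus_ratio, wall[j],
            fam$n_points, fam$noise_sd, cseed[j])
          visits$contour_id[visits$subject_id == id[idx[j]] &
                              visits$stage == stage] <- cid
        }
      }
    }
  }

  list(subjects = subjects, visits = visits, contours = contours)
}

#' Write / read a cohort as a flat UTF-8 CSV
#'
#' One row per visit with the subject covariates joined on `subject_id`;
#' missing values as empty fields.
#'
#' @param cohort list with `subjects` and `visits` as returned by
#'   [generate_cohort].
#' @param path CSV file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   the joined visit-level tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  joined <- merge(cohort$visits, cohort$subjects, by = "subject_id",
                  sort = FALSE)
  utils::write.csv(joined, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    fileEncoding = "UTF-8"))
}
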