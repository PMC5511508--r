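p_flag <- function(p) {
  ifelse(p < 0.001, "†", ifelse(p < 0.01, "**",
                                     ifelse(p < 0.05, "*", "")))
}

#' Group-by-stage summary table of cardiac structure and function
#'
#' Mean (SD) per group at the birth and 3-month assessments for the
#' standard measure set (volumes, mass indices, mass/EDV, ejection
#' fraction, stroke volume, TAPSE, diastolic indices), with the two-group
#' test p-value per stage flagged at * p<0.05, ** p<0.01, and a dagger for
#' p<0.001.
#'
#' @param derived derived visit-level table ([derive_measures]) joined with
#'   the subject `group` column.
#' @param method two-group test passed to [two_group_test].
#' @param digits display rounding for the mean (SD) strings.
#' @return tibble: `measure`, `stage`, `preterm`, `term` (mean (SD)
#'   strings), `p_value`, `flag`.
#' @export
summarize_table2 <- function(derived, method = "welch", digits = 1) {
  measures <- c("lv_edv", "lv_edvi", "lv_esv", "lv_esvi", "lv_mass", "lvmi",
                "mass_edv_ratio", "ef", "sv", "ea_ratio", "lat_e_prime",
                "e_over_eprime", "ivsd", "pwd", "tapse",
                "rv_edv", "rv_edvi", "rv_mass", "rvmi")
  measures <- intersect(measures, names(derived))
  if (!"group" %in% names(derived)) stop("derived table must carry 'group'")
  rows <- list()
  for (stage in c("birth", "followup")) {
    d <- derived[derived$stage == stage, ]
    for (m in measures) {
      a <- d[[m]][d$group == "preterm"]; a <- a[is.finite(a)]
      b <- d[[m]][d$group == "term"]; b <- b[is.finite(b)]
      if (length(a) < 2 || length(b) < 2) stop("empty group for ", m)
      tt <- two_group_test(a, b, method)
      fmt <- function(v) sprintf(paste0("%.", digits, "f (%.", digits, "f)"),
                                 mean(v), stats::sd(v))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        measure = m, stage = stage, preterm = fmt(a), term = fmt(b),
        p_value = tt$p_value, flag = p_flag(tt$p_value))
    }
  }
  do.call(rbind, rows)
}

hash_or_na <- function(path) {
  if (file.exists(path)) unname(tools::md5sum(path)) else NA_character_
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates generate -> derive -> centiles -> shape -> stats into one
#' deterministic run: writes the cohort and contour CSVs, the derived
#' table, centile-model JSONs with curve exports, the shape-model summary,
#' the statistics JSON, and a markdown summary table. Any requested prefix
#' of the stage DAG may be run; later stages read the in-memory results of
#' earlier ones. A stage failure halts the run with an error naming the
#' stage.
#'
#' @param config a [generator_config][default_calibration].
#' @param outdir output directory (created if needed).
#' @param seed master seed for the run (defaults to `config$seed`).
#' @param stages stages to run; must be a prefix of
#'   `c("generate", "derive", "centiles", "shape", "stats")`.
#' @return a `run_report` list: per-stage status, output files with md5
#'   hashes, and element counts.
#' @export
run_pipeline <- function(config = default_calibration(), outdir,
                         seed = config$seed,
                         stages = c("generate", "derive", "centiles",
                                    "shape", "stats")) {
  all_stages <- c("generate", "derive", "centiles", "shape", "stats")
  stopifnot(all(stages %in% all_stages))
  if (!identical(stages, all_stages[seq_along(stages)]))
    stop("stages must form a prefix of the pipeline DAG")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  status <- list()
  files <- character()
  counts <- list()
  out <- function(f) file.path(outdir, f)
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    status[[name]] <<- "ok"
    res
  }

  cohort <- derived <- NULL
  if ("generate" %in% stages) {
    cohort <- run_stage("generate", {
      ch <- generate_cohort(config, seed = seed)
      write_cohort_csv(ch, out("cohort.csv"))
      if (length(ch$contours)) {
        flat <- list()
        for (id in names(ch$contours)) {
          flat[[paste0(id, "_endo")]] <- ch$contours[[id]]$endo
          flat[[paste0(id, "_epi")]] <- ch$contours[[id]]$epi
        }
        write_contours_csv(flat, out("contours.csv"))
      }
      ch
    })
    files <- c(files, out("cohort.csv"), out("contours.csv"))
    counts$subjects <- nrow(cohort$subjects)
    counts$visits <- nrow(cohort$visits)
    counts$contour_pairs <- length(cohort$contours)
  }
  if ("derive" %in% stages) {
    derived <- run_stage("derive", {
      joined <- merge(cohort$visits, cohort$subjects, by = "subject_id",
                      sort = FALSE)
      d <- derive_measures(joined)
      utils::write.csv(d, out("derived.csv"), row.names = FALSE, na = "")
      d
    })
    files <- c(files, out("derived.csv"))
  }
  if ("centiles" %in% stages) {
    run_stage("centiles", {
      ref <- derived[derived$group == "term", ]
      for (oc in c("lv_mass", "rv_mass", "mass_per_hc")) {
        mdl <- fit_centile_model(ref, oc, repeated = TRUE)
        write_centile_model(mdl, out(paste0("centiles_", oc, ".json")))
        export_centile_curves(mdl, out(paste0("centiles_", oc, ".csv")))
      }
    })
    files <- c(files, out("centiles_lv_mass.json"), out("centiles_lv_mass.csv"),
               out("centiles_rv_mass.json"), out("centiles_rv_mass.csv"),
               out("centiles_mass_per_hc.json"),
               out("centiles_mass_per_hc.csv"))
  }
  shape_res <- NULL
  if ("shape" %in% stages) {
    shape_res <- run_stage("shape", {
      res <- list()
      for (stage in c("birth", "followup")) {
        ids <- names(cohort$contours)[endsWith(names(cohort$contours),
                                               stage)]
        shp <- shapes_from_contours(cohort$contours[ids], "endo")
        sid <- sub(paste0("_", stage, "$"), "", ids)
        lab <- cohort$subjects$group[match(sid, cohort$subjects$subject_id)]
        aligned <- generalized_procrustes(shp, retain_scale = TRUE)
        pdm <- fit_pdm(aligned)
        sc <- project(pdm, aligned)$standardized
        max_mode <- min(8L, ncol(sc))
        sel <- select_mode_subset(sc, lab, max_mode)
        res[[stage]] <- list(
          per_mode = per_mode_group_test(sc[, seq_len(max_mode)], lab),
          selection = sel)
        ext <- rbind(
          data.frame(extreme = "+3SD",
                     reconstruct_axis(pdm, sel$model, +3)),
          data.frame(extreme = "-3SD",
                     reconstruct_axis(pdm, sel$model, -3)))
        utils::write.csv(ext, out(paste0("shape_extremes_", stage, ".csv")),
                         row.names = FALSE)
      }
      json <- lapply(res, function(r) list(
        subset = r$selection$subset,
        loo_auc = r$selection$model$loo_auc,
        auc_resub = r$selection$model$auc_resub,
        per_mode_p = r$per_mode$p_value))
      jsonlite::write_json(json, out("shape_model.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      res
    })
    files <- c(files, out("shape_model.json"),
               out("shape_extremes_birth.csv"),
               out("shape_extremes_followup.csv"))
  }
  if ("stats" %in% stages) {
    run_stage("stats", {
      tbl <- summarize_table2(derived)
      md <- c("| Measure | Stage | Preterm | Term | p |",
              "|---|---|---|---|---|",
              sprintf("| %s | %s | %s | %s | %.3g%s |", tbl$measure,
                      tbl$stage, tbl$preterm, tbl$term, tbl$p_value,
                      tbl$flag))
      writeLines(md, out("summary_table.md"))
      b <- derived[derived$stage == "birth", ]
      f <- derived[derived$stage == "followup", ]
      i <- match(b$subject_id, f$subject_id)
      pct <- percent_change(b$lvmi, f$lvmi[i])
      ga <- b$ga_birth
      stats_out <- list(
        pct_lvmi_preterm = mean(pct[b$group == "preterm"], na.rm = TRUE),
        pct_lvmi_term = mean(pct[b$group == "term"], na.rm = TRUE),
        r_ga_pct_lvmi = pearson_r(ga, pct)$estimate,
        mde_sd_units = mde_two_sample(sum(b$group == "term"),
                                      sum(b$group == "preterm")))
      jsonlite::write_json(stats_out, out("stats.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    })
    files <- c(files, out("summary_table.md"), out("stats.json"))
  }
  report <- list(stages = status, seed = seed,
                 files = tibble::tibble(file = files,
                                        md5 = vapply(files, hash_or_na, "")),
                 counts = counts)
  class(report) <- "run_report"
  report
}

# shape at +/- k SD along a fitted discriminant axis, as x/y data frame
reconstruct_axis <- function(pdm, lda_model, k) {
  w <- lda_model$weights / sqrt(sum(lda_model$weights^2))
  scores <- numeric(max(lda_model$mode_subset))
  scores[lda_model$mode_subset] <- k * w
  p <- reconstruct(pdm, scores)
  data.frame(x_cm = p[, 1], y_cm = p[, 2])
}
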