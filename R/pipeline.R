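# End-to-end orchestration: cohort -> traces -> ROIs -> first-order +
# texture features -> visual scores -> correlations, LOPO SVR, kappa,
# ROC/AUC -> result bundle.

resolve_frames <- function(patient) {
  if (is.null(patient$frames)) load_patient_frames(patient) else patient
}

#' Per-frame texture features for a whole cohort
#'
#' For every frame: pleural trace (automatic unless supplied), constant-area
#' ROI, 44-dimensional GLCM feature vector.
#'
#' @param cohort an `lus_cohort`
#' @param area ROI area in pixels
#' @param levels,distance GLCM settings, see [feature_vector()]
#' @param traces optional named list of [pleural_trace()] keyed by
#'   `"<patient_id>/<view>"`; missing entries fall back to [auto_trace()]
#' @return list: `features` (n_frames x 44 matrix), `meta` (data frame
#'   `patient_id`, `view`), `conventions` (table of fired degenerate-case
#'   conventions)
#' @export
cohort_features <- function(cohort, area = 50000, levels = 256, distance = 2,
                            traces = NULL) {
  rows <- list(); meta <- list(); conv <- character(0)
  for (p in cohort) {
    p <- resolve_frames(p)
    for (f in p$frames) {
      key <- paste0(p$patient_id, "/", f$view)
      tr <- if (!is.null(traces) && key %in% names(traces)) traces[[key]]
      else auto_trace(f)
      roi <- build_roi(tr, dim(f$pixels), area)
      fv <- feature_vector(f, roi, levels = levels, distance = distance)
      conv <- c(conv, attr(fv, "conventions"))
      rows[[key]] <- fv
      meta[[key]] <- data.frame(patient_id = p$patient_id, view = f$view,
                                stringsAsFactors = FALSE)
    }
  }
  list(features = do.call(rbind, rows), meta = do.call(rbind, c(meta, list(make.row.names = FALSE))),
       conventions = table(conv))
}

#' Per-frame ROI mean intensities and per-patient intensity scores
#'
#' @inheritParams cohort_features
#' @return list: `frame_means` (data frame `patient_id`, `view`, `mean`),
#'   `scores` (named per-patient mean intensity score)
#' @export
cohort_intensity <- function(cohort, area = 50000, traces = NULL) {
  fm <- list()
  for (p in cohort) {
    p <- resolve_frames(p)
    means <- vapply(p$frames, function(f) {
      key <- paste0(p$patient_id, "/", f$view)
      tr <- if (!is.null(traces) && key %in% names(traces)) traces[[key]]
      else auto_trace(f)
      roi <- build_roi(tr, dim(f$pixels), area)
      first_order_stats(extract_pixels(f, roi))$mean
    }, numeric(1))
    fm[[p$patient_id]] <- data.frame(patient_id = p$patient_id,
                                     view = vapply(p$frames, function(f) f$view, character(1)),
                                     mean = means, stringsAsFactors = FALSE)
  }
  frame_means <- do.call(rbind, c(fm, list(make.row.names = FALSE)))
  scores <- vapply(split(frame_means$mean, frame_means$patient_id), mean, numeric(1))
  list(frame_means = frame_means, scores = scores)
}

#' Per-patient oxygenation indices of a cohort
#'
#' @param cohort an `lus_cohort`
#' @return data frame: `patient_id`, `fio2`, `pao2`, `paco2`, `pf_ratio`,
#'   `aa_gradient`
#' @export
cohort_indices <- function(cohort) {
  do.call(rbind, lapply(cohort, function(p) {
    data.frame(patient_id = p$patient_id, fio2 = p$fio2, pao2 = p$pao2,
               paco2 = p$paco2,
               pf_ratio = pf_ratio(p$pao2, p$fio2),
               aa_gradient = aa_gradient(p$fio2, p$pao2, p$paco2),
               stringsAsFactors = FALSE)
  }))
}

#' Pipeline run configuration
#'
#' @param mode `"synthetic"` (generate a cohort) or `"manifest"` (read one)
#' @param n_patients synthetic cohort size
#' @param manifest_path manifest CSV for manifest mode
#' @param views_per_patient frames per patient
#' @param rater_error_rate simulated rater error (synthetic mode)
#' @param roi_areas ROI areas to analyze (pixels)
#' @param glcm_levels,glcm_distance GLCM settings
#' @param pf_cutoff,aa_cutoff dichotomization cutoffs (mmHg)
#' @param groups feature groups for [group_analysis()] (`NULL` to skip,
#'   `c("all","1","2","3")` for the full table)
#' @param pca_k component counts for [pca_sweep()] (`NULL` to skip)
#' @param seed global seed
#' @param out_dir optional output directory for CSV/JSON results
#' @return list of class `run_config`
#' @export
run_config <- function(mode = c("synthetic", "manifest"), n_patients = 75,
                       manifest_path = NULL, views_per_patient = 8,
                       rater_error_rate = 0.05, roi_areas = c(50000, 100000),
                       glcm_levels = 256, glcm_distance = 2,
                       pf_cutoff = 200, aa_cutoff = 150,
                       groups = "all", pca_k = NULL, seed = 1L,
                       out_dir = NULL) {
  mode <- match.arg(mode)
  stop_if_not(length(roi_areas) >= 1 && all(roi_areas > 0), "need at least one ROI area")
  stop_if_not(pf_cutoff > 0 && aa_cutoff > 0, "cutoffs must be positive")
  if (mode == "manifest") stop_if_not(!is.null(manifest_path), "manifest mode needs manifest_path")
  structure(list(mode = mode, n_patients = n_patients,
                 manifest_path = manifest_path,
                 views_per_patient = views_per_patient,
                 rater_error_rate = rater_error_rate, roi_areas = roi_areas,
                 glcm_levels = glcm_levels, glcm_distance = glcm_distance,
                 pf_cutoff = pf_cutoff, aa_cutoff = aa_cutoff,
                 groups = groups, pca_k = pca_k, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes cohort generation (or manifest loading), pleural tracing, ROI
#' construction for each configured area, first-order intensity scoring,
#' 44-dimensional texture features, visual score sums, Spearman
#' correlations of both scores with both oxygenation indices, frame-level
#' interobserver kappa, LOPO SVR with per-group AUCs and an optional PCA
#' sweep, and ROC/AUC of every score at the configured cutoffs.
#'
#' @param config a [run_config()]
#' @return a result list (class `lus_run`); see the elements `indices`,
#'   `visual`, `kappa`, `per_area` (per ROI area: intensity scores,
#'   correlations, model results), and `log`
#' @export
run_pipeline <- function(config = run_config()) {
  stop_if_not(inherits(config, "run_config"), "config must be a run_config")

  cohort <- stage("cohort", {
    if (config$mode == "synthetic") {
      generate_cohort(cohort_config(
        n_patients = config$n_patients,
        views_per_patient = config$views_per_patient,
        rater_error_rate = config$rater_error_rate, seed = config$seed))
    } else {
      read_cohort_manifest(config$manifest_path,
                           views_per_patient = config$views_per_patient,
                           load_frames = TRUE)
    }
  })

  indices <- stage("indices", cohort_indices(cohort))
  pf <- stats::setNames(indices$pf_ratio, indices$patient_id)
  aa <- stats::setNames(indices$aa_gradient, indices$patient_id)

  visual <- stage("visual_score", {
    sums <- do.call(rbind, lapply(cohort, function(p) {
      data.frame(patient_id = p$patient_id,
                 rater1 = visual_score_sum(p$rater_grades$rater1, config$views_per_patient),
                 rater2 = visual_score_sum(p$rater_grades$rater2, config$views_per_patient),
                 stringsAsFactors = FALSE)
    }))
    sums$consensus <- (sums$rater1 + sums$rater2) / 2
    sums
  })
  vis <- stats::setNames(visual$consensus, visual$patient_id)

  kappa <- stage("kappa", {
    g1 <- unlist(lapply(cohort, function(p) p$rater_grades$rater1))
    g2 <- unlist(lapply(cohort, function(p) p$rater_grades$rater2))
    list(frame_level = cohen_kappa(g1, g2),
         patient_sums = cohen_kappa(visual$rater1, visual$rater2,
                                    categories = 0:(3 * config$views_per_patient)))
  })

  visual_stats <- stage("visual_correlation", list(
    pf = spearman_ci(vis, pf[names(vis)]),
    aa = spearman_ci(vis, aa[names(vis)]),
    auc_pf = { d <- dichotomize(pf[names(vis)], -vis, "pf_ratio", config$pf_cutoff)
               roc_auc(d$scores, d$labels)$auc },
    auc_aa = { d <- dichotomize(aa[names(vis)], vis, "aa_gradient", config$aa_cutoff)
               roc_auc(d$scores, d$labels)$auc }
  ))
  # Visual score rises with severity while PaO2/FiO2 falls, hence the sign
  # flip feeding the pf ROC (higher score must predict the positive class).

  per_area <- lapply(config$roi_areas, function(area) {
    lab <- sprintf("%dK", round(area / 1000))
    inten <- stage(paste0("intensity_", lab), cohort_intensity(cohort, area))
    sc <- inten$scores
    corr <- stage(paste0("intensity_correlation_", lab), list(
      pf = spearman_ci(sc, pf[names(sc)]),
      aa = spearman_ci(sc, aa[names(sc)]),
      auc_pf = { d <- dichotomize(pf[names(sc)], -sc, "pf_ratio", config$pf_cutoff)
                 roc_auc(d$scores, d$labels)$auc },
      auc_aa = { d <- dichotomize(aa[names(sc)], sc, "aa_gradient", config$aa_cutoff)
                 roc_auc(d$scores, d$labels)$auc }
    ))
    feats <- stage(paste0("features_", lab),
                   cohort_features(cohort, area, config$glcm_levels, config$glcm_distance))
    model <- stage(paste0("model_", lab), {
      out <- list()
      if (!is.null(config$groups)) {
        out$groups_pf <- group_analysis(feats$features, feats$meta$patient_id,
                                        pf, "pf_ratio", config$groups,
                                        config$pf_cutoff)
        out$groups_aa <- group_analysis(feats$features, feats$meta$patient_id,
                                        aa, "aa_gradient", config$groups,
                                        config$aa_cutoff)
      }
      if (!is.null(config$pca_k)) {
        out$pca_pf <- pca_sweep(feats$features, feats$meta$patient_id, pf,
                                "pf_ratio", config$pca_k, config$pf_cutoff)
      }
      out
    })
    list(area = area, intensity = inten, correlations = corr,
         features = feats, model = model)
  })
  names(per_area) <- sprintf("%dK", round(config$roi_areas / 1000))

  result <- structure(list(
    config = config,
    n_patients = length(cohort), n_frames = sum(vapply(cohort, function(p)
      max(length(p$frames), length(p$frame_paths)), numeric(1))),
    indices = indices, visual = visual, visual_stats = visual_stats,
    kappa = kappa, per_area = per_area,
    log = list(seed = config$seed,
               conventions = lapply(per_area, function(a) a$features$conventions))
  ), class = "lus_run")

  if (!is.null(config$out_dir)) write_run(result, config$out_dir)
  result
}

#' @export
print.lus_run <- function(x, ...) {
  cat(sprintf("<lus_run> %d patients, %d frames, ROI areas: %s\n",
              x$n_patients, x$n_frames,
              paste(names(x$per_area), collapse = ", ")))
  cat(sprintf("  visual score vs PaO2/FiO2: rho = %.3f; vs A-a: rho = %.3f; kappa = %.3f\n",
              x$visual_stats$pf$rho, x$visual_stats$aa$rho, x$kappa$frame_level))
  for (a in names(x$per_area)) {
    co <- x$per_area[[a]]$correlations
    cat(sprintf("  %s intensity score vs PaO2/FiO2: rho = %.3f; vs A-a: rho = %.3f\n",
                a, co$pf$rho, co$aa$rho))
  }
  invisible(x)
}

#' Write a pipeline result bundle to disk
#'
#' Emits per-patient and per-frame CSVs, the per-group AUC tables, and a
#' plain-text run log recording the seed, the headline statistics and every
#' degenerate-case convention that fired.
#'
#' @param result an `lus_run` from [run_pipeline()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_run <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$indices, file.path(dir, "patients.csv"), row.names = FALSE)
  utils::write.csv(result$visual, file.path(dir, "visual_scores.csv"), row.names = FALSE)
  for (a in names(result$per_area)) {
    pa <- result$per_area[[a]]
    utils::write.csv(cbind(pa$features$meta, as.data.frame(pa$features$features)),
                     file.path(dir, sprintf("features_%s.csv", a)), row.names = FALSE)
    utils::write.csv(pa$intensity$frame_means,
                     file.path(dir, sprintf("frame_means_%s.csv", a)), row.names = FALSE)
    if (!is.null(pa$model$groups_pf))
      utils::write.csv(rbind(cbind(index = "pf_ratio", pa$model$groups_pf),
                             cbind(index = "aa_gradient", pa$model$groups_aa)),
                       file.path(dir, sprintf("group_auc_%s.csv", a)), row.names = FALSE)
  }
  summary_lines <- c(
    sprintf("seed: %d", result$config$seed),
    sprintf("n_patients: %d", result$n_patients),
    sprintf("n_frames: %d", result$n_frames),
    sprintf("kappa_frame_level: %.6f", result$kappa$frame_level),
    sprintf("visual_rho_pf: %.6f", result$visual_stats$pf$rho),
    sprintf("visual_rho_aa: %.6f", result$visual_stats$aa$rho),
    unlist(lapply(names(result$per_area), function(a) {
      co <- result$per_area[[a]]$correlations
      c(sprintf("intensity_rho_pf_%s: %.6f", a, co$pf$rho),
        sprintf("intensity_rho_aa_%s: %.6f", a, co$aa$rho))
    })),
    unlist(lapply(names(result$per_area), function(a) {
      cv <- result$log$conventions[[a]]
      if (length(cv)) sprintf("conventions_%s: %s", a,
                              paste(names(cv), cv, sep = "=", collapse = "; "))
      else sprintf("conventions_%s: none", a)
    }))
  )
  writeLines(summary_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}
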