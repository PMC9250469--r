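#' End-to-end pipeline configuration
#'
#' Bundles the simulation settings with every stage threshold, so one object
#' (serialisable to JSON) determines the whole analysis.
#'
#' @param sim a [simulation_config()].
#' @param drop_k,bp_low,bp_high,fd_threshold time-series cleaning settings.
#' @param screen_alpha FDR level of the edge screening.
#' @param psi_alpha PSI-relatedness correlation threshold.
#' @param n_perm,edge_alpha,component_percentile NBS settings.
#' @param gm_threshold GM-probability mask threshold for regional SUVR.
#' @param pet_p_thresh,pet_min_cluster voxelwise t-map thresholds.
#' @param pet_fwhm_mm PET smoothing FWHM (mm).
#' @param pet_grid voxel grid edge length for the simulated PET stage.
#' @param run_pet_voxelwise run the voxelwise PET stage on simulated volumes
#'   (the regional stage always runs on the cohort SUVR table).
#' @param seed pipeline seed (overrides `sim$seed` when given).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            drop_k = 10, bp_low = 0.01, bp_high = 0.08,
                            fd_threshold = 0.2,
                            screen_alpha = 0.05, psi_alpha = 0.05,
                            n_perm = 1000, edge_alpha = 0.05,
                            component_percentile = 95,
                            gm_threshold = 0.60,
                            pet_p_thresh = 0.05, pet_min_cluster = 100,
                            pet_fwhm_mm = 6, pet_grid = 24,
                            run_pet_voxelwise = TRUE,
                            seed = NULL) {
  stopifnot(inherits(sim, "sim_config"),
            screen_alpha > 0, screen_alpha < 1,
            edge_alpha > 0, edge_alpha < 1,
            component_percentile > 50, component_percentile < 100,
            gm_threshold >= 0, gm_threshold < 1, fd_threshold > 0)
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, drop_k = drop_k, bp_low = bp_low,
                 bp_high = bp_high, fd_threshold = fd_threshold,
                 screen_alpha = screen_alpha, psi_alpha = psi_alpha,
                 n_perm = n_perm, edge_alpha = edge_alpha,
                 component_percentile = component_percentile,
                 gm_threshold = gm_threshold, pet_p_thresh = pet_p_thresh,
                 pet_min_cluster = pet_min_cluster, pet_fwhm_mm = pet_fwhm_mm,
                 pet_grid = pet_grid, run_pet_voxelwise = run_pet_voxelwise),
            class = "pipeline_config")
}

test_row <- function(term, res, q = NA_real_) {
  data.frame(term = term, statistic = res$statistic, df = res$df,
             estimate = res$estimate, p = res$p_value, q = q,
             stringsAsFactors = FALSE)
}

#' Clinical group-comparison table
#'
#' Gender by uncorrected Pearson chi-square; age at scan and the five WISC-IV
#' indices by two-sample t-test.
#'
#' @param subjects cohort subjects data.frame.
#' @param variant t-test variant.
#' @return data.frame with term, group summaries, statistic and p.
#' @export
clinical_table <- function(subjects, variant = "pooled") {
  pat <- subjects[subjects$group == "patient", ]
  con <- subjects[subjects$group == "control", ]
  gtab <- matrix(c(sum(pat$gender == "F"), sum(pat$gender == "M"),
                   sum(con$gender == "F"), sum(con$gender == "M")),
                 2, 2, dimnames = list(c("F", "M"), c("patient", "control")))
  rows <- list(test_row("gender", chi_square_2x2(t(gtab))))
  fmt <- function(x) sprintf("%.2f ± %.2f", mean(x), stats::sd(x))
  vars <- c(age_at_scan = "age_at_scan", vci = "vci", pri = "pri",
            wmi = "wmi", psi = "psi", fsiq = "fsiq")
  for (v in names(vars))
    rows <- c(rows, list(test_row(v, t_test_two_sample(pat[[vars[v]]],
                                                       con[[vars[v]]],
                                                       variant = variant))))
  out <- do.call(rbind, rows)
  out$patient <- c(sprintf("%d F / %d M", gtab["F", 1], gtab["M", 1]),
                   vapply(vars, function(v) fmt(pat[[v]]), ""))
  out$control <- c(sprintf("%d F / %d M", gtab["F", 2], gtab["M", 2]),
                   vapply(vars, function(v) fmt(con[[v]]), ""))
  out[, c("term", "patient", "control", "statistic", "df", "p")]
}

#' Stepwise regression of clinical factors on the WISC-IV indices
#'
#' Patients only; candidates are gender (F = 1), age at scan, age at onset,
#' seizure duration, AED time, and AED category coded 0/1/2
#' (naive/mono/polytherapy).
#'
#' @param subjects cohort subjects data.frame.
#' @param outcomes index columns to model.
#' @return named list of [stepwise_regression()] models.
#' @export
clinical_stepwise <- function(subjects,
                              outcomes = c("vci", "pri", "wmi", "psi", "fsiq")) {
  pat <- subjects[subjects$group == "patient", ]
  cand <- data.frame(
    gender = as.numeric(pat$gender == "F"),
    age_at_scan = pat$age_at_scan,
    age_at_onset = pat$age_at_onset,
    seizure_duration = pat$seizure_duration,
    aed_time = pat$aed_time,
    aed_category = match(pat$aed_category,
                         c("naive", "monotherapy", "polytherapy")) - 1)
  stats::setNames(lapply(outcomes, function(y)
    stepwise_regression(pat[[y]], cand)), outcomes)
}

#' Run the full corticostriatal analysis pipeline on a simulated cohort
#'
#' Simulates the cohort, cleans every subject's ROI time series (dropping
#' subjects rejected by scrubbing), builds Fisher-z FC matrices, screens
#' edges, selects PSI-related edges, runs the NBS, compares regional SUVR
#' with FDR, optionally runs the voxelwise PET stage on simulated volumes,
#' and computes the PSI correlations. When `output_dir` is given, TSV tables,
#' a JSON statistics bundle and a run log are written there.
#'
#' @param config a [pipeline_config()].
#' @param output_dir optional output directory.
#' @return a `pipeline_report` list with all stage outputs.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  logln <- character(0)
  note <- function(...) logln <<- c(logln, sprintf(...))
  note("ectsnet %s | seed %d", as.character(utils::packageVersion("ectsnet")),
       config$sim$seed)

  cohort <- simulate_cohort(config$sim)
  note("simulated %d patients, %d controls, %d ROIs",
       config$sim$n_patients, config$sim$n_controls, config$sim$n_rois)

  clinical <- clinical_table(cohort$subjects)
  stepwise <- clinical_stepwise(cohort$subjects)

  # --- fMRI arm -------------------------------------------------------------
  fc <- list()
  for (id in names(cohort$timeseries)) {
    res <- tryCatch(
      fc_matrix(clean_timeseries(cohort$timeseries[[id]],
                                 drop_k = config$drop_k,
                                 low = config$bp_low, high = config$bp_high,
                                 fd_threshold = config$fd_threshold)),
      error = function(e) {
        if (grepl("subject rejected|retained frames", conditionMessage(e))) {
          note("excluded %s: %s", id, conditionMessage(e))
          NULL
        } else
          stop(sprintf("fmri stage, subject %s: %s", id,
                       conditionMessage(e)), call. = FALSE)
      })
    if (!is.null(res)) fc[[id]] <- res
  }
  if (length(fc) < 4) stop("too few subjects survive motion scrubbing")
  keep <- names(fc)
  subjects <- cohort$subjects[cohort$subjects$id %in% keep, ]
  groups <- subjects$group
  note("cleaned %d subjects; FD threshold %g mm", length(fc), config$fd_threshold)

  screened <- screen_edges(fc, groups, alpha = config$screen_alpha)
  psi_edges <- select_psi_edges(screened, fc, subjects$psi, groups,
                                alpha = config$psi_alpha)
  note("screened edges: %d of %d; PSI-related: %d",
       nrow(screened), config$sim$n_rois * (config$sim$n_rois - 1) / 2,
       nrow(psi_edges))

  nbs_res <- if (nrow(psi_edges) >= 1)
    nbs(fc, groups, edge_set = psi_edges, n_perm = config$n_perm,
        edge_alpha = config$edge_alpha,
        component_percentile = config$component_percentile,
        seed = config$sim$seed + 1L)
  else NULL
  main_comp <- if (!is.null(nbs_res) && length(nbs_res$components))
    nbs_res$components[[1]] else NULL
  subnet_cor <- if (!is.null(main_comp))
    subnetwork_psi_correlation(main_comp, fc, subjects$psi, groups) else NULL
  if (!is.null(nbs_res))
    note("NBS: %d suprathreshold edges, threshold %g, %d component(s)",
         nrow(nbs_res$suprathreshold), nbs_res$threshold,
         length(nbs_res$components))

  # --- PET arm --------------------------------------------------------------
  suvr_cmp <- compare_regional_suvr(cohort$suvr, cohort$subjects$group)
  sig_rois <- suvr_cmp$roi[suvr_cmp$significant]
  suvr_cor <- lapply(stats::setNames(sig_rois, sig_rois), function(roi)
    suvr_psi_correlation(cohort$suvr, cohort$subjects, roi))

  pet_vox <- NULL
  if (isTRUE(config$run_pet_voxelwise)) {
    vols <- lapply(seq_len(nrow(cohort$subjects)), function(i)
      simulate_pet_volume(config$sim, cohort$subjects[i, ],
                          grid_dim = config$pet_grid))
    ref <- vols[[1]]
    suvr_vols <- lapply(vols, function(v) {
      sm <- smooth_gaussian(v$pet, config$pet_fwhm_mm, v$voxel_mm)
      normalize_suvr(sm, v$ref_mask)
    })
    names(suvr_vols) <- cohort$subjects$id
    grp <- cohort$subjects$group
    cm <- voxelwise_group_tmap(suvr_vols[grp == "patient"],
                               suvr_vols[grp == "control"],
                               p_thresh = config$pet_p_thresh,
                               min_cluster = config$pet_min_cluster)
    sel <- select_rois_from_clusters(cm, ref$atlas,
                                     min_voxels_in_roi = config$pet_min_cluster)
    reg <- if (length(sel))
      regional_suvr(suvr_vols, ref$atlas, ref$gm_prob, rois = sel,
                    gm_threshold = config$gm_threshold,
                    roi_names = config$sim$roi_labels)
    else NULL
    pet_vox <- list(cluster_map = cm, selected_rois = sel, regional = reg,
                    comparison = if (!is.null(reg))
                      compare_regional_suvr(reg, grp) else NULL)
    note("PET voxelwise: %d cluster(s), %d ROI(s) selected",
         length(cm$clusters), length(sel))
  }

  report <- structure(list(
    config = config, subjects = cohort$subjects,
    fmri_subjects = subjects$id, clinical = clinical,
    stepwise = stepwise, screened = screened, psi_edges = psi_edges,
    nbs = nbs_res, main_component = main_comp,
    subnetwork_psi = subnet_cor,
    suvr_table = cohort$suvr, suvr_comparison = suvr_cmp,
    suvr_psi = suvr_cor, pet_voxelwise = pet_vox,
    log = logln), class = "pipeline_report")
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

report_json <- function(report) {
  comp_sum <- lapply(report$nbs$components %||% list(), function(cp)
    list(n_edges = cp$n_edges, n_nodes = cp$n_nodes, p = cp$p,
         significant = cp$significant))
  list(
    seed = report$config$sim$seed,
    thresholds = report$config[setdiff(names(report$config), "sim")],
    clinical = report$clinical[, c("term", "statistic", "df", "p")],
    stepwise = lapply(report$stepwise, function(m)
      list(selected = m$selected_predictors, r_squared = m$r_squared)),
    n_screened_edges = nrow(report$screened),
    n_psi_edges = nrow(report$psi_edges),
    nbs = if (!is.null(report$nbs)) list(
      threshold = report$nbs$threshold,
      components = comp_sum),
    subnetwork_psi = if (!is.null(report$subnetwork_psi)) list(
      r = report$subnetwork_psi$estimate, p = report$subnetwork_psi$p_value),
    suvr = report$suvr_comparison,
    suvr_psi = lapply(report$suvr_psi, function(x)
      list(r = x$estimate, p = x$p_value)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pipeline report to disk
#'
#' TSV analogues of the clinical, regional-SUVR and PSI-related-edge tables,
#' the NBS edge table, a machine-readable JSON of all statistics, and the run
#' log.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) {
    p <- file.path(dir, f)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    wt(render_tables(report)$clinical, "table_clinical.tsv"),
    wt(render_tables(report)$suvr, "table_suvr.tsv"))
  if (!is.null(report$nbs)) {
    paths <- c(paths, wt(render_tables(report)$edges, "table_psi_edges.tsv"),
               wt(report$nbs$edges, "nbs_edges.tsv"))
  }
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(report_json(report), jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  lp <- file.path(dir, "run_log.txt")
  writeLines(report$log, lp)
  invisible(c(paths, jp, lp))
}

round_p <- function(p) formatC(round(p, 2), format = "g")

#' Render the report's human-readable tables
#'
#' Produces the three table shapes of the study report: the clinical
#' comparison (group summaries, p to 2 decimals), the regional SUVR
#' comparison (means to 3 decimals, raw and FDR-corrected p, significance
#' stars after FDR), and the PSI-related FC comparison (per-group mean FC to
#' 3 decimals with the NBS edge p).
#'
#' @param report a `pipeline_report`.
#' @return list of data.frames: `clinical`, `suvr`, `edges` (NULL without an
#'   NBS result).
#' @export
render_tables <- function(report) {
  cl <- report$clinical
  clinical <- data.frame(term = cl$term, patient = cl$patient,
                         control = cl$control, p = round_p(cl$p))
  sc <- report$suvr_comparison
  suvr <- data.frame(
    roi = sc$roi,
    patient = sprintf("%.3f", sc$mean_patient),
    control = sprintf("%.3f", sc$mean_control),
    p_uncorrected = sprintf("%.3f", sc$p),
    p_fdr = paste0(sprintf("%.3f", sc$q), ifelse(sc$significant, "*", "")))
  edges <- NULL
  if (!is.null(report$nbs) && !is.null(report$main_component)) {
    e <- report$main_component$edges
    edges <- data.frame(
      region_1 = e$label_a, region_2 = e$label_b,
      patient = sprintf("%.3f", e$mean_patient),
      control = sprintf("%.3f", e$mean_control),
      p = sprintf("%.3f", e$p))
  }
  list(clinical = clinical, suvr = suvr, edges = edges)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("ectsnet pipeline report\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}
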