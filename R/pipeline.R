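# End-to-end orchestration: per-subject metric extraction, the cohort-level
# design table, every statistical stage, and the report bundle.

#' Compute all network metrics for one subject
#'
#' Applies the modality transforms, builds both spanning-tree layers and
#' the two-layer multiplex, and returns one row with frontoparietal and
#' dorsal-attention centrality summaries plus mean eccentricities for the
#' structural layer, the functional layer and the multiplex (averaged over
#' all 2N supra-nodes).
#'
#' @param structural Raw structural [connectivity_matrix].
#' @param functional Raw functional [connectivity_matrix] (correlations) or
#'   a regions x time panel.
#' @param parc A [parcellation].
#' @return One-row data.frame of per-subject metrics.
#' @export
run_subject <- function(structural, functional, parc) {
  st <- preprocess_structural(structural)
  fn <- preprocess_functional(functional)
  mst_s <- maximum_spanning_tree(st)
  mst_f <- maximum_spanning_tree(fn)
  mplex <- build_multiplex(list(mst_s, mst_f))
  ec_s <- eigenvector_centrality(mst_s$adjacency)
  ec_f <- eigenvector_centrality(mst_f$adjacency)
  ec_m <- multilayer_nodal_ec(mplex)
  ecc_s <- eccentricity(mst_s)
  ecc_f <- eccentricity(mst_f)
  ecc_m <- eccentricity(mplex)
  data.frame(
    subject_id = st$subject_id,
    ec_fpn_structural = as.numeric(subnetwork_mean(ec_s, parc,
                                                   "frontoparietal")),
    ec_fpn_functional = as.numeric(subnetwork_mean(ec_f, parc,
                                                   "frontoparietal")),
    ec_fpn_multiplex = as.numeric(subnetwork_mean(ec_m, parc,
                                                  "frontoparietal")),
    ec_dan_structural = as.numeric(subnetwork_mean(ec_s, parc,
                                                   "dorsal_attention")),
    ec_dan_functional = as.numeric(subnetwork_mean(ec_f, parc,
                                                   "dorsal_attention")),
    ec_dan_multiplex = as.numeric(subnetwork_mean(ec_m, parc,
                                                  "dorsal_attention")),
    ecc_mean_structural = ecc_s$mean,
    ecc_mean_functional = ecc_f$mean,
    ecc_mean_multiplex = ecc_m$mean,
    stringsAsFactors = FALSE
  )
}

#' Per-subject metrics for a whole cohort
#'
#' Runs [run_subject] over paired matrix lists; per-subject failures are
#' caught, logged and summarized rather than aborting the run.
#'
#' @param structural,functional Lists of raw [connectivity_matrix] in the
#'   same subject order.
#' @param parc A [parcellation].
#' @return data.frame of metric rows (one per successful subject) with
#'   attribute `"failures"`: data.frame subject_id / error for the rest.
#' @export
run_cohort_metrics <- function(structural, functional, parc) {
  stopifnot(length(structural) == length(functional))
  rows <- vector("list", length(structural))
  fails <- list()
  for (i in seq_along(structural)) {
    id <- structural[[i]]$subject_id
    rows[[i]] <- tryCatch(
      run_subject(structural[[i]], functional[[i]], parc),
      error = function(e) {
        fails[[length(fails) + 1L]] <<-
          data.frame(subject_id = id, error = conditionMessage(e))
        message(sprintf("[mplexnet] subject %s failed: %s", id,
                        conditionMessage(e)))
        NULL
      })
  }
  out <- do.call(rbind, rows)
  attr(out, "failures") <- if (length(fails) > 0) do.call(rbind, fails)
    else data.frame(subject_id = character(0), error = character(0))
  out
}

#' Assemble the regression design table
#'
#' Joins the cohort manifest to the per-subject metric table.
#'
#' @param manifest A [cohort_manifest].
#' @param metrics Output of [run_cohort_metrics].
#' @return data.frame (one row per subject present in both inputs).
#' @export
assemble_design_table <- function(manifest, metrics) {
  merge(as.data.frame(manifest), metrics, by = "subject_id", sort = FALSE)
}

#' Default block structures for the regression stages
#'
#' Block 1: covariates (age, gender); block 2: the two single-layer
#' metrics; block 3: the multiplex metric. With `fd_covariate = TRUE`,
#' mean framewise displacement joins block 1.
#'
#' @param metric `"ec_fpn"`, `"ec_dan"`, or `"ecc_mean"`.
#' @param fd_covariate Add `mean_fd` to block 1?
#' @return List of character vectors (one per block).
#' @export
default_blocks <- function(metric = c("ec_fpn", "ec_dan", "ecc_mean"),
                           fd_covariate = FALSE) {
  metric <- match.arg(metric)
  block1 <- c("age", "gender")
  if (fd_covariate) block1 <- c(block1, "mean_fd")
  list(block1,
       paste0(metric, c("_structural", "_functional")),
       paste0(metric, "_multiplex"))
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, computes per-subject network metrics,
#' and runs every statistical stage: the three-block frontoparietal
#' centrality regression, the eccentricity and dorsal-attention variants,
#' the quadratic age model for multiplex ECfpn, leave-site-out
#' cross-validation with Levene's test for the ECfpn and eccentricity
#' models, and the impairment-rate summary. Optionally applies a
#' motion-exclusion threshold and/or adds mean FD as a covariate first.
#'
#' @param config A `pipeline_config` (see [pipeline_config]).
#' @return A `pipeline_report` list; if `config$out_dir` is set the report
#'   files (TSV/JSON) are written there as a side effect.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  parc <- if (is.character(config$parcellation)) {
    read_parcellation(config$parcellation)
  } else {
    config$parcellation
  }

  if (config$mode == "simulate") {
    cohort <- generate_cohort(config$cohort_config, parc)
    manifest <- cohort$manifest
    structural <- cohort$structural
    functional <- cohort$functional
  } else {
    cohort <- read_cohort(config$cohort_dir)
    manifest <- cohort$manifest
    structural <- cohort$structural
    functional <- cohort$functional
  }

  if (!is.null(config$fd_exclusion_mm)) {
    thr <- config$fd_exclusion_mm
    keep_ids <- manifest$subject_id[is.na(manifest$mean_fd) |
                                      manifest$mean_fd <= thr]
    sel <- manifest$subject_id %in% keep_ids
    manifest <- filter_subjects(manifest,
                                function(m) m$subject_id %in% keep_ids)
    structural <- structural[sel]
    functional <- functional[sel]
  }

  metrics <- run_cohort_metrics(structural, functional, parc)
  design <- assemble_design_table(manifest, metrics)

  fdcov <- isTRUE(config$fd_covariate)
  blocks_fpn <- default_blocks("ec_fpn", fdcov)
  blocks_dan <- default_blocks("ec_dan", fdcov)
  blocks_ecc <- default_blocks("ecc_mean", fdcov)

  report <- list(
    n_subjects = nrow(design),
    failures = attr(metrics, "failures"),
    regression_fpn = hierarchical_regression(design, blocks_fpn, "sdmt_z"),
    regression_dan = hierarchical_regression(design, blocks_dan, "sdmt_z"),
    regression_ecc = hierarchical_regression(design, blocks_ecc, "sdmt_z"),
    collinearity_fpn = collinearity_diagnostics(design, unlist(blocks_fpn)),
    quadratic_age = quadratic_age_model(design$ec_fpn_multiplex,
                                        design$age),
    cv_fpn = leave_site_out_cv(design, blocks_fpn, "sdmt_z"),
    cv_ecc = leave_site_out_cv(design, blocks_ecc, "sdmt_z"),
    impairment = impairment_rate(design$sdmt_z,
                                 threshold = config$impairment_threshold),
    design = design,
    config = config
  )
  class(report) <- "pipeline_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Configuration for [run_full_pipeline]
#'
#' @param mode `"simulate"` or `"load"`.
#' @param parcellation A [parcellation] object or a path to a parcellation
#'   TSV.
#' @param cohort_config A [cohort_config] (simulate mode).
#' @param cohort_dir Cohort directory written by [write_cohort] (load mode).
#' @param out_dir Optional output directory for the report bundle.
#' @param fd_covariate Add mean FD to the covariate block?
#' @param fd_exclusion_mm Optional motion-exclusion threshold in mm.
#' @param impairment_threshold Impairment cutoff on the cognition z-score.
#' @param seed Seed forwarded to the cohort config in simulate mode.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("simulate", "load"),
                            parcellation,
                            cohort_config = NULL,
                            cohort_dir = NULL,
                            out_dir = NULL,
                            fd_covariate = FALSE,
                            fd_exclusion_mm = NULL,
                            impairment_threshold = -1.5,
                            seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "simulate") {
    if (is.null(cohort_config)) {
      stop("simulate mode needs `cohort_config`", call. = FALSE)
    }
    if (!is.null(seed)) cohort_config$seed <- as.integer(seed)
  } else if (is.null(cohort_dir)) {
    stop("load mode needs `cohort_dir`", call. = FALSE)
  }
  structure(
    list(mode = mode, parcellation = parcellation,
         cohort_config = cohort_config, cohort_dir = cohort_dir,
         out_dir = out_dir, fd_covariate = fd_covariate,
         fd_exclusion_mm = fd_exclusion_mm,
         impairment_threshold = impairment_threshold),
    class = "pipeline_config"
  )
}

# internal: regression result -> long TSV rows mirroring the usual
# hierarchical-regression table (per-model coefficient rows + footer rows)
regression_report_df <- function(res) {
  coefs <- res$model_coefficients
  coefs$row_type <- "coefficient"
  foot <- res$blocks
  foot_long <- do.call(rbind, lapply(seq_len(nrow(foot)), function(k) {
    data.frame(model = k,
               term = c("R2", "F", "delta_R2", "delta_F"),
               b_raw = c(foot$r2[k], foot$f_stat[k], foot$delta_r2[k],
                         foot$delta_f[k]),
               b_std = NA_real_,
               p_value = c(foot$f_p[k], foot$f_p[k], foot$delta_f_p[k],
                           foot$delta_f_p[k]),
               row_type = "summary")
  }))
  rbind(coefs, foot_long)
}

#' Write a pipeline report bundle to disk
#'
#' TSV tables (design table, regression reports, CV folds) plus a
#' full-precision JSON of every statistic.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(report$design, "design_table.tsv")
  wt(regression_report_df(report$regression_fpn), "regression_fpn.tsv")
  wt(regression_report_df(report$regression_dan), "regression_dan.tsv")
  wt(regression_report_df(report$regression_ecc), "regression_ecc.tsv")
  wt(report$cv_fpn$folds, "cv_fpn_folds.tsv")
  wt(report$cv_ecc$folds, "cv_ecc_folds.tsv")
  if (nrow(report$failures) > 0) wt(report$failures, "failures.tsv")

  strip <- function(r) r[setdiff(names(r), "fit")]
  json <- list(
    n_subjects = report$n_subjects,
    impairment = report$impairment,
    regression_fpn = strip(unclass(report$regression_fpn)),
    regression_dan = strip(unclass(report$regression_dan)),
    regression_ecc = strip(unclass(report$regression_ecc)),
    quadratic_age = strip(unclass(report$quadratic_age)),
    collinearity_fpn = report$collinearity_fpn,
    cv_fpn = unclass(report$cv_fpn)[c("folds", "mean_r2", "sd_r2",
                                      "levene")],
    cv_ecc = unclass(report$cv_ecc)[c("folds", "mean_r2", "sd_r2",
                                      "levene")],
    seed = if (!is.null(report$config$cohort_config))
      report$config$cohort_config$seed else NULL
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report: %d subjects (%d failures)\n",
              x$n_subjects, nrow(x$failures)))
  cat(sprintf("Impairment (z < %.2f): %d (%.1f%%)\n",
              x$config$impairment_threshold, x$impairment$count,
              100 * x$impairment$proportion))
  cat("\n-- Frontoparietal centrality model --\n")
  print(x$regression_fpn)
  cat("\n-- Leave-site-out CV (frontoparietal model) --\n")
  print(x$cv_fpn)
  invisible(x)
}
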