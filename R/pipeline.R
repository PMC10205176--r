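#' End-to-end pipeline configuration
#'
#' Bundles the cohort sizes, phantom parameters and every stage's tunables
#' into one reproducible configuration object. All randomness downstream
#' derives from `seed`.
#'
#' @param n_ad,n_hc cohort sizes (defaults 19 and 21).
#' @param phantom a [phantom_config()].
#' @param seed master integer seed.
#' @param t_star Logan linearization start (minutes, default 20).
#' @param ref_fraction reference-region fraction for
#'   [extract_reference_tac()] (default 0.1).
#' @param window_min texture summation window (minutes, default `c(40, 60)`).
#' @param n_gray_levels GLCM gray levels (default 64).
#' @param svm_cost linear-SVM cost (default 1).
#' @param cor_threshold correlation-filter threshold (default 0.9).
#' @param sample_feature_ratio samples-per-feature ratio (default 10).
#' @param alpha significance level (default 0.05).
#' @param write_images also write per-subject NIfTI volumes (default FALSE;
#'   feature tables, reports and metrics are always written).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_ad = 19, n_hc = 21, phantom = phantom_config(),
                            seed = 1L, t_star = 20, ref_fraction = 0.1,
                            window_min = c(40, 60), n_gray_levels = 64,
                            svm_cost = 1, cor_threshold = 0.9,
                            sample_feature_ratio = 10, alpha = 0.05,
                            write_images = FALSE) {
  stopifnot(n_ad >= 1, n_hc >= 1, inherits(phantom, "phantom_config"),
            t_star > 0, ref_fraction > 0, ref_fraction <= 1,
            n_gray_levels >= 2, svm_cost > 0, cor_threshold > 0,
            sample_feature_ratio > 0, alpha > 0, alpha < 1)
  structure(list(n_ad = as.integer(n_ad), n_hc = as.integer(n_hc),
                 phantom = phantom, seed = as.integer(seed), t_star = t_star,
                 ref_fraction = ref_fraction, window_min = window_min,
                 n_gray_levels = n_gray_levels, svm_cost = svm_cost,
                 cor_threshold = cor_threshold,
                 sample_feature_ratio = sample_feature_ratio, alpha = alpha,
                 write_images = write_images),
            class = "pipeline_config")
}

# Stable hash of a configuration: md5 of its deterministic JSON rendering.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass_recursive(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else unclass(x)
}

#' Run the full simulate-quantify-classify pipeline
#'
#' Generates a synthetic cohort, quantifies every subject along both
#' branches (supervised-cluster reference + voxelwise Logan DVR reduced to
#' ROI means; late-window summation + pooled 3D GLCM Haralick features),
#' writes per-family feature tables and group-statistics reports, runs the
#' paired classifier comparison and writes its predictions and metrics.
#' Re-running with the same config reproduces every numeric output
#' bit-for-bit.
#'
#' Output files (all under `out_dir`, each carrying the config hash):
#' `manifest.tsv`, `features_kinetic.tsv`, `features_texture.tsv`,
#' `group_stats_kinetic.tsv`, `group_stats_texture.tsv`, `selection.json`,
#' `predictions.tsv`, `metrics.json`, `config.json`, `run.log` (and, with
#' `write_images = TRUE`, per-subject NIfTI volumes plus DVR maps under
#' `images/`).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with `kinetic_table`, `texture_table`,
#'   `stats` (per family), `comparison` (a [compare_classifiers()] result),
#'   `out_dir` and `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  comments <- c(config_hash = hash, seed = as.character(config$seed))
  log_lines <- c(sprintf("pettex %s | R %s.%s",
                         as.character(utils::packageVersion("pettex")),
                         R.version$major, R.version$minor),
                 sprintf("seed: %d | config_hash: %s", config$seed, hash))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    log_lines <<- c(log_lines, sprintf("stage %-10s %7.2f s", name,
                                       proc.time()[["elapsed"]] - t0))
    res
  }

  cohort <- stage("simulate", generate_cohort(config$n_ad, config$n_hc,
                                              config$phantom, config$seed))
  manifest <- data.frame(subject_id = vapply(cohort, `[[`, "", "subject_id"),
                         group = vapply(cohort, `[[`, "", "label"))
  if (config$write_images) {
    img_dir <- file.path(out_dir, "images")
    for (s in cohort) write_subject_nifti(s, img_dir)
    manifest$dynamic <- file.path("images", paste0(manifest$subject_id,
                                                   "_dynamic.nii.gz"))
    manifest$mask <- file.path("images", paste0(manifest$subject_id,
                                                "_mask.nii.gz"))
    manifest$atlas <- file.path("images", paste0(manifest$subject_id,
                                                 "_atlas.nii.gz"))
  }
  write_tsv <- function(df, file) {
    path <- file.path(out_dir, file)
    con <- file(path, "w")
    writeLines(sprintf("# %s: %s", names(comments), comments), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    path
  }
  write_tsv(manifest, "manifest.tsv")

  basis <- make_kinetic_basis(config$phantom$schedule,
                              amplitude = config$phantom$amplitude)
  roi_map <- stats::setNames(seq_along(phantom_roi_names()),
                             phantom_roi_names())

  kin_rows <- list(); tex_rows <- list()
  t_kin <- 0; t_tex <- 0
  for (s in cohort) {
    t0 <- proc.time()[["elapsed"]]
    ref <- extract_reference_tac(s$dynamic_image, s$brain_mask, basis,
                                 fraction = config$ref_fraction)
    dvr <- logan_dvr_image(s$dynamic_image, s$brain_mask, ref$reference_tac,
                           t_star = config$t_star)
    rm <- roi_means(dvr, s$atlas, roi_map)
    kin_rows[[s$subject_id]] <- c(list(subject_id = s$subject_id,
                                       group = s$label),
                                  as.list(stats::setNames(rm$mean, rm$roi)))
    if (config$write_images) {
      img <- RNifti::asNifti(dvr$data)
      RNifti::writeNifti(img, file.path(out_dir, "images",
                                        paste0(s$subject_id, "_dvr.nii.gz")))
    }
    t_kin <- t_kin + proc.time()[["elapsed"]] - t0
    t0 <- proc.time()[["elapsed"]]
    hf <- texture_pipeline(s$dynamic_image, s$brain_mask,
                           window_min = config$window_min,
                           Ng = config$n_gray_levels)
    tex_rows[[s$subject_id]] <- c(list(subject_id = s$subject_id,
                                       group = s$label), as.list(unclass(hf)))
    t_tex <- t_tex + proc.time()[["elapsed"]] - t0
  }
  log_lines <- c(log_lines, sprintf("stage %-10s %7.2f s", "kinetics", t_kin),
                 sprintf("stage %-10s %7.2f s", "texture", t_tex))
  kinetic_table <- feature_table(do.call(rbind.data.frame, kin_rows))
  texture_table <- feature_table(do.call(rbind.data.frame, tex_rows))
  rownames(kinetic_table) <- rownames(texture_table) <- NULL
  write_tsv(kinetic_table, "features_kinetic.tsv")
  write_tsv(texture_table, "features_texture.tsv")

  stats_out <- stage("stats", list(
    kinetic = feature_report(kinetic_table, alpha = config$alpha),
    texture = feature_report(texture_table, alpha = config$alpha)))
  write_tsv(stats_out$kinetic, "group_stats_kinetic.tsv")
  write_tsv(stats_out$texture, "group_stats_texture.tsv")

  comparison <- stage("classify", compare_classifiers(
    kinetic_table, texture_table, ratio = config$sample_feature_ratio,
    threshold = config$cor_threshold, cost = config$svm_cost,
    alpha = config$alpha))
  write_tsv(comparison$predictions, "predictions.tsv")

  sel_json <- lapply(comparison$selection, function(s) {
    list(retained_after_correlation = s$retained_after_correlation,
         ranking = s$ranking, selected = s$selected, k = s$k)
  })
  jsonlite::write_json(c(list(config_hash = hash), sel_json),
                       file.path(out_dir, "selection.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  metrics <- list(
    config_hash = hash, seed = config$seed,
    kinetic = as.list(comparison$metrics$kinetic),
    texture = as.list(comparison$metrics$texture),
    cochran_q = list(Q = comparison$cochran$Q, df = comparison$cochran$df,
                     p_value = comparison$cochran$p_value,
                     reject_at_alpha_0_05 = comparison$cochran$reject_at_alpha))
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(c(list(config_hash = hash),
                         unclass_recursive(config)),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(kinetic_table = kinetic_table, texture_table = texture_table,
                 stats = stats_out, comparison = comparison,
                 out_dir = out_dir, config_hash = hash))
}
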